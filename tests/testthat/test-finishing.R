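test_that("contigs scaffold back into truth order and orientation", {
  p <- small_plastome(21)
  cs <- fragment_plastome(p, "at_IR_boundaries")
  sc <- scaffold_contigs(cs, p)
  expect_equal(sc$placements$id, cs$contigs$id)  # truth order
  expect_equal(sc$placements$ref_start, cs$contigs$truth_start)
  expect_true(all(sc$gaps$est_len == 0L))

  # single contig equal to the reference: one placement, no gap
  sc1 <- scaffold_contigs(tibble::tibble(id = "c", sequence = p$sequence), p)
  expect_equal(nrow(sc1$placements), 1L)
  expect_true(all(sc1$gaps$est_len == 0L))

  # reverse-complemented single-copy contig is placed on the minus strand
  ctg <- cs$contigs
  ctg$sequence[1] <- revcomp(ctg$sequence[1])
  sc2 <- scaffold_contigs(ctg, p)
  expect_equal(sc2$placements$orientation[sc2$placements$id == "contig01"], "-")

  # unrelated contigs cannot be scaffolded
  expect_error(
    scaffold_contigs(tibble::tibble(id = "x", sequence = random_dna(5000)), p),
    "unscaffoldable")
})

test_that("close_gaps recovers the truth circle from fragments and reads", {
  p <- small_plastome(22)
  rs <- simulate_reads(p, coverage = 25, read_len = 100, seed = 23)
  sc <- scaffold_contigs(fragment_plastome(p, "at_IR_boundaries"), p)
  fin <- close_gaps(sc, reads = rs, min_overlap = 20)
  expect_s3_class(fin, "plastome")
  expect_true(same_circle(fin$sequence, p$sequence))
  expect_true(all(grepl("closed", attr(fin, "gap_report")$status)))
})

test_that("close_gaps honours the paired-end mate check", {
  p <- small_plastome(24)
  rp <- simulate_reads(p, coverage = 25, read_len = 100, pairing = "paired",
                       seed = 25)
  sc <- scaffold_contigs(fragment_plastome(p, "at_IR_boundaries"), p)
  fin <- close_gaps(sc, reads = rp, min_overlap = 20)
  expect_s3_class(fin, "plastome")
  expect_true(same_circle(fin$sequence, p$sequence))
})

test_that("overlap acceptance obeys the length and zero-mismatch rules", {
  # synthetic junction: flank plus evidence reads engineered around the rules
  left <- random_dna(500)
  right <- random_dna(500)
  sc <- structure(list(
    placements = tibble::tibble(id = c("A", "B"),
                                sequence = c(left, right),
                                ref_start = c(1L, 501L),
                                ref_end = c(500L, 1000L),
                                orientation = "+"),
    gaps = tibble::tibble(left_id = c("A", "B"), right_id = c("B", "A"),
                          est_len = 0L),
    unplaced = character(0), reference_len = 1000L), class = "scaffold")

  bridge <- function(o_left, o_right, mismatch_at = NA) {
    ev <- paste0(substr(left, 501 - o_left, 500), substr(right, 1, o_right))
    if (!is.na(mismatch_at)) {
      b <- substr(ev, mismatch_at, mismatch_at)
      substr(ev, mismatch_at, mismatch_at) <- setdiff(c("A", "C", "G", "T"), b)[1]
    }
    ev
  }
  as_reads <- function(seqs) {
    structure(list(reads = tibble::tibble(
      id = sprintf("e%02d", seq_along(seqs)), mate = NA_integer_,
      sequence = seqs, quality = strrep("I", nchar(seqs)),
      start = NA_integer_, end = NA_integer_, strand = "+"),
      pairing = "single", read_len = max(nchar(seqs)),
      insert_size = NA_integer_, insert_sd = NA_integer_,
      genome_len = 1000L), class = "read_set")
  }

  # a 19 bp overlap with the left flank is below threshold: junction open
  res19 <- close_gaps(sc, reads = as_reads(bridge(19, 60)), min_overlap = 20)
  expect_s3_class(res19, "open_scaffold")
  # 25 bp overlap with one mismatch in it: rejected (zero-mismatch rule)
  res_mm <- close_gaps(sc, reads = as_reads(bridge(25, 60, mismatch_at = 5)),
                       min_overlap = 20)
  expect_s3_class(res_mm, "open_scaffold")
  # the same evidence without the mismatch closes the A|B junction
  res_ok <- close_gaps(sc, reads = as_reads(bridge(25, 60)), min_overlap = 20)
  rep_ok <- attr(res_ok, "gap_report")
  expect_true(any(grepl("^A\\|B:closed", rep_ok$status)))
})

test_that("raising min_overlap never closes more junctions", {
  p <- small_plastome(26)
  rs <- simulate_reads(p, coverage = 6, read_len = 100, seed = 27)
  sc <- scaffold_contigs(fragment_plastome(p, "at_IR_boundaries"), p)
  n_closed <- function(min_overlap) {
    fin <- close_gaps(sc, reads = rs, min_overlap = min_overlap)
    sum(grepl(":closed", attr(fin, "gap_report")$status))
  }
  closed <- vapply(c(20L, 40L, 70L, 95L), n_closed, numeric(1))
  expect_true(all(diff(closed) <= 0))
})

test_that("assess_assembly maps reads, measures depth, finds inconsistencies", {
  p <- small_plastome(28)
  rs <- simulate_reads(p, coverage = 30, read_len = 100, seed = 29)
  rep0 <- assess_assembly(p, rs)
  expect_equal(nrow(rep0$inconsistencies), 0L)
  expect_equal(rep0$n_mapped, nrow(rs$reads))
  # mean depth equals total mapped bases / genome length, within 5% of target
  expect_equal(rep0$mean_depth,
               rep0$n_mapped * 100 / nchar(p$sequence))
  expect_lt(abs(rep0$mean_depth - 30) / 30, 0.05)

  # plant-and-recover: one corrupted base yields exactly one inconsistency
  s2 <- p$sequence
  substr(s2, 777, 777) <- setdiff(c("A", "C", "G", "T"),
                                  substr(s2, 777, 777))[1]
  rep1 <- assess_assembly(s2, rs)
  expect_equal(rep1$inconsistencies$position, 777L)
  expect_equal(rep1$inconsistencies$read_majority_base,
               substr(p$sequence, 777, 777))
})

test_that("junction bases of a closed assembly are re-verifiable", {
  # gap-closure soundness: every junction is spanned by an end-anchored,
  # zero-mismatch overlap of at least min_overlap in the evidence
  p <- small_plastome(30)
  rs <- simulate_reads(p, coverage = 25, read_len = 100, seed = 31)
  cs <- fragment_plastome(p, "at_IR_boundaries")
  fin <- close_gaps(scaffold_contigs(cs, p), reads = rs, min_overlap = 20)
  expect_s3_class(fin, "plastome")
  expect_true(same_circle(fin$sequence, p$sequence))
  # every junction's 40 bp centre (20 bp each side) is contained in at
  # least one evidence read, in one orientation or the other
  for (j in cs$contigs$truth_start) {
    centre <- plastomics:::circ_substr(p$sequence, j - 20L, 40L)
    hit <- any(grepl(centre, rs$reads$sequence, fixed = TRUE)) ||
      any(grepl(revcomp(centre), rs$reads$sequence, fixed = TRUE))
    expect_true(hit)
  }
})
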