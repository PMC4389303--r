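test_that("generated plastomes satisfy the quadripartite invariants", {
  spec <- small_spec(seed = 42)
  p <- generate_plastome(spec)

  expect_equal(nchar(p$sequence),
               spec$lsc_len + spec$ssc_len + 2L * spec$ir_len)
  # regions tile the circle without overlap or gap
  r <- p$regions[match(c("LSC", "IRb", "SSC", "IRa"), p$regions$region), ]
  expect_equal(r$start, c(1L, cumsum(r$end - r$start + 1L)[-4] + 1L))
  expect_equal(r$end[4], nchar(p$sequence))
  # IR mirror property
  irb <- substr(p$sequence, r$start[2], r$end[2])
  ira <- substr(p$sequence, r$start[4], r$end[4])
  expect_identical(revcomp(ira), irb)
  # base composition within 1% of the requested AT fraction
  expect_lt(abs(at_fraction_of(p$sequence) - spec$at_fraction), 0.01)
  # features non-overlapping with at least 1 bp spacers
  f <- p$features[order(p$features$start), ]
  expect_true(all(f$start[-1] > f$end[-nrow(f)] + 1L - 1L))
  expect_true(all(f$end <= nchar(p$sequence)))
})

test_that("generation is deterministic and degenerate compositions work", {
  expect_identical(generate_plastome(small_spec(7))$sequence,
                   generate_plastome(small_spec(7))$sequence)
  # different seeds give different genomes
  expect_false(identical(generate_plastome(small_spec(7))$sequence,
                         generate_plastome(small_spec(8))$sequence))
  pure_at <- generate_plastome(small_spec(3, at_fraction = 1.0))
  expect_true(all(chars(pure_at$sequence) %in% c("A", "T")))
})

test_that("an infeasible gene complement raises an explicit error", {
  expect_error(generate_plastome(plastome_spec(lsc_len = 5000, ssc_len = 1300,
                                               ir_len = 1400, n_genes = 88)),
               "infeasible")
  expect_error(plastome_spec(lsc_len = 1000, ssc_len = 500, ir_len = 2000),
               "ir_len")
})

test_that("plant_variants applies exactly the requested edits", {
  p <- small_plastome(1)
  # empty spec list: identity
  id <- plant_variants(p, list())
  expect_identical(id$plastome$sequence, p$sequence)
  expect_equal(nrow(id$truth), 0L)

  pv <- plant_variants(p, variant_spec("insertion", "rps16-trnQ", 500), seed = 2)
  expect_equal(nchar(pv$plastome$sequence), nchar(p$sequence) + 500L)
  tr <- pv$truth
  expect_equal(tr$length, 500L)
  # the recorded post-edit interval carries the planted payload, and
  # removing it restores the original genome
  s <- pv$plastome$sequence
  restored <- paste0(substr(s, 1, tr$start - 1), substr(s, tr$end + 1, nchar(s)))
  expect_identical(restored, p$sequence)

  # deletion: the removed bases come back from the ancestor
  pd <- plant_variants(p, variant_spec("deletion", "trnD-psbM", 200), seed = 3)
  expect_equal(nchar(pd$plastome$sequence), nchar(p$sequence) - 200L)

  # inversion involution
  pi <- plant_variants(p, variant_spec("inversion", "trnD-psbM", 150), seed = 4)
  ti <- pi$truth
  si <- pi$plastome$sequence
  undone <- paste0(substr(si, 1, ti$start - 1),
                   revcomp(substr(si, ti$start, ti$end)),
                   substr(si, ti$end + 1, nchar(si)))
  expect_identical(undone, p$sequence)
})

test_that("IR-resident insertions are mirrored into both repeat copies", {
  p <- small_plastome(5)
  pm <- plant_variants(p, variant_spec("insertion", "rpl23-ndhB", 300), seed = 6)
  expect_equal(nchar(pm$plastome$sequence), nchar(p$sequence) + 600L)
  expect_equal(nrow(pm$truth), 2L)
  expect_setequal(pm$truth$mirrored, c(TRUE, FALSE))
  q <- pm$plastome
  irb <- region_interval(q, "IRb"); ira <- region_interval(q, "IRa")
  expect_identical(revcomp(substr(q$sequence, ira["start"], ira["end"])),
                   substr(q$sequence, irb["start"], irb["end"]))
  # without mirroring the length grows by exactly the payload
  p1 <- plant_variants(p, variant_spec("insertion", "rpl23-ndhB", 300),
                       seed = 6, mirror_ir = FALSE)
  expect_equal(nchar(p1$plastome$sequence), nchar(p$sequence) + 300L)
})

test_that("plant_variants rejects bad loci and overlapping edits", {
  p <- small_plastome(2)
  expect_error(plant_variants(p, variant_spec("insertion", "foo-bar", 100)),
               "locus not found")
  expect_error(
    plant_variants(p, list(variant_spec("deletion", 5000, 500),
                           variant_spec("inversion", 5100, 400))),
    "overlapping")
})

test_that("planted foreign inserts show the expected AT contrast", {
  p <- generate_plastome(small_spec(9))
  pv <- plant_variants(p, variant_spec("insertion", "rps16-trnQ", 2500,
                                       payload_at_fraction = 0.55), seed = 10)
  tr <- pv$truth
  ins_at <- at_fraction_of(substr(pv$plastome$sequence, tr$start, tr$end))
  expect_gte(0.61 - ins_at, 0.04)
})

test_that("simulated reads have the requested count, length and origin", {
  p <- small_plastome(3)
  L <- nchar(p$sequence)
  rs <- simulate_reads(p, coverage = 10, read_len = 100, seed = 4)
  expect_lte(abs(nrow(rs$reads) - 10 * L / 100), 1)
  expect_true(all(nchar(rs$reads$sequence) == 100L))
  # error-free reads are exact substrings of the doubled circle
  doubled <- paste0(p$sequence, p$sequence)
  idx <- seq_len(200)
  ok <- vapply(idx, function(i) {
    r <- rs$reads[i, ]
    sq <- if (r$strand == "+") r$sequence else revcomp(r$sequence)
    identical(substr(doubled, r$start, r$start + 99L), sq)
  }, logical(1))
  expect_true(all(ok))
  expect_error(simulate_reads(p, coverage = 10, read_len = L + 1), "read_len")
  expect_error(simulate_reads(p, coverage = 10, error_rate = 0.2), "error_rate")
})

test_that("paired read sets have equal mate lists and plausible inserts", {
  p <- small_plastome(4)
  rp <- simulate_reads(p, coverage = 8, read_len = 100, pairing = "paired",
                       insert_size = 300, insert_sd = 30, seed = 5)
  expect_equal(sum(rp$reads$mate == 1L), sum(rp$reads$mate == 2L))
  frag <- rp$reads$end[rp$reads$mate == 1L] - rp$reads$start[rp$reads$mate == 1L] + 1L
  expect_lt(abs(mean(frag) - 300), 10)
})

test_that("substitution errors appear at the requested rate", {
  p <- small_plastome(6)
  rs <- simulate_reads(p, coverage = 15, read_len = 100, error_rate = 0.01,
                       seed = 7)
  doubled <- paste0(p$sequence, p$sequence)
  nmm <- vapply(seq_len(nrow(rs$reads)), function(i) {
    r <- rs$reads[i, ]
    sq <- if (r$strand == "+") r$sequence else revcomp(r$sequence)
    sum(chars(sq) != chars(substr(doubled, r$start, r$start + 99L)))
  }, numeric(1))
  expect_lt(abs(mean(nmm) - 1.0), 0.15)  # 100 bp at 1% per base
})

test_that("fragmentation partitions the circle and round-trips", {
  p <- small_plastome(8)
  cs <- fragment_plastome(p, "at_IR_boundaries")
  expect_gte(nrow(cs$contigs), 3L)
  # contig ends coincide with region boundaries
  expect_setequal(cs$contigs$truth_start, p$regions$start)
  expect_true(same_circle(paste(cs$contigs$sequence, collapse = ""),
                          p$sequence))
  # random_k with k = 1: one contig equal to a rotation of the genome
  c1 <- fragment_plastome(p, "random_k", k = 1, seed = 3)
  expect_equal(nrow(c1$contigs), 1L)
  expect_true(same_circle(c1$contigs$sequence[1], p$sequence))
  # overlapping contigs collapse back to the original circle
  co <- fragment_plastome(p, "random_k", k = 5, overlap = 30, seed = 4)
  joined <- paste(substr(co$contigs$sequence, 1L,
                         co$contigs$length - 30L), collapse = "")
  expect_true(same_circle(joined, p$sequence))
})

test_that("seeded determinism holds across the generator operations", {
  p <- small_plastome(11)
  specs <- list(variant_spec("insertion", "rps16-trnQ", 400))
  expect_identical(plant_variants(p, specs, seed = 1)$plastome$sequence,
                   plant_variants(p, specs, seed = 1)$plastome$sequence)
  expect_identical(simulate_reads(p, 5, seed = 2)$reads$sequence,
                   simulate_reads(p, 5, seed = 2)$reads$sequence)
  expect_identical(fragment_plastome(p, "random_k", k = 4, seed = 3)$contigs,
                   fragment_plastome(p, "random_k", k = 4, seed = 3)$contigs)
})
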