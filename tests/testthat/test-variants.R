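test_that("anchor_align produces full-coverage collinear chains", {
  p <- small_plastome(61)
  # identical sequences: a single full-length block with no gaps
  ch <- anchor_align(p$sequence, p$sequence)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$q_start, 1L)
  expect_equal(ch$q_end, nchar(p$sequence))
  expect_equal(ch$strand, "+")
  # reverse complement: a single minus-strand block
  ch2 <- anchor_align(revcomp(p$sequence), p$sequence)
  expect_equal(nrow(ch2), 1L)
  expect_equal(ch2$strand, "-")
  expect_equal(ch2$t_start, 1L)
  expect_equal(ch2$t_end, nchar(p$sequence))
})

test_that("a planted deletion appears as a single target-side gap", {
  p <- small_plastome(62)
  pd <- plant_variants(p, variant_spec("deletion", 7000, 1500), seed = 63)
  ch <- anchor_align(pd$plastome$sequence, p$sequence)
  recs <- detect_indels(ch, annotations = p$features, annotated = "target",
                        min_len = 100)
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$kind, "deletion")
  expect_equal(recs$length, 1500L)
  # chain blocks cover >= 95% of the query
  expect_gte(chain_coverage(ch), 0.95)
})

test_that("indel loci are named from the flanking genes", {
  p <- small_plastome(64)
  pv <- plant_variants(p, variant_spec("insertion", "rps16-trnQ", 500), seed = 65)
  recs <- detect_indels(anchor_align(pv$plastome$sequence, p$sequence),
                        annotations = p$features, annotated = "target")
  expect_equal(recs$locus, "rps16-trnQ")
  expect_equal(recs$length, 500L)
  # events below min_len are not reported
  p2 <- plant_variants(p, variant_spec("insertion", "rps16-trnQ", 99), seed = 66)
  expect_equal(nrow(detect_indels(anchor_align(p2$plastome$sequence, p$sequence),
                                  min_len = 100)), 0L)
})

test_that("inversions are detected with exact interval and round-trip", {
  p <- small_plastome(67)
  pv <- plant_variants(p, variant_spec("inversion", "trnD-psbM", 150), seed = 68)
  inv <- detect_inversions(pv$plastome$sequence, p$sequence,
                           annotations = p$features, annotated = "target")
  expect_equal(nrow(inv), 1L)
  expect_equal(inv$length, 150L)
  expect_equal(inv$start, pv$truth$start)
  expect_equal(inv$end, pv$truth$end)
  # undoing the detected interval restores end-to-end collinearity
  s <- pv$plastome$sequence
  undone <- paste0(substr(s, 1, inv$start - 1),
                   revcomp(substr(s, inv$start, inv$end)),
                   substr(s, inv$end + 1, nchar(s)))
  ch <- anchor_align(undone, p$sequence)
  expect_equal(nrow(ch), 1L)
  expect_true(all(ch$strand == "+"))
  # no planted inversion: empty result
  expect_equal(nrow(detect_inversions(p$sequence, p$sequence)), 0L)
})

test_that("masking detected inversion columns removes minus-strand signal", {
  p <- small_plastome(69)
  pv <- plant_variants(p, variant_spec("inversion", "trnD-psbM", 200), seed = 70)
  q <- pv$plastome$sequence; t <- p$sequence
  inv <- detect_inversions(q, t)
  # excise the inverted interval from both genomes
  q2 <- paste0(substr(q, 1, inv$start - 1), substr(q, inv$end + 1, nchar(q)))
  t2 <- paste0(substr(t, 1, inv$t_start - 1), substr(t, inv$t_end + 1, nchar(t)))
  ch <- anchor_align(q2, t2)
  expect_true(all(ch$strand == "+"))
  expect_equal(nrow(detect_inversions(q2, t2)), 0L)
})

test_that("find_inverted_flanks handles IUPAC motifs and edge cases", {
  # the stem-loop signature: CCYTTTTY ... inversion ... GAAAAAGG is an
  # 8 bp imperfect inverted repeat under IUPAC compatibility
  s <- paste0(strrep("A", 50), "CCYTTTTY", strrep("G", 30), "GAAAAAGG",
              strrep("C", 50))
  res <- find_inverted_flanks(s, c(59, 88))
  expect_equal(res$flank_len, 8L)
  expect_equal(res$upstream, "CCYTTTTY")
  expect_equal(res$downstream, "GAAAAAGG")
  # exact palindromic flanks
  s2 <- paste0(strrep("C", 20), "AAAA", strrep("G", 10), "TTTT", strrep("C", 20))
  expect_equal(find_inverted_flanks(s2, c(25, 34))$flank_len, 4L)
  # no flank at all is f = 0, not an error
  s3 <- paste0(strrep("A", 20), strrep("G", 10), strrep("A", 20))
  expect_equal(find_inverted_flanks(s3, c(21, 30))$flank_len, 0L)
})

test_that("find_inverted_flanks agrees with a brute-force oracle", {
  brute <- function(s, iv, max_flank = 12L) {
    v <- strsplit(s, "")[[1]]
    L <- length(v)
    at <- function(i) v[((i - 1) %% L) + 1]
    sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                 Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                 K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                 D = c("A", "G", "T"), H = c("A", "C", "T"),
                 V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
              W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
              N = "N")
    for (f in rev(seq_len(max_flank))) {
      ok <- TRUE
      for (t in seq_len(f)) {
        a <- at(iv[1] - f + t - 1)
        b <- comp[[at(iv[2] + (f - t + 1))]]
        if (length(intersect(sets[[a]], sets[[b]])) == 0) { ok <- FALSE; break }
      }
      if (ok) return(f)
    }
    0L
  }
  set.seed(71)
  codes <- c("A", "C", "G", "T", "R", "Y", "N")
  for (i in 1:300) {
    s <- paste(sample(codes, 80, replace = TRUE,
                      prob = c(rep(0.23, 4), 0.03, 0.03, 0.02)), collapse = "")
    iv <- sort(sample(20:60, 2))
    expect_equal(find_inverted_flanks(s, iv, max_flank = 12L)$flank_len,
                 brute(s, iv), info = sprintf("case %d", i))
  }
})

test_that("synapomorphy mapping labels clades, tips and conflicts", {
  tree <- ape::read.tree(text = paste0(
    "(((Eremitis_sp,Pariana_radiciflora),((Olyra,Raddia),Lithachne)),",
    "(Bambusa,Guadua));"))
  res <- map_synapomorphies(
    list(c("Eremitis_sp", "Pariana_radiciflora"),   # monophyletic pair
         c("Olyra", "Raddia", "Lithachne"),          # monophyletic triple
         c("Olyra", "Bambusa"),                      # straddles two clades
         "Guadua"),                                  # single tip
    tree)
  expect_equal(res$label, c("synapomorphy", "synapomorphy",
                            "homoplastic/conflicting", "autapomorphy"))
  # the conflicting record reports its minimal covering clade
  expect_true(all(c("Olyra", "Bambusa") %in% res$clade_taxa[[3]]))
  expect_gt(length(res$clade_taxa[[3]]), 2L)
  expect_error(map_synapomorphies(list("NotATaxon"), tree), "unknown taxon")
})

test_that("monophyly calls agree with exhaustive clade enumeration", {
  # independent oracle: enumerate every clade's tip set by edge recursion
  clades_of <- function(tree) {
    n_tip <- length(tree$tip.label)
    kids <- split(tree$edge[, 2], tree$edge[, 1])
    leafset <- function(node) {
      if (node <= n_tip) return(tree$tip.label[node])
      sort(unlist(lapply(kids[[as.character(node)]], leafset)))
    }
    lapply((n_tip + 1):(n_tip + tree$Nnode), leafset)
  }
  set.seed(72)
  for (i in 1:120) {
    tree <- ape::rtree(10)
    taxa <- sample(tree$tip.label, sample(2:6, 1))
    res <- map_synapomorphies(list(taxa), tree)
    oracle <- any(vapply(clades_of(tree), setequal, logical(1), y = taxa))
    expect_equal(res$label == "synapomorphy", oracle,
                 info = sprintf("tree %d", i))
  }
})

test_that("chain_to_alignment round-trips both sequences", {
  p <- small_plastome(73)
  pv <- plant_variants(p, list(variant_spec("insertion", "rps16-trnQ", 400),
                               variant_spec("deletion", 7000, 250)), seed = 74)
  q <- pv$plastome$sequence; t <- p$sequence
  aln <- chain_to_alignment(q, t, anchor_align(q, t))
  expect_equal(nchar(aln[["query"]]), nchar(aln[["target"]]))
  expect_identical(gsub("-", "", aln[["query"]], fixed = TRUE), q)
  expect_identical(gsub("-", "", aln[["target"]], fixed = TRUE), t)
})
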