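make_panels <- function(insert, seed = 1) {
  withr::with_seed(seed, {
    mutate_at <- function(s, rate) {
      v <- strsplit(s, "")[[1]]
      idx <- which(stats::runif(length(v)) < rate)
      for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
      paste(v, collapse = "")
    }
    list(
      mito = c(mito_ctx = paste0(random_dna(1500, 0.55),
                                 mutate_at(insert, 0.01),
                                 random_dna(1500, 0.55))),
      plastid = c(cp_a = random_dna(4000, 0.61), cp_b = random_dna(4000, 0.61))
    )
  })
}

test_that("insert origin classification distinguishes the panels", {
  set.seed(81)
  insert <- random_dna(2500, 0.55)
  panels <- make_panels(insert, seed = 82)
  # verbatim copy of a mito-panel region: identity 1
  verb <- substr(panels$mito[[1]], 1600, 3500)
  oc <- classify_insert_origin(verb, panels$plastid, panels$mito)
  expect_equal(oc$best_source, "mito_panel")
  expect_equal(oc$identity, 1)
  # ~99% identity mito-derived insert is still called mitochondrial
  oc2 <- classify_insert_origin(insert, panels$plastid, panels$mito)
  expect_equal(oc2$best_source, "mito_panel")
  expect_gte(oc2$identity, 0.98)
  # random sequence matches nothing well
  oc3 <- classify_insert_origin(random_dna(2000), panels$plastid, panels$mito)
  expect_equal(oc3$best_source, "unclassified")
  expect_error(classify_insert_origin("", panels$plastid, panels$mito),
               "empty insert")
})

test_that("junction coverage separates real inserts from artifacts", {
  p <- small_plastome(83)
  pv <- plant_variants(p, variant_spec("insertion", "rps16-trnQ", 2000,
                                       payload_at_fraction = 0.55), seed = 84)
  withins <- pv$plastome
  tr <- pv$truth
  # positive control: reads drawn from the genome WITH the insert
  rs_pos <- simulate_reads(withins, coverage = 30, read_len = 100, seed = 85)
  rep_pos <- assess_assembly(withins, rs_pos)
  jc_pos <- junction_coverage(rep_pos, c(tr$start, tr$end))
  expect_false(jc_pos$suspect_up)
  expect_false(jc_pos$suspect_down)
  expect_gt(jc_pos$depth_ratio_up, 0.5)
  expect_gt(jc_pos$depth_ratio_down, 0.5)
  # negative control: reads lacking the insert, mapped to the genome with it
  rs_neg <- simulate_reads(p, coverage = 30, read_len = 100, seed = 86)
  rep_neg <- assess_assembly(withins, rs_neg)
  jc_neg <- junction_coverage(rep_neg, c(tr$start, tr$end))
  expect_true(jc_neg$suspect_up)
  expect_true(jc_neg$suspect_down)
})

test_that("junction coverage handles empty mappings and bad input", {
  p <- small_plastome(87)
  rs <- simulate_reads(p, coverage = 2, read_len = 100, seed = 88)
  # map reads against an unrelated genome: nothing maps, depth zero
  set.seed(89)
  rep0 <- assess_assembly(random_dna(20000), rs)
  expect_equal(rep0$mean_depth, 0)
  jc <- junction_coverage(rep0, c(5000, 6000))
  expect_equal(jc$upstream_depth, 0)
  expect_equal(jc$depth_ratio_down, 0)
  expect_error(junction_coverage(rep0, c(-5, 100)), "outside genome")
})

test_that("composition contrast counts are exact and complementary", {
  # all-A genome: both fractions are 1
  cc0 <- composition_contrast(strrep("A", 1000), c(100, 200))
  expect_equal(cc0$at_insert, 1)
  expect_equal(cc0$at_rest, 1)
  # planted 55%-AT insert in a 61%-AT genome
  p <- small_plastome(90)
  pv <- plant_variants(p, variant_spec("insertion", "rps16-trnQ", 2500,
                                       payload_at_fraction = 0.55), seed = 91)
  tr <- pv$truth
  cc <- composition_contrast(pv$plastome, c(tr$start, tr$end))
  expect_lt(cc$at_insert, cc$at_rest)
  # exact complementarity with the whole-genome AT count
  total_at <- cc$at_insert * cc$insert_len + cc$at_rest * cc$rest_len
  expect_equal(total_at,
               at_fraction_of(pv$plastome$sequence) * nchar(pv$plastome$sequence))
  expect_error(composition_contrast(strrep("A", 100), c(1, 100)),
               "whole genome")
})

test_that("in-silico PCR finds convergent products incl. wrap-around", {
  set.seed(92)
  tmpl <- random_dna(6000, 0.5)
  fwd <- substr(tmpl, 1001, 1025)
  rev <- revcomp(substr(tmpl, 3377, 3400))
  prod <- insilico_pcr(tmpl, fwd, rev, max_product = 3000)
  expect_equal(nrow(prod), 1L)
  expect_equal(prod$length, 2400L)
  expect_equal(prod$start, 1001L)
  # absent reverse site: no product
  expect_equal(nrow(insilico_pcr(tmpl, fwd, revcomp(random_dna(24)),
                                 max_product = 3000)), 0L)
  # size bound excludes distant site pairs
  expect_equal(nrow(insilico_pcr(tmpl, fwd, rev, max_product = 2399)), 0L)
  # wrap-around product across the origin
  fwd2 <- substr(tmpl, 5501, 5525)
  rev2 <- revcomp(substr(tmpl, 477, 500))
  prod2 <- insilico_pcr(tmpl, fwd2, rev2, max_product = 1200)
  expect_equal(prod2$length, 1000L)
})

test_that("degenerate primers anneal by IUPAC compatibility with 3'-exact ends", {
  tmpl <- paste0(strrep("G", 600), "CCCTTTTT", strrep("G", 592),
                 "ACACACACACACACACAC", strrep("G", 582))
  # primer with Y degeneracies matches the CT-rich site
  fwd <- paste0("GGGGGGGGGG", "CCYTTTTY", "GGGGGGG")       # 25 bp
  rev <- revcomp(paste0("CACACACACACACACAC", "GGGGGGGG"))  # 25 bp
  prod <- insilico_pcr(tmpl, fwd, rev, max_product = 2000)
  expect_gte(nrow(prod), 1L)
  # one internal mismatch is rejected at max_mismatch = 0, accepted at 1
  fwd_mm <- paste0("GGGGGGGGGG", "CCATTTTY", "GGGGGGG")  # Y->A incompatible
  expect_equal(nrow(insilico_pcr(tmpl, fwd_mm, rev, max_product = 2000,
                                 max_mismatch = 0)), 0L)
  expect_gte(nrow(insilico_pcr(tmpl, fwd_mm, rev, max_product = 2000,
                               max_mismatch = 1)), 1L)
  expect_error(insilico_pcr(tmpl, "ACGT", rev), "primer length")
})

test_that("in-silico PCR agrees with a brute-force site scan", {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
               Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
               K = c("G", "T"), M = c("A", "C"), N = c("A", "C", "G", "T"))
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", N = "N")
  brute_sites <- function(tmpl, primer) {
    tv <- strsplit(tmpl, "")[[1]]; L <- length(tv)
    pv <- strsplit(primer, "")[[1]]; n <- length(pv)
    plus <- integer(0); minus <- integer(0)
    for (p in 1:L) {
      ok <- TRUE
      for (i in 1:n) {
        a <- tv[((p + i - 2) %% L) + 1]
        if (length(intersect(sets[[a]], sets[[pv[i]]])) == 0) { ok <- FALSE; break }
      }
      if (ok) plus <- c(plus, p)
      ok <- TRUE
      rcp <- rev(unname(comp[pv]))
      for (i in 1:n) {
        a <- tv[((p + i - 2) %% L) + 1]
        if (length(intersect(sets[[a]], sets[[rcp[i]]])) == 0) { ok <- FALSE; break }
      }
      if (ok) minus <- c(minus, ((p + n - 1 - 1) %% L) + 1)
    }
    list(plus = plus, minus = minus)
  }
  brute_products <- function(tmpl, fwd, rev, max_product) {
    L <- nchar(tmpl)
    sF <- brute_sites(tmpl, fwd); sR <- brute_sites(tmpl, rev)
    lens <- integer(0)
    for (cb in list(list(sF$plus, sR$minus), list(sR$plus, sF$minus))) {
      for (a in cb[[1]]) for (b in cb[[2]]) {
        d <- ((b - a) %% L) + 1
        if (d <= max_product && d >= max(nchar(fwd), nchar(rev))) {
          lens <- c(lens, d)
        }
      }
    }
    sort(lens)
  }
  set.seed(93)
  n_cases <- 60
  for (i in seq_len(n_cases)) {
    tmpl <- random_dna(400, 0.5)
    # plant a site for each primer so products are reasonably frequent
    fwd <- substr(tmpl, 50, 69)
    rev <- revcomp(substr(tmpl, sample(150:350, 1) - 19, sample(330:350, 1)))
    rev <- substr(paste0(rev, "ACGTACGTACGTACGTACGT"), 1, 20)
    got <- insilico_pcr(tmpl, fwd, rev, max_product = 400)
    want <- brute_products(tmpl, fwd, rev, 400)
    expect_equal(sort(got$length), want, info = sprintf("case %d", i))
  }
})
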