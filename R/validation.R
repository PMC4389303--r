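# Seeded validation batteries over the synthetic study conditions. These
# drive the package's self-checks: plant-and-recover for structural
# variants, finishing round trips, and the HGT verification controls.

#' Quadripartite accounting of the published region table
#'
#' Checks every row of [bamboo_region_table()] for the identity
#' `total = LSC + SSC + 2 * IR` and computes the total-length range over
#' the newly assembled taxa.
#'
#' @return a list: `n_rows`, `n_consistent`, `range_min`, `range_max`
#'   (over `new_assembly` rows), `range_min_all`, `range_max_all`.
#' @export
table_accounting <- function() {
  rt <- bamboo_region_table()
  consistent <- rt$total_len == rt$lsc_len + rt$ssc_len + 2L * rt$ir_len
  new <- rt[rt$new_assembly, ]
  list(n_rows = nrow(rt), n_consistent = sum(consistent),
       range_min = min(new$total_len), range_max = max(new$total_len),
       range_min_all = min(rt$total_len), range_max_all = max(rt$total_len))
}

#' Arithmetic of the Parianinae mitochondrial insert
#'
#' The shared insert plus the 3' extension of the longer copy must equal
#' the stated total; the alternative extension figure recorded from the
#' results section is flagged as inconsistent when it does not.
#'
#' @return a list: `shared_bp`, `extension_bp`, `total_bp`,
#'   `consistent`, `alt_extension_bp`, `alt_consistent`.
#' @export
parianinae_insert_arithmetic <- function() {
  ev <- bamboo_marker_events()
  row <- ev[ev$event == "parianinae_mito_insertion", ]
  list(shared_bp = row$shared_insert_bp,
       extension_bp = row$extension_3p_bp,
       total_bp = row$shared_insert_bp + row$extension_3p_bp,
       consistent = row$shared_insert_bp + row$extension_3p_bp == row$length_bp,
       alt_extension_bp = row$extension_3p_results_bp,
       alt_consistent = row$shared_insert_bp + row$extension_3p_results_bp ==
         row$length_bp)
}

# a random bamboo-sized spec within the published region-length ranges
random_study_spec <- function(seed) {
  run_seeded(seed, {
    plastome_spec(lsc_len = sample(79500:83300, 1),
                  ssc_len = sample(12400:13700, 1),
                  ir_len = sample(19800:25000, 1),
                  at_fraction = 0.61, n_genes = 88L, seed = seed)
  })
}

# the marker-event catalogue sized like the four published events
marker_event_specs <- function(ir_insert_len) {
  list(
    inversion = function(p) variant_spec("inversion", "trnD-psbM", 150L,
                                         flank_repeat = "CCYTTTTY"),
    lsc_insertion = function(p) variant_spec("insertion", "rps16-trnQ", 500L,
                                             payload_at_fraction = 0.55),
    deletion = function(p) {
      lsc_end <- unname(region_interval(p, "LSC")["end"])
      variant_spec("deletion", as.integer(lsc_end * 0.6), 1500L)
    },
    ir_insertion = function(p) variant_spec("insertion", "rpl23-ndhB",
                                            ir_insert_len,
                                            payload_at_fraction = 0.55)
  )
}

#' Plant-and-recover battery for structural variants
#'
#' For each seeded replicate, generates a bamboo-sized plastome, plants a
#' random subset of the marker-sized events (150 bp inversion; 500,
#' 1,500 and 2,706 or 4,938 bp indels), re-detects them by anchored
#' alignment against the ancestral genome, and scores exact-length
#' recovery with endpoints within `endpoint_tol` bp.
#'
#' @param n_genomes number of replicates.
#' @param seed battery seed.
#' @param endpoint_tol endpoint tolerance in bp.
#' @return a list: `n_genomes`, `n_events`, `n_recovered`,
#'   `recovery_rate`, `max_endpoint_error`, `per_genome` (tibble).
#' @export
plant_recover_battery <- function(n_genomes = 50L, seed = 1L,
                                  endpoint_tol = 2L) {
  seed <- as.integer(seed) %% 100000L  # derived seeds stay under 2^31
  rows <- list()
  for (g in seq_len(n_genomes)) {
    gseed <- seed * 1000L + g
    p <- generate_plastome(random_study_spec(gseed))
    picks <- run_seeded(gseed + 1L, {
      ir_len <- sample(c(2706L, 4938L), 1)
      ev <- marker_event_specs(ir_len)
      ev[sample(names(ev), sample(1:4, 1))]
    })
    specs <- lapply(picks, function(f) f(p))
    pv <- plant_variants(p, unname(specs), seed = gseed + 2L)
    q <- pv$plastome; t <- pv$ancestral
    chain <- anchor_align(q, t)
    indels <- detect_indels(chain, annotations = t$features,
                            annotated = "target", min_len = 100L)
    invs <- detect_inversions(q, t, min_len = 50L, chain = chain)
    det <- rbind(indels[, c("kind", "start", "end", "length")],
                 invs[, c("kind", "start", "end", "length")])

    truth <- pv$truth
    errs <- integer(0)
    matched <- logical(nrow(truth))
    for (i in seq_len(nrow(truth))) {
      if (truth$kind[i] == "deletion") {
        # deletions have no extent on the derived genome; match on length
        hit <- det$kind == "deletion" & det$length == truth$length[i]
        matched[i] <- any(hit)
        if (any(hit)) errs <- c(errs, 0L)
      } else {
        hit <- det$kind == truth$kind[i] & det$length == truth$length[i] &
          abs(det$start - truth$start[i]) <= endpoint_tol &
          abs(det$end - truth$end[i]) <= endpoint_tol
        matched[i] <- any(hit)
        if (any(hit)) {
          j <- which(hit)[1]
          errs <- c(errs, max(abs(det$start[j] - truth$start[i]),
                              abs(det$end[j] - truth$end[i])))
        }
      }
    }
    rows[[g]] <- tibble::tibble(genome = g, n_truth = nrow(truth),
                                n_matched = sum(matched),
                                all_recovered = all(matched),
                                max_err = if (length(errs)) max(errs) else NA_integer_)
  }
  per <- do.call(rbind, rows)
  list(n_genomes = n_genomes,
       n_events = sum(per$n_truth),
       n_recovered = sum(per$n_matched),
       recovery_rate = sum(per$n_matched) / sum(per$n_truth),
       genomes_fully_recovered = sum(per$all_recovered),
       max_endpoint_error = max(per$max_err, na.rm = TRUE),
       per_genome = per)
}

#' Finishing round-trip battery
#'
#' For each seeded replicate: generate a bamboo-sized plastome, simulate
#' reads, fragment at the IR boundaries, scaffold against the truth
#' genome, close gaps, and test rotation-invariant equality with the
#' truth circle.
#'
#' @param n_runs replicates.
#' @param seed battery seed.
#' @param coverage read coverage.
#' @param error_rate per-base substitution rate of the simulated reads.
#' @return a list: `n_runs`, `n_recovered`, `recovery_rate`.
#' @export
finishing_battery <- function(n_runs = 20L, seed = 1L, coverage = 25,
                              error_rate = 0) {
  seed <- as.integer(seed) %% 100000L  # derived seeds stay under 2^31
  ok <- logical(n_runs)
  for (r in seq_len(n_runs)) {
    rseed <- seed * 2000L + r
    p <- generate_plastome(random_study_spec(rseed))
    rs <- simulate_reads(p, coverage = coverage, read_len = 100L,
                         error_rate = error_rate, seed = rseed + 1L)
    cs <- fragment_plastome(p, "at_IR_boundaries", seed = rseed + 2L)
    sc <- scaffold_contigs(cs, p)
    fin <- close_gaps(sc, reads = rs, min_overlap = 20L)
    ok[r] <- inherits(fin, "plastome") && same_circle(fin$sequence, p$sequence)
  }
  list(n_runs = n_runs, n_recovered = sum(ok),
       recovery_rate = sum(ok) / n_runs)
}

#' HGT verification battery
#'
#' Seeded positive/negative junction-coverage controls (reads with and
#' without the planted foreign insert), origin classification of a
#' 99%-identity mitochondrial-derived insert, and the AT-composition
#' contrast of the planted 55%-AT insert against the 61%-AT background.
#'
#' @param n_runs control replicates.
#' @param seed battery seed.
#' @param coverage read coverage for the controls.
#' @return a list with discrimination counts and the classification and
#'   composition results of the final replicate.
#' @export
hgt_battery <- function(n_runs = 20L, seed = 1L, coverage = 30) {
  seed <- as.integer(seed) %% 100000L  # derived seeds stay under 2^31
  pos_ok <- logical(n_runs); neg_ok <- logical(n_runs)
  last <- NULL
  for (r in seq_len(n_runs)) {
    rseed <- seed * 3000L + r
    p <- generate_plastome(plastome_spec(lsc_len = 30000L, ssc_len = 6000L,
                                         ir_len = 8000L, n_genes = 40L,
                                         seed = rseed))
    pv <- plant_variants(p, variant_spec("insertion", "rps16-trnQ", 2706L,
                                         payload_at_fraction = 0.55),
                         seed = rseed + 1L)
    tr <- pv$truth
    rs_pos <- simulate_reads(pv$plastome, coverage = coverage,
                             read_len = 100L, seed = rseed + 2L)
    jc_pos <- junction_coverage(assess_assembly(pv$plastome, rs_pos),
                                c(tr$start, tr$end))
    rs_neg <- simulate_reads(p, coverage = coverage, read_len = 100L,
                             seed = rseed + 3L)
    jc_neg <- junction_coverage(assess_assembly(pv$plastome, rs_neg),
                                c(tr$start, tr$end))
    pos_ok[r] <- !jc_pos$suspect_up && !jc_pos$suspect_down
    neg_ok[r] <- jc_neg$suspect_up && jc_neg$suspect_down
    last <- list(p = p, pv = pv)
  }
  # classification + composition on the final replicate
  tr <- last$pv$truth
  insert_seq <- substr(last$pv$plastome$sequence, tr$start, tr$end)
  panels <- run_seeded(seed * 3000L + n_runs + 10L, {
    list(mito = c(mito_ctx = paste0(rand_dna(1500, 0.55),
                                    mutate_sequence(insert_seq, 0.01),
                                    rand_dna(1500, 0.55))),
         plastid = c(cp_a = rand_dna(5000, 0.61), cp_b = rand_dna(5000, 0.61)))
  })
  oc <- classify_insert_origin(insert_seq, panels$plastid, panels$mito)
  cc <- composition_contrast(last$pv$plastome, c(tr$start, tr$end))
  list(n_runs = n_runs,
       positive_controls_passed = sum(pos_ok),
       negative_controls_passed = sum(neg_ok),
       origin_call = oc$best_source, origin_identity = oc$identity,
       at_insert = cc$at_insert, at_rest = cc$at_rest)
}
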