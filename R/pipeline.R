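# End-to-end orchestration: simulate -> finish -> canonicalize ->
# annotate -> variants -> hgt -> matrix, driven by a plain-text key=value
# configuration, with per-stage artifacts and a machine-readable summary.

#' Default pipeline configuration
#'
#' Returns the full configuration as a named list. Defaults emulate the
#' sequencing study conditions: a bamboo-sized plastome (~139 kb; LSC
#' 82 kb, SSC 12.8 kb, IR 21.8 kb), 61% AT, the four marker structural
#' events (2,706 bp IR insertion of 55%-AT foreign sequence, 1,500 bp
#' deletion, 150 bp inversion with an 8 bp inverted flank repeat, 500 bp
#' insertion), single-end 100 bp reads at 25-fold coverage.
#'
#' @param ... overrides of individual fields.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    stages = "simulate,finish,canonicalize,annotate,variants,hgt,matrix",
    seed = 1L,
    out_dir = "plastomics_run",
    # synthetic genome
    lsc_len = 82000L, ssc_len = 12800L, ir_len = 21800L,
    at_fraction = 0.61, n_genes = 88L,
    # planted events (the four marker events by default)
    insert_ir_len = 2706L, insert_lsc_len = 500L,
    deletion_len = 1500L, inversion_len = 150L,
    payload_at_fraction = 0.55, flank_repeat = "CCYTTTTY",
    # reads
    coverage = 25, read_len = 100L, pairing = "single", error_rate = 0,
    # finishing
    min_overlap = 20L, anchor_k = 31L,
    # structure
    min_ir_len = 1000L, min_similarity = 0.70,
    # variants
    min_indel = 100L, min_inv = 50L, k_anchor = 21L,
    # hgt
    junction_window = 100L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  for (nm in names(dots)) {
    proto <- cfg[[nm]]
    cfg[[nm]] <- if (is.integer(proto)) as.integer(dots[[nm]])
                 else if (is.numeric(proto)) as.numeric(dots[[nm]])
                 else as.character(dots[[nm]])
  }
  structure(cfg, class = "run_config")
}

#' Write a configuration as plain-text key=value
#' @param cfg a `run_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  writeLines(sprintf("%s=%s", names(cfg),
                     vapply(cfg, function(v) as.character(v)[1], character(1))),
             path)
  invisible(path)
}

#' Read a key=value configuration file
#' @param path configuration file.
#' @return a `run_config` (values coerced back to the default's types).
#' @export
read_run_config <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  kv <- strsplit(ln, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = "="),
                                 character(1)),
                          vapply(kv, `[`, character(1), 1L))
  defaults <- run_config()
  out <- defaults
  for (nm in names(vals)) {
    if (!nm %in% names(defaults)) stop("unknown config field: ", nm)
    proto <- defaults[[nm]]
    out[[nm]] <- if (is.integer(proto)) as.integer(vals[[nm]])
                 else if (is.numeric(proto)) as.numeric(vals[[nm]])
                 else vals[[nm]]
  }
  structure(out, class = "run_config")
}

pipeline_log <- function(...) message(sprintf("[plastomics] %s", sprintf(...)))

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order inside `cfg$out_dir`,
#' writing per-stage artifacts (FASTA, FASTQ, GFF3, TSV, JSON) plus a
#' `summary.json` with provenance (config hash and seed). Identical
#' config and seed reproduce an identical summary.
#'
#' @param cfg a `run_config` (or path to a key=value file).
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(cfg = run_config()) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  stages <- strsplit(cfg$stages, ",", fixed = TRUE)[[1]]
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(cfg$out_dir, "config.txt")
  write_run_config(cfg, cfg_path)
  summary <- list(config_hash = unname(tools::md5sum(cfg_path)),
                  seed = cfg$seed)
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fn) {
    if (!name %in% stages) return(invisible(NULL))
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    pipeline_log("stage %-12s %.1fs", name,
                 as.numeric(difftime(Sys.time(), t0, units = "secs")))
    summary[[name]] <<- res
    invisible(res)
  }

  run_stage("simulate", function() stage_simulate(cfg, state))
  run_stage("finish", function() stage_finish(cfg, state))
  run_stage("canonicalize", function() stage_canonicalize(cfg, state))
  run_stage("annotate", function() stage_annotate(cfg, state))
  run_stage("variants", function() stage_variants(cfg, state))
  run_stage("hgt", function() stage_hgt(cfg, state))
  run_stage("matrix", function() stage_matrix(cfg, state))

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

stage_simulate <- function(cfg, state) {
  spec <- plastome_spec(cfg$lsc_len, cfg$ssc_len, cfg$ir_len,
                        cfg$at_fraction, cfg$n_genes, seed = cfg$seed)
  base <- generate_plastome(spec)
  lsc <- region_interval(base, "LSC")
  events <- list(
    variant_spec("insertion", "rpl23-ndhB", cfg$insert_ir_len,
                 payload_at_fraction = cfg$payload_at_fraction),
    variant_spec("insertion", "rps16-trnQ", cfg$insert_lsc_len,
                 payload_at_fraction = cfg$payload_at_fraction),
    variant_spec("deletion", as.integer(lsc["end"] * 0.6), cfg$deletion_len),
    variant_spec("inversion", "trnD-psbM", cfg$inversion_len,
                 flank_repeat = cfg$flank_repeat)
  )
  pv <- plant_variants(base, events, seed = cfg$seed + 1L)
  reads <- simulate_reads(pv$plastome, coverage = cfg$coverage,
                          read_len = cfg$read_len, pairing = cfg$pairing,
                          error_rate = cfg$error_rate, seed = cfg$seed + 2L)
  contigs <- fragment_plastome(pv$plastome, "at_IR_boundaries",
                               seed = cfg$seed + 3L)
  d <- cfg$out_dir
  write_fasta(pv$ancestral, file.path(d, "reference.fasta"), name = "reference")
  write_gff3(pv$ancestral, file.path(d, "reference.gff3"), seqid = "reference")
  write_fasta(pv$plastome, file.path(d, "derived.fasta"), name = "derived")
  write_fasta(contigs, file.path(d, "contigs.fasta"))
  write_fastq(reads, file.path(d, "reads"))
  write_variants_tsv(pv$truth, file.path(d, "truth_variants.tsv"))
  state$base <- base; state$pv <- pv; state$reads <- reads
  state$contigs <- contigs
  list(genome_len = nchar(pv$plastome$sequence),
       n_variants = nrow(pv$truth),
       n_reads = nrow(reads$reads),
       n_contigs = nrow(contigs$contigs))
}

stage_finish <- function(cfg, state) {
  sc <- scaffold_contigs(state$contigs, state$pv$ancestral,
                         anchor_k = cfg$anchor_k)
  fin <- close_gaps(sc, reads = state$reads, min_overlap = cfg$min_overlap)
  closed <- inherits(fin, "plastome")
  report <- if (closed) assess_assembly(fin, state$reads) else NULL
  if (closed) {
    write_fasta(fin, file.path(cfg$out_dir, "finished.fasta"), name = "finished")
  }
  state$finished <- fin
  state$assembly_report <- report
  list(closed = closed,
       finished_len = if (closed) nchar(fin$sequence) else NA_integer_,
       matches_truth = closed &&
         same_circle(fin$sequence, state$pv$plastome$sequence),
       mean_depth = if (closed) report$mean_depth else NA_real_,
       n_inconsistencies = if (closed) nrow(report$inconsistencies) else NA_integer_)
}

stage_canonicalize <- function(cfg, state) {
  src <- if (inherits(state$finished, "plastome")) state$finished else state$pv$plastome
  canon <- canonicalize(src, min_ir_len = cfg$min_ir_len)
  state$canonical <- canon
  write_fasta(canon, file.path(cfg$out_dir, "canonical.fasta"), name = "canonical")
  rt <- region_table(canonical = canon)
  write_region_table(rt, file.path(cfg$out_dir, "region_table.tsv"))
  as.list(rt[1, c("total_len", "lsc_len", "ssc_len", "ir_len")])
}

stage_annotate <- function(cfg, state) {
  canon <- state$canonical %||% state$pv$plastome
  ann <- transfer_annotations(canon, state$pv$ancestral,
                              min_similarity = cfg$min_similarity)
  state$annotated <- ann
  write_gff3(ann, file.path(cfg$out_dir, "annotated.gff3"), seqid = "canonical")
  list(n_transferred = nrow(ann$features),
       n_untransferred = length(attr(ann, "untransferred")))
}

stage_variants <- function(cfg, state) {
  q <- state$pv$plastome; t <- state$pv$ancestral
  chain <- anchor_align(q, t, k = cfg$k_anchor)
  indels <- detect_indels(chain, annotations = t$features,
                          annotated = "target", min_len = cfg$min_indel)
  invs <- detect_inversions(q, t, annotations = t$features,
                            annotated = "target", min_len = cfg$min_inv,
                            k = cfg$k_anchor, chain = chain)
  flanks <- if (nrow(invs)) {
    vapply(seq_len(nrow(invs)), function(i) {
      find_inverted_flanks(q$sequence, c(invs$start[i], invs$end[i]))$flank_len
    }, integer(1))
  } else integer(0)
  recovered <- rbind(indels[, c("kind", "locus", "length")],
                     invs[, c("kind", "locus", "length")])
  write_variants_tsv(cbind(recovered,
                           flank_len = c(rep(NA_integer_, nrow(indels)), flanks)),
                     file.path(cfg$out_dir, "variants.tsv"))
  # synapomorphy mapping of the IR insertion on a bamboo-like topology
  tree_txt <- "(((Eremitis_sp,Pariana_radiciflora),(Olyra_latifolia,Raddia_brasiliensis)),(Bambusa_bambos,Guadua_weberbaueri));"
  writeLines(tree_txt, file.path(cfg$out_dir, "demo_tree.nwk"))
  syn <- map_synapomorphies(list(c("Eremitis_sp", "Pariana_radiciflora")),
                            tree_txt)
  state$chain <- chain; state$indels <- indels; state$invs <- invs
  list(n_indels = nrow(indels), n_inversions = nrow(invs),
       inversion_flank_len = if (length(flanks)) max(flanks) else 0L,
       chain_coverage = chain_coverage(chain),
       ir_insert_label = syn$label[1])
}

stage_hgt <- function(cfg, state) {
  pv <- state$pv
  tr <- pv$truth
  ins <- tr[tr$kind == "insertion" & tr$length == cfg$insert_ir_len &
              !tr$mirrored, ][1, ]
  g <- pv$plastome$sequence
  insert_seq <- substr(g, ins$start, ins$end)
  # panels: plastid = single-copy slices of the ancestor; mito = a
  # synthetic mitogenome context carrying a 99%-identity copy of the insert
  run <- run_seeded(cfg$seed + 7L, {
    mito_core <- mutate_sequence(insert_seq, 0.01)
    mito_panel <- c(Ferrocalamus_mito_rps7_atp6 = paste0(
      rand_dna(2000, 0.55), mito_core, rand_dna(2000, 0.55)))
    anc <- pv$ancestral$sequence
    plastid_panel <- c(anc_lsc = substr(anc, 1000, 9000),
                       anc_ssc = substr(anc, cfg$lsc_len + cfg$ir_len + 100,
                                        cfg$lsc_len + cfg$ir_len + 8000))
    list(mito = mito_panel, plastid = plastid_panel)
  })
  oc <- classify_insert_origin(insert_seq, run$plastid, run$mito)

  report <- state$assembly_report %||% assess_assembly(pv$plastome, state$reads)
  jc <- junction_coverage(report, c(ins$start, ins$end),
                          window = cfg$junction_window)
  cc <- composition_contrast(g, c(ins$start, ins$end))

  # junction-spanning PCR: one primer upstream of the insert, one inside,
  # sited so the expected product is ~2,400 bp
  up_off <- 1200L
  in_off <- max(24L, min(1199L, ins$length - 1L))  # reverse site inside insert
  fwd <- substr(g, ins$start - up_off, ins$start - up_off + 24L)
  rev_site <- ins$start + in_off
  rev <- revcomp(substr(g, rev_site - 24L, rev_site))
  prod <- insilico_pcr(g, fwd, rev, max_product = 5000L)
  neg <- insilico_pcr(pv$ancestral$sequence, fwd, rev, max_product = 5000L)

  res <- list(origin = oc$best_source, origin_identity = oc$identity,
              depth_ratio_up = jc$depth_ratio_up,
              depth_ratio_down = jc$depth_ratio_down,
              suspect = jc$suspect_up || jc$suspect_down,
              at_insert = cc$at_insert, at_rest = cc$at_rest,
              pcr_product_len = if (nrow(prod)) prod$length[1] else NA_integer_,
              pcr_products_without_insert = nrow(neg))
  jsonlite::write_json(res, file.path(cfg$out_dir, "hgt_report.json"),
                       auto_unbox = TRUE, digits = NA)
  res
}

stage_matrix <- function(cfg, state) {
  # drop IRa (the final canonical region) from both genomes, then align
  drop_ira <- function(p) {
    ira <- region_interval(p, "IRa")
    substr(p$sequence, 1L, ira["start"] - 1L)
  }
  q <- drop_ira(state$pv$plastome)
  t <- drop_ira(state$pv$ancestral)
  chain <- anchor_align(q, t, k = cfg$k_anchor)
  aln <- chain_to_alignment(q, t, chain)
  anns <- state$pv$ancestral$features
  anns <- anns[anns$end < nchar(t), , drop = FALSE]
  m <- assemble_matrix(aln, annotations = anns, reference_row = "target")
  m_nogap <- strip_gapped_columns(m)
  coding <- extract_coding(m)
  coding_nogap <- strip_gapped_columns(coding)
  write_phylip(m_nogap, file.path(cfg$out_dir, "matrix_nogap.phy"))
  write_partitions(m, file.path(cfg$out_dir, "partitions.txt"))
  list(aligned_cols = ncol(m$mat),
       gapped_cols = sum(m$masks$gapped),
       stripped_cols = ncol(m_nogap$mat),
       coding_cols = ncol(coding$mat),
       coding_stripped_cols = ncol(coding_nogap$mat))
}

# substitution-mutate a sequence at the given per-base rate
mutate_sequence <- function(s, rate) {
  v <- chars(s)
  n <- length(v)
  k <- stats::rbinom(1, n, rate)
  if (k > 0L) {
    idx <- sample.int(n, k)
    for (i in idx) v[i] <- sample(setdiff(DNA_BASES, v[i]), 1)
  }
  paste(v, collapse = "")
}
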