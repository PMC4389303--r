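#' Specification for a synthetic grass plastome
#'
#' Region lengths default to the quadripartite dimensions typical of bamboo
#' plastomes (total 135-144 kb; LSC ~79.5-83.3 kb, SSC ~12.4-13.7 kb,
#' IR ~19.8-25.0 kb) and an AT-rich base composition of 61%.
#'
#' @param lsc_len,ssc_len,ir_len region lengths in bp; the total genome
#'   length is `lsc_len + ssc_len + 2 * ir_len`.
#' @param at_fraction target AT fraction of the genome, in `[0, 1]`.
#' @param n_genes number of distinct genes to place (IR genes are present
#'   in both repeat copies in addition to this count).
#' @param seed integer seed making the genome reproducible.
#' @return an object of class `plastome_spec`.
#' @export
plastome_spec <- function(lsc_len = 82000L, ssc_len = 12800L, ir_len = 21800L,
                          at_fraction = 0.61, n_genes = 88L, seed = 1L) {
  lsc_len <- as.integer(lsc_len); ssc_len <- as.integer(ssc_len)
  ir_len <- as.integer(ir_len)
  if (lsc_len <= 0L || ssc_len <= 0L || ir_len <= 0L) {
    stop("region lengths must be positive")
  }
  if (!(ir_len < ssc_len + lsc_len)) stop("ir_len must be < lsc_len + ssc_len")
  if (at_fraction < 0 || at_fraction > 1) stop("at_fraction must be in [0, 1]")
  structure(
    list(lsc_len = lsc_len, ssc_len = ssc_len, ir_len = ir_len,
         at_fraction = at_fraction, n_genes = as.integer(n_genes),
         seed = as.integer(seed)),
    class = "plastome_spec"
  )
}

#' @export
print.plastome_spec <- function(x, ...) {
  cat(sprintf(
    "<plastome_spec> total %s bp (LSC %s, SSC %s, IR 2x%s), AT %.2f, %d genes, seed %d\n",
    format(x$lsc_len + x$ssc_len + 2L * x$ir_len, big.mark = ","),
    format(x$lsc_len, big.mark = ","), format(x$ssc_len, big.mark = ","),
    format(x$ir_len, big.mark = ","), x$at_fraction, x$n_genes, x$seed))
  invisible(x)
}

# Place k genes with the given lengths into a region of length L:
# returns start positions such that genes are non-overlapping and separated
# by spacers of at least 1 bp (also >= 1 bp before the first and after the
# last gene, so region boundaries never abut a gene).
place_genes <- function(gene_lens, region_len) {
  k <- length(gene_lens)
  if (k == 0L) return(integer(0))
  slack <- region_len - sum(gene_lens) - (k + 1L)
  if (slack < 0L) {
    stop("infeasible spec: ", k, " genes (", sum(gene_lens),
         " bp) do not fit in a ", region_len, " bp region")
  }
  # random composition of the slack over the k+1 spacers
  extra <- as.vector(stats::rmultinom(1, slack, rep(1, k + 1L)))
  spacers <- extra + 1L
  starts <- integer(k)
  pos <- 0L
  for (i in seq_len(k)) {
    pos <- pos + spacers[i]
    starts[i] <- pos + 1L
    pos <- pos + gene_lens[i]
  }
  starts
}

#' Generate a synthetic plastome
#'
#' Composes a circular genome in canonical quadripartite order
#' (LSC, IRb, SSC, IRa) with IRa the exact reverse complement of IRb,
#' random background sequence at the requested AT fraction, and
#' non-overlapping gene features drawn from the canonical grass plastid
#' gene list. Genes assigned to the IR appear in both repeat copies.
#' Bases immediately outside the IR pair are constrained so that the
#' maximal inverted repeat equals the annotated one exactly.
#'
#' @param spec a [plastome_spec()].
#' @return a `plastome` with regions and features; deterministic for a
#'   fixed spec (byte-identical sequences for the same seed).
#' @export
generate_plastome <- function(spec) {
  stopifnot(inherits(spec, "plastome_spec"))
  run_seeded(spec$seed, {
    genes <- select_genes(spec$n_genes)
    by_region <- split(genes$name, factor(genes$region, levels = c("LSC", "IR", "SSC")))
    # preserve genome order within region
    by_region <- lapply(by_region, function(v) v[order(match(v, genes$name))])

    lens <- list(LSC = spec$lsc_len, IR = spec$ir_len, SSC = spec$ssc_len)
    feats <- list()
    seqs <- list()
    for (reg in c("LSC", "IR", "SSC")) {
      nm <- by_region[[reg]] %||% character(0)
      gl <- unname(vapply(nm, gene_length_for, integer(1)))
      # compact gene models when the region is small (miniature test genomes)
      avail <- lens[[reg]] - (length(gl) + 1L)
      if (length(gl) && sum(gl) > avail) {
        gl <- pmax(60L, as.integer(floor(gl * 0.9 * avail / sum(gl))))
      }
      starts <- place_genes(gl, lens[[reg]])
      strand <- if (length(nm)) sample(c("+", "-"), length(nm), replace = TRUE) else character(0)
      # the orientation marker gene defines the canonical strand
      strand[nm == "psbA"] <- "+"
      kind <- ifelse(grepl("^trn", nm), "tRNA", ifelse(grepl("^rrn", nm), "rRNA", "CDS"))
      feats[[reg]] <- tibble::tibble(
        name = nm, kind = kind, strand = strand,
        start = starts, end = starts + gl - 1L
      )
      seqs[[reg]] <- rand_dna(lens[[reg]], spec$at_fraction)
    }

    lsc <- seqs$LSC; irb <- seqs$IR; ssc <- seqs$SSC
    ira <- revcomp(irb)
    s <- paste0(lsc, irb, ssc, ira)
    L <- nchar(s)

    # break chance reverse-complement symmetry just outside the IR pair so
    # the maximal IR equals the annotated interval
    allowed <- if (spec$at_fraction >= 1) c("A", "T")
               else if (spec$at_fraction <= 0) c("C", "G")
               else DNA_BASES
    guard <- function(s, pos_a, pos_b) {
      # replace the base at pos_a so it is not the complement of the base
      # at pos_b (choices respect a degenerate composition)
      bad <- unname(IUPAC_COMP[substr(s, pos_b, pos_b)])
      if (substr(s, pos_a, pos_a) == bad) {
        choices <- setdiff(allowed, bad)
        substr(s, pos_a, pos_a) <- choices[sample.int(length(choices), 1)]
      }
      s
    }
    j_lsc_irb <- spec$lsc_len                       # last LSC base
    j_ssc_a <- spec$lsc_len + spec$ir_len + 1L      # first SSC base
    j_ssc_b <- spec$lsc_len + spec$ir_len + spec$ssc_len  # last SSC base
    s <- guard(s, j_lsc_irb, 1L)        # IRb left edge vs IRa right edge (wraps)
    s <- guard(s, j_ssc_a, j_ssc_b)     # IRb right edge vs IRa left edge

    off <- c(LSC = 0L, IR = spec$lsc_len, SSC = spec$lsc_len + spec$ir_len)
    shift_feat <- function(df, o) {
      df$start <- df$start + o; df$end <- df$end + o; df
    }
    f_lsc <- shift_feat(feats$LSC, off["LSC"])
    f_irb <- shift_feat(feats$IR, off["IR"])
    f_ssc <- shift_feat(feats$SSC, off["SSC"])
    # mirror IR features into IRa
    ira_start <- spec$lsc_len + spec$ir_len + spec$ssc_len + 1L
    f_ira <- feats$IR
    rs <- f_ira$start; re <- f_ira$end
    f_ira$start <- ira_start + (spec$ir_len - re)
    f_ira$end <- ira_start + (spec$ir_len - rs)
    f_ira$strand <- ifelse(f_ira$strand == "+", "-", "+")
    features <- rbind(f_lsc, f_irb, f_ssc, f_ira)
    features <- features[order(features$start), ]

    regions <- tibble::tibble(
      region = c("LSC", "IRb", "SSC", "IRa"),
      start = c(1L, spec$lsc_len + 1L, spec$lsc_len + spec$ir_len + 1L, ira_start),
      end = c(spec$lsc_len, spec$lsc_len + spec$ir_len,
              spec$lsc_len + spec$ir_len + spec$ssc_len, L)
    )
    plastome(s, regions = regions, features = features)
  })
}
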