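#' Simulate Illumina-style reads from a circular plastome
#'
#' Draws read start positions uniformly from the circle (wrap-around
#' allowed) on both strands, applies i.i.d. substitution errors, and
#' records per-read truth origin. Paired-end mode draws fragments of
#' normally distributed insert size and reports both mates in
#' convergent orientation. Quality strings are constant high quality.
#'
#' @param p a `plastome` (or a plain DNA string).
#' @param coverage requested mean fold coverage (> 0).
#' @param read_len read length in bp (the emulated platforms produced
#'   99-100 bp reads).
#' @param pairing `"single"` or `"paired"`.
#' @param error_rate per-base substitution probability, in `[0, 0.05]`.
#' @param insert_size,insert_sd mean and sd of fragment length (paired only).
#' @param seed integer seed.
#' @return a `read_set`: list with a `reads` tibble (id, mate, sequence,
#'   quality, start, end, strand — truth origin on the forward circle),
#'   plus pairing metadata.
#' @export
simulate_reads <- function(p, coverage, read_len = 100L,
                           pairing = c("single", "paired"),
                           error_rate = 0, insert_size = 300L, insert_sd = 30L,
                           seed = 1L) {
  pairing <- match.arg(pairing)
  s <- if (inherits(p, "plastome")) p$sequence else toupper(p)
  L <- nchar(s)
  read_len <- as.integer(read_len)
  if (coverage <= 0) stop("coverage must be > 0")
  if (read_len > L) stop("read_len exceeds genome length")
  if (error_rate < 0 || error_rate > 0.05) stop("error_rate must be in [0, 0.05]")
  run_seeded(seed, {
    doubled <- paste0(s, s)
    n_reads <- as.integer(round(coverage * L / read_len))
    if (pairing == "single") {
      starts <- sample.int(L, n_reads, replace = TRUE)
      strand <- sample(c("+", "-"), n_reads, replace = TRUE)
      raw <- substring(doubled, starts, starts + read_len - 1L)
      seqs <- raw; seqs[strand == "-"] <- revcomp_vec(raw[strand == "-"])
      reads <- tibble::tibble(
        id = sprintf("r%07d", seq_len(n_reads)), mate = NA_integer_,
        sequence = add_seq_errors(seqs, error_rate),
        quality = strrep("I", read_len),
        start = starts, end = starts + read_len - 1L, strand = strand
      )
    } else {
      n_pairs <- n_reads %/% 2L
      frag_len <- pmax(read_len, pmin(2L * insert_size,
                                      as.integer(round(stats::rnorm(n_pairs, insert_size, insert_sd)))))
      starts <- sample.int(L, n_pairs, replace = TRUE)
      strand <- sample(c("+", "-"), n_pairs, replace = TRUE)
      frags <- substring(doubled, starts, starts + frag_len - 1L)
      flip <- strand == "-"
      frags[flip] <- revcomp_vec(frags[flip])
      r1 <- substr(frags, 1L, read_len)
      r2 <- revcomp_vec(substring(frags, frag_len - read_len + 1L, frag_len))
      ids <- sprintf("p%07d", seq_len(n_pairs))
      reads <- tibble::tibble(
        id = c(ids, ids), mate = rep(1:2, each = n_pairs),
        sequence = add_seq_errors(c(r1, r2), error_rate),
        quality = strrep("I", read_len),
        start = c(starts, starts), end = c(starts, starts) + frag_len - 1L,
        strand = c(strand, strand)
      )
    }
    structure(list(reads = reads, pairing = pairing, read_len = read_len,
                   insert_size = if (pairing == "paired") insert_size else NA_integer_,
                   insert_sd = if (pairing == "paired") insert_sd else NA_integer_,
                   genome_len = L),
              class = "read_set")
  })
}

add_seq_errors <- function(seqs, error_rate) {
  if (error_rate == 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), error_rate)
  idx <- which(n_err > 0L)
  for (i in idx) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    for (j in pos) {
      old <- substr(seqs[i], j, j)
      substr(seqs[i], j, j) <- sample(setdiff(DNA_BASES, old), 1)
    }
  }
  seqs
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads (%s, %d bp)\n", nrow(x$reads), x$pairing,
              x$read_len))
  invisible(x)
}

#' Fragment a plastome into contigs
#'
#' Emulates the segmented output of de Bruijn graph assembly, which breaks
#' at the inverted repeats: `at_IR_boundaries` cuts at the four
#' single-copy/IR junctions, `random_k` at `k` random circle positions.
#' Contigs partition the circle (optionally with a fixed overlap into the
#' next contig) and carry truth provenance.
#'
#' @param p a `plastome` (with regions for `at_IR_boundaries`).
#' @param break_policy `"at_IR_boundaries"` or `"random_k"`.
#' @param k number of breakpoints for `random_k`.
#' @param overlap bases of overlap carried into the following contig.
#' @param seed integer seed.
#' @return a `contig_set`: list with a `contigs` tibble (id, sequence,
#'   truth_start, length) ordered around the circle.
#' @export
fragment_plastome <- function(p, break_policy = c("at_IR_boundaries", "random_k"),
                              k = 6L, overlap = 0L, seed = 1L) {
  break_policy <- match.arg(break_policy)
  stopifnot(inherits(p, "plastome"))
  L <- nchar(p$sequence)
  run_seeded(seed, {
    if (break_policy == "at_IR_boundaries") {
      if (is.null(p$regions)) stop("at_IR_boundaries requires a region table")
      breaks <- sort(p$regions$start)
    } else {
      k <- max(1L, as.integer(k))
      breaks <- sort(unique(sample.int(L, k)))
    }
    doubled <- paste0(p$sequence, p$sequence)
    n <- length(breaks)
    lens <- diff(c(breaks, breaks[1] + L))
    seqs <- substring(doubled, breaks, breaks + lens - 1L + overlap)
    tibble_out <- tibble::tibble(
      id = sprintf("contig%02d", seq_len(n)),
      sequence = seqs,
      truth_start = breaks,
      length = nchar(seqs)
    )
    structure(list(contigs = tibble_out, overlap = as.integer(overlap),
                   genome_len = L, break_policy = break_policy),
              class = "contig_set")
  })
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("<contig_set> %d contigs (%s, overlap %d bp)\n",
              nrow(x$contigs), x$break_policy, x$overlap))
  invisible(x)
}
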