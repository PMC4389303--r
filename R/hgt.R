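# Verification of putative foreign (mitochondrial-like) insertions:
# origin classification against sequence panels, junction read-depth
# profiling, base-composition contrast, and in-silico PCR.

#' Classify the origin of a putative foreign insert
#'
#' Aligns the insert locally against a plastid panel and a mitochondrial
#' panel and calls the panel of the highest-scoring hit. The call is
#' `"unclassified"` when the best hit has identity below `min_identity`
#' or an aligned span under `min_span` bp.
#'
#' @param insert DNA string (the putative foreign sequence).
#' @param plastid_panel,mito_panel named character vectors of panel
#'   sequences (or `DNAStringSet`).
#' @param min_identity,min_span acceptance thresholds.
#' @return a list (`origin_call`): `best_source` one of `"plastid_panel"`,
#'   `"mito_panel"`, `"unclassified"`; `identity`; `aligned_span`;
#'   `best_hit` (panel sequence name).
#' @export
classify_insert_origin <- function(insert, plastid_panel, mito_panel,
                                   min_identity = 0.70, min_span = 100L) {
  insert <- as.character(insert)
  if (length(insert) != 1L || nchar(insert) == 0L) stop("empty insert")
  as_panel <- function(x) {
    x <- vapply(as.character(x), toupper, character(1))
    if (is.null(names(x)) || any(names(x) == "")) names(x) <- paste0("seq", seq_along(x))
    x
  }
  panels <- list(plastid_panel = as_panel(plastid_panel),
                 mito_panel = as_panel(mito_panel))
  if (any(lengths(panels) == 0L)) stop("panels must be non-empty")

  q <- Biostrings::DNAString(toupper(insert))
  best <- list(score = -Inf, source = "unclassified", identity = 0,
               span = 0L, hit = NA_character_)
  for (src in names(panels)) {
    for (nm in names(panels[[src]])) {
      aln <- Biostrings::pairwiseAlignment(
        q, Biostrings::DNAString(panels[[src]][[nm]]), type = "local")
      sc <- Biostrings::score(aln)
      if (sc > best$score) {
        pr <- Biostrings::pattern(aln)
        span <- Biostrings::end(pr) - Biostrings::start(pr) + 1L
        best <- list(score = sc, source = src,
                     identity = Biostrings::pid(aln, type = "PID1") / 100,
                     span = span, hit = nm)
      }
    }
  }
  call <- if (best$identity < min_identity || best$span < min_span) {
    "unclassified"
  } else {
    best$source
  }
  list(best_source = call, identity = best$identity,
       aligned_span = best$span, best_hit = best$hit, score = best$score)
}

#' Junction coverage of an insertion
#'
#' Mean mapped depth in a window centred on each insert boundary,
#' expressed relative to the genome-wide mean. A boundary whose ratio
#' falls below `suspect_ratio` is flagged as a possible assembly artifact;
#' a genuine, clonally present insert shows junction depth comparable to
#' the rest of the genome.
#'
#' @param report an `assembly_report` from [assess_assembly()] (reads
#'   mapped to the genome that carries the insert).
#' @param insert integer `c(start, end)` of the insert on that genome.
#' @param window window width in bp centred on each boundary.
#' @param suspect_ratio flag threshold on depth ratio.
#' @return a list (`junction_report`): `upstream_depth`,
#'   `downstream_depth`, `genome_mean_depth`, `depth_ratio_up`,
#'   `depth_ratio_down`, `suspect_up`, `suspect_down`.
#' @export
junction_coverage <- function(report, insert, window = 100L,
                              suspect_ratio = 0.25) {
  stopifnot(inherits(report, "assembly_report"))
  depth <- report$per_position_depth
  L <- length(depth)
  if (window > L) stop("window exceeds genome length")
  insert <- as.integer(insert)
  if (insert[1] < 1L || insert[2] > L || insert[1] > insert[2]) {
    stop("insert interval outside genome")
  }
  win_mean <- function(centre) {
    idx <- (centre - window %/% 2L):(centre + window %/% 2L - 1L)
    idx <- ((idx - 1L) %% L) + 1L
    mean(depth[idx])
  }
  up <- win_mean(insert[1]); down <- win_mean(insert[2])
  gm <- report$mean_depth
  ru <- if (gm > 0) up / gm else 0
  rd <- if (gm > 0) down / gm else 0
  list(upstream_depth = up, downstream_depth = down,
       genome_mean_depth = gm, depth_ratio_up = ru, depth_ratio_down = rd,
       suspect_up = ru < suspect_ratio, suspect_down = rd < suspect_ratio)
}

#' AT-composition contrast of an insert against its host genome
#'
#' Exact base counts (no sampling): AT fraction of the insert interval and
#' of the remaining sequence. Mitochondrial-derived inserts in grass
#' plastomes are typically less AT rich (~55%) than the plastome
#' background (~61%).
#'
#' @param genome DNA string or `plastome`.
#' @param insert integer `c(start, end)` (1-based closed).
#' @return a list: `at_insert`, `at_rest`, `insert_len`, `rest_len`.
#' @export
composition_contrast <- function(genome, insert) {
  s <- toupper(if (inherits(genome, "plastome")) genome$sequence else genome)
  L <- nchar(s)
  insert <- as.integer(insert)
  if (insert[1] < 1L || insert[2] > L || insert[1] > insert[2]) {
    stop("insert interval outside genome")
  }
  if (insert[2] - insert[1] + 1L == 0L) stop("zero-length insert")
  if (insert[2] - insert[1] + 1L == L) stop("insert covers the whole genome; remainder undefined")
  ins <- substr(s, insert[1], insert[2])
  rest <- paste0(substr(s, 1L, insert[1] - 1L), substr(s, insert[2] + 1L, L))
  list(at_insert = at_fraction_of(ins), at_rest = at_fraction_of(rest),
       insert_len = nchar(ins), rest_len = nchar(rest))
}

# positions (5' end, forward-circle coordinates) where `primer` anneals,
# on both strands, with <= max_mismatch incompatible bases and the last
# `exact_3p` primer bases incompatibility-free
primer_sites <- function(template_chars, primer, max_mismatch = 0L,
                         exact_3p = 3L) {
  L <- length(template_chars)
  compat <- iupac_compat()
  pc <- chars(toupper(primer))
  plen <- length(pc)
  scan <- function(pc) {
    mm <- integer(L); mm3 <- integer(L)
    for (i in seq_len(plen)) {
      idx <- (((seq_len(L) + i - 2L) %% L) + 1L)
      bad <- !compat[cbind(template_chars[idx], pc[i])]
      mm <- mm + bad
      if (i > plen - exact_3p) mm3 <- mm3 + bad
    }
    which(mm <= max_mismatch & mm3 == 0L)
  }
  plus <- scan(pc)                      # 5' end at the match start
  rc <- rev(complement_chars(pc))
  minus_start <- scan(rc)               # match start of the revcomp text
  minus <- ((minus_start + plen - 1L - 1L) %% L) + 1L  # 5' end position
  list(plus = plus, minus = minus, plen = plen)
}

#' In-silico PCR on a circular template
#'
#' Finds annealing sites of the two primers on both strands (IUPAC
#' compatibility, at most `max_mismatch` incompatible bases, the 3' last
#' three bases exact) and reports a product for every convergent site
#' pair within `max_product` bp. Product length is the distance from the
#' forward 5' end to the reverse 5' end inclusive; wrap-around products
#' are found.
#'
#' @param template DNA string or `plastome`; circular.
#' @param forward,reverse primer sequences (IUPAC, 5'->3', 18-30 bp).
#' @param max_product maximum product length in bp.
#' @param max_mismatch tolerated incompatible bases per site.
#' @return tibble of products: `length`, `start`, `end` (5' ends of the
#'   two primers on the forward circle), `fwd_primer`, `rev_primer`.
#' @export
insilico_pcr <- function(template, forward, reverse, max_product = 5000L,
                         max_mismatch = 0L) {
  s <- toupper(if (inherits(template, "plastome")) template$sequence else template)
  for (pr in c(forward, reverse)) {
    n <- nchar(pr)
    if (n < 18L || n > 30L) stop("primer length must be 18-30 bp")
    if (!all(chars(toupper(pr)) %in% names(IUPAC_SETS))) {
      stop("primer must be IUPAC DNA")
    }
  }
  tc <- chars(s)
  L <- length(tc)
  sF <- primer_sites(tc, forward, max_mismatch)
  sR <- primer_sites(tc, reverse, max_mismatch)
  # convergent pairs: one site on the plus strand, one on the minus
  # strand downstream of it; either primer may provide either site
  combos <- list(
    list(p = sF$plus, m = sR$minus, fp = "forward", rp = "reverse"),
    list(p = sR$plus, m = sF$minus, fp = "reverse", rp = "forward")
  )
  out <- list()
  for (cb in combos) {
    for (a in cb$p) for (b in cb$m) {
      d <- ((b - a) %% L) + 1L
      if (d <= max_product && d >= max(sF$plen, sR$plen)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          length = d, start = a, end = b,
          fwd_primer = cb$fp, rev_primer = cb$rp)
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(length = integer(0), start = integer(0),
                          end = integer(0), fwd_primer = character(0),
                          rev_primer = character(0)))
  }
  res <- unique(do.call(rbind, out))
  res[order(res$start, res$length), ]
}
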