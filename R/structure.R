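# Quadripartite structure: inverted-repeat detection, canonical
# arrangement (LSC, IRb, SSC, IRa), and annotation transfer by local
# alignment against an annotated reference.

#' Detect the inverted repeat pair of a circular plastome
#'
#' Finds the maximal pair of disjoint intervals whose sequences are
#' reverse complements of one another (allowing up to `mismatch_frac` of
#' the genome length in substitutions), each at least `min_ir_len` long.
#' Detection is seeded with exact k-mer matches between the sequence and
#' its reverse complement, merged along anti-diagonals; the result is
#' rotation-invariant (the search is repeated on a half-genome rotation so
#' a copy spanning the origin is still seen intact).
#'
#' @param sequence DNA string or `plastome`; interpreted as circular.
#' @param min_ir_len minimum repeat length in bp.
#' @param mismatch_frac tolerated mismatch fraction of genome length.
#' @param k seed k-mer length.
#' @return a list with `found`; when `TRUE` also `ir1` and `ir2`
#'   (integer `c(start, end)`, 1-based closed, `end` may wrap past the
#'   origin so that `end < start`), `ir_len`, and the two single-copy gap
#'   lengths `sc_long` and `sc_short`. `ir1` is the copy that follows the
#'   long single-copy region (the IRb of a canonical genome).
#' @export
detect_inverted_repeats <- function(sequence, min_ir_len = 1000L,
                                    mismatch_frac = 0.001, k = 25L) {
  s <- toupper(if (inherits(sequence, "plastome")) sequence$sequence else sequence)
  L <- nchar(s)
  if (L < 4L * min_ir_len) stop("sequence shorter than 4 * min_ir_len")
  budget <- as.integer(floor(mismatch_frac * L))

  best <- NULL
  half <- L %/% 2L
  for (offset in c(0L, half)) {
    rot <- if (offset == 0L) s else
      paste0(substr(s, offset + 1L, L), substr(s, 1L, offset))
    cand <- best_ir_pair_linear(rot, min_ir_len, budget, k)
    if (is.null(cand)) next
    # map back to input coordinates
    cand$a1 <- ((cand$a1 + offset - 1L) %% L) + 1L
    cand$a2 <- ((cand$a2 + offset - 1L) %% L) + 1L
    if (is.null(best) || cand$len > best$len) best <- cand
  }
  if (is.null(best)) return(list(found = FALSE))

  wrap_end <- function(start, len) ((start + len - 1L - 1L) %% L) + 1L
  e1 <- wrap_end(best$a1, best$len); e2 <- wrap_end(best$a2, best$len)
  # single-copy gaps between the copies, walking the circle forward
  gap_after <- function(end_pos, next_start) (next_start - end_pos - 1L) %% L
  g12 <- gap_after(e1, best$a2)  # gap following copy1
  g21 <- gap_after(e2, best$a1)  # gap following copy2
  # the copy that follows the LONG gap is IRb in canonical orientation
  if (g12 >= g21) {
    # long gap lies after copy1, so copy2 follows it
    ir1 <- c(best$a2, e2); ir2 <- c(best$a1, e1)
    sc_long <- g12; sc_short <- g21
  } else {
    ir1 <- c(best$a1, e1); ir2 <- c(best$a2, e2)
    sc_long <- g21; sc_short <- g12
  }
  list(found = TRUE, ir1 = ir1, ir2 = ir2, ir_len = best$len,
       sc_long = sc_long, sc_short = sc_short)
}

# best reverse-complement repeat pair fully visible in the LINEAR string
best_ir_pair_linear <- function(s, min_ir_len, budget, k) {
  L <- nchar(s)
  n <- L - k + 1L
  km <- substring(s, 1:n, k:L)
  rc <- revcomp(s)
  kmr <- substring(rc, 1:n, k:L)
  # unique k-mers on each side (IR k-mers are unique within one strand)
  dupf <- duplicated(km) | duplicated(km, fromLast = TRUE)
  dupr <- duplicated(kmr) | duplicated(kmr, fromLast = TRUE)
  fi <- which(!dupf); ri <- which(!dupr)
  m <- match(km[fi], kmr[ri])
  keep <- !is.na(m)
  if (!any(keep)) return(NULL)
  i <- fi[keep]              # position in s
  j <- ri[m[keep]]           # position in revcomp(s)
  dg <- i - j                # constant along an exact run
  ord <- order(dg, i)
  i <- i[ord]; j <- j[ord]; dg <- dg[ord]

  run_id <- cumsum(c(TRUE, diff(dg) != 0L | diff(i) != 1L))
  run_start <- tapply(i, run_id, min)
  run_end <- tapply(i, run_id, max)
  run_dg <- tapply(dg, run_id, min)
  runs <- data.frame(start = as.integer(run_start),
                     end = as.integer(run_end) + k - 1L,
                     dg = as.integer(run_dg))
  runs <- runs[order(runs$dg, runs$start), ]

  # merge runs on the same anti-diagonal within the mismatch budget
  merged <- list()
  cur <- NULL
  flush <- function(cur) if (!is.null(cur)) merged[[length(merged) + 1L]] <<- cur
  for (r in seq_len(nrow(runs))) {
    row <- runs[r, ]
    if (!is.null(cur) && row$dg == cur$dg) {
      gap_mm <- max(1L, row$start - cur$end - 1L - (k - 1L) + 1L)
      if (row$start - cur$end - 1L <= 3L * k && cur$mm + gap_mm <= budget) {
        cur$end <- row$end
        cur$mm <- cur$mm + gap_mm
        next
      }
    }
    flush(cur)
    cur <- list(start = row$start, end = row$end, dg = row$dg, mm = 0L)
  }
  flush(cur)

  best <- NULL
  for (cu in merged) {
    len <- cu$end - cu$start + 1L
    if (len < min_ir_len) next
    # partner interval of s[start..end] under the reverse complement:
    # position i in s pairs with position L - (i - dg) + 1
    p_start <- L - (cu$end - cu$dg) + 1L
    p_end <- L - (cu$start - cu$dg) + 1L
    if (p_start == cu$start && p_end == cu$end) {
      # the run is its own partner: a self-reverse-complementary segment
      # whose first half pairs with its second half (adjacent IR copies)
      half <- len %/% 2L
      if (half >= min_ir_len &&
          (is.null(best) || half > best$len)) {
        best <- list(a1 = cu$start, a2 = cu$end - half + 1L, len = half)
      }
      next
    }
    # deduplicate the symmetric hit and reject self-overlap
    if (p_start <= cu$start) next
    if (p_start <= cu$end) next
    if (is.null(best) || len > best$len) {
      best <- list(a1 = cu$start, a2 = p_start, len = len)
    }
  }
  best
}

#' Arrange a plastome in canonical quadripartite order
#'
#' Rotates (and if necessary reflects) the circle so that the sequence
#' begins with the large single-copy region followed by IRb, the small
#' single-copy region, and IRa. The strand is chosen so that the
#' orientation marker gene lies on the forward strand when features are
#' present; otherwise the lexicographically smaller of the two candidate
#' arrangements is taken, making the operation a deterministic projection
#' (idempotent, invariant under rotation and reflection of the input).
#'
#' @param p a `plastome`.
#' @param marker orientation marker gene name (default `"psbA"`).
#' @param min_ir_len passed to [detect_inverted_repeats()].
#' @return the canonical `plastome` with a rebuilt region table. Genomes
#'   without a detectable IR are returned unchanged with attribute
#'   `no_ir = TRUE` and a warning.
#' @export
canonicalize <- function(p, marker = "psbA", min_ir_len = 1000L) {
  stopifnot(inherits(p, "plastome"))
  det <- detect_inverted_repeats(p$sequence, min_ir_len = min_ir_len)
  if (!det$found) {
    warning("no inverted repeat detected; returning input unchanged")
    attr(p, "no_ir") <- TRUE
    return(p)
  }
  L <- nchar(p$sequence)
  # LSC starts right after IRa (= copy preceding the long gap). det$ir1 is
  # the copy following the long gap (IRb); IRa is the other copy.
  lsc_start <- ((det$ir2[2] - 1L + 1L) %% L) + 1L
  cand1 <- rotate_plastome(p, lsc_start)
  cand1$regions <- build_region_table(det$sc_long, det$ir_len, det$sc_short)

  pr <- revcomp_plastome(p)
  # in the reflected genome the long gap maps to [L-e+1, L-s+1]; its
  # canonical start is the position after the reflected IRa
  lsc_end_orig <- ((lsc_start + det$sc_long - 1L - 1L) %% L) + 1L
  lsc_start_rc <- L - lsc_end_orig + 1L
  cand2 <- rotate_plastome(pr, lsc_start_rc)
  cand2$regions <- build_region_table(det$sc_long, det$ir_len, det$sc_short)

  pick_by_marker <- function() {
    for (cand in list(cand1, cand2)) {
      f <- cand$features
      if (!is.null(f) && marker %in% f$name) {
        if (f$strand[match(marker, f$name)] == "+") return(cand)
      }
    }
    NULL
  }
  out <- pick_by_marker()
  if (is.null(out)) {
    out <- if (cand1$sequence <= cand2$sequence) cand1 else cand2
  }
  out
}

build_region_table <- function(lsc_len, ir_len, ssc_len) {
  tibble::tibble(
    region = c("LSC", "IRb", "SSC", "IRa"),
    start = c(1L, lsc_len + 1L, lsc_len + ir_len + 1L,
              lsc_len + ir_len + ssc_len + 1L),
    end = c(lsc_len, lsc_len + ir_len, lsc_len + ir_len + ssc_len,
            lsc_len + 2L * ir_len + ssc_len)
  )
}

#' Transfer annotations from a reference plastome
#'
#' For every reference feature, candidate locations in the target are
#' seeded by exact sub-sequence matches (both strands, so IR-resident
#' features reach both repeat copies), and the feature is aligned locally
#' against each candidate window. The feature is transferred iff percent
#' identity over the aligned span is at least `min_similarity` and the
#' aligned span covers at least `min_span_frac` of the feature length.
#'
#' @param target the `plastome` to annotate.
#' @param reference an annotated `plastome`.
#' @param min_similarity minimum percent identity as a proportion
#'   (default 0.70).
#' @param min_span_frac minimum aligned-span fraction of feature length.
#' @return the target `plastome` with transferred features; attribute
#'   `untransferred` lists reference feature names that found no
#'   acceptable placement.
#' @export
transfer_annotations <- function(target, reference, min_similarity = 0.70,
                                 min_span_frac = 0.90) {
  stopifnot(inherits(target, "plastome"), inherits(reference, "plastome"))
  if (is.null(reference$features) || nrow(reference$features) == 0L) {
    stop("reference has no features")
  }
  tg <- target$sequence
  tg_dna <- Biostrings::DNAString(tg)
  feats <- reference$features
  out <- list(); untransferred <- character(0)

  for (i in seq_len(nrow(feats))) {
    ft <- feats[i, ]
    fseq <- substr(reference$sequence, ft$start, ft$end)
    if (ft$strand == "-") fseq <- revcomp(fseq)  # coding-strand sequence
    hits <- transfer_one(fseq, tg, tg_dna, min_similarity, min_span_frac)
    if (nrow(hits) == 0L) {
      untransferred <- c(untransferred, ft$name)
    } else {
      # `hits$strand` is the genomic strand at the target locus (the
      # feature was queried as its coding-strand sequence)
      hits$name <- ft$name; hits$kind <- ft$kind
      out[[length(out) + 1L]] <- hits[, c("name", "kind", "strand",
                                          "start", "end", "identity")]
    }
  }
  features <- if (length(out)) do.call(rbind, out) else
    tibble::tibble(name = character(0), kind = character(0),
                   strand = character(0), start = integer(0),
                   end = integer(0), identity = numeric(0))
  # both annotated copies of an IR feature resolve to the same placements
  features <- unique(features)
  features <- features[order(features$start), ]
  res <- plastome(target$sequence, regions = target$regions,
                  features = features)
  attr(res, "untransferred") <- unique(untransferred)
  res
}

# candidate placements of one feature sequence in the target
transfer_one <- function(fseq, tg, tg_dna, min_similarity, min_span_frac) {
  flen <- nchar(fseq)
  seed_len <- min(25L, flen)
  offs <- unique(pmax(1L, c(1L, flen %/% 2L - seed_len %/% 2L,
                            flen - seed_len + 1L)))
  cands <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") fseq else revcomp(fseq)
    for (off in offs) {
      seed <- substr(q, off, off + seed_len - 1L)
      m <- Biostrings::matchPattern(Biostrings::DNAString(seed), tg_dna)
      for (h in IRanges::start(m)) {
        est <- h - off + 1L
        cands[[length(cands) + 1L]] <- list(strand = strand, est = est)
      }
    }
  }
  if (length(cands) == 0L) {
    return(tibble::tibble(strand = character(0), start = integer(0),
                          end = integer(0), identity = numeric(0)))
  }
  cd <- unique(do.call(rbind, lapply(cands, as.data.frame)))
  # cluster nearby estimates (same placement seeded by several seeds)
  cd <- cd[order(cd$strand, cd$est), ]
  keep <- c(TRUE, diff(cd$est) > 200L | cd$strand[-1] != cd$strand[-nrow(cd)])
  cd <- cd[keep, , drop = FALSE]

  rows <- list()
  for (r in seq_len(nrow(cd))) {
    win_s <- max(1L, cd$est[r] - 200L)
    win_e <- min(nchar(tg), cd$est[r] + flen + 200L)
    win <- substr(tg, win_s, win_e)
    q <- if (cd$strand[r] == "+") fseq else revcomp(fseq)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(q), Biostrings::DNAString(win), type = "local")
    ident <- Biostrings::pid(aln, type = "PID1") / 100
    span <- Biostrings::nchar(Biostrings::pattern(aln))
    if (ident >= min_similarity && span >= min_span_frac * flen) {
      s_start <- win_s + IRanges::start(Biostrings::Views(aln)) - 1L
      s_end <- win_s + IRanges::end(Biostrings::Views(aln)) - 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        strand = cd$strand[r], start = s_start, end = s_end,
        identity = ident)
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(strand = character(0), start = integer(0),
                          end = integer(0), identity = numeric(0)))
  }
  out <- do.call(rbind, rows)
  unique(out)
}
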