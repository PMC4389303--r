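#' Specification of a structural variant to plant
#'
#' @param kind one of `"insertion"`, `"deletion"`, `"inversion"`.
#' @param locus either an intergenic spacer name `"geneA-geneB"` (gene order
#'   insensitive) or an integer coordinate on the genome the variant is
#'   planted into.
#' @param length variant length in bp (> 0).
#' @param payload_at_fraction AT fraction of inserted sequence (insertions
#'   only); foreign, mitochondrial-like inserts are typically less AT rich
#'   (~0.55) than the plastome background (~0.61).
#' @param flank_repeat optional IUPAC motif (inversions only): a concrete
#'   instance is planted immediately 5' of the inverted interval and its
#'   reverse complement immediately 3', emulating the stem-loop signature
#'   of recombination-mediated inversions.
#' @return an object of class `variant_spec`.
#' @export
variant_spec <- function(kind = c("insertion", "deletion", "inversion"),
                         locus, length, payload_at_fraction = 0.55,
                         flank_repeat = NULL) {
  kind <- match.arg(kind)
  length <- as.integer(length)
  if (length <= 0L) stop("variant length must be > 0")
  if (payload_at_fraction < 0 || payload_at_fraction > 1) {
    stop("payload_at_fraction must be in [0, 1]")
  }
  if (!is.null(flank_repeat)) {
    if (kind != "inversion") stop("flank_repeat applies to inversions only")
    flank_repeat <- toupper(flank_repeat)
    if (!all(chars(flank_repeat) %in% names(IUPAC_SETS))) {
      stop("flank_repeat must be an IUPAC DNA motif")
    }
  }
  structure(list(kind = kind, locus = locus, length = length,
                 payload_at_fraction = payload_at_fraction,
                 flank_repeat = flank_repeat),
            class = "variant_spec")
}

# Resolve a spacer name "geneA-geneB" to the interval strictly between the
# two genes (first adjacent occurrence in genome order; for IR spacers this
# is the IRb copy in a canonical genome).
resolve_spacer <- function(p, locus) {
  if (is.numeric(locus)) {
    pos <- as.integer(locus)
    if (pos < 1L || pos > nchar(p$sequence)) stop("locus coordinate outside genome")
    return(c(start = pos, end = pos))
  }
  parts <- strsplit(locus, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("locus must be 'geneA-geneB' or a coordinate")
  f <- p$features
  if (is.null(f) || nrow(f) == 0) stop("plastome has no features; cannot resolve ", locus)
  f <- f[order(f$start), ]
  for (i in seq_len(nrow(f) - 1L)) {
    pair <- c(f$name[i], f$name[i + 1L])
    if (setequal(pair, parts)) {
      return(c(start = unname(f$end[i]) + 1L, end = unname(f$start[i + 1L]) - 1L))
    }
  }
  stop("locus not found: ", locus)
}

in_region <- function(p, pos, region) {
  if (is.null(p$regions)) return(FALSE)
  iv <- region_interval(p, region)
  pos >= iv["start"] && pos <= iv["end"]
}

#' Plant structural variants into a plastome
#'
#' Applies the specified insertions, deletions and inversions and returns
#' the edited genome together with a truth table carrying exact post-edit
#' coordinates. Insertions that fall inside an inverted repeat are mirrored
#' into the other IR copy (reverse-complemented) unless `mirror_ir = FALSE`.
#' An inversion with a `flank_repeat` motif has a concrete instance of the
#' motif planted immediately upstream and its reverse complement
#' immediately downstream of the inverted interval.
#'
#' @param p a `plastome`.
#' @param specs a list of [variant_spec()] objects (a single spec may be
#'   passed unwrapped).
#' @param seed integer seed for payload sequence generation.
#' @param mirror_ir mirror IR-resident insertions into both repeat copies.
#' @return a list with elements `plastome` (the edited genome), `truth`
#'   (a tibble of variant records: kind, locus, start, end, length,
#'   mirrored, flank_repeat_len) and `ancestral` (the input genome with
#'   only the inversion flank repeats planted — the pre-variant state to
#'   compare the edited genome against).
#' @export
plant_variants <- function(p, specs, seed = 1L, mirror_ir = TRUE) {
  stopifnot(inherits(p, "plastome"))
  if (inherits(specs, "variant_spec")) specs <- list(specs)
  if (length(specs) == 0L) {
    return(list(plastome = p, truth = empty_truth(), ancestral = p))
  }
  stopifnot(all(vapply(specs, inherits, logical(1), "variant_spec")))
  run_seeded(seed, plant_variants_impl(p, specs, mirror_ir))
}

empty_truth <- function() {
  tibble::tibble(kind = character(0), locus = character(0),
                 start = integer(0), end = integer(0), length = integer(0),
                 mirrored = logical(0), flank_repeat_len = integer(0))
}

instantiate_motif <- function(motif) {
  paste(vapply(chars(motif), function(cd) {
    set <- IUPAC_SETS[[cd]]
    if (length(set) == 1L) set else sample(set, 1)
  }, character(1)), collapse = "")
}

plant_variants_impl <- function(p, specs, mirror_ir) {
  L <- nchar(p$sequence)
  edits <- list()   # each: kind, start, end (pre-edit), payload, locus, mirrored, flank_len
  add_edit <- function(e) edits[[length(edits) + 1L]] <<- e

  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    iv <- resolve_spacer(p, sp$locus)
    mid <- as.integer(floor((iv["start"] + iv["end"]) / 2))
    locus_name <- if (is.numeric(sp$locus)) as.character(sp$locus) else sp$locus
    if (sp$kind == "insertion") {
      payload <- rand_dna(sp$length, sp$payload_at_fraction)
      add_edit(list(kind = "insertion", start = mid, end = mid, payload = payload,
                    locus = locus_name, mirrored = FALSE, flank_len = NA_integer_))
      if (mirror_ir && !is.null(p$regions) &&
          (in_region(p, mid, "IRb") || in_region(p, mid, "IRa"))) {
        this_ir <- if (in_region(p, mid, "IRb")) "IRb" else "IRa"
        other_ir <- if (this_ir == "IRb") "IRa" else "IRb"
        b <- region_interval(p, this_ir); a <- region_interval(p, other_ir)
        # insertion after `mid` mirrors to insertion after mirror(mid + 1)
        mpos <- a["start"] + (b["end"] - (mid + 1L))
        add_edit(list(kind = "insertion", start = unname(mpos), end = unname(mpos),
                      payload = revcomp(payload), locus = locus_name,
                      mirrored = TRUE, flank_len = NA_integer_))
      }
    } else if (sp$kind == "deletion") {
      s <- mid - as.integer(floor(sp$length / 2)) + 1L
      e <- s + sp$length - 1L
      if (s < 1L || e > L) stop("deletion interval outside genome")
      add_edit(list(kind = "deletion", start = s, end = e, payload = "",
                    locus = locus_name, mirrored = FALSE, flank_len = NA_integer_))
    } else {
      s <- mid - as.integer(floor(sp$length / 2)) + 1L
      e <- s + sp$length - 1L
      # slide to a position where the inversion breakpoints are unambiguous
      # (first base must not equal the complement of the last base, or the
      # inverted interval has more than one equally valid placement)
      for (off in c(0L, 1L, -1L, 2L, -2L, 3L, -3L, 4L, -4L, 5L, -5L)) {
        s2 <- s + off; e2 <- e + off
        if (s2 < 1L || e2 > L) next
        b1 <- substr(p$sequence, s2, s2); b2 <- substr(p$sequence, e2, e2)
        if (b1 != IUPAC_COMP[b2]) { s <- s2; e <- e2; break }
      }
      flank_len <- if (is.null(sp$flank_repeat)) NA_integer_ else nchar(sp$flank_repeat)
      if (!is.na(flank_len) && (s - flank_len < 1L || e + flank_len > L)) {
        stop("inversion flanks outside genome")
      }
      if (s < 1L || e > L) stop("inversion interval outside genome")
      add_edit(list(kind = "inversion", start = s, end = e, payload = "",
                    locus = locus_name, mirrored = FALSE, flank_len = flank_len,
                    flank_motif = sp$flank_repeat))
    }
  }

  # overlap check on pre-edit footprints (insertion points count as 1 bp)
  ord <- order(vapply(edits, function(e) e$start, numeric(1)))
  edits <- edits[ord]
  foot <- t(vapply(edits, function(e) c(e$start, e$end), numeric(2)))
  if (length(edits) > 1L) {
    for (j in 2:length(edits)) {
      if (foot[j, 1] <= foot[j - 1L, 2]) stop("overlapping variant intervals")
    }
  }

  # plant inversion flank repeats (sequence overwrite, no length change)
  s0 <- p$sequence
  for (e in edits) {
    if (e$kind == "inversion" && !is.na(e$flank_len)) {
      up <- instantiate_motif(e$flank_motif)
      substr(s0, e$start - e$flank_len, e$start - 1L) <- up
      substr(s0, e$end + 1L, e$end + e$flank_len) <- revcomp(up)
      # break symmetry just outside the planted pair so the maximal
      # inverted flank equals the motif length
      pa <- e$start - e$flank_len - 1L; pb <- e$end + e$flank_len + 1L
      if (pa >= 1L && pb <= L) {
        while (substr(s0, pa, pa) == IUPAC_COMP[substr(s0, pb, pb)]) {
          substr(s0, pa, pa) <- sample(DNA_BASES, 1)
        }
      }
    }
  }

  # stitch the edited sequence and compute post-edit coordinates
  pieces <- character(0)
  truth <- empty_truth()
  cursor <- 1L
  delta <- 0L
  for (e in edits) {
    if (e$kind == "insertion") {
      pieces <- c(pieces, substr(s0, cursor, e$start), e$payload)
      post_start <- e$start + delta + 1L
      post_end <- post_start + nchar(e$payload) - 1L
      truth <- rbind(truth, tibble::tibble(
        kind = "insertion", locus = e$locus, start = post_start, end = post_end,
        length = nchar(e$payload), mirrored = e$mirrored,
        flank_repeat_len = e$flank_len))
      delta <- delta + nchar(e$payload)
      cursor <- e$start + 1L
    } else if (e$kind == "deletion") {
      pieces <- c(pieces, substr(s0, cursor, e$start - 1L))
      post_pos <- e$start + delta - 1L  # base immediately left of the breakpoint
      truth <- rbind(truth, tibble::tibble(
        kind = "deletion", locus = e$locus, start = post_pos, end = post_pos,
        length = e$end - e$start + 1L, mirrored = FALSE,
        flank_repeat_len = NA_integer_))
      delta <- delta - (e$end - e$start + 1L)
      cursor <- e$end + 1L
    } else {
      pieces <- c(pieces, substr(s0, cursor, e$start - 1L),
                  revcomp(substr(s0, e$start, e$end)))
      truth <- rbind(truth, tibble::tibble(
        kind = "inversion", locus = e$locus, start = e$start + delta,
        end = e$end + delta, length = e$end - e$start + 1L, mirrored = FALSE,
        flank_repeat_len = e$flank_len))
      cursor <- e$end + 1L
    }
  }
  pieces <- c(pieces, substr(s0, cursor, L))
  s1 <- paste(pieces, collapse = "")

  # report insertions at their canonical (leftmost) placement, the same
  # normalization the detector applies, so truth and calls coincide even
  # when boundary bases repeat
  ins_rows <- which(truth$kind == "insertion")
  for (i in ins_rows) {
    iv <- left_normalize_interval(s1, truth$start[i], truth$end[i])
    truth$start[i] <- iv[1]; truth$end[i] <- iv[2]
  }

  regions <- remap_regions(p$regions, edits)
  if (!is.null(regions)) {
    w <- regions$end - regions$start + 1L
    if (w[regions$region == "IRb"] != w[regions$region == "IRa"]) {
      # an unmirrored IR edit leaves unequal repeat copies; the
      # quadripartite table no longer applies
      regions <- NULL
    }
  }
  list(
    plastome = plastome(s1,
                        regions = regions,
                        features = remap_features(p$features, edits)),
    truth = truth,
    # the input genome with only the flank-repeat overwrites applied: the
    # ancestral state (flanking repeats pre-date the inversion they mediate)
    ancestral = plastome(s0, regions = p$regions, features = p$features)
  )
}

edit_delta <- function(e) {
  switch(e$kind,
         insertion = nchar(e$payload),
         deletion = -(e$end - e$start + 1L),
         inversion = 0L)
}

# All interval remapping is computed against ORIGINAL coordinates (edits
# are pairwise disjoint), accumulating start/end shifts, then applied once.
remap_regions <- function(regions, edits) {
  if (is.null(regions)) return(NULL)
  add_s <- integer(nrow(regions)); add_e <- integer(nrow(regions))
  for (e in edits) {
    d <- edit_delta(e)
    if (d == 0L) next
    anchor <- e$start  # edits lie strictly inside one region
    grow <- regions$start <= anchor & regions$end >= anchor
    add_e[grow] <- add_e[grow] + d
    after <- regions$start > anchor
    add_s[after] <- add_s[after] + d
    add_e[after] <- add_e[after] + d
  }
  out <- regions
  out$start <- out$start + add_s
  out$end <- out$end + add_e
  out
}

remap_features <- function(features, edits) {
  if (is.null(features) || nrow(features) == 0) return(features)
  out <- features
  n <- nrow(out)
  add_s <- integer(n); add_e <- integer(n)
  drop <- rep(FALSE, n)
  for (e in edits) {
    d <- edit_delta(e)
    if (e$kind == "deletion") {
      drop <- drop | (out$start <= e$end & out$end >= e$start)
      after <- out$start > e$end
      add_s[after] <- add_s[after] + d
      add_e[after] <- add_e[after] + d
      span <- out$start < e$start & out$end > e$end
      add_e[span] <- add_e[span] + d
    } else if (e$kind == "insertion") {
      # insertion after position e$start
      after <- out$start > e$start
      add_s[after] <- add_s[after] + d
      add_e[after] <- add_e[after] + d
      span <- out$start <= e$start & out$end > e$start
      add_e[span] <- add_e[span] + d
    } else {
      inside <- out$start >= e$start & out$end <= e$end
      if (any(inside)) {
        ns <- e$start + (e$end - out$end[inside])
        ne <- e$start + (e$end - out$start[inside])
        out$start[inside] <- ns; out$end[inside] <- ne
        out$strand[inside] <- ifelse(out$strand[inside] == "+", "-", "+")
      }
    }
  }
  out$start <- out$start + add_s
  out$end <- out$end + add_e
  out <- out[!drop, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}
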