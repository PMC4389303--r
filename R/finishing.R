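# Assembly finishing: anchored scaffolding of contigs against a reference,
# gap closure by exact end-anchored overlaps with mate verification, and
# assessment of the finished circle by read re-mapping.

#' Scaffold contigs against an annotated reference
#'
#' Places each contig by its longest collinear chain of unique shared
#' anchor k-mers with the reference; orientation is the strand of the
#' winning chain (forward preferred on ties, which resolves the inherent
#' two-fold ambiguity of inverted-repeat contigs deterministically).
#' Contigs with no unique anchors are reported unplaced. Gap lengths are
#' estimated from the reference distance between adjacent placements.
#'
#' @param contigs a `contig_set` (or tibble with `id` and `sequence`).
#' @param reference a `plastome` or DNA string.
#' @param anchor_k anchor k-mer length (>= 15).
#' @return a `scaffold`: list with `placements` (tibble: id, sequence in
#'   reference orientation, ref_start, ref_end, orientation), `gaps`
#'   (tibble: left_id, right_id, est_len; the last row wraps the circle)
#'   and `unplaced` (character vector of contig ids).
#' @export
scaffold_contigs <- function(contigs, reference, anchor_k = 31L) {
  if (anchor_k < 15L) stop("anchor_k must be >= 15")
  ctg <- if (inherits(contigs, "contig_set")) contigs$contigs else tibble::as_tibble(contigs)
  if (nrow(ctg) == 0L) stop("contigs must be non-empty")
  ref <- if (inherits(reference, "plastome")) reference$sequence else toupper(reference)
  L <- nchar(ref)

  place_one <- function(s) {
    fwd <- chain_anchors(s, ref, anchor_k)
    rev <- chain_anchors(revcomp(s), ref, anchor_k)
    if (length(fwd$qpos) == 0L && length(rev$qpos) == 0L) return(NULL)
    if (length(fwd$qpos) >= length(rev$qpos)) {
      list(orientation = "+", seq = s,
           ref_start = min(fwd$tpos), ref_end = max(fwd$tpos) + anchor_k - 1L)
    } else {
      list(orientation = "-", seq = revcomp(s),
           ref_start = min(rev$tpos), ref_end = max(rev$tpos) + anchor_k - 1L)
    }
  }

  placed <- list(); unplaced <- character(0)
  for (i in seq_len(nrow(ctg))) {
    pl <- place_one(ctg$sequence[i])
    if (is.null(pl)) {
      unplaced <- c(unplaced, ctg$id[i])
    } else {
      placed[[length(placed) + 1L]] <- tibble::tibble(
        id = ctg$id[i], sequence = pl$seq,
        ref_start = pl$ref_start, ref_end = pl$ref_end,
        orientation = pl$orientation)
    }
  }
  if (length(placed) == 0L) stop("unscaffoldable: no contig shares unique anchors with the reference")
  placements <- do.call(rbind, placed)
  placements <- placements[order(placements$ref_start), ]

  n <- nrow(placements)
  gaps <- tibble::tibble(
    left_id = placements$id,
    right_id = placements$id[c(seq_len(n)[-1], 1L)],
    est_len = pmax(0L, c(placements$ref_start[-1], placements$ref_start[1] + L) -
                     placements$ref_end - 1L)
  )
  structure(list(placements = placements, gaps = gaps, unplaced = unplaced,
                 reference_len = L),
            class = "scaffold")
}

#' @export
print.scaffold <- function(x, ...) {
  cat(sprintf("<scaffold> %d placed contig(s), %d unplaced, %d junction(s)\n",
              nrow(x$placements), length(x$unplaced), nrow(x$gaps)))
  invisible(x)
}

# index evidence sequences by their first `min_overlap` bases
# (environment hash: constant-time lookup)
build_prefix_index <- function(seqs) {
  pref <- substr(seqs, 1L, attr(seqs, "pk"))
  list2env(split(seq_along(seqs), pref), hash = TRUE,
           size = length(seqs) * 2L)
}

# all admissible end-anchored overlaps of `left`'s terminus with evidence
# prefixes: overlap >= min_overlap, zero mismatches, anchored at the
# evidence 5' end. Returns a tibble sorted by decreasing overlap, id.
admissible_overlaps <- function(left, ev_seqs, ev_index, ev_id, min_overlap) {
  ll <- nchar(left)
  if (length(ev_seqs) == 0L) {
    return(tibble::tibble(j = integer(0), o = integer(0), id = character(0)))
  }
  from_o <- min(ll, max(nchar(ev_seqs)) - 1L)
  if (from_o < min_overlap) {
    return(tibble::tibble(j = integer(0), o = integer(0), id = character(0)))
  }
  hits <- list()
  for (o in seq(from = from_o, to = min_overlap)) {
    key <- substr(left, ll - o + 1L, ll - o + min_overlap)
    cand <- get0(key, envir = ev_index, inherits = FALSE)
    if (is.null(cand)) next
    suff <- substr(left, ll - o + 1L, ll)
    for (j in cand) {
      if (nchar(ev_seqs[j]) <= o) next           # no extension to offer
      if (substr(ev_seqs[j], 1L, o) == suff) {
        hits[[length(hits) + 1L]] <- list(j = j, o = o)
      }
    }
  }
  if (length(hits) == 0L) {
    return(tibble::tibble(j = integer(0), o = integer(0), id = character(0)))
  }
  out <- tibble::tibble(j = vapply(hits, `[[`, integer(1), "j"),
                        o = vapply(hits, `[[`, integer(1), "o"))
  out$id <- ev_id[out$j]
  out[order(-out$o, out$id), ]
}

# does `left` already overlap `right` end-to-start by >= min_overlap with
# zero mismatches? returns the overlap length or 0
direct_overlap <- function(left, right, min_overlap, search_window = 5000L) {
  seed <- substr(left, nchar(left) - min_overlap + 1L, nchar(left))
  win <- substr(right, 1L, min(nchar(right), search_window))
  pos <- -1L
  m <- gregexpr(seed, win, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(0L)
  for (p in as.integer(m)) {
    o <- p + min_overlap - 1L
    if (o > nchar(left)) next
    if (substr(left, nchar(left) - o + 1L, nchar(left)) == substr(right, 1L, o)) {
      return(o)
    }
  }
  0L
}

#' Close scaffold gaps with contig and read evidence
#'
#' Extends each junction base-by-base using evidence sequences whose
#' terminus overlaps the growing flank by at least `min_overlap` bp with
#' zero mismatches (the overlap must be anchored at one end of the
#' evidence). When several admissible evidences cover the next base, the
#' longest-overlap evidence supplies it and must agree with the strict
#' majority of the others; an unresolvable conflict leaves the gap open
#' and flagged. Paired reads are admissible only if the mate lies within
#' three standard deviations of the expected insert size in convergent
#' orientation. Iteration proceeds until the circle closes (the duplicated
#' junction overlap is collapsed once) or no admissible evidence remains.
#'
#' @param scaffold a `scaffold` from [scaffold_contigs()].
#' @param reads a `read_set`, or `NULL`.
#' @param contigs additional evidence contigs (e.g. unplaced ones), or `NULL`.
#' @param min_overlap minimum exact overlap in bp (default 20).
#' @param max_extension per-junction extension cap in bp.
#' @return a `plastome` when the circle closes; otherwise a list of the
#'   merged pieces. Both carry a `gap_report` attribute (tibble: junction,
#'   status) describing every junction.
#' @export
close_gaps <- function(scaffold, reads = NULL, contigs = NULL,
                       min_overlap = 20L, max_extension = 2000L) {
  stopifnot(inherits(scaffold, "scaffold"))
  if (min_overlap < 1L) stop("min_overlap must be >= 1")

  ev_seqs <- character(0); ev_id <- character(0); ev_mate <- character(0)
  paired <- !is.null(reads) && reads$pairing == "paired"
  if (!is.null(reads)) {
    r <- reads$reads
    ev_seqs <- c(r$sequence, revcomp_vec(r$sequence))
    ev_id <- c(paste0(r$id, "/f"), paste0(r$id, "/r"))
    if (paired) {
      # mate lookup: same pair id, other mate
      key <- paste0(r$id, ".", r$mate)
      other <- paste0(r$id, ".", 3L - r$mate)
      mate_seq <- r$sequence[match(other, key)]
      ev_mate <- c(mate_seq, mate_seq)
    }
  }
  if (!is.null(contigs)) {
    cc <- if (inherits(contigs, "contig_set")) contigs$contigs else tibble::as_tibble(contigs)
    ev_seqs <- c(ev_seqs, cc$sequence,
                 revcomp_vec(cc$sequence))
    ev_id <- c(ev_id, paste0(cc$id, "/f"), paste0(cc$id, "/r"))
    if (paired) ev_mate <- c(ev_mate, rep(NA_character_, 2L * nrow(cc)))
  }
  if (length(ev_seqs) == 0L) ev_index <- list()
  else {
    attr(ev_seqs, "pk") <- min_overlap
    ev_index <- build_prefix_index(ev_seqs)
  }

  # a paired evidence read is admissible only if its mate maps in
  # convergent orientation within 3 sd of the expected insert size; the
  # mate may lie on either side of the junction, so both flanks are
  # searched. `o` is the evidence overlap with the left flank.
  mate_ok <- function(j, o, left, right) {
    if (!paired) return(TRUE)
    m <- ev_mate[j]
    if (is.na(m)) return(TRUE)
    ins <- reads$insert_size; sd3 <- 3L * reads$insert_sd
    rl <- nchar(m)
    wl <- min(nchar(left), ins + sd3 + rl)
    wr <- min(nchar(right), ins + sd3 + rl)
    up <- substr(left, nchar(left) - wl + 1L, nchar(left))
    ctx <- paste0(up, substr(right, 1L, wr))
    epos <- wl - o + 1L  # evidence 5' position within ctx
    # mate reverse-complemented downstream of the evidence read
    q <- as.integer(gregexpr(revcomp(m), ctx, fixed = TRUE)[[1]])
    for (p in q[q > 0L]) {
      frag <- p + rl - epos
      if (p >= epos && frag >= ins - sd3 && frag <= ins + sd3) return(TRUE)
    }
    # mate forward, upstream of the evidence read
    q <- as.integer(gregexpr(m, ctx, fixed = TRUE)[[1]])
    for (p in q[q > 0L]) {
      frag <- epos + nchar(ev_seqs[j]) - p
      if (p <= epos && frag >= ins - sd3 && frag <= ins + sd3) return(TRUE)
    }
    FALSE
  }

  pieces <- scaffold$placements$sequence
  piece_ids <- scaffold$placements$id
  status <- character(0)

  admissible_filtered <- function(left, right) {
    adm <- admissible_overlaps(left, ev_seqs, ev_index, ev_id, min_overlap)
    if (nrow(adm) > 0L && paired) {
      keep <- mapply(mate_ok, adm$j, adm$o,
                     MoreArgs = list(left = left, right = right))
      adm <- adm[as.logical(keep), , drop = FALSE]
    }
    adm
  }

  # one consensus base appended to `left`, or a terminal status
  extend_base <- function(left, right) {
    adm <- admissible_filtered(left, right)
    if (nrow(adm) == 0L) return(list(status = "no_evidence"))
    # candidate next bases, one per admissible evidence
    nb <- substr(ev_seqs[adm$j], adm$o + 1L, adm$o + 1L)
    tab <- sort(table(nb), decreasing = TRUE)
    if (length(tab) > 1L && tab[1] == tab[2]) {
      return(list(status = "ambiguous"))
    }
    consensus <- names(tab)[1]
    # the longest-overlap evidence supplies the base unless it conflicts
    # with the strict majority of the admissible evidence
    base <- if (nb[1] == consensus || length(nb) == 1L) nb[1] else consensus
    list(status = "extended", base = base)
  }

  # admissible evidence whose 5' end overlaps `left` and whose remaining 3'
  # suffix (also >= min_overlap) matches the start of `target_prefix`:
  # direct single-evidence bridge across a junction. The reference-ordered
  # right-hand piece arbitrates the structural isomer at IR junctions.
  find_bridge <- function(left, target_prefix) {
    adm <- admissible_filtered(left, target_prefix)
    for (r in seq_len(nrow(adm))) {
      e <- ev_seqs[adm$j[r]]
      ext <- substr(e, adm$o[r] + 1L, nchar(e))
      m <- nchar(ext)
      if (m < min_overlap || m > nchar(target_prefix)) next
      if (substr(target_prefix, 1L, m) == ext) {
        return(list(ext = ext, m = m))
      }
    }
    NULL
  }

  join_two <- function(left, right) {
    extended <- 0L
    repeat {
      o <- direct_overlap(left, right, min_overlap)
      if (o > 0L) {
        return(list(seq = paste0(left, substr(right, o + 1L, nchar(right))),
                    status = "closed"))
      }
      br <- find_bridge(left, right)
      if (!is.null(br)) {
        return(list(seq = paste0(left, br$ext,
                                 substr(right, br$m + 1L, nchar(right))),
                    status = "closed"))
      }
      if (extended >= max_extension) return(list(seq = NULL, status = "extension_limit"))
      step <- extend_base(left, right)
      if (step$status != "extended") return(list(seq = NULL, status = step$status))
      left <- paste0(left, step$base)
      extended <- extended + 1L
    }
  }

  # the single remaining piece must wrap onto its own start; the
  # duplicated junction overlap is collapsed once
  close_circle <- function(left) {
    start_prefix <- substr(left, 1L, 10000L)
    extended <- 0L
    repeat {
      max_o <- nchar(left) %/% 2L
      o <- direct_overlap(left, left, min_overlap, search_window = max_o)
      if (o > 0L && o <= max_o) {
        return(list(seq = substr(left, 1L, nchar(left) - o), status = "closed"))
      }
      br <- find_bridge(left, start_prefix)
      if (!is.null(br)) {
        # the bridge extension duplicates the circle start: drop it
        return(list(seq = left, status = "closed"))
      }
      if (extended >= max_extension) return(list(seq = NULL, status = "extension_limit"))
      step <- extend_base(left, start_prefix)
      if (step$status != "extended") return(list(seq = NULL, status = step$status))
      left <- paste0(left, step$base)
      extended <- extended + 1L
    }
  }

  while (length(pieces) > 1L) {
    res <- join_two(pieces[1], pieces[2])
    status <- c(status, sprintf("%s|%s:%s", piece_ids[1], piece_ids[2], res$status))
    if (is.null(res$seq)) break
    pieces <- c(res$seq, pieces[-(1:2)])
    piece_ids <- c(paste0(piece_ids[1], "+", piece_ids[2]), piece_ids[-(1:2)])
  }

  closed <- FALSE
  if (length(pieces) == 1L) {
    res <- close_circle(pieces[1])
    status <- c(status, paste0("circular:", res$status))
    if (!is.null(res$seq)) {
      closed <- TRUE
      pieces[1] <- res$seq
    }
  }

  report <- tibble::tibble(junction = seq_along(status), status = status)
  if (closed) {
    out <- plastome(pieces[1])
    attr(out, "gap_report") <- report
    out
  } else {
    structure(list(pieces = pieces, piece_ids = piece_ids),
              class = "open_scaffold", gap_report = report)
  }
}

#' @export
print.open_scaffold <- function(x, ...) {
  cat(sprintf("<open_scaffold> %d piece(s); unresolved junctions remain\n",
              length(x$pieces)))
  print(attr(x, "gap_report"))
  invisible(x)
}

# ---- read re-mapping assessment ------------------------------------------

# map constant-width reads onto the doubled circle: exact first, then
# seeded rescue allowing up to max_mismatch substitutions
map_reads_exact_then_rescue <- function(read_seqs, genome, max_mismatch = 2L) {
  L <- nchar(genome)
  doubled <- Biostrings::DNAString(paste0(genome, genome))
  W <- unique(nchar(read_seqs))
  stopifnot(length(W) == 1L)
  n <- length(read_seqs)
  pos <- rep(NA_integer_, n)       # 1-based start on the forward circle
  strand <- rep(NA_character_, n)
  mism <- rep(NA_integer_, n)

  dss <- Biostrings::DNAStringSet(read_seqs)
  # exact mapping by hash join against every window of the doubled circle
  # (first occurrence = lowest forward-circle position, deterministic)
  windows <- substring(paste0(genome, genome), 1:L, W:(L + W - 1L))
  rc_reads <- revcomp_vec(read_seqs)
  for (str in c("+", "-")) {
    un <- which(is.na(pos))
    if (length(un) == 0L) break
    qs <- if (str == "+") read_seqs[un] else rc_reads[un]
    starts <- match(qs, windows)
    ok <- !is.na(starts)
    pos[un[ok]] <- starts[ok]
    strand[un[ok]] <- str
    mism[un[ok]] <- 0L
  }

  # seeded rescue for remaining reads
  un <- which(is.na(pos))
  if (length(un) > 0L && max_mismatch > 0L) {
    seed_len <- 20L
    offsets <- unique(pmax(1L, c(1L, (W - seed_len) %/% 2L + 1L, W - seed_len + 1L)))
    for (str in c("+", "-")) {
      un <- which(is.na(pos))
      if (length(un) == 0L) break
      qs <- if (str == "+") dss[un] else Biostrings::reverseComplement(dss[un])
      for (off in offsets) {
        still <- which(is.na(pos[un]))
        if (length(still) == 0L) break
        seeds <- IRanges::narrow(qs[still], start = off, end = off + seed_len - 1L)
        hits <- Biostrings::matchPDict(Biostrings::PDict(seeds), doubled)
        for (i in seq_along(hits)) {
          s <- IRanges::start(hits[[i]])
          if (length(s) == 0L) next
          cand <- s - off + 1L
          cand <- cand[cand >= 1L & cand <= L]
          for (p in cand) {
            nm <- nmismatch_at(as.character(qs[still[i]]), doubled, p, W)
            if (nm <= max_mismatch) {
              ridx <- un[still[i]]
              pos[ridx] <- p; strand[ridx] <- str; mism[ridx] <- nm
              break
            }
          }
        }
      }
    }
  }
  list(pos = pos, strand = strand, mismatches = mism, read_len = W, genome_len = L)
}

nmismatch_at <- function(read, doubled, at, W) {
  ref <- as.character(Biostrings::subseq(doubled, at, at + W - 1L))
  sum(chars(read) != chars(ref))
}

#' Assess a finished assembly by read re-mapping
#'
#' Maps each read to its best exact or near-exact (<= 2 substitutions)
#' location on the doubled circle, computes per-position depth, and lists
#' every position where the majority of covering reads disagree with the
#' assembly. Unmapped reads are ignored (in real data they may derive from
#' the nuclear or mitochondrial genomes).
#'
#' @param p the assembled `plastome` (or DNA string).
#' @param reads a `read_set`.
#' @return an `assembly_report`: list with `mean_depth`,
#'   `per_position_depth`, `inconsistencies` (tibble: position,
#'   reference_base, read_majority_base, depth), `n_reads`, `n_mapped`.
#' @export
assess_assembly <- function(p, reads) {
  s <- if (inherits(p, "plastome")) p$sequence else toupper(p)
  stopifnot(inherits(reads, "read_set"), nrow(reads$reads) > 0L)
  L <- nchar(s)
  mp <- map_reads_exact_then_rescue(reads$reads$sequence, s)
  W <- mp$read_len
  mapped <- which(!is.na(mp$pos))

  depth <- integer(L)
  if (length(mapped)) {
    idx <- rep(mp$pos[mapped], each = W) + rep.int(0:(W - 1L), length(mapped))
    idx <- ((idx - 1L) %% L) + 1L
    depth <- tabulate(idx, nbins = L)
  }

  # mismatch pileup from rescued reads
  inc <- tibble::tibble(position = integer(0), reference_base = character(0),
                        read_majority_base = character(0), depth = integer(0))
  withmm <- mapped[which(mp$mismatches[mapped] > 0L)]
  if (length(withmm)) {
    doubled <- paste0(s, s)
    alt_pos <- integer(0); alt_base <- character(0)
    for (i in withmm) {
      rd <- reads$reads$sequence[i]
      if (mp$strand[i] == "-") rd <- revcomp(rd)
      ref <- substr(doubled, mp$pos[i], mp$pos[i] + W - 1L)
      d <- which(chars(rd) != chars(ref))
      gp <- ((mp$pos[i] + d - 1L - 1L) %% L) + 1L
      alt_pos <- c(alt_pos, gp)
      alt_base <- c(alt_base, chars(rd)[d])
    }
    tab <- table(alt_pos, alt_base)
    for (ps in rownames(tab)) {
      pnum <- as.integer(ps)
      counts <- tab[ps, , drop = TRUE]
      if (is.null(names(counts))) names(counts) <- colnames(tab)
      best <- names(counts)[which.max(counts)]
      if (2L * max(counts) > depth[pnum]) {
        inc <- rbind(inc, tibble::tibble(
          position = pnum, reference_base = substr(s, pnum, pnum),
          read_majority_base = best, depth = depth[pnum]))
      }
    }
    inc <- inc[order(inc$position), ]
  }

  structure(list(mean_depth = mean(depth), per_position_depth = depth,
                 inconsistencies = inc, n_reads = nrow(reads$reads),
                 n_mapped = length(mapped)),
            class = "assembly_report")
}

#' @export
print.assembly_report <- function(x, ...) {
  cat(sprintf("<assembly_report> mean depth %.1fx; %d/%d reads mapped; %d inconsistencies\n",
              x$mean_depth, x$n_mapped, x$n_reads, nrow(x$inconsistencies)))
  invisible(x)
}
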