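# Anchored pairwise genome alignment and structural-variant detection.
#
# Plastomes are collinear apart from rare large events, so a light-weight
# unique k-mer anchor chain is sufficient at desk scale and gives exact
# breakpoints after base-level extension of the flanking blocks.

unique_kmer_positions <- function(s, k) {
  n <- nchar(s) - k + 1L
  if (n < 1L) return(list(kmer = character(0), pos = integer(0)))
  km <- substring(s, 1:n, k:(n + k - 1L))
  dup <- duplicated(km) | duplicated(km, fromLast = TRUE)
  list(kmer = km[!dup], pos = which(!dup))
}

# longest strictly-increasing subsequence (patience sorting), returns indices
lis_indices <- function(v) {
  n <- length(v)
  if (n == 0L) return(integer(0))
  tails <- numeric(0)      # smallest tail value for each chain length
  tails_idx <- integer(0)
  prev <- integer(n)
  for (i in seq_len(n)) {
    j <- findInterval(v[i] - 0.5, tails) + 1L  # first tail >= v[i]
    tails[j] <- v[i]
    tails_idx[j] <- i
    prev[i] <- if (j > 1L) tails_idx[j - 1L] else 0L
  }
  out <- integer(length(tails))
  i <- tails_idx[length(tails)]
  for (j in rev(seq_along(tails))) {
    out[j] <- i
    i <- prev[i]
  }
  out
}

chain_anchors <- function(q, t, k) {
  uq <- unique_kmer_positions(q, k)
  ut <- unique_kmer_positions(t, k)
  m <- match(uq$kmer, ut$kmer)
  keep <- !is.na(m)
  qpos <- uq$pos[keep]
  tpos <- ut$pos[m[keep]]
  if (length(qpos) == 0L) return(list(qpos = integer(0), tpos = integer(0)))
  ord <- order(qpos)
  qpos <- qpos[ord]; tpos <- tpos[ord]
  # thin very dense anchor sets before chaining; block edges are recovered
  # exactly later by base-level extension
  max_anchors <- 20000L
  if (length(qpos) > max_anchors) {
    sel <- unique(as.integer(round(seq(1L, length(qpos), length.out = max_anchors))))
    qpos <- qpos[sel]; tpos <- tpos[sel]
  }
  sel <- lis_indices(tpos)
  list(qpos = qpos[sel], tpos = tpos[sel])
}

# merge chained anchors into collinear blocks; same-diagonal anchors within
# merge_gap are absorbed (isolated substitutions), diagonal changes or large
# gaps start a new block
anchors_to_blocks <- function(qpos, tpos, k, merge_gap = 3L * k) {
  n <- length(qpos)
  if (n == 0L) {
    return(tibble::tibble(q_start = integer(0), q_end = integer(0),
                          t_start = integer(0), t_end = integer(0)))
  }
  diag <- tpos - qpos
  newblk <- c(TRUE, diff(diag) != 0L | diff(qpos) > merge_gap)
  grp <- cumsum(newblk)
  qs <- tapply(qpos, grp, min); qe <- tapply(qpos, grp, max) + k - 1L
  ts <- tapply(tpos, grp, min); te <- tapply(tpos, grp, max) + k - 1L
  tibble::tibble(q_start = as.integer(qs), q_end = as.integer(qe),
                 t_start = as.integer(ts), t_end = as.integer(te))
}

# extend block boundaries base-by-base into the flanking gaps (exact match),
# giving breakpoint-exact gaps for clean planted events
refine_blocks <- function(blocks, q, t) {
  n <- nrow(blocks)
  if (n == 0L) return(blocks)
  qc <- chars(q); tc <- chars(t)
  for (i in seq_len(n)) {
    # leftward
    lim_q <- if (i > 1L) blocks$q_end[i - 1L] + 1L else 1L
    lim_t <- if (i > 1L) blocks$t_end[i - 1L] + 1L else 1L
    while (blocks$q_start[i] > lim_q && blocks$t_start[i] > lim_t &&
           qc[blocks$q_start[i] - 1L] == tc[blocks$t_start[i] - 1L]) {
      blocks$q_start[i] <- blocks$q_start[i] - 1L
      blocks$t_start[i] <- blocks$t_start[i] - 1L
    }
    # rightward
    lim_q <- if (i < n) blocks$q_start[i + 1L] - 1L else length(qc)
    lim_t <- if (i < n) blocks$t_start[i + 1L] - 1L else length(tc)
    while (blocks$q_end[i] < lim_q && blocks$t_end[i] < lim_t &&
           qc[blocks$q_end[i] + 1L] == tc[blocks$t_end[i] + 1L]) {
      blocks$q_end[i] <- blocks$q_end[i] + 1L
      blocks$t_end[i] <- blocks$t_end[i] + 1L
    }
  }
  # homology at an event breakpoint can leave consecutive blocks claiming
  # the same bases on one sequence; trim the later block so gap sizes are
  # exact (this resolves the usual indel placement ambiguity leftward)
  for (i in seq_len(n - 1L)) {
    ov <- max(blocks$t_end[i] - blocks$t_start[i + 1L] + 1L,
              blocks$q_end[i] - blocks$q_start[i + 1L] + 1L)
    if (ov > 0L) {
      blocks$t_start[i + 1L] <- blocks$t_start[i + 1L] + ov
      blocks$q_start[i + 1L] <- blocks$q_start[i + 1L] + ov
    }
  }
  blocks
}

#' Anchored pairwise alignment of two genomes
#'
#' Chains unique shared k-mers into the longest collinear chain, merges
#' them into blocks, and extends block edges by exact base matching. If the
#' forward-strand chain explains less of the query than the reverse-strand
#' chain, the reverse chain is returned with strand `"-"`.
#'
#' @param query,target DNA strings (or `plastome` objects).
#' @param k anchor k-mer length.
#' @return an `alignment_chain`: tibble of blocks (`q_start`, `q_end`,
#'   `t_start`, `t_end`, `strand`) ordered along the query, with the input
#'   lengths and `k` as attributes. Zero rows when no anchors are shared.
#' @export
anchor_align <- function(query, target, k = 21L) {
  q <- if (inherits(query, "plastome")) query$sequence else toupper(query)
  t <- if (inherits(target, "plastome")) target$sequence else toupper(target)
  if (nchar(q) < k || nchar(t) < k) stop("sequences must be at least k long")

  fwd <- chain_anchors(q, t, k)
  rc_t <- revcomp(t)
  rev <- chain_anchors(q, rc_t, k)

  use_rev <- length(rev$qpos) > length(fwd$qpos)
  if (use_rev) {
    blocks <- anchors_to_blocks(rev$qpos, rev$tpos, k)
    blocks <- refine_blocks(blocks, q, rc_t)
    nt <- nchar(t)
    ts <- nt - blocks$t_end + 1L
    te <- nt - blocks$t_start + 1L
    blocks$t_start <- ts; blocks$t_end <- te
    blocks$strand <- "-"
  } else {
    blocks <- anchors_to_blocks(fwd$qpos, fwd$tpos, k)
    blocks <- refine_blocks(blocks, q, t)
    blocks$strand <- if (nrow(blocks)) "+" else character(0)
  }
  structure(blocks, class = c("alignment_chain", class(blocks)),
            query_len = nchar(q), target_len = nchar(t), k = k,
            query_seq = q, target_seq = t)
}

# canonical (leftmost) placement of an indel interval: repeated boundary
# bases make several placements equivalent; sliding left while the base
# before the interval equals its last base picks one representative
left_normalize_interval <- function(s, start, end) {
  if (!is.null(s)) {
    while (start > 1L &&
           substr(s, start - 1L, start - 1L) == substr(s, end, end)) {
      start <- start - 1L
      end <- end - 1L
    }
  }
  c(start, end)
}

#' Fraction of the query covered by alignment blocks
#' @param chain an `alignment_chain`.
#' @return proportion of query bases inside blocks.
#' @export
chain_coverage <- function(chain) {
  sum(chain$q_end - chain$q_start + 1L) / attr(chain, "query_len")
}

#' Detect large insertions and deletions from an alignment chain
#'
#' Every inter-block gap of at least `min_len` bp on exactly one sequence is
#' emitted: a query-side gap as an `insertion` (sequence present in the
#' query, absent from the target), a target-side gap as a `deletion`
#' (sequence the query lacks). Loci are named `"geneA-geneB"` from the
#' nearest flanking annotated genes.
#'
#' @param chain an `alignment_chain` from [anchor_align()].
#' @param annotations optional feature table (columns `name`, `start`,
#'   `end`) used for locus naming.
#' @param annotated which genome the annotations describe.
#' @param min_len minimum event length in bp.
#' @return a tibble of variant records: `kind`, `locus`, `genome`,
#'   `start`, `end`, `length`.
#' @export
detect_indels <- function(chain, annotations = NULL,
                          annotated = c("target", "query"), min_len = 100L) {
  annotated <- match.arg(annotated)
  bl <- chain[chain$strand == "+", , drop = FALSE]
  out <- list()
  if (nrow(bl) >= 2L) {
    for (i in seq_len(nrow(bl) - 1L)) {
      qgap <- bl$q_start[i + 1L] - bl$q_end[i] - 1L
      tgap <- bl$t_start[i + 1L] - bl$t_end[i] - 1L
      big_q <- qgap >= min_len; big_t <- tgap >= min_len
      if (big_q == big_t) next  # neither, or both (divergent/inverted region)
      if (big_q) {
        anno_pos <- if (annotated == "target") bl$t_end[i] else bl$q_end[i] + 1L
        iv <- left_normalize_interval(attr(chain, "query_seq"),
                                      bl$q_end[i] + 1L, bl$q_start[i + 1L] - 1L)
        out[[length(out) + 1L]] <- tibble::tibble(
          kind = "insertion",
          locus = locus_name(annotations, anno_pos),
          genome = "query", start = iv[1], end = iv[2], length = qgap)
      } else {
        anno_pos <- if (annotated == "target") bl$t_end[i] + 1L else bl$q_end[i]
        iv <- left_normalize_interval(attr(chain, "target_seq"),
                                      bl$t_end[i] + 1L, bl$t_start[i + 1L] - 1L)
        out[[length(out) + 1L]] <- tibble::tibble(
          kind = "deletion",
          locus = locus_name(annotations, anno_pos),
          genome = "target", start = iv[1], end = iv[2], length = tgap)
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(kind = character(0), locus = character(0),
                          genome = character(0), start = integer(0),
                          end = integer(0), length = integer(0)))
  }
  do.call(rbind, out)
}

# name a position by its nearest flanking annotated genes
locus_name <- function(annotations, pos) {
  if (is.null(annotations) || nrow(annotations) == 0L) return(NA_character_)
  a <- annotations[order(annotations$start), ]
  left <- a[a$end < pos, ]
  right <- a[a$start > pos, ]
  ln <- if (nrow(left)) left$name[nrow(left)] else a$name[nrow(a)]
  rn <- if (nrow(right)) right$name[1] else a$name[1]
  inside <- a[a$start <= pos & a$end >= pos, ]
  if (nrow(inside)) return(inside$name[1])
  paste0(ln, "-", rn)
}

#' Detect inversions between two genomes
#'
#' A region that interrupts the forward-strand chain on both sequences with
#' near-equal gap sizes, and whose two gap sequences align on the reverse
#' strand, is emitted as an inversion. The inverted interval excludes any
#' flanking repeat motifs (block extension stops at the first
#' forward-strand mismatch).
#'
#' @param query,target DNA strings or `plastome` objects.
#' @param annotations,annotated optional locus naming, as [detect_indels()].
#' @param min_len minimum inversion length in bp.
#' @param k anchor k-mer length.
#' @param chain optionally, a precomputed [anchor_align()] chain for the
#'   same query/target pair (avoids re-anchoring).
#' @return tibble of inversion records with coordinates on both genomes
#'   (`start`/`end` on the query, `t_start`/`t_end` on the target).
#' @export
detect_inversions <- function(query, target, annotations = NULL,
                              annotated = c("target", "query"),
                              min_len = 50L, k = 21L, chain = NULL) {
  annotated <- match.arg(annotated)
  q <- if (inherits(query, "plastome")) query$sequence else toupper(query)
  t <- if (inherits(target, "plastome")) target$sequence else toupper(target)
  if (is.null(chain)) chain <- anchor_align(q, t, k)
  bl <- chain[chain$strand == "+", , drop = FALSE]
  out <- list()
  if (nrow(bl) >= 2L) {
    for (i in seq_len(nrow(bl) - 1L)) {
      qgap <- bl$q_start[i + 1L] - bl$q_end[i] - 1L
      tgap <- bl$t_start[i + 1L] - bl$t_end[i] - 1L
      if (qgap < min_len || tgap < min_len) next
      qs <- bl$q_end[i] + 1L; qe <- bl$q_start[i + 1L] - 1L
      ts <- bl$t_end[i] + 1L; te <- bl$t_start[i + 1L] - 1L
      qseg <- substr(q, qs, qe)
      tseg <- substr(t, ts, te)
      if (!segments_revcomp_similar(qseg, tseg, min(k, 15L))) next
      anno_pos <- if (annotated == "target") ts else qs
      out[[length(out) + 1L]] <- tibble::tibble(
        kind = "inversion", locus = locus_name(annotations, anno_pos),
        genome = "query", start = qs, end = qe,
        t_start = ts, t_end = te, length = qgap)
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(kind = character(0), locus = character(0),
                          genome = character(0), start = integer(0),
                          end = integer(0), t_start = integer(0),
                          t_end = integer(0), length = integer(0)))
  }
  do.call(rbind, out)
}

# do two segments align on opposite strands? (shared-kmer vote)
segments_revcomp_similar <- function(a, b, k) {
  if (nchar(a) < k || nchar(b) < k) return(FALSE)
  rb <- revcomp(b)
  ka <- unique(substring(a, 1:(nchar(a) - k + 1L), k:nchar(a)))
  kb <- unique(substring(rb, 1:(nchar(rb) - k + 1L), k:nchar(rb)))
  mean(ka %in% kb) >= 0.5
}

#' Longest inverted repeat flanking an inversion
#'
#' Finds the longest f (up to `max_flank`) such that the f bases
#' immediately 5' of the inversion interval and the f bases immediately 3'
#' of it are reverse complements under IUPAC compatibility: two codes match
#' iff their base sets intersect (so Y matches C or T but not A). This is
#' the stem-loop signature suggestive of hairpin-mediated recombination.
#'
#' @param sequence a DNA string (IUPAC codes permitted); treated as circular.
#' @param inversion integer vector `c(start, end)` (1-based closed).
#' @param max_flank maximum flank length examined.
#' @return a list with `flank_len` (0 when no flank), `upstream` and
#'   `downstream` motifs.
#' @export
find_inverted_flanks <- function(sequence, inversion, max_flank = 30L) {
  s <- toupper(if (inherits(sequence, "plastome")) sequence$sequence else sequence)
  L <- nchar(s)
  start <- as.integer(inversion[1]); end <- as.integer(inversion[2])
  if (start < 1L || end > L || start > end) stop("inversion interval outside sequence")
  max_flank <- min(as.integer(max_flank), (L - (end - start + 1L)) %/% 2L)
  compat <- iupac_compat()
  sc <- chars(s)
  at <- function(i) sc[((i - 1L) %% L) + 1L]
  for (f in rev(seq_len(max_flank))) {
    up <- at((start - f):(start - 1L))
    down <- at((end + 1L):(end + f))
    # up must be the IUPAC-compatible reverse complement of down
    rc_down <- rev(complement_chars(down))
    ok <- all(compat[cbind(up, rc_down)])
    if (ok) {
      return(list(flank_len = f, upstream = paste(up, collapse = ""),
                  downstream = paste(down, collapse = "")))
    }
  }
  list(flank_len = 0L, upstream = "", downstream = "")
}

#' Map variant records onto a phylogeny
#'
#' A record whose taxa form a monophyletic group is assigned to the branch
#' subtending their most recent common ancestor and labelled
#' `"synapomorphy"` (`"autapomorphy"` for a single taxon); otherwise it is
#' labelled `"homoplastic/conflicting"` and the minimal clade covering the
#' taxa is reported.
#'
#' @param records a tibble of variant records with a `taxa` list-column
#'   (character vectors of tip labels), or a list of character vectors.
#' @param tree an `ape::phylo` tree, a newick string, or a path to a
#'   newick file. The tree is treated as rooted.
#' @return a tibble: `record`, `label`, `node` (the MRCA node number),
#'   `branch` (row of `tree$edge` subtending it, NA for the root),
#'   `clade_taxa` (list-column: tips of the minimal covering clade).
#' @export
map_synapomorphies <- function(records, tree) {
  tree <- as_phylo_tree(tree)
  taxa_sets <- if (is.data.frame(records)) records$taxa else records
  if (is.character(taxa_sets)) taxa_sets <- list(taxa_sets)
  tips <- tree$tip.label
  rows <- lapply(seq_along(taxa_sets), function(i) {
    taxa <- unique(taxa_sets[[i]])
    unknown <- setdiff(taxa, tips)
    if (length(unknown)) stop("unknown taxon name: ", paste(unknown, collapse = ", "))
    if (length(taxa) == 1L) {
      node <- match(taxa, tips)
      return(tibble::tibble(record = i, label = "autapomorphy", node = node,
                            branch = which(tree$edge[, 2] == node),
                            clade_taxa = list(taxa)))
    }
    node <- ape::getMRCA(tree, taxa)
    clade <- ape::extract.clade(tree, node)$tip.label
    mono <- setequal(clade, taxa)
    br <- which(tree$edge[, 2] == node)
    tibble::tibble(
      record = i,
      label = if (mono) "synapomorphy" else "homoplastic/conflicting",
      node = node,
      branch = if (length(br)) br else NA_integer_,
      clade_taxa = list(sort(clade)))
  })
  do.call(rbind, rows)
}

as_phylo_tree <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  stop("tree must be a phylo object, newick string, or newick file path")
}

#' Render an anchor chain as a two-row gapped alignment
#'
#' Expands a forward-strand [anchor_align()] chain into an aligned pair of
#' sequences with `-` filling indel gaps; regions divergent on both
#' genomes (e.g. inversions) are stacked column-wise and padded to equal
#' length. Useful for building small matrices from synthetic genome pairs
#' without an external aligner.
#'
#' @param query,target the DNA strings (or `plastome`s) that were aligned.
#' @param chain an `alignment_chain` from [anchor_align()]; only its
#'   forward-strand blocks are used.
#' @return a named character vector of two equal-length aligned rows.
#' @export
chain_to_alignment <- function(query, target, chain) {
  q <- if (inherits(query, "plastome")) query$sequence else toupper(query)
  t <- if (inherits(target, "plastome")) target$sequence else toupper(target)
  bl <- chain[chain$strand == "+", , drop = FALSE]
  if (nrow(bl) == 0L) stop("chain has no forward-strand blocks")
  qa <- character(0); ta <- character(0)
  emit <- function(qs, ts) {
    w <- max(nchar(qs), nchar(ts))
    qa <<- c(qa, paste0(qs, strrep("-", w - nchar(qs))))
    ta <<- c(ta, paste0(ts, strrep("-", w - nchar(ts))))
  }
  # leading unaligned context
  emit(substr(q, 1L, bl$q_start[1] - 1L), substr(t, 1L, bl$t_start[1] - 1L))
  for (i in seq_len(nrow(bl))) {
    emit(substr(q, bl$q_start[i], bl$q_end[i]),
         substr(t, bl$t_start[i], bl$t_end[i]))
    if (i < nrow(bl)) {
      emit(substr(q, bl$q_end[i] + 1L, bl$q_start[i + 1L] - 1L),
           substr(t, bl$t_end[i] + 1L, bl$t_start[i + 1L] - 1L))
    }
  }
  n <- nrow(bl)
  emit(substr(q, bl$q_end[n] + 1L, nchar(q)), substr(t, bl$t_end[n] + 1L, nchar(t)))
  c(query = paste(qa, collapse = ""), target = paste(ta, collapse = ""))
}
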