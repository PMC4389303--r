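# Phylogenomic character matrices: assembly from aligned plastomes (IRa
# already excluded upstream), gap-column stripping, inversion masking,
# and coding-region extraction.

#' Build a character matrix from aligned sequences
#'
#' @param aligned a named character vector of equal-length aligned
#'   sequences (gaps as `-`), a `DNAStringSet`, or a path to an aligned
#'   FASTA file. By convention the inverted repeat region A has been
#'   removed from each genome before alignment so the repeat is not
#'   represented twice.
#' @param annotations optional feature table (columns `name`, `kind`,
#'   `strand`, `start`, `end`) in ungapped coordinates of the reference
#'   row, used to initialize the coding mask.
#' @param reference_row name or index of the row the annotations (and any
#'   later inversion records) refer to.
#' @return a `character_matrix`: list with `taxa`, `mat` (character
#'   matrix, taxa x columns), and `masks` (logical vectors `gapped`,
#'   `inversion`, `coding`).
#' @export
assemble_matrix <- function(aligned, annotations = NULL, reference_row = 1L) {
  if (is.character(aligned) && length(aligned) == 1L && file.exists(aligned)) {
    aligned <- Biostrings::readDNAStringSet(aligned)
  }
  nm <- names(aligned)
  seqs <- toupper(as.character(aligned))
  names(seqs) <- nm
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    names(seqs) <- paste0("taxon", seq_along(seqs))
  }
  if (length(unique(nchar(seqs))) != 1L) stop("ragged input: aligned rows differ in length")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  nc <- ncol(mat)
  gapped <- apply(mat == "-", 2, any)
  coding <- rep(FALSE, nc)
  if (!is.null(annotations) && nrow(annotations) > 0L) {
    ref <- if (is.character(reference_row)) reference_row else names(seqs)[reference_row]
    colmap <- ref_position_to_column(mat[ref, ])
    cds <- annotations[annotations$kind == "CDS", , drop = FALSE]
    for (i in seq_len(nrow(cds))) {
      cols <- colmap[cds$start[i]]:colmap[cds$end[i]]
      coding[cols] <- TRUE
    }
  }
  structure(list(taxa = names(seqs), mat = mat,
                 masks = list(gapped = unname(gapped),
                              inversion = rep(FALSE, nc),
                              coding = coding),
                 reference_row = if (is.character(reference_row)) reference_row
                                 else names(seqs)[reference_row],
                 annotations = annotations),
            class = "character_matrix")
}

# column index of each ungapped reference position
ref_position_to_column <- function(ref_chars) {
  which(ref_chars != "-")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("<character_matrix> %d taxa x %s columns (%s gapped, %s inversion-masked, %s coding)\n",
              length(x$taxa), format(ncol(x$mat), big.mark = ","),
              format(sum(x$masks$gapped), big.mark = ","),
              format(sum(x$masks$inversion), big.mark = ","),
              format(sum(x$masks$coding), big.mark = ",")))
  invisible(x)
}

subset_matrix_columns <- function(m, keep) {
  m$mat <- m$mat[, keep, drop = FALSE]
  m$masks <- lapply(m$masks, `[`, keep)
  m
}

#' Remove every column containing a gap
#'
#' @param m a `character_matrix`.
#' @return the matrix restricted to columns with no gap in any taxon;
#'   column order preserved; idempotent.
#' @export
strip_gapped_columns <- function(m) {
  stopifnot(inherits(m, "character_matrix"))
  subset_matrix_columns(m, !m$masks$gapped)
}

#' Mask (remove) columns covered by inversion records
#'
#' Regions containing inversions are excluded because their site-wise
#' homology across taxa is spurious.
#'
#' @param m a `character_matrix`.
#' @param records tibble of inversion records with `start`, `end` in
#'   ungapped coordinates of the matrix's reference row.
#' @return the matrix with all overlapping columns removed; idempotent
#'   (already-removed columns cannot match again).
#' @export
mask_inversions <- function(m, records) {
  stopifnot(inherits(m, "character_matrix"))
  if (is.null(records) || nrow(records) == 0L) return(m)
  colmap <- ref_position_to_column(m$mat[m$reference_row, ])
  drop <- rep(FALSE, ncol(m$mat))
  for (i in seq_len(nrow(records))) {
    if (records$start[i] < 1L || records$end[i] > length(colmap)) {
      stop("inversion record outside matrix reference coordinates")
    }
    drop[colmap[records$start[i]]:colmap[records$end[i]]] <- TRUE
  }
  m$masks$inversion <- m$masks$inversion | drop
  subset_matrix_columns(m, !drop)
}

#' Extract and concatenate protein-coding columns
#'
#' Columns overlapping CDS features of the reference row, concatenated in
#' genome order and normalized to the coding strand (minus-strand
#' features are reverse complemented column-wise).
#'
#' @param m a `character_matrix` built with annotations.
#' @param annotations optional override of the feature table.
#' @return a `character_matrix` containing only the coding columns.
#' @export
extract_coding <- function(m, annotations = NULL) {
  stopifnot(inherits(m, "character_matrix"))
  anns <- annotations %||% m$annotations
  if (is.null(anns)) stop("no CDS annotations available")
  cds <- anns[anns$kind == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) stop("no CDS features")
  cds <- cds[order(cds$start), ]
  colmap <- ref_position_to_column(m$mat[m$reference_row, ])
  blocks <- list(); gap_mask <- logical(0); inv_mask <- logical(0)
  for (i in seq_len(nrow(cds))) {
    cols <- colmap[cds$start[i]]:colmap[cds$end[i]]
    blk <- m$mat[, cols, drop = FALSE]
    gm <- m$masks$gapped[cols]; im <- m$masks$inversion[cols]
    if (cds$strand[i] == "-") {
      blk <- complement_matrix(blk)[, rev(seq_along(cols)), drop = FALSE]
      gm <- rev(gm); im <- rev(im)
    }
    blocks[[i]] <- blk
    gap_mask <- c(gap_mask, gm); inv_mask <- c(inv_mask, im)
  }
  mat <- do.call(cbind, blocks)
  structure(list(taxa = m$taxa, mat = mat,
                 masks = list(gapped = gap_mask, inversion = inv_mask,
                              coding = rep(TRUE, ncol(mat))),
                 reference_row = m$reference_row, annotations = anns),
            class = "character_matrix")
}

complement_matrix <- function(mat) {
  comp <- c(IUPAC_COMP, "-" = "-")
  out <- matrix(comp[mat], nrow = nrow(mat))
  rownames(out) <- rownames(mat)
  out
}

#' Write a character matrix as relaxed PHYLIP
#' @param m a `character_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(m, path) {
  stopifnot(inherits(m, "character_matrix"))
  rows <- apply(m$mat, 1, paste, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(m$taxa), ncol(m$mat)), con)
  writeLines(sprintf("%s  %s", m$taxa, rows), con)
  invisible(path)
}

#' Write a character matrix as aligned FASTA
#' @param m a `character_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix_fasta <- function(m, path) {
  stopifnot(inherits(m, "character_matrix"))
  rows <- apply(m$mat, 1, paste, collapse = "")
  writeLines(as.vector(rbind(paste0(">", m$taxa), rows)), path)
  invisible(path)
}

#' Write a coding/noncoding partition file (RAxML-style)
#' @param m a `character_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_partitions <- function(m, path) {
  stopifnot(inherits(m, "character_matrix"))
  runs <- function(mask) {
    if (!any(mask)) return(character(0))
    r <- rle(mask)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    sprintf("%d-%d", starts[r$values], ends[r$values])
  }
  lines <- c(
    if (any(m$masks$coding)) sprintf("DNA, coding = %s",
                                     paste(runs(m$masks$coding), collapse = ", ")),
    if (any(!m$masks$coding)) sprintf("DNA, noncoding = %s",
                                      paste(runs(!m$masks$coding), collapse = ", "))
  )
  writeLines(lines, path)
  invisible(path)
}
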