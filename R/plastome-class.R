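#' Plastome objects
#'
#' A `plastome` is a circular DNA molecule with an optional quadripartite
#' region table (LSC, IRb, SSC, IRa) and a feature table (genes, CDS, tRNA,
#' rRNA). All coordinates are 1-based closed intervals on the stored
#' orientation; the circle's origin is the first base of the LSC when the
#' molecule is in canonical order.
#'
#' @param sequence a DNA string (upper-case A/C/G/T, IUPAC codes permitted).
#' @param regions a data frame with columns `region`, `start`, `end`
#'   (rows among LSC, IRb, SSC, IRa), or `NULL` if boundaries are unknown.
#' @param features a data frame with columns `name`, `kind`, `strand`,
#'   `start`, `end`, or `NULL`.
#' @param circular logical; plastomes are circular.
#' @return an object of class `plastome`.
#' @export
plastome <- function(sequence, regions = NULL, features = NULL, circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  sequence <- toupper(sequence)
  if (!is.null(regions)) {
    regions <- tibble::as_tibble(regions)
    stopifnot(all(c("region", "start", "end") %in% names(regions)))
    validate_regions(regions, nchar(sequence))
  }
  if (!is.null(features)) {
    features <- tibble::as_tibble(features)
    stopifnot(all(c("name", "kind", "strand", "start", "end") %in% names(features)))
    if (nrow(features) > 0 &&
        (min(features$start) < 1L || max(features$end) > nchar(sequence))) {
      stop("feature interval outside sequence")
    }
  }
  structure(
    list(sequence = sequence, regions = regions, features = features,
         circular = isTRUE(circular)),
    class = "plastome"
  )
}

validate_regions <- function(regions, len) {
  need <- c("LSC", "IRb", "SSC", "IRa")
  if (!all(need %in% regions$region)) stop("regions must contain LSC, IRb, SSC, IRa")
  r <- regions[match(need, regions$region), ]
  widths <- r$end - r$start + 1L
  if (sum(widths) != len) stop("regions must tile the circle exactly")
  if (widths[2] != widths[4]) stop("IRa and IRb must have equal length")
  invisible(TRUE)
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("<plastome> %s bp%s\n", format(nchar(x$sequence), big.mark = ","),
              if (x$circular) " (circular)" else ""))
  if (!is.null(x$regions)) {
    w <- x$regions$end - x$regions$start + 1L
    cat("  regions: ",
        paste(sprintf("%s=%s", x$regions$region, format(w, big.mark = ",")),
              collapse = " "), "\n", sep = "")
  }
  if (!is.null(x$features)) {
    cat(sprintf("  features: %d\n", nrow(x$features)))
  }
  invisible(x)
}

#' @export
length.plastome <- function(x) nchar(x$sequence)

region_interval <- function(p, name) {
  r <- p$regions[p$regions$region == name, ]
  if (nrow(r) != 1L) stop("region not present: ", name)
  c(start = r$start, end = r$end)
}

#' Region lengths of one or more plastomes
#'
#' Tabulates total, LSC, SSC and IR lengths, one row per genome, mirroring
#' the layout used to report quadripartite plastome structure.
#'
#' @param ... named `plastome` objects with region tables.
#' @return a tibble with columns `genome`, `total_len`, `lsc_len`,
#'   `ssc_len`, `ir_len`.
#' @export
region_table <- function(...) {
  ps <- list(...)
  if (length(ps) == 1L && is.list(ps[[1]]) && !inherits(ps[[1]], "plastome")) {
    ps <- ps[[1]]
  }
  if (is.null(names(ps)) || any(names(ps) == "")) {
    names(ps) <- paste0("genome", seq_along(ps))
  }
  rows <- lapply(names(ps), function(nm) {
    p <- ps[[nm]]
    if (is.null(p$regions)) stop("plastome '", nm, "' has no region table")
    w <- function(reg) {
      iv <- region_interval(p, reg)
      unname(iv["end"] - iv["start"] + 1L)
    }
    tibble::tibble(genome = nm, total_len = nchar(p$sequence),
                   lsc_len = w("LSC"), ssc_len = w("SSC"), ir_len = w("IRb"))
  })
  out <- do.call(rbind, rows)
  stopifnot(all(out$total_len == out$lsc_len + out$ssc_len + 2L * out$ir_len))
  out
}

# --- circle transforms (used by canonicalize and by tests) ----------------

# Rotate so that position `origin` becomes base 1; features/regions remapped.
rotate_plastome <- function(p, origin) {
  L <- nchar(p$sequence)
  origin <- ((origin - 1L) %% L) + 1L
  if (origin == 1L) return(p)
  seq2 <- paste0(substr(p$sequence, origin, L), substr(p$sequence, 1L, origin - 1L))
  shift <- function(pos) ((pos - origin) %% L) + 1L
  remap <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(df)
    s <- shift(df$start); e <- shift(df$end)
    # intervals that straddle the new origin are dropped from the remap
    keep <- s <= e
    df <- df[keep, , drop = FALSE]
    df$start <- s[keep]; df$end <- e[keep]
    df[order(df$start), , drop = FALSE]
  }
  regions <- NULL
  if (!is.null(p$regions)) {
    regions <- remap(p$regions)
    # a rotation through a region invalidates the quadripartite table
    if (nrow(regions) < 4L) regions <- NULL
  }
  plastome(seq2, regions = regions, features = remap(p$features),
           circular = p$circular)
}

revcomp_plastome <- function(p) {
  L <- nchar(p$sequence)
  seq2 <- revcomp(p$sequence)
  remap <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(df)
    s <- L - df$end + 1L; e <- L - df$start + 1L
    df$start <- s; df$end <- e
    if ("strand" %in% names(df)) {
      df$strand <- ifelse(df$strand == "+", "-", "+")
    }
    df[order(df$start), , drop = FALSE]
  }
  regions <- NULL
  if (!is.null(p$regions)) {
    regions <- remap(p$regions)
    # reversing swaps the identities of the two IR copies
    regions$region[regions$region == "IRa"] <- "tmp"
    regions$region[regions$region == "IRb"] <- "IRa"
    regions$region[regions$region == "tmp"] <- "IRb"
  }
  plastome(seq2, regions = regions, features = remap(p$features),
           circular = p$circular)
}
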