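# Internal string / sequence helpers shared across modules.
#
# Sequences are held as plain upper-case character scalars inside package
# objects; Biostrings objects are created at I/O and matching boundaries.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC degenerate codes as base sets (used by the in-silico PCR engine and
# the inverted-flank scanner; two codes are compatible iff their sets intersect).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMP <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

# 15x15 logical compatibility matrix, rows/cols named by IUPAC code.
iupac_compat_matrix <- function() {
  codes <- names(IUPAC_SETS)
  m <- matrix(FALSE, length(codes), length(codes), dimnames = list(codes, codes))
  for (a in codes) for (b in codes) {
    m[a, b] <- length(intersect(IUPAC_SETS[[a]], IUPAC_SETS[[b]])) > 0L
  }
  m
}
.IUPAC_COMPAT <- NULL  # filled at load time (see zzz.R)

iupac_compat <- function() {
  if (is.null(.IUPAC_COMPAT)) iupac_compat_matrix() else .IUPAC_COMPAT
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Reverse complement of a DNA string
#'
#' IUPAC-aware reverse complement of a plain character scalar.
#'
#' @param x a DNA string (may contain IUPAC degenerate codes).
#' @return the reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

complement_chars <- function(v) unname(IUPAC_COMP[v])

# vectorised reverse complement (one C pass over a DNAStringSet)
revcomp_vec <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA with a given AT fraction: A and T equiprobable, likewise C/G.
rand_dna <- function(n, at_fraction) {
  if (n == 0L) return("")
  p <- c(at_fraction / 2, (1 - at_fraction) / 2, (1 - at_fraction) / 2, at_fraction / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

at_fraction_of <- function(x) {
  n <- nchar(x)
  if (n == 0L) stop("AT fraction of an empty sequence is undefined")
  at <- sum(charToRaw(x) %in% charToRaw("ATat"))
  at / n
}

# Circular substring: 1-based start, wraps around the sequence end.
circ_substr <- function(s, start, len) {
  L <- nchar(s)
  stopifnot(len <= L)
  start <- ((start - 1L) %% L) + 1L
  if (start + len - 1L <= L) {
    substr(s, start, start + len - 1L)
  } else {
    paste0(substr(s, start, L), substr(s, 1L, start + len - 1L - L))
  }
}

# All k-mers of s at the given start positions (default: every position).
kmers_at <- function(s, k, starts = seq_len(nchar(s) - k + 1L)) {
  substring(s, starts, starts + k - 1L)
}

run_seeded <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Rotation-invariant equality of two circular sequences (either strand).
#' Compare two circular sequences up to rotation and strand
#'
#' Two circular DNA molecules are equivalent when one is a rotation of the
#' other, or a rotation of its reverse complement.
#'
#' @param a,b DNA strings interpreted as circles.
#' @return `TRUE` or `FALSE`.
#' @export
same_circle <- function(a, b) {
  if (nchar(a) != nchar(b)) return(FALSE)
  doubled <- paste0(a, a)
  grepl(b, doubled, fixed = TRUE) || grepl(revcomp(b), doubled, fixed = TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
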