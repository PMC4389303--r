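# File-format boundaries: FASTA and FASTQ through Biostrings, GFF3-style
# feature tables and TSV truth/region tables through base R writers.

#' Write a plastome (or any named sequences) as FASTA
#'
#' @param x a `plastome`, named character vector, or `contig_set`.
#' @param path output file.
#' @param name sequence name used for a single `plastome`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, name = "plastome") {
  if (inherits(x, "plastome")) {
    seqs <- stats::setNames(x$sequence, name)
  } else if (inherits(x, "contig_set")) {
    seqs <- stats::setNames(x$contigs$sequence, x$contigs$id)
  } else {
    seqs <- x
  }
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @param as `"plastome"` (first record), `"contig_set"`, or
#'   `"character"`.
#' @return the requested object.
#' @export
read_fasta <- function(path, as = c("character", "plastome", "contig_set")) {
  as <- match.arg(as)
  dss <- Biostrings::readDNAStringSet(path)
  seqs <- stats::setNames(as.character(dss), names(dss))
  # FASTA headers may carry descriptions after the identifier
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  switch(as,
         character = seqs,
         plastome = plastome(seqs[[1]]),
         contig_set = structure(
           list(contigs = tibble::tibble(id = names(seqs), sequence = unname(seqs),
                                         truth_start = NA_integer_,
                                         length = nchar(unname(seqs))),
                overlap = NA_integer_, genome_len = NA_integer_,
                break_policy = "unknown"),
           class = "contig_set"))
}

#' Write a read set as FASTQ
#'
#' Paired sets are written as two files, `<stem>_1.fastq` and
#' `<stem>_2.fastq`; single-end sets as `<stem>.fastq`.
#'
#' @param rs a `read_set`.
#' @param stem output path stem (no extension).
#' @return the written paths, invisibly.
#' @export
write_fastq <- function(rs, stem) {
  stopifnot(inherits(rs, "read_set"))
  write_one <- function(df, path) {
    dss <- Biostrings::DNAStringSet(stats::setNames(df$sequence, df$id))
    Biostrings::writeXStringSet(dss, path, format = "fastq",
                                qualities = Biostrings::BStringSet(df$quality))
    path
  }
  if (rs$pairing == "paired") {
    p1 <- write_one(rs$reads[rs$reads$mate == 1L, ], paste0(stem, "_1.fastq"))
    p2 <- write_one(rs$reads[rs$reads$mate == 2L, ], paste0(stem, "_2.fastq"))
    invisible(c(p1, p2))
  } else {
    invisible(write_one(rs$reads, paste0(stem, ".fastq")))
  }
}

#' Read FASTQ file(s) into a read set
#'
#' @param path a FASTQ file, or a length-2 vector of mate files.
#' @return a `read_set` (truth origin unknown: NA).
#' @export
read_fastq <- function(path) {
  read_one <- function(f, mate) {
    dss <- Biostrings::readDNAStringSet(f, format = "fastq", with.qualities = TRUE)
    tibble::tibble(id = sub("\\s.*$", "", names(dss)), mate = mate,
                   sequence = unname(as.character(dss)),
                   quality = unname(as.character(S4Vectors::mcols(dss)$qualities)),
                   start = NA_integer_, end = NA_integer_,
                   strand = NA_character_)
  }
  if (length(path) == 2L) {
    reads <- rbind(read_one(path[1], 1L), read_one(path[2], 2L))
    pairing <- "paired"
  } else {
    reads <- read_one(path, NA_integer_)
    pairing <- "single"
  }
  structure(list(reads = reads, pairing = pairing,
                 read_len = as.integer(stats::median(nchar(reads$sequence))),
                 insert_size = NA_integer_, insert_sd = NA_integer_,
                 genome_len = NA_integer_),
            class = "read_set")
}

#' Write plastome features as GFF3
#'
#' @param p an annotated `plastome`.
#' @param path output file.
#' @param seqid sequence identifier for column 1.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(p, path, seqid = "plastome") {
  stopifnot(inherits(p, "plastome"))
  f <- p$features
  if (is.null(f)) f <- tibble::tibble(name = character(0), kind = character(0),
                                      strand = character(0), start = integer(0),
                                      end = integer(0))
  type <- c(CDS = "CDS", gene = "gene", tRNA = "tRNA", rRNA = "rRNA")[f$kind]
  type[is.na(type)] <- "gene"
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", seqid, nchar(p$sequence)),
             sprintf("%s\tplastomics\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                     seqid, type, f$start, f$end, f$strand,
                     make.unique(f$name, sep = "_"), f$name))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 file into a feature table
#'
#' @param path GFF3 file.
#' @return a tibble with columns `name`, `kind`, `strand`, `start`, `end`.
#' @export
read_gff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (length(ln) == 0L) {
    return(tibble::tibble(name = character(0), kind = character(0),
                          strand = character(0), start = integer(0),
                          end = integer(0)))
  }
  parts <- strsplit(ln, "\t", fixed = TRUE)
  stopifnot(all(lengths(parts) == 9L))
  attr_name <- vapply(parts, function(x) {
    m <- regmatches(x[9], regexec("Name=([^;]+)", x[9]))[[1]]
    if (length(m) == 2L) m[2] else sub("^ID=", "", strsplit(x[9], ";")[[1]][1])
  }, character(1))
  tibble::tibble(
    name = attr_name,
    kind = vapply(parts, `[`, character(1), 3L),
    strand = vapply(parts, `[`, character(1), 7L),
    start = as.integer(vapply(parts, `[`, character(1), 4L)),
    end = as.integer(vapply(parts, `[`, character(1), 5L))
  )
}

#' Write a variant truth/record table as TSV
#' @param records a tibble of variant records.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(records, path) {
  df <- as.data.frame(records)
  if ("taxa" %in% names(df)) {
    df$taxa <- vapply(df$taxa, paste, character(1), collapse = ",")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a variant record table from TSV
#' @param path TSV file written by [write_variants_tsv()].
#' @return a tibble; a `taxa` column is split back into a list-column.
#' @export
read_variants_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  if ("taxa" %in% names(out)) {
    out$taxa <- strsplit(out$taxa, ",", fixed = TRUE)
  }
  out
}

#' Write a region table as TSV
#' @param rt a region table from [region_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(rt, path) {
  utils::write.table(as.data.frame(rt), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
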