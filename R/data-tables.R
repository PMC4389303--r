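#' Published bamboo plastome region lengths
#'
#' Region lengths (total, LSC, SSC, IR) with NCBI accessions for the 33
#' grass plastomes of the bamboo phylogenomic study this package's
#' synthetic conditions emulate. `new_assembly` marks the taxa that were
#' newly assembled there (the reported length range 135,320-143,810 bp is
#' the range over these rows).
#'
#' @return a tibble with columns `taxon`, `tribe`, `total_len`,
#'   `lsc_len`, `ssc_len`, `ir_len`, `accession`, `new_assembly`.
#' @export
bamboo_region_table <- function() {
  path <- system.file("extdata", "bamboo_plastome_regions.tsv",
                      package = "plastomics", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Marker structural events of bamboo plastomes
#'
#' The four rare structural events used as clade markers: the Parianinae
#' mitochondrial insertion in the rpl23-ndhB spacer (a 2,706 bp shared
#' insert plus a 2,232 bp 3' extension in one taxon, 4,938 bp in total;
#' the originally reported extension figure of 1,242 bp is kept in
#' `extension_3p_results_bp` as a known internal inconsistency, since only
#' 2,706 + 2,232 matches the stated total), the 1,500 bp Guaduinae
#' deletion, the 150 bp Olyrinae inversion with its CCYTTTTY stem-loop
#' flank, and the ~500 bp Arundinarieae insertion in rps16-trnQ.
#'
#' @return a tibble, one row per event; `taxa` is a list-column.
#' @export
bamboo_marker_events <- function() {
  path <- system.file("extdata", "bamboo_marker_events.tsv",
                      package = "plastomics", mustWork = TRUE)
  out <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE,
                                             na.strings = "NA"))
  out$taxa <- strsplit(out$taxa, ",", fixed = TRUE)
  out
}
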