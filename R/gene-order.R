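# Canonical grass plastid gene complement, in genome order per region.
#
# The order follows the conserved gene arrangement of grass (Poaceae)
# plastomes so that intergenic spacer names produced by the generator
# (e.g. "rps16-trnQ", "trnD-psbM" in the LSC, "rpl23-ndhB" in the IR)
# are the ones used in the plastome literature. tRNA genes are given
# their short symbol without the anticodon suffix.

GRASS_PLASTID_GENES <- list(
  LSC = c(
    "psbA", "matK", "rps16", "trnQ", "psbK", "psbI", "atpA", "atpF",
    "atpH", "atpI", "rps2", "rpoC2", "rpoC1", "rpoB", "trnC", "petN",
    "trnD", "psbM", "trnE", "trnY", "trnT", "psbD", "psbC", "psbZ",
    "rps14", "psaB", "psaA", "ycf3", "rps4", "trnL", "trnF", "ndhJ",
    "ndhK", "ndhC", "atpE", "atpB", "rbcL", "psaI", "ycf4", "cemA",
    "petA", "psbJ", "psbL", "psbF", "psbE", "petL", "petG", "psaJ",
    "rpl33", "rps18", "rpl20", "clpP", "psbB", "psbT", "psbN", "psbH",
    "petB", "petD", "rpoA", "rps11", "rpl36", "rps8", "rpl14", "rpl16",
    "rps3", "rpl22", "rps19"
  ),
  IR = c("rpl2", "rpl23", "ndhB", "rps7", "rrn16", "trnI", "trnA",
         "rrn23", "rrn4.5", "rrn5"),
  SSC = c("ndhF", "rpl32", "ccsA", "ndhD", "psaC", "ndhE", "ndhG",
          "ndhI", "ndhA", "ndhH", "rps15")
)

# Marker gene pairs whose spacers anchor the structural events studied in
# bamboo plastomes; kept adjacent under any gene-count subsetting.
REQUIRED_SPACER_PAIRS <- list(
  c("psbA"),  # orientation marker, always present
  c("rps16", "trnQ"), c("trnD", "psbM"), c("rpl23", "ndhB")
)

#' Canonical grass plastid gene list
#'
#' The packaged gene complement used by [generate_plastome()], in genome
#' order, with the region each gene resides in.
#'
#' @return a tibble with columns `name` and `region`.
#' @export
grass_plastid_genes <- function() {
  tibble::tibble(
    name = unlist(GRASS_PLASTID_GENES, use.names = FALSE),
    region = rep(names(GRASS_PLASTID_GENES),
                 lengths(GRASS_PLASTID_GENES))
  )
}

# Deterministically choose n genes from the master list, preserving order
# and always keeping the marker spacer pairs adjacent.
select_genes <- function(n_genes) {
  all_genes <- grass_plastid_genes()
  total <- nrow(all_genes)
  if (n_genes >= total) return(all_genes)
  required <- unique(unlist(REQUIRED_SPACER_PAIRS))
  if (n_genes < length(required) + 3L) {
    stop("n_genes too small: need at least ", length(required) + 3L,
         " to retain marker spacers and populate every region")
  }
  req_idx <- match(required, all_genes$name)
  # fill remaining slots evenly across the list
  pool <- setdiff(seq_len(total), req_idx)
  extra <- pool[unique(round(seq(1, length(pool),
                                 length.out = n_genes - length(req_idx))))]
  idx <- sort(unique(c(req_idx, extra)))
  # ensure every region keeps at least one gene
  for (reg in names(GRASS_PLASTID_GENES)) {
    if (!any(all_genes$region[idx] == reg)) {
      idx <- sort(c(idx, which(all_genes$region == reg)[1]))
    }
  }
  all_genes[idx[seq_len(min(length(idx), max(n_genes, length(idx))))], ]
}

# Plausible gene length for a symbol (deterministic given the RNG state).
gene_length_for <- function(name) {
  if (grepl("^trn", name)) return(sample(72:90, 1))
  if (grepl("^rrn", name)) {
    return(switch(name, rrn16 = 1491L, rrn23 = 2810L, `rrn4.5` = 95L,
                  rrn5 = 121L, 1200L))
  }
  sample(seq(300L, 1500L, by = 3L), 1)
}
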