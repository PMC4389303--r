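# Miniature study-shaped genomes for fast unit tests: same quadripartite
# layout and AT composition as the full-size defaults, scaled down.
small_spec <- function(seed = 1L, at_fraction = 0.61) {
  plastome_spec(lsc_len = 12000L, ssc_len = 2400L, ir_len = 3200L,
                at_fraction = at_fraction, n_genes = 24L, seed = seed)
}

small_plastome <- function(seed = 1L) generate_plastome(small_spec(seed))

# a bamboo-sized spec (full study scale), used sparingly
study_spec <- function(seed = 1L) {
  plastome_spec(lsc_len = 82000L, ssc_len = 12800L, ir_len = 21800L,
                at_fraction = 0.61, n_genes = 88L, seed = seed)
}

random_dna <- function(n, at = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}
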