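.onLoad <- function(libname, pkgname) {
  # precompute the IUPAC compatibility table once per session
  assign(".IUPAC_COMPAT", iupac_compat_matrix(), envir = parent.env(environment()))
  invisible()
}
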