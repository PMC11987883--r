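.onLoad <- function(libname, pkgname) {
  register_flow_backend("block_matching", block_matching_flow)
  invisible()
}
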