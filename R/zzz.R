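.onLoad <- function(libname, pkgname) {
  .registry_env$registry <- .default_registry()
  .registry_env$structure_cache <- new.env(parent = emptyenv())
}
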