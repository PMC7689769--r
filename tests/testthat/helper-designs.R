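# designed coils are expensive; build each once per test run
.design_cache <- new.env(parent = emptyenv())

cached_coil <- function(axis, ...) {
  key <- paste0("coil_", axis)
  if (is.null(.design_cache[[key]])) {
    .design_cache[[key]] <- design_gradient_coil(axis, ...)
  }
  .design_cache[[key]]
}
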