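# Scaled-down configuration used throughout the suite: 50 neurons per
# population keeps a full 4-second trial around a second of compute while
# preserving the qualitative dynamics.
small_config <- function(variant = "all_types", N = 50, ...) {
  network_config(variant, N = N, ...)
}

# Cache expensive shared objects across tests within one run.
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}
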