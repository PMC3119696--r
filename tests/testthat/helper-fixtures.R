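# lazily built shared fixtures (expensive geometry reused across test files)
.fixtures <- new.env()

shared_batch <- function(n = 12, seed = 42) {
  key <- sprintf("batch_%d_%d", n, seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_stimulus_batch(n, seed = seed)
  }
  .fixtures[[key]]
}
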