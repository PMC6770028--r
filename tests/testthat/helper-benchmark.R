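# The canonical synthetic benchmark (study-condition defaults, all seeds 42)
# is computed once per test run and shared by the acceptance tests.

.benchmark_cache <- new.env(parent = emptyenv())

canonical_benchmark <- function() {
  if (is.null(.benchmark_cache$run)) {
    .benchmark_cache$run <- run_comfa(list(), quiet = TRUE)
  }
  .benchmark_cache$run
}
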