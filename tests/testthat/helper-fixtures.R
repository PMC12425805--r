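# Small shared simulated datasets, built once per test run.

small_cfg <- function(...) {
  sim_config(n_sites = 200L, n_genes = 30L, seed = 11L, ...)
}

# cached small dataset for tests that only read it
.small_data <- NULL
small_data <- function() {
  if (is.null(.small_data)) {
    .small_data <<- simulate_moa_dataset(small_cfg())
  }
  .small_data
}
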