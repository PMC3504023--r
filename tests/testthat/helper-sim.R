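## Small shared simulation fixtures, built once per test run.

suppressPackageStartupMessages(library(dplyr))

small_config <- function(seed = 7, ...) {
  sim_config(genome_length = 2e5, n_sites = 30, n_duplicated_loci = 2,
             insert_range = c(120L, 300L), coverage = 30, seed = seed, ...)
}

.fixture_cache <- new.env()

small_truth <- function() {
  if (is.null(.fixture_cache$truth)) {
    .fixture_cache$truth <- simulate_reference(small_config())
  }
  .fixture_cache$truth
}

small_library <- function() {
  if (is.null(.fixture_cache$lib)) {
    .fixture_cache$lib <- simulate_rad_library(small_truth(), small_config())
  }
  .fixture_cache$lib
}

small_run <- function() {
  if (is.null(.fixture_cache$run)) {
    .fixture_cache$run <- run_rad_pipeline(small_config(),
                                           truth = small_truth())
  }
  .fixture_cache$run
}
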