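# Shared desk-scale fixtures: one short five-run session (24 TRs per run at
# a 20 Hz log) reused across files, with designs cached per kernel width.

small_config <- function(...) {
  sim_config(n_runs = 5, trs_per_run = 24, sample_rate = 20, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

small_log <- function() {
  if (is.null(.fixture_cache$log)) {
    .fixture_cache$log <- simulate_session(small_config(), seed = 101)
  }
  .fixture_cache$log
}

small_design <- function(fwhm = 30) {
  key <- paste0("design_", fwhm)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- build_design(small_log(), fwhm)
  }
  .fixture_cache[[key]]
}

# A small tuned dataset on the 30-degree basis: one shared unimodal truth.
small_dataset <- function(noise = 1, n_voxels = 30, seed = 7) {
  truth <- make_ground_truth("unimodal", 30, noise_multiplier = noise,
                             seed = seed)
  simulate_voxels(small_log(), truth, n_voxels, seed = seed + 1,
                  design = small_design(30))
}
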