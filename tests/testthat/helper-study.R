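# The scaled-down replication of the simulation study is expensive (a few
# minutes), so it is computed once per test run and shared by the acceptance
# blocks. Geometry: 100 x 100 fine cells per landscape, 50 landscapes,
# 20 replicates, window area fractions 1/4/9/49% — fixed study conditions,
# with fixed seeds.

.study_cache <- new.env(parent = emptyenv())

acceptance_study <- function(kind) {
  key <- paste0("study_", kind)
  if (is.null(.study_cache[[key]])) {
    cfgs <- study_grid(kind = kind, n_landscapes = 50, n_rows = 100,
                       n_cols = 100, n_replicates = 20, base_seed = 1)
    .study_cache[[key]] <- run_simulation_study(cfgs)
  }
  .study_cache[[key]]
}

# hardest regime: categorical, no autocorrelation, 40 replicates
acceptance_worst_case <- function() {
  if (is.null(.study_cache$worst)) {
    cfg <- scenario_config("none", kind = "categorical", n_landscapes = 50,
                           n_rows = 100, n_cols = 100, n_replicates = 40,
                           base_seed = 901)
    .study_cache$worst <- run_simulation_study(cfg,
                                               noise_levels = "high")
  }
  .study_cache$worst
}
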