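# End-to-end simulation study: for each spatial-autocorrelation scenario,
# simulate replicate datasets of neutral landscapes, aggregate by MWDA and
# DDA at every window size, calibrate noise, simulate responses and score
# AIC-based recovery of the scale-of-effect.

#' Run the scale-of-effect simulation study for one scenario
#'
#' For each replicate dataset: simulate `n_landscapes` landscapes (one per
#' coarse cell), compute the MWDA measure at every candidate window (the
#' window metric is averaged across each landscape, which is its own torus)
#' and the DDA measure for the whole landscape. The metric is the population
#' variance for continuous landscapes and Shannon evenness for categorical
#' ones. Then, for every true window `w` and noise level, simulate
#' `y = MWDA_w + N(0, sigma)` with sigma the stated percentile of the MWDA
#' values pooled across replicates within this scenario x window combination,
#' fit the four candidate models and select the scale by AIC.
#'
#' @param config a [scenario_config()] (or list of them, results row-bound).
#' @param noise_levels subset of `c("low", "moderate", "high")`.
#' @param progress print per-scenario progress lines.
#' @return An object of class `mwda_study`: a list of data frames
#'   `correlations` (scenario, window, rho), `selection` (scenario, window,
#'   noise, pct_correct, n_replicates), `fits` (one row per replicate x true
#'   window x noise: chosen radius, correctness, true-model R^2 and AIC) and
#'   `rsq` (mean true-model R^2 per combination), plus `sigma` (the
#'   calibrated noise levels).
#' @examples
#' \donttest{
#' cfg <- scenario_config("high", n_landscapes = 15, n_rows = 40,
#'                        n_cols = 40, n_replicates = 3, base_seed = 42)
#' st <- run_simulation_study(cfg)
#' st$selection
#' }
#' @export
run_simulation_study <- function(config,
                                 noise_levels = c("low", "moderate", "high"),
                                 progress = FALSE) {
  if (inherits(config, "scenario_config")) config <- list(config)
  stopifnot(all(vapply(config, inherits, logical(1), "scenario_config")))
  noise_levels <- match.arg(noise_levels, several.ok = TRUE)
  parts <- lapply(config, .run_one_scenario, noise_levels = noise_levels,
                  progress = progress)
  out <- list(
    correlations = do.call(rbind, lapply(parts, `[[`, "correlations")),
    selection    = do.call(rbind, lapply(parts, `[[`, "selection")),
    fits         = do.call(rbind, lapply(parts, `[[`, "fits")),
    rsq          = do.call(rbind, lapply(parts, `[[`, "rsq")),
    sigma        = do.call(rbind, lapply(parts, `[[`, "sigma"))
  )
  rownames(out$correlations) <- rownames(out$selection) <-
    rownames(out$fits) <- rownames(out$rsq) <- rownames(out$sigma) <- NULL
  class(out) <- "mwda_study"
  out
}

.run_one_scenario <- function(config, noise_levels, progress = FALSE) {
  radii <- config$window_radii
  nw <- length(radii)
  nl <- config$n_landscapes
  nr <- config$n_replicates
  spec <- if (config$kind == "continuous") metric_spec("variance")
          else metric_spec("shannon_evenness")
  mwda <- array(NA_real_, c(nr, nl, nw))
  dda <- matrix(NA_real_, nr, nl)
  t0 <- proc.time()[3]
  for (rep in seq_len(nr)) {
    ds <- generate_dataset(config, replicate = rep)
    for (i in seq_len(nl)) {
      g <- ds$landscapes[[i]]
      for (w in seq_len(nw)) {
        mwda[rep, i, w] <- mean(winmove(g, radii[w], spec)$values)
      }
      dda[rep, i] <- compute_metric(as.vector(g$values), spec)
    }
    if (progress) {
      message(sprintf("  %s/%s: replicate %d/%d (%.1fs elapsed)",
                      config$scenario, config$kind, rep, nr,
                      proc.time()[3] - t0))
    }
  }

  correlations <- data.frame(
    scenario = config$scenario, kind = config$kind, radius = radii,
    window_fraction = (2 * radii / config$coarse_cell_size)^2,
    rho = vapply(seq_len(nw), function(w)
      spearman_mwda_dda(as.vector(mwda[, , w]), as.vector(dda)), numeric(1))
  )

  sigma <- do.call(rbind, lapply(noise_levels, function(lv) {
    data.frame(scenario = config$scenario, kind = config$kind,
               radius = radii, noise = lv,
               sigma = vapply(seq_len(nw), function(w)
                 compute_sigma(as.vector(mwda[, , w]), lv), numeric(1)))
  }))

  # response simulation and selection; separate seed stream from generation
  set.seed((config$base_seed + 104729L) %% .Machine$integer.max)
  rows <- vector("list", nr * nw * length(noise_levels))
  ri <- 0L
  for (rep in seq_len(nr)) {
    cand <- lapply(seq_len(nw), function(w) mwda[rep, , w])
    names(cand) <- as.character(radii)
    for (w in seq_len(nw)) {
      for (lv in noise_levels) {
        sg <- sigma$sigma[sigma$radius == radii[w] & sigma$noise == lv]
        y <- mwda[rep, , w] + stats::rnorm(nl, 0, sg)
        sel <- select_scale(y, cand, true_radius = radii[w])
        truefit <- sel$fits[sel$fits$radius == radii[w], ]
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          scenario = config$scenario, kind = config$kind,
          replicate = rep, radius = radii[w], noise = lv, sigma = sg,
          chosen_radius = sel$chosen_radius, correct = sel$correct,
          r_squared_true = truefit$r_squared, aic_true = truefit$aic
        )
      }
    }
  }
  fits <- do.call(rbind, rows)

  agg <- function(v, by, f) stats::aggregate(v, by = by, FUN = f)
  by <- list(scenario = fits$scenario, kind = fits$kind,
             radius = fits$radius, noise = fits$noise)
  selection <- agg(list(pct_correct = fits$correct), by,
                   function(x) 100 * mean(x))
  selection$n_replicates <- nr
  rsq <- agg(list(r_squared = fits$r_squared_true), by, mean)

  list(correlations = correlations, selection = selection, fits = fits,
       rsq = rsq, sigma = sigma)
}

#' @export
print.mwda_study <- function(x, ...) {
  sc <- unique(x$selection$scenario)
  cat(sprintf("<mwda_study> %d scenario(s): %s\n", length(sc),
              paste(sc, collapse = ", ")))
  cat(sprintf("  %d selection combinations, %d replicate fits\n",
              nrow(x$selection), nrow(x$fits)))
  s <- summarize_study(x)
  cat("  mean %% correct by noise level:\n")
  print(s$pct_correct_by_noise, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Summarise a simulation study across scenarios and windows
#'
#' Reports, per noise level: the mean percentage of replicates with the
#' correct scale-of-effect averaged across scenario x window combinations
#' (and, separately, averaged across scenarios only), and the range of the
#' per-combination mean R^2 of the correct-scale model.
#'
#' @param study an `mwda_study` from [run_simulation_study()].
#' @return List of data frames: `pct_correct_by_noise`,
#'   `pct_correct_by_scenario`, `rsq_range_by_noise`.
#' @export
summarize_study <- function(study) {
  stopifnot(inherits(study, "mwda_study"))
  sel <- study$selection
  by_noise <- stats::aggregate(list(mean_pct_correct = sel$pct_correct),
                               by = list(kind = sel$kind, noise = sel$noise),
                               FUN = mean)
  by_scen <- stats::aggregate(list(mean_pct_correct = sel$pct_correct),
                              by = list(kind = sel$kind, noise = sel$noise,
                                        scenario = sel$scenario),
                              FUN = mean)
  rsq <- study$rsq
  rng <- stats::aggregate(list(r_squared = rsq$r_squared),
                          by = list(noise = rsq$noise),
                          FUN = function(v) c(min = min(v), max = max(v)))
  rng <- data.frame(noise = rng$noise, r_squared_min = rng$r_squared[, "min"],
                    r_squared_max = rng$r_squared[, "max"])
  list(pct_correct_by_noise = by_noise,
       pct_correct_by_scenario = by_scen,
       rsq_range_by_noise = rng)
}

#' Write study tables to CSV
#'
#' Writes `correlations.csv`, `selection.csv`, `fits.csv`, `rsq.csv` and
#' `sigma.csv` into a directory.
#'
#' @param study an `mwda_study`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study_csvs <- function(study, dir) {
  stopifnot(inherits(study, "mwda_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("correlations", "selection", "fits", "rsq", "sigma")) {
    utils::write.csv(study[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Build the full scenario grid of the simulation study
#'
#' Convenience constructor for the five spatial-autocorrelation scenarios at
#' shared geometry and replication, with per-scenario seeds derived from
#' `base_seed`.
#'
#' @param scenarios scenario names (default: all five).
#' @param base_seed integer; scenario `i` uses `base_seed + 101 * (i - 1)`.
#' @inheritParams scenario_config
#' @param ... further arguments passed to [scenario_config()].
#' @return List of [scenario_config()] objects.
#' @export
study_grid <- function(scenarios = c("none", "low_varied", "varied",
                                     "high_varied", "high"),
                       kind = "continuous", n_landscapes = 50,
                       n_rows = 100, n_cols = 100, n_replicates = 20,
                       base_seed = 1, ...) {
  lapply(seq_along(scenarios), function(i) {
    scenario_config(scenarios[i], kind = kind, n_landscapes = n_landscapes,
                    n_rows = n_rows, n_cols = n_cols,
                    n_replicates = n_replicates,
                    base_seed = (base_seed + 101L * (i - 1L)) %%
                      .Machine$integer.max, ...)
  })
}
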