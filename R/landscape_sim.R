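# Neutral-landscape generation: fractal Brownian surfaces by spectral
# synthesis, and weighted classification into land-cover classes.

#' Simulate a fractal Brownian surface
#'
#' Generates a continuous neutral landscape whose spatial autocorrelation is
#' controlled by a single parameter `fractal_dim` in (0, 1]: values near zero
#' give a rough, fragmented, essentially uncorrelated surface; a value of one
#' gives a smooth, highly aggregated landscape. Values are min-max rescaled
#' to `[0, 1]`.
#'
#' Synthesis is spectral: white Gaussian noise is filtered in the Fourier
#' domain with amplitude proportional to `f^(-beta/2)`, giving a Gaussian
#' field with power-spectrum exponent `beta`. The mapping from
#' `fractal_dim` to `beta` is
#' `beta = 0.5347 + 4.1861 * fractal_dim - 1.6817 * fractal_dim^2`,
#' calibrated so that the lag-1 Moran's I of synthesized surfaces matches
#' that of exact fractional Brownian surfaces with variogram `r^fractal_dim`
#' (simulated by Cholesky factorisation of the intrinsic covariance on 40-64
#' cell grids). The surrogate reproduces the rough-to-smooth autocorrelation
#' gradient of fractional Brownian landscapes rather than their exact
#' distribution. The zero frequency is suppressed; the filtered field is
#' real up to rounding because the amplitude filter is symmetric in
#' frequency.
#'
#' @param fractal_dim autocorrelation parameter in (0, 1].
#' @param n_rows,n_cols grid dimensions (positive integers).
#' @param seed optional integer; when given the surface is reproducible.
#' @param cell_size cell edge length in map units for the returned grid.
#' @return A continuous [raster_grid()] with values in `[0, 1]`.
#' @examples
#' rough  <- simulate_fbm(0.1, 50, 50, seed = 1)
#' smooth <- simulate_fbm(1.0, 50, 50, seed = 1)
#' @export
simulate_fbm <- function(fractal_dim, n_rows, n_cols, seed = NULL,
                         cell_size = 1) {
  if (!is.numeric(fractal_dim) || length(fractal_dim) != 1L ||
      fractal_dim <= 0 || fractal_dim > 1) {
    stop("`fractal_dim` must lie in (0, 1]", call. = FALSE)
  }
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 2L, n_cols >= 2L)
  if (!is.null(seed)) set.seed(seed)
  # spectral exponent calibrated against exact fractional Brownian surfaces
  # (variogram r^fractal_dim) by matching lag-1 Moran's I; monotone on (0,1]
  beta <- 0.5347 + 4.1861 * fractal_dim - 1.6817 * fractal_dim^2
  fr <- .fft_freq(n_rows)
  fc <- .fft_freq(n_cols)
  k2 <- outer(fr^2, fc^2, "+")
  amp <- k2^(-beta / 4)
  amp[1, 1] <- 0                      # remove the mean component
  wn <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  field <- Re(stats::fft(stats::fft(wn) * amp, inverse = TRUE)) /
    (n_rows * n_cols)
  rng <- range(field)
  vals <- if (rng[2] > rng[1]) (field - rng[1]) / (rng[2] - rng[1])
          else matrix(0.5, n_rows, n_cols)
  raster_grid(vals, cell_size = cell_size, kind = "continuous")
}

# cycles per grid length, as in the usual discrete Fourier frequency layout
.fft_freq <- function(n) {
  half <- floor(n / 2)
  c(0:half, seq.int(-(n - half - 1), -1)) / n
}

#' Sample land-cover class weightings
#'
#' Draws the intended proportion of each land-cover class for one simulated
#' landscape: the class count `k` is uniform on `k_range`, and the weights
#' are a symmetric Dirichlet(1) draw (uniform on the simplex) sorted in
#' descending order, so class 0 is always the commonest intended class.
#'
#' @param k_range integer interval for the number of classes, within
#'   `[2, 10]`; a single value fixes `k` (e.g. `5` for five land-cover
#'   classes).
#' @param seed optional integer for reproducibility.
#' @return Numeric weight vector of length `k`, positive, summing to 1.
#' @examples
#' sample_class_weights(5, seed = 1)
#' @export
sample_class_weights <- function(k_range = 5, seed = NULL) {
  k_range <- as.integer(range(k_range))
  if (k_range[1] < 2L || k_range[2] > 10L) {
    stop("`k_range` must lie within [2, 10]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  k <- if (k_range[1] == k_range[2]) k_range[1]
       else sample(k_range[1]:k_range[2], 1L)
  # Dirichlet(1, ..., 1) via normalised Exp(1) draws
  g <- stats::rexp(k)
  sort(g / sum(g), decreasing = TRUE)
}

#' Classify a continuous surface into land-cover classes by weightings
#'
#' Assigns each cell the class whose cumulative-weight interval contains its
#' value: with weights `(0.5, 0.25, 0.25)`, values in `[0, 0.5)` become class
#' 0, `[0.5, 0.75)` class 1, and `[0.75, 1]` class 2. Intervals are half-open
#' on the right except the last, which is closed at 1. Classes are coded
#' `0 .. k-1`.
#'
#' @param cont a continuous [raster_grid()] with values in `[0, 1]`.
#' @param weights positive weight vector summing to 1 (length `k >= 2`).
#' @return A categorical [raster_grid()] of class codes.
#' @examples
#' g <- simulate_fbm(0.5, 20, 20, seed = 2)
#' table(classify(g, c(0.5, 0.25, 0.25))$values)
#' @export
classify <- function(cont, weights) {
  stopifnot(inherits(cont, "raster_grid"))
  if (cont$kind != "continuous") {
    stop("`cont` must be a continuous grid", call. = FALSE)
  }
  if (length(weights) < 2L || any(weights <= 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    stop("`weights` must be >= 2 positive proportions summing to 1",
         call. = FALSE)
  }
  v <- cont$values
  ok <- is.na(v) | (v >= 0 & v <= 1)
  if (!all(ok)) {
    stop("continuous values must lie in [0, 1] to be classified",
         call. = FALSE)
  }
  breaks <- cumsum(weights)[-length(weights)]
  cls <- matrix(findInterval(v, breaks), nrow(v), ncol(v))
  cls[is.na(v)] <- NA_real_
  raster_grid(cls, cell_size = cont$cell_size, origin = cont$origin,
              kind = "categorical")
}

.fd_ranges <- list(
  none        = c(0.1, 0.1),
  low_varied  = c(0.1, 0.5),
  varied      = c(0.1, 1.0),
  high_varied = c(0.5, 1.0),
  high        = c(1.0, 1.0)
)

#' Scenario configuration for the simulation study
#'
#' Bundles one spatial-autocorrelation scenario with the geometry and
#' replication of the study. The five named scenarios fix the range the
#' per-landscape autocorrelation parameter is drawn from: `none` (0.1 for
#' every landscape), `low_varied` (0.1-0.5), `varied` (0.1-1), `high_varied`
#' (0.5-1) and `high` (1 for every landscape).
#'
#' Each simulated landscape stands for one coarse response-grain cell, built
#' of `n_rows x n_cols` fine predictor-grain cells. Window radii are given as
#' map units; the default radii cover window areas of 1%, 4%, 9% and 49% of
#' the coarse cell (window side 10%, 20%, 30% and 70% of the coarse cell
#' side).
#'
#' @param scenario one of `"none"`, `"low_varied"`, `"varied"`,
#'   `"high_varied"`, `"high"`.
#' @param n_landscapes number of coarse cells (independent landscapes).
#' @param n_rows,n_cols fine cells per landscape.
#' @param n_replicates replicate datasets (each regenerates all landscapes).
#' @param fine_cell_size fine cell edge, map units.
#' @param window_radii window radii in map units; defaults to the 1/4/9/49%
#'   area fractions of the coarse cell.
#' @param kind `"continuous"` (variance metric) or `"categorical"` (Shannon
#'   evenness of sampled land-cover classes).
#' @param n_classes land-cover classes for categorical landscapes.
#' @param base_seed integer seed making the whole scenario reproducible.
#' @param max_cells resource guard: error if
#'   `n_replicates * n_landscapes * n_rows * n_cols` exceeds this.
#' @return An object of class `scenario_config`.
#' @examples
#' scenario_config("varied", n_landscapes = 10, n_replicates = 2,
#'                 n_rows = 50, n_cols = 50)
#' @export
scenario_config <- function(scenario = c("none", "low_varied", "varied",
                                         "high_varied", "high"),
                            n_landscapes = 50, n_rows = 100, n_cols = 100,
                            n_replicates = 20, fine_cell_size = 25,
                            window_radii = NULL,
                            kind = c("continuous", "categorical"),
                            n_classes = 5, base_seed = 1,
                            max_cells = 2e9) {
  scenario <- match.arg(scenario)
  kind <- match.arg(kind)
  coarse <- n_cols * fine_cell_size
  if (is.null(window_radii)) {
    # window side fractions 0.1, 0.2, 0.3, 0.7 of the coarse cell side,
    # i.e. window areas 1%, 4%, 9%, 49% of the coarse cell
    window_radii <- coarse * c(0.05, 0.10, 0.15, 0.35)
  }
  total <- as.numeric(n_replicates) * n_landscapes * n_rows * n_cols
  if (total > max_cells) {
    stop(sprintf(
      "scenario asks for %.3g fine cells, above the cap of %.3g; %s",
      total, max_cells,
      "raise `max_cells` explicitly to run at this scale"), call. = FALSE)
  }
  structure(
    list(scenario = scenario, fd_range = .fd_ranges[[scenario]],
         n_landscapes = as.integer(n_landscapes),
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         n_replicates = as.integer(n_replicates),
         fine_cell_size = as.numeric(fine_cell_size),
         coarse_cell_size = as.numeric(coarse),
         window_radii = as.numeric(window_radii),
         kind = kind, n_classes = as.integer(n_classes),
         base_seed = as.integer(base_seed), max_cells = max_cells),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s (autocorrelation %g-%g), %s landscapes\n",
              x$scenario, x$fd_range[1], x$fd_range[2], x$kind))
  cat(sprintf("  %d landscapes of %d x %d cells (%g map units), %d replicates, seed %d\n",
              x$n_landscapes, x$n_rows, x$n_cols, x$fine_cell_size,
              x$n_replicates, x$base_seed))
  cat(sprintf("  window radii: %s map units\n",
              paste(format(x$window_radii), collapse = ", ")))
  invisible(x)
}

#' Generate one replicate dataset of neutral landscapes
#'
#' Simulates `n_landscapes` independent landscapes for a scenario: each draws
#' its own autocorrelation parameter uniformly from the scenario's range,
#' and, for categorical scenarios, its own land-cover class weightings, which
#' are then used to classify the continuous surface. Fully reproducible from
#' `config$base_seed` (offset by `replicate` so replicate datasets differ but
#' are each reproducible).
#'
#' @param config a [scenario_config()].
#' @param replicate replicate index (>= 1) mixed into the seed.
#' @return A list with `landscapes` (list of [raster_grid()]) and `manifest`
#'   (data frame: landscape id, fractal_dim, and class weights for
#'   categorical runs).
#' @examples
#' d <- generate_dataset(scenario_config("high", n_landscapes = 2,
#'                                       n_rows = 30, n_cols = 30))
#' d$manifest
#' @export
generate_dataset <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed((config$base_seed + 7919L * (as.integer(replicate) - 1L)) %%
             .Machine$integer.max)
  n <- config$n_landscapes
  fd <- if (diff(config$fd_range) == 0) rep(config$fd_range[1], n)
        else stats::runif(n, config$fd_range[1], config$fd_range[2])
  landscapes <- vector("list", n)
  wts <- vector("list", n)
  for (i in seq_len(n)) {
    g <- simulate_fbm(fd[i], config$n_rows, config$n_cols,
                      cell_size = config$fine_cell_size)
    if (config$kind == "categorical") {
      w <- sample_class_weights(config$n_classes)
      wts[[i]] <- w
      g <- classify(g, w)
    }
    landscapes[[i]] <- g
  }
  manifest <- data.frame(landscape = seq_len(n), fractal_dim = fd)
  if (config$kind == "categorical") {
    manifest$weights <- vapply(wts, function(w)
      paste(formatC(w, format = "g", digits = 6), collapse = ";"),
      character(1))
  }
  list(landscapes = landscapes, manifest = manifest)
}

#' Moran's I at lag one
#'
#' Spatial autocorrelation of a grid between rook-adjacent cells, used to
#' check that the fractal surface generator orders landscapes from rough to
#' smooth as its parameter increases.
#'
#' @param grid a [raster_grid()] or numeric matrix.
#' @return Moran's I (about 0 for white noise, toward 1 for smooth fields).
#' @export
morans_i_lag1 <- function(grid) {
  m <- if (inherits(grid, "raster_grid")) grid$values else grid
  z <- m - mean(m)
  num <- sum(z[-nrow(z), ] * z[-1, ]) + sum(z[, -ncol(z)] * z[, -1])
  w <- (nrow(z) - 1) * ncol(z) + nrow(z) * (ncol(z) - 1)
  (length(z) / (2 * w)) * (2 * num / sum(z^2))
}
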