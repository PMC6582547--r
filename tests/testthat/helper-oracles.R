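# Independent brute-force oracles. These deliberately share no code with the
# package's summed-area-table / vectorised engines.

# metric over one vector, naive formulas
oracle_metric <- function(values, spec) {
  values <- values[!is.na(values)]
  if (spec$name == "shannon_evenness") {
    if (!is.null(spec$include_classes)) {
      values <- values[values %in% spec$include_classes]
    }
    if (!length(values)) return(NA_real_)
    tab <- table(values)
    s <- if (!is.null(spec$class_universe)) length(spec$class_universe)
         else length(tab)
    if (s <= 1) return(0)
    p <- as.numeric(tab) / sum(tab)
    return(-sum(p * log(p)) / log(s))
  }
  if (!length(values)) return(NA_real_)
  switch(spec$name,
         variance = sum((values - sum(values) / length(values))^2) /
           length(values),
         range = max(values) - min(values),
         mean = sum(values) / length(values),
         user_defined = spec$fn(values))
}

# naive double-loop moving window with torus wrap
oracle_winmove <- function(grid, radius, spec) {
  h <- floor(radius / grid$cell_size + 0.5)
  v <- grid$values
  n <- nrow(v); m <- ncol(v)
  out <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      ri <- ((i - h):(i + h) - 1) %% n + 1
      ci <- ((j - h):(j + h) - 1) %% m + 1
      win <- as.vector(v[ri, ci])
      if (anyNA(win) && spec$name != "shannon_evenness") {
        out[i, j] <- NA_real_
      } else if (anyNA(win)) {
        out[i, j] <- NA_real_
      } else {
        out[i, j] <- oracle_metric(win, spec)
      }
    }
  }
  out
}

# naive aggregation of a value matrix into coarse blocks of `f` fine cells
oracle_block_agg <- function(values, f, stat = mean) {
  n <- nrow(values) / f; m <- ncol(values) / f
  out <- matrix(NA_real_, n, m)
  for (r in seq_len(n)) {
    for (cc in seq_len(m)) {
      block <- values[((r - 1) * f + 1):(r * f), ((cc - 1) * f + 1):(cc * f)]
      block <- block[!is.na(block)]
      out[r, cc] <- if (length(block)) stat(block) else NA_real_
    }
  }
  out
}

# Spearman via explicit average ranks then the Pearson formula
oracle_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# percentile by explicit sort-and-interpolate (the linear interpolation rule)
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  hpos <- (n - 1) * p + 1
  lo <- floor(hpos); hi <- ceiling(hpos)
  x[lo] + (hpos - lo) * (x[hi] - x[lo])
}

# Gaussian log-likelihood of an OLS fit, by the closed form
oracle_gauss_loglik <- function(y, x) {
  fit <- stats::lm(y ~ x)
  n <- length(y)
  rss <- sum(stats::residuals(fit)^2)
  -n / 2 * (log(2 * pi) + log(rss / n) + 1)
}

random_grid <- function(n, m, kind = "continuous", n_classes = 3,
                        cell_size = 1) {
  vals <- if (kind == "continuous") matrix(stats::runif(n * m), n, m)
          else matrix(sample(0:(n_classes - 1), n * m, replace = TRUE), n, m)
  raster_grid(vals, cell_size = cell_size, kind = kind)
}
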