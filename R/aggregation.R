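# Moving-window data aggregation (MWDA) and the direct aggregation baseline.
#
# The window engines are exact, not strided: every fine cell receives the
# metric of its full Moore neighbourhood, with edges resolved by torus
# wrapping. Sums and sums of squares use summed-area tables on the padded
# grid; counts per land-cover class use one summed-area table per class.

# summed-area table (no zero padding row/col; caller adds it)
.sat <- function(M) {
  S <- apply(M, 2, cumsum)
  t(apply(S, 1, cumsum))
}

# Box sums of all (2h+1)^2 torus windows of `mat`. NA must be pre-masked.
.torus_window_sums <- function(mat, h) {
  n <- nrow(mat); m <- ncol(mat)
  ri <- ((seq.int(1L - h, n + h) - 1L) %% n) + 1L
  ci <- ((seq.int(1L - h, m + h) - 1L) %% m) + 1L
  P <- mat[ri, ci, drop = FALSE]
  w <- 2L * h + 1L
  S0 <- matrix(0, n + w, m + w)
  S0[-1L, -1L] <- .sat(P)
  S0[(1:n) + w, (1:m) + w, drop = FALSE] -
    S0[1:n, (1:m) + w, drop = FALSE] -
    S0[(1:n) + w, 1:m, drop = FALSE] +
    S0[1:n, 1:m, drop = FALSE]
}

# torus-wrapped padded copy of a plain matrix
.torus_pad_mat <- function(mat, h) {
  n <- nrow(mat); m <- ncol(mat)
  ri <- ((seq.int(1L - h, n + h) - 1L) %% n) + 1L
  ci <- ((seq.int(1L - h, m + h) - 1L) %% m) + 1L
  mat[ri, ci, drop = FALSE]
}

.check_metric_kind <- function(spec, kind) {
  mk <- metric_kind(spec)
  if (mk != "any" && mk != kind) {
    stop(sprintf("metric \"%s\" needs a %s grid but the input is %s",
                 spec$name, mk, kind), call. = FALSE)
  }
}

#' Moving-window heterogeneity surface
#'
#' Evaluates a heterogeneity metric over the Moore neighbourhood of every
#' fine-grain cell. The output has the same shape and resolution as the
#' input; cell `(i, j)` holds the metric of the `(2h+1) x (2h+1)` window
#' centred there, where `h` is the window radius converted to cells. Edges
#' are resolved by torus wrapping (opposite edges are neighbours), so every
#' cell sees a full window.
#'
#' A window containing any missing fine cell yields a missing value, except
#' that cells excluded by `include_classes` in a categorical metric are
#' simply not counted (a window with no retained cells is missing).
#'
#' @param fine a [raster_grid()] at the predictor grain.
#' @param window a [window_spec()] or bare radius in map units.
#' @param metric a [metric_spec()] or metric name string.
#' @return A continuous `raster_grid` of window metric values.
#' @examples
#' g <- raster_grid(matrix(runif(400), 20), cell_size = 25)
#' wm <- winmove(g, window_spec(50), "var")
#' @export
winmove <- function(fine, window, metric) {
  stopifnot(inherits(fine, "raster_grid"))
  if (is.character(metric)) metric <- metric_spec(metric)
  if (is.numeric(window)) window <- window_spec(window)
  .check_metric_kind(metric, fine$kind)
  h <- radius_to_cells(window, fine$cell_size)
  d <- dim(fine$values)
  if (2L * h + 1L > min(d) || h > min(d)) {
    stop(sprintf("window of %d x %d cells exceeds the %d x %d landscape",
                 2L * h + 1L, 2L * h + 1L, d[1], d[2]), call. = FALSE)
  }
  vals <- fine$values
  w2 <- (2 * h + 1)^2
  bad <- NULL
  if (any(fine$missing_mask)) {
    bad <- .torus_window_sums(fine$missing_mask * 1, h) > 0
  }
  out <- switch(metric$name,
    mean = {
      v0 <- vals; v0[is.na(v0)] <- 0
      .torus_window_sums(v0, h) / w2
    },
    variance = {
      # centre on the grand mean before squaring to keep the summed-area
      # tables well conditioned on large windows
      mu <- mean(vals, na.rm = TRUE)
      xc <- vals - mu; xc[is.na(xc)] <- 0
      s1 <- .torus_window_sums(xc, h)
      s2 <- .torus_window_sums(xc * xc, h)
      pmax(s2 / w2 - (s1 / w2)^2, 0)
    },
    range = {
      P <- .torus_pad_mat(vals, h)
      n <- d[1]; m <- d[2]
      mx <- mn <- matrix(-Inf, n, m); mn <- matrix(Inf, n, m)
      for (dx in -h:h) for (dy in -h:h) {
        sub <- P[(1 + h + dx):(n + h + dx), (1 + h + dy):(m + h + dy),
                 drop = FALSE]
        mx <- pmax(mx, sub)
        mn <- pmin(mn, sub)
      }
      mx - mn
    },
    shannon_evenness = .winmove_shannon(fine, metric, h),
    user_defined = .winmove_user(fine, metric, h)
  )
  if (!is.null(bad) && metric$name != "user_defined") out[bad] <- NA_real_
  raster_grid(out, cell_size = fine$cell_size, origin = fine$origin,
              kind = "continuous")
}

.winmove_shannon <- function(fine, spec, h) {
  vals <- fine$values
  classes <- sort(unique(vals[!is.na(vals)]))
  if (!is.null(spec$include_classes)) {
    classes <- intersect(classes, spec$include_classes)
  }
  d <- dim(vals)
  total <- matrix(0, d[1], d[2])
  plnp <- matrix(0, d[1], d[2])
  counts <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    counts[[i]] <- .torus_window_sums((!is.na(vals) & vals == classes[i]) * 1, h)
    total <- total + counts[[i]]
  }
  s_local <- matrix(0L, d[1], d[2])
  for (cnt in counts) s_local <- s_local + (cnt > 0)
  for (cnt in counts) {
    p <- cnt / total          # total = 0 gives NaN, resolved below
    term <- p * log(p)
    term[cnt == 0] <- 0
    plnp <- plnp + term
  }
  if (!is.null(spec$class_universe)) {
    s <- length(spec$class_universe)
    out <- if (s <= 1L) matrix(0, d[1], d[2]) else -plnp / log(s)
  } else {
    out <- matrix(0, d[1], d[2])            # S = 1 windows: evenness 0
    multi <- s_local > 1L
    out[multi] <- -plnp[multi] / log(s_local[multi])
  }
  out[total == 0] <- NA_real_               # nothing retained in the window
  out
}

.winmove_user <- function(fine, spec, h) {
  vals <- fine$values
  P <- .torus_pad_mat(vals, h)
  d <- dim(vals)
  out <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      win <- P[i:(i + 2L * h), j:(j + 2L * h)]
      if (anyNA(win)) next
      out[i, j] <- compute_metric(as.vector(win), spec,
                                  where = sprintf("cell (%d, %d)", i, j))
    }
  }
  out
}

.resolve_grain <- function(fine, grain) {
  if (inherits(grain, "grain_map")) grain else build_grain_map(fine, grain)
}

.agg_by_grain <- function(values, gm, stat) {
  f <- factor(as.vector(gm$assignment), levels = gm$coarse_ids$id)
  v <- vapply(split(as.vector(values), f), function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_
    else if (stat == "mean") mean(x) else stats::median(x)
  }, numeric(1))
  out <- matrix(NA_real_, gm$n_rows, gm$n_cols)
  out[cbind(gm$coarse_ids$row, gm$coarse_ids$col)] <- v
  out
}

#' Moving-window data aggregation (MWDA)
#'
#' The three-step aggregation: evaluate a heterogeneity metric in a moving
#' window sized by the scale-of-effect ([winmove()]), then summarise the
#' window surface within each coarse response-grain cell with `agg_stat`.
#' The result carries within-cell spatial structure that a direct summary of
#' the coarse cell would smooth away.
#'
#' `edge` controls how neighbourhoods behave at coarse-cell boundaries:
#' `"whole"` (default) computes the window surface once across the full fine
#' raster with torus padding of the full extent, so windows near a coarse
#' boundary see into the neighbouring coarse cell, as on a real contiguous
#' study region; `"per_landscape"` treats every coarse cell as an independent
#' landscape with its own torus, the design used when coarse cells are
#' simulated independently.
#'
#' @param fine a [raster_grid()] at the predictor grain.
#' @param window a [window_spec()] or bare radius in map units.
#' @param metric a [metric_spec()] or metric name string.
#' @param grain a [grain_map()][build_grain_map()] built from `fine`, or a
#'   coarse cell size in map units.
#' @param agg_stat `"mean"` (default) or `"median"`.
#' @param edge `"whole"` or `"per_landscape"` (see Details).
#' @return A `coarse_grid`: coarse-resolution values plus a provenance record
#'   of metric, window and aggregation statistic.
#' @examples
#' g <- raster_grid(matrix(runif(1600), 40), cell_size = 25)
#' winmove_agg(g, 50, "var", grain = 500)
#' @export
winmove_agg <- function(fine, window, metric, grain,
                        agg_stat = c("mean", "median"),
                        edge = c("whole", "per_landscape")) {
  agg_stat <- match.arg(agg_stat)
  edge <- match.arg(edge)
  if (is.character(metric)) metric <- metric_spec(metric)
  if (is.numeric(window)) window <- window_spec(window)
  gm <- .resolve_grain(fine, grain)
  if (edge == "whole") {
    wm <- winmove(fine, window, metric)
    vals <- .agg_by_grain(wm$values, gm, agg_stat)
  } else {
    vals <- matrix(NA_real_, gm$n_rows, gm$n_cols)
    f <- gm$factor
    for (k in seq_len(nrow(gm$coarse_ids))) {
      r <- gm$coarse_ids$row[k]; cc <- gm$coarse_ids$col[k]
      rows <- ((r - 1L) * f + 1L):(r * f)
      cols <- ((cc - 1L) * f + 1L):(cc * f)
      sub <- raster_grid(fine$values[rows, cols, drop = FALSE],
                         cell_size = fine$cell_size, kind = fine$kind)
      wv <- winmove(sub, window, metric)$values
      wv <- wv[!is.na(wv)]
      vals[r, cc] <- if (!length(wv)) NA_real_
                     else if (agg_stat == "mean") mean(wv) else stats::median(wv)
    }
  }
  coarse_grid(vals, gm$coarse_cell_size,
              provenance = list(metric = metric$name, window = window$radius,
                                agg_stat = agg_stat, edge = edge,
                                method = "mwda"))
}

#' Direct data aggregation (DDA)
#'
#' The baseline the moving-window approach is compared against: the
#' heterogeneity metric is computed once over all fine cells of each coarse
#' cell, ignoring within-cell spatial arrangement.
#'
#' @inheritParams winmove_agg
#' @return A `coarse_grid` with provenance `window = "direct"`.
#' @examples
#' g <- raster_grid(matrix(sample(0:1, 1600, TRUE), 40), cell_size = 25,
#'                  kind = "categorical")
#' nomove_agg(g, "shannon", grain = 500)
#' @export
nomove_agg <- function(fine, metric, grain) {
  if (is.character(metric)) metric <- metric_spec(metric)
  .check_metric_kind(metric, fine$kind)
  gm <- .resolve_grain(fine, grain)
  f <- factor(as.vector(gm$assignment), levels = gm$coarse_ids$id)
  v <- vapply(split(as.vector(fine$values), f),
              function(x) compute_metric(x, metric), numeric(1))
  vals <- matrix(NA_real_, gm$n_rows, gm$n_cols)
  vals[cbind(gm$coarse_ids$row, gm$coarse_ids$col)] <- v
  coarse_grid(vals, gm$coarse_cell_size,
              provenance = list(metric = metric$name, window = "direct",
                                agg_stat = NA_character_, edge = NA_character_,
                                method = "dda"))
}

#' Coarse response-grain grid
#'
#' Container for aggregated values at the response grain, with a provenance
#' record identifying how each value was produced (metric, window radius or
#' `"direct"`, aggregation statistic).
#'
#' @param values numeric matrix at the coarse grain.
#' @param coarse_cell_size coarse cell edge length in map units.
#' @param provenance named list describing the computation.
#' @return An object of class `coarse_grid`.
#' @export
coarse_grid <- function(values, coarse_cell_size, provenance = list()) {
  stopifnot(is.matrix(values), is.numeric(coarse_cell_size),
            coarse_cell_size > 0)
  structure(list(values = values, coarse_cell_size = coarse_cell_size,
                 provenance = provenance),
            class = "coarse_grid")
}

#' @export
print.coarse_grid <- function(x, ...) {
  d <- dim(x$values)
  p <- x$provenance
  win <- if (identical(p$window, "direct")) "direct (no window)"
         else sprintf("window radius %s", format(p$window))
  cat(sprintf("<coarse_grid> %d x %d cells of %g map units\n", d[1], d[2],
              x$coarse_cell_size))
  cat(sprintf("  %s, metric %s, %s\n", toupper(p$method %||% "?"),
              p$metric %||% "?", win))
  invisible(x)
}

#' @export
as.data.frame.coarse_grid <- function(x, ...) {
  d <- dim(x$values)
  data.frame(
    coarse_id = seq_len(d[1] * d[2]),
    row = rep(seq_len(d[1]), each = d[2]),
    col = rep(seq_len(d[2]), times = d[1]),
    value = as.vector(t(x$values))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
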