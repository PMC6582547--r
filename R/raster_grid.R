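#' In-memory raster grid
#'
#' A `raster_grid` is a rectangular 2-D array of cell values with a square
#' cell size in map units, the map coordinate of the lower-left corner of the
#' extent, and a kind flag distinguishing continuous surfaces (e.g. elevation,
#' NDVI) from categorical ones (e.g. land-cover class codes). Array indexing
#' is row-major with cell `[1, 1]` at the top-left of the array; the `origin`
#' refers to the lower-left corner of the mapped extent. Missing cells are
#' encoded as `NA` in `values` and mirrored in `missing_mask`.
#'
#' @param values numeric matrix of cell values; `NA` marks missing cells.
#'   For categorical grids all non-missing values must be non-negative
#'   integers (class codes).
#' @param cell_size positive cell edge length in map units (cells are square).
#' @param origin length-2 numeric, map coordinates `(x, y)` of the lower-left
#'   corner of the extent.
#' @param kind `"continuous"` or `"categorical"`.
#' @param missing_mask optional logical matrix the same shape as `values`;
#'   cells flagged `TRUE` are treated as missing in addition to `NA`s.
#'
#' @return An object of class `raster_grid` with fields `values`,
#'   `cell_size`, `origin`, `kind` and `missing_mask`.
#' @examples
#' r <- raster_grid(matrix(runif(100), 10), cell_size = 25)
#' dim(r)
#' @export
raster_grid <- function(values, cell_size = 1, origin = c(0, 0),
                        kind = c("continuous", "categorical"),
                        missing_mask = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("`values` must be non-empty", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || !is.finite(cell_size) ||
      cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  if (length(origin) != 2L || !is.numeric(origin)) {
    stop("`origin` must be a length-2 numeric (x, y)", call. = FALSE)
  }
  if (is.null(missing_mask)) {
    missing_mask <- is.na(values)
  } else {
    if (!is.logical(missing_mask) || !identical(dim(missing_mask), dim(values))) {
      stop("`missing_mask` must be a logical matrix with the shape of `values`",
           call. = FALSE)
    }
    missing_mask <- missing_mask | is.na(values)
    values[missing_mask] <- NA_real_
  }
  if (kind == "categorical") {
    v <- values[!missing_mask]
    if (length(v) && (any(v < 0) || any(v != round(v)))) {
      stop("categorical grids must hold non-negative integer class codes",
           call. = FALSE)
    }
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), kind = kind, missing_mask = missing_mask),
    class = "raster_grid"
  )
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<raster_grid> %d x %d cells, %s, cell size %g map units\n",
              d[1], d[2], x$kind, x$cell_size))
  cat(sprintf("  extent: %g x %g map units, origin (%g, %g)\n",
              d[2] * x$cell_size, d[1] * x$cell_size, x$origin[1], x$origin[2]))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values: [%g, %g], %d missing cells\n",
              rng[1], rng[2], sum(x$missing_mask)))
  invisible(x)
}

#' Moving-window specification
#'
#' The scale-of-effect of an ecological process is expressed as a Moore
#' (square, queen's-rule) neighbourhood whose radius is the distance in map
#' units from the focal cell to the edge of the window.
#'
#' @param radius positive distance from the focal cell to the window edge, in
#'   map units.
#' @return An object of class `window_spec`.
#' @examples
#' window_spec(500)
#' @export
window_spec <- function(radius) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0) {
    stop("`radius` must be a single positive number (map units)", call. = FALSE)
  }
  structure(list(radius = as.numeric(radius), shape = "moore"),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> Moore neighbourhood, radius %g map units\n",
              x$radius))
  invisible(x)
}

#' Convert a window radius in map units to a half-width in cells
#'
#' Uses round-half-up so a radius exactly midway between two cell multiples
#' rounds to the larger half-width. The full window side is `2 * result + 1`
#' cells.
#'
#' @param window a [window_spec()] (a bare positive number is also accepted).
#' @param cell_size cell edge length in map units.
#' @return Integer half-width in cells (>= 1).
#' @examples
#' radius_to_cells(window_spec(500), 25) # 20 cells, window side 41
#' @export
radius_to_cells <- function(window, cell_size) {
  if (is.numeric(window)) window <- window_spec(window)
  stopifnot(inherits(window, "window_spec"))
  if (!is.numeric(cell_size) || cell_size <= 0) {
    stop("`cell_size` must be positive", call. = FALSE)
  }
  h <- floor(window$radius / cell_size + 0.5)  # round half up
  if (h < 1) {
    stop(sprintf(
      "window radius %g map units is below half a cell (%g): the window %s",
      window$radius, cell_size / 2,
      "degenerates to the focal cell only"), call. = FALSE)
  }
  as.integer(h)
}

#' Pad a raster with wrap-around (torus) borders
#'
#' Appends `pad_cells` rows/columns on every side, copied from the opposite
#' edge, so that cells on one edge neighbour cells on the opposite edge. Used
#' to remove edge effects from moving-window computations on simulated
#' landscapes.
#'
#' @param grid a [raster_grid()].
#' @param pad_cells positive integer number of cells to add on each side; must
#'   not exceed either grid dimension (a larger wrap would overlap itself).
#' @return A `raster_grid` enlarged by `2 * pad_cells` on each axis; the
#'   origin is shifted so the original interior keeps its map position.
#' @examples
#' g <- raster_grid(matrix(1:9, 3, byrow = TRUE))
#' dim(pad_torus(g, 1))
#' @export
pad_torus <- function(grid, pad_cells) {
  stopifnot(inherits(grid, "raster_grid"))
  p <- as.integer(pad_cells)
  if (p < 1L) stop("`pad_cells` must be a positive integer", call. = FALSE)
  d <- dim(grid$values)
  if (p > min(d)) {
    stop(sprintf("`pad_cells` (%d) exceeds a grid dimension (%d x %d): %s",
                 p, d[1], d[2], "the wrap would self-overlap"), call. = FALSE)
  }
  ri <- ((seq.int(1L - p, d[1] + p) - 1L) %% d[1]) + 1L
  ci <- ((seq.int(1L - p, d[2] + p) - 1L) %% d[2]) + 1L
  raster_grid(grid$values[ri, ci, drop = FALSE],
              cell_size = grid$cell_size,
              origin = grid$origin - p * grid$cell_size,
              kind = grid$kind)
}

# central crop undoing pad_torus; internal
crop_border <- function(grid, pad_cells) {
  p <- as.integer(pad_cells)
  d <- dim(grid$values)
  stopifnot(p >= 1L, 2L * p < min(d))
  raster_grid(grid$values[(p + 1L):(d[1] - p), (p + 1L):(d[2] - p), drop = FALSE],
              cell_size = grid$cell_size,
              origin = grid$origin + p * grid$cell_size,
              kind = grid$kind)
}

#' Map fine cells to the coarse response-grain cells containing them
#'
#' Builds the correspondence between a fine predictor-grain raster and a
#' coarse response grain that tiles it exactly. Coarse cells are numbered
#' row-major from the top-left of the array.
#'
#' @param fine a [raster_grid()] at the predictor grain.
#' @param coarse_cell_size coarse cell edge length in map units; must be an
#'   integer multiple of the fine cell size, and the fine extent must divide
#'   into whole coarse cells.
#' @return An object of class `grain_map` with fields `coarse_cell_size`,
#'   `factor` (fine cells per coarse cell edge), `assignment` (integer matrix,
#'   coarse id of every fine cell) and `coarse_ids` (data frame: `id`, `row`,
#'   `col` in the coarse grid).
#' @examples
#' f <- raster_grid(matrix(0, 4, 4), cell_size = 1)
#' build_grain_map(f, 2)$coarse_ids
#' @export
build_grain_map <- function(fine, coarse_cell_size) {
  stopifnot(inherits(fine, "raster_grid"))
  if (!is.numeric(coarse_cell_size) || coarse_cell_size <= 0) {
    stop("`coarse_cell_size` must be positive", call. = FALSE)
  }
  f <- coarse_cell_size / fine$cell_size
  if (abs(f - round(f)) > 1e-9 * f) {
    stop(sprintf(
      "coarse cell size %g is not an integer multiple of fine cell size %g",
      coarse_cell_size, fine$cell_size), call. = FALSE)
  }
  f <- as.integer(round(f))
  d <- dim(fine$values)
  if (d[1] %% f != 0L || d[2] %% f != 0L) {
    stop(sprintf(
      "fine extent (%d x %d cells of %g) does not tile into coarse cells of %g map units",
      d[1], d[2], fine$cell_size, coarse_cell_size), call. = FALSE)
  }
  n_cr <- d[1] %/% f
  n_cc <- d[2] %/% f
  crow <- (seq_len(d[1]) - 1L) %/% f + 1L
  ccol <- (seq_len(d[2]) - 1L) %/% f + 1L
  assignment <- outer(crow, ccol, function(r, c) (r - 1L) * n_cc + c)
  storage.mode(assignment) <- "integer"
  coarse_ids <- data.frame(
    id  = seq_len(n_cr * n_cc),
    row = rep(seq_len(n_cr), each = n_cc),
    col = rep(seq_len(n_cc), times = n_cr)
  )
  structure(
    list(coarse_cell_size = as.numeric(coarse_cell_size), factor = f,
         n_rows = n_cr, n_cols = n_cc,
         assignment = assignment, coarse_ids = coarse_ids),
    class = "grain_map"
  )
}

#' @export
print.grain_map <- function(x, ...) {
  cat(sprintf("<grain_map> %d x %d coarse cells of %g map units (%d x %d fine cells each)\n",
              x$n_rows, x$n_cols, x$coarse_cell_size, x$factor, x$factor))
  invisible(x)
}
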