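#' Read an ESRI ASCII grid
#'
#' Reads a single-band plain-text raster in ESRI ASCII grid format (`.asc`):
#' a six-line header (`ncols`, `nrows`, `xllcorner`/`xllcenter`,
#' `yllcorner`/`yllcenter`, `cellsize`, optional `NODATA_value`) followed by
#' rows of cell values from the top row down. Cells equal to the nodata value
#' become missing.
#'
#' @param path file to read.
#' @param kind `"auto"` infers `"categorical"` when every non-missing value is
#'   a non-negative integer; pass `"continuous"` or `"categorical"` to force.
#' @return A [raster_grid()].
#' @export
read_asc <- function(path, kind = c("auto", "continuous", "categorical")) {
  kind <- match.arg(kind)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("not an ESRI ASCII grid: ", path, call. = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("ESRI ASCII header is missing ", paste(setdiff(need, names(hdr)),
         collapse = ", "), ": ", path, call. = FALSE)
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop(sprintf("expected %d cell values, found %d: %s", nr * nc,
                 length(vals), path), call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  # llcenter variants store the centre of the lower-left cell
  ox <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else
        if (!is.null(hdr$xllcenter)) hdr$xllcenter - hdr$cellsize / 2 else 0
  oy <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else
        if (!is.null(hdr$yllcenter)) hdr$yllcenter - hdr$cellsize / 2 else 0
  if (kind == "auto") {
    v <- m[!is.na(m)]
    kind <- if (length(v) && all(v >= 0) && all(v == round(v)))
      "categorical" else "continuous"
  }
  raster_grid(m, cell_size = hdr$cellsize, origin = c(ox, oy), kind = kind)
}

#' Write an ESRI ASCII grid
#'
#' @param grid a [raster_grid()].
#' @param path file to write.
#' @param nodata value used to encode missing cells (default -9999).
#' @param digits significant digits for continuous values (categorical grids
#'   are written as integers).
#' @return `path`, invisibly.
#' @export
write_asc <- function(grid, path, nodata = -9999, digits = 10) {
  stopifnot(inherits(grid, "raster_grid"))
  m <- grid$values
  m[grid$missing_mask] <- nodata
  d <- dim(m)
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2]),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  )
  fmt <- function(row) {
    if (grid$kind == "categorical") paste(formatC(row, format = "d"),
                                          collapse = " ")
    else paste(formatC(row, format = "g", digits = digits), collapse = " ")
  }
  body <- vapply(seq_len(d[1]), function(i) fmt(m[i, ]), character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
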