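test_that("winmove matches the naive double-loop on random grids", {
  set.seed(20)
  for (case in 1:24) {
    kind <- if (case %% 2 == 0) "categorical" else "continuous"
    g <- random_grid(sample(7:30, 1), sample(7:30, 1), kind = kind,
                     n_classes = sample(2:5, 1))
    h <- sample(1:3, 1)
    spec <- if (kind == "categorical") metric_spec("shannon")
            else metric_spec(sample(c("variance", "range", "mean"), 1))
    got <- winmove(g, h * g$cell_size, spec)$values
    want <- oracle_winmove(g, h * g$cell_size, spec)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("checkerboard evenness is uniform by torus symmetry", {
  cb <- raster_grid(outer(1:8, 1:8, function(i, j) (i + j) %% 2),
                    kind = "categorical")
  wv <- winmove(cb, 1, metric_spec("shannon"))$values
  # every 3x3 window holds 5 of one class and 4 of the other
  expected <- -(5 / 9 * log(5 / 9) + 4 / 9 * log(4 / 9)) / log(2)
  expect_equal(wv, matrix(expected, 8, 8), tolerance = 1e-12)
})

test_that("winmove on a constant surface is identically zero variance", {
  g <- raster_grid(matrix(0.37, 12, 15), cell_size = 25)
  for (r in c(25, 75)) {
    expect_true(all(winmove(g, r, "var")$values == 0))
  }
})

test_that("winmove is translation-equivariant on the torus", {
  shift_mat <- function(m, dr, dc) {
    n <- nrow(m); k <- ncol(m)
    m[((seq_len(n) - 1 - dr) %% n) + 1, ((seq_len(k) - 1 - dc) %% k) + 1]
  }
  for (s in 1:5) {
    set.seed(s)
    g <- random_grid(11, 13)
    wm <- winmove(g, 2, "var")$values
    gs <- raster_grid(shift_mat(g$values, 3, 5), kind = "continuous")
    wms <- winmove(gs, 2, "var")$values
    expect_equal(wms, shift_mat(wm, 3, 5), tolerance = 1e-12)
  }
})

test_that("winmove rejects incompatible metrics and oversized windows", {
  gcont <- random_grid(10, 10)
  gcat <- random_grid(10, 10, kind = "categorical")
  expect_error(winmove(gcont, 1, "shannon"), "categorical")
  expect_error(winmove(gcat, 1, "var"), "continuous")
  expect_error(winmove(gcont, 8, "var"), "exceeds")
})

test_that("windows touching a missing cell are missing; aggregation skips them", {
  vals <- matrix(runif(100), 10)
  vals[4, 6] <- NA
  g <- raster_grid(vals, cell_size = 1)
  wm <- winmove(g, 1, "var")$values
  miss <- which(is.na(wm), arr.ind = TRUE)
  expect_equal(nrow(miss), 9L)  # the 3x3 block of windows covering the hole
  expect_true(all(abs(miss[, 1] - 4) <= 1 & abs(miss[, 2] - 6) <= 1))
  cg <- winmove_agg(g, 1, "var", grain = 5)
  expect_false(anyNA(cg$values))  # mean over the remaining windows
})

test_that("winmove_agg equals brute-force window metrics averaged per block", {
  set.seed(31)
  for (case in 1:6) {
    kind <- if (case %% 2 == 0) "categorical" else "continuous"
    g <- random_grid(40, 40, kind = kind, n_classes = 3)
    spec <- if (kind == "categorical") metric_spec("shannon")
            else metric_spec("variance")
    got <- winmove_agg(g, 1, spec, grain = 20)$values # 4 coarse cells
    want <- oracle_block_agg(oracle_winmove(g, 1, spec), 20)
    expect_equal(got, want, tolerance = 1e-12)
    med <- winmove_agg(g, 1, spec, grain = 20, agg_stat = "median")$values
    wantm <- oracle_block_agg(oracle_winmove(g, 1, spec), 20, stats::median)
    expect_equal(med, wantm, tolerance = 1e-12)
  }
})

test_that("a single coarse cell aggregates to the mean of the window surface", {
  g <- random_grid(12, 12)
  cg <- winmove_agg(g, 2, "var", grain = 12)
  expect_equal(dim(cg$values), c(1L, 1L))
  expect_equal(cg$values[1, 1], mean(winmove(g, 2, "var")$values))
})

test_that("direct aggregation computes the metric over whole coarse cells", {
  half <- raster_grid(cbind(matrix(0, 8, 4), matrix(1, 8, 4)),
                      kind = "categorical")
  dda <- nomove_agg(half, "shannon", grain = 8)
  expect_equal(dda$values[1, 1], 1.0)

  const <- raster_grid(matrix(2.5, 8, 8))
  expect_equal(nomove_agg(const, "var", grain = 4)$values,
               matrix(0, 2, 2))

  set.seed(8)
  g <- random_grid(20, 20, kind = "categorical", n_classes = 4)
  got <- nomove_agg(g, "shannon", grain = 10)$values
  gm <- build_grain_map(g, 10)
  for (id in 1:4) {
    want <- oracle_metric(g$values[gm$assignment == id],
                          metric_spec("shannon"))
    expect_equal(got[gm$coarse_ids$row[id], gm$coarse_ids$col[id]], want)
  }
})

test_that("a window spanning the whole coarse cell reproduces direct aggregation for the mean", {
  # under torus wrap every window sees every cell, so MWDA(mean) = DDA(mean)
  set.seed(9)
  g <- random_grid(9, 9)
  mw <- winmove_agg(g, 4, "mean", grain = 9, edge = "per_landscape")
  dd <- nomove_agg(g, "mean", grain = 9)
  expect_equal(mw$values, dd$values, tolerance = 1e-12)
  # and MWDA(mean, mean) = DDA(mean) at any window size on the torus
  mw2 <- winmove_agg(g, 2, "mean", grain = 9, edge = "per_landscape")
  expect_equal(mw2$values, dd$values, tolerance = 1e-12)
})

test_that("edge modes agree on a single landscape and differ across boundaries", {
  set.seed(10)
  g <- random_grid(10, 10)
  whole <- winmove_agg(g, 2, "var", grain = 10, edge = "whole")
  per <- winmove_agg(g, 2, "var", grain = 10, edge = "per_landscape")
  expect_equal(whole$values, per$values, tolerance = 1e-12)

  g2 <- random_grid(20, 20)
  whole2 <- winmove_agg(g2, 2, "var", grain = 10, edge = "whole")
  per2 <- winmove_agg(g2, 2, "var", grain = 10, edge = "per_landscape")
  expect_false(isTRUE(all.equal(whole2$values, per2$values)))
})

test_that("coarse grids carry provenance and export to data frames", {
  g <- random_grid(10, 10)
  cg <- winmove_agg(g, 2, "var", grain = 5)
  expect_identical(cg$provenance$method, "mwda")
  expect_identical(cg$provenance$agg_stat, "mean")
  df <- as.data.frame(cg)
  expect_equal(nrow(df), 4L)
  expect_equal(df$value, as.vector(t(cg$values)))
  dd <- nomove_agg(g, "var", grain = 5)
  expect_identical(dd$provenance$window, "direct")
})
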