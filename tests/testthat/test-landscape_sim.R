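test_that("fractal surfaces are reproducible, rescaled and validated", {
  a <- simulate_fbm(0.5, 40, 40, seed = 11)
  b <- simulate_fbm(0.5, 40, 40, seed = 11)
  expect_identical(a$values, b$values)
  expect_equal(min(a$values), 0)
  expect_equal(max(a$values), 1)
  expect_identical(a$kind, "continuous")
  expect_error(simulate_fbm(0, 20, 20), "0, 1")
  expect_error(simulate_fbm(1.2, 20, 20), "0, 1")
})

test_that("spatial autocorrelation increases with the fractal parameter", {
  mi <- function(fd) {
    vapply(1:32, function(s)
      morans_i_lag1(simulate_fbm(fd, 60, 60, seed = s)), numeric(1))
  }
  rough <- mi(0.1); mid <- mi(0.5); smooth <- mi(1.0)
  expect_lt(mean(rough), mean(mid))
  expect_lt(mean(mid), mean(smooth))
  expect_gt(mean(smooth), 0.85)
  expect_lt(mean(rough), 0.45)
})

test_that("classification follows the cumulative-weight intervals", {
  w <- c(0.5, 0.25, 0.25)
  g <- raster_grid(matrix(c(0.49, 0.5, 1.0, 0, 0.74, 0.75), 2, 3))
  cls <- classify(g, w)
  expect_identical(cls$kind, "categorical")
  expect_equal(cls$values, matrix(c(0, 1, 2, 0, 1, 2), 2, 3))
  const <- raster_grid(matrix(0.6, 3, 3))
  expect_true(all(classify(const, w)$values == 1))
  expect_error(classify(raster_grid(matrix(c(-0.1, 0.5, 0.5, 0.5), 2)), w),
               "\\[0, 1\\]")
  expect_error(classify(const, c(0.5, 0.4)), "summing to 1")
})

test_that("classification is monotone and recovers weights on uniform values", {
  set.seed(12)
  v <- matrix(runif(1e5), 250, 400)
  g <- raster_grid(v)
  w <- c(0.4, 0.3, 0.2, 0.1)
  cls <- classify(g, w)
  # monotone: sort cells by value, classes must be non-decreasing
  ord <- order(v)
  expect_true(all(diff(cls$values[ord]) >= 0))
  # realised proportions within 3 binomial SEs of the intended weights
  p <- as.vector(table(factor(cls$values, levels = 0:3))) / length(v)
  se <- sqrt(w * (1 - w) / length(v))
  expect_true(all(abs(p - w) < 3 * se))
})

test_that("class weightings are a sorted uniform-simplex draw", {
  w <- sample_class_weights(5, seed = 13)
  expect_length(w, 5)
  expect_true(all(w > 0))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(diff(w) <= 0))
  expect_identical(w, sample_class_weights(5, seed = 13))
  expect_error(sample_class_weights(c(1, 5)), "\\[2, 10\\]")
  # mean sorted weights match the Dirichlet(1) order-statistic closed form:
  # E[j-th largest of k] = (1/k) * sum_{i=j..k} 1/i
  set.seed(14)
  draws <- t(replicate(4000, sample_class_weights(5)))
  want <- rev(cumsum(1 / (5:1))) / 5
  expect_equal(colMeans(draws), want, tolerance = 0.01)
})

test_that("scenario datasets honour their autocorrelation range and seed", {
  cfg_none <- scenario_config("none", n_landscapes = 4, n_rows = 20,
                              n_cols = 20, n_replicates = 1, base_seed = 3)
  expect_true(all(generate_dataset(cfg_none)$manifest$fractal_dim == 0.1))
  cfg_high <- scenario_config("high", n_landscapes = 4, n_rows = 20,
                              n_cols = 20, n_replicates = 1, base_seed = 3)
  expect_true(all(generate_dataset(cfg_high)$manifest$fractal_dim == 1))
  cfg_var <- scenario_config("varied", n_landscapes = 20, n_rows = 10,
                             n_cols = 10, n_replicates = 1, base_seed = 3)
  fd <- generate_dataset(cfg_var)$manifest$fractal_dim
  expect_true(all(fd >= 0.1 & fd <= 1))
  expect_gt(stats::sd(fd), 0)

  d1 <- generate_dataset(cfg_var, replicate = 2)
  d2 <- generate_dataset(cfg_var, replicate = 2)
  expect_identical(lapply(d1$landscapes, `[[`, "values"),
                   lapply(d2$landscapes, `[[`, "values"))
  d3 <- generate_dataset(cfg_var, replicate = 3)
  expect_false(identical(d1$landscapes[[1]]$values, d3$landscapes[[1]]$values))

  cat_cfg <- scenario_config("varied", kind = "categorical", n_landscapes = 3,
                             n_rows = 15, n_cols = 15, n_replicates = 1)
  dcat <- generate_dataset(cat_cfg)
  expect_true(all(vapply(dcat$landscapes, function(g)
    g$kind == "categorical", logical(1))))
  expect_true(all(unlist(lapply(dcat$landscapes, function(g)
    g$values %in% 0:4))))

  expect_error(scenario_config("high", n_landscapes = 1e6, n_rows = 1000,
                               n_cols = 1000), "cap")
})
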