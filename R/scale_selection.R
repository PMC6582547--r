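# Validation statistics: MWDA-vs-DDA correlation, synthetic responses at
# calibrated noise levels, univariate fits with AIC selection of the
# scale-of-effect, and the logit-proportion regression used for coarse
# response data.

#' Spearman correlation between MWDA and DDA measures
#'
#' Rank correlation (average ranks for ties) between the moving-window and
#' direct aggregation measures over the same coarse cells. Low values mean
#' the moving-window measure carries information about within-cell spatial
#' structure that the direct measure does not.
#'
#' @param mwda,dda equal-length numeric vectors over coarse cells (n >= 3).
#' @return Spearman's rho in `[-1, 1]`; `NA` if either vector is constant.
#' @examples
#' spearman_mwda_dda(1:10, (1:10)^2) # 1: a monotone transform
#' @export
spearman_mwda_dda <- function(mwda, dda) {
  if (length(mwda) != length(dda)) {
    stop("`mwda` and `dda` must have equal length", call. = FALSE)
  }
  ok <- stats::complete.cases(mwda, dda)
  mwda <- mwda[ok]; dda <- dda[ok]
  if (length(mwda) < 3L) {
    stop("need at least 3 paired values", call. = FALSE)
  }
  if (stats::sd(mwda) == 0 || stats::sd(dda) == 0) return(NA_real_)
  stats::cor(mwda, dda, method = "spearman")
}

#' Noise level calibrated to the aggregated measure
#'
#' The simulation study sets the response-noise standard deviation as an
#' empirical percentile of the pooled MWDA values within one scenario and
#' window combination: `"low"` is the 1st percentile, `"moderate"` the 10th,
#' `"high"` the median.
#'
#' @param mwda_values pooled MWDA values (non-empty numeric).
#' @param level `"low"`, `"moderate"` or `"high"`.
#' @return The noise standard deviation sigma (>= 0).
#' @examples
#' compute_sigma(1:100, "high") # interpolated median, 50.5
#' @export
compute_sigma <- function(mwda_values, level = c("low", "moderate", "high")) {
  level <- match.arg(level)
  mwda_values <- mwda_values[!is.na(mwda_values)]
  if (!length(mwda_values)) stop("`mwda_values` is empty", call. = FALSE)
  p <- c(low = 0.01, moderate = 0.10, high = 0.50)[[level]]
  unname(stats::quantile(mwda_values, p, type = 7))
}

#' Simulate a coarse-grain response from an aggregated measure
#'
#' Draws `y = mwda_w + e` with `e ~ N(0, sigma)`: the response has unit slope
#' and zero intercept on the true-scale measure, plus calibrated noise.
#'
#' @param mwda_w MWDA values at the true scale-of-effect, one per coarse
#'   cell.
#' @param sigma noise standard deviation (>= 0).
#' @param seed optional integer for reproducibility.
#' @return List of class `response_sim`: `y`, `sigma`, `seed`.
#' @examples
#' simulate_response(c(1, 2, 3), sigma = 0)$y
#' @export
simulate_response <- function(mwda_w, sigma, seed = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stop("`sigma` must be a single non-negative number", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  y <- mwda_w + stats::rnorm(length(mwda_w), 0, sigma)
  structure(list(y = y, sigma = sigma, seed = seed), class = "response_sim")
}

#' Univariate OLS fit with information criteria
#'
#' Fits `y ~ x` by ordinary least squares and reports the information
#' criteria used for scale selection: `AIC = n log(RSS/n) + 2k` and
#' `BIC = n log(RSS/n) + k log(n)` with `k = 3` (intercept, slope, error
#' variance). Additive constants of the Gaussian log-likelihood are dropped;
#' they are shared by every candidate, so differences and rankings are
#' unaffected.
#'
#' @param y response vector (length > 3).
#' @param x covariate vector, non-constant.
#' @return List: `intercept`, `slope`, `r_squared`, `aic`, `bic`, `n`.
#' @examples
#' fit_univariate(2 * (1:10) + 1, 1:10)
#' @export
fit_univariate <- function(y, x) {
  n <- length(y)
  if (length(x) != n) stop("`x` and `y` lengths differ", call. = FALSE)
  if (n <= 3L) stop("need more than 3 observations", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("covariate is constant; the slope is unidentifiable", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  k <- 3
  list(
    intercept = unname(stats::coef(fit)[1]),
    slope     = unname(stats::coef(fit)[2]),
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    aic       = n * log(rss / n) + 2 * k,
    bic       = n * log(rss / n) + k * log(n),
    n         = n
  )
}

#' Select the scale-of-effect by AIC
#'
#' Fits the response against the MWDA measure of every candidate window and
#' selects the radius whose model minimises AIC. Exact ties are broken toward
#' the smaller radius. Because every candidate model has the same number of
#' parameters and observations, AIC and BIC always rank the candidates
#' identically here.
#'
#' @param y response vector over coarse cells.
#' @param candidates named list (or data frame) of MWDA vectors, one per
#'   candidate window; names are the radii in map units.
#' @param true_radius optional radius that generated `y`; when given, the
#'   result records whether selection was correct.
#' @return List of class `scale_selection_result`: `fits` (data frame with
#'   radius, intercept, slope, r_squared, aic, bic), `chosen_radius`, and
#'   `correct` (logical or `NA`).
#' @examples
#' x1 <- rnorm(50); x2 <- rnorm(50)
#' select_scale(x2, list(`100` = x1, `500` = x2))$chosen_radius
#' @export
select_scale <- function(y, candidates, true_radius = NULL) {
  candidates <- as.list(candidates)
  if (length(candidates) < 2L) {
    stop("need at least 2 candidate scales", call. = FALSE)
  }
  if (is.null(names(candidates)) || any(!nzchar(names(candidates)))) {
    stop("`candidates` must be named by window radius", call. = FALSE)
  }
  radii <- as.numeric(names(candidates))
  if (anyNA(radii)) stop("candidate names must be numeric radii", call. = FALSE)
  fits <- lapply(seq_along(candidates), function(i) {
    f <- tryCatch(fit_univariate(y, candidates[[i]]), error = function(e) {
      stop(sprintf("candidate radius %s: %s", names(candidates)[i],
                   conditionMessage(e)), call. = FALSE)
    })
    data.frame(radius = radii[i], intercept = f$intercept, slope = f$slope,
               r_squared = f$r_squared, aic = f$aic, bic = f$bic)
  })
  fits <- do.call(rbind, fits)
  ord <- order(fits$aic, fits$radius)  # ties toward the smaller radius
  chosen <- fits$radius[ord[1]]
  structure(
    list(fits = fits, chosen_radius = chosen,
         correct = if (is.null(true_radius)) NA else
           isTRUE(all.equal(chosen, true_radius))),
    class = "scale_selection_result"
  )
}

#' @export
print.scale_selection_result <- function(x, ...) {
  cat(sprintf("<scale_selection_result> chosen radius: %g\n",
              x$chosen_radius))
  print(x$fits, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Logit-transformed proportion regression
#'
#' Models a non-binomial proportion response (e.g. an occupancy index per
#' coarse cell) by applying a logit transform and fitting ordinary linear
#' regression, with optional two-way interactions. Proportions at exactly 0
#' or 1 are adjusted before the transform, either by the empirical squeeze
#' `(y (n - 1) + 0.5) / n` or by clamping into `[eps, 1 - eps]`.
#'
#' @param data data frame holding the response and covariates.
#' @param response name of the proportion column (values in `[0, 1]`).
#' @param covariates character vector of covariate column names.
#' @param interactions optional list of length-2 character vectors naming
#'   covariate pairs to interact.
#' @param adjust `"empirical"` (default) or `"clamp"`.
#' @param eps clamp margin when `adjust = "clamp"`.
#' @return List of class `logit_prop_fit`: `coefficients`, `r_squared`,
#'   `aic`, `bic`, `n`, `model` (the underlying `lm`).
#' @examples
#' d <- data.frame(y = plogis(rnorm(100)), a = rnorm(100), b = rnorm(100))
#' logit_proportion_model(d, "y", c("a", "b"),
#'                        interactions = list(c("a", "b")))$r_squared
#' @export
logit_proportion_model <- function(data, response, covariates,
                                   interactions = NULL,
                                   adjust = c("empirical", "clamp"),
                                   eps = 0.005) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(data), response %in% names(data),
            all(covariates %in% names(data)))
  y <- data[[response]]
  if (any(!is.na(y) & (y < 0 | y > 1))) {
    stop(sprintf("`%s` must hold proportions in [0, 1]", response),
         call. = FALSE)
  }
  keep <- stats::complete.cases(data[, c(response, covariates)])
  data <- data[keep, , drop = FALSE]
  y <- data[[response]]
  n <- length(y)
  yadj <- if (adjust == "empirical") (y * (n - 1) + 0.5) / n
          else pmin(pmax(y, eps), 1 - eps)
  data$.logit_y <- stats::qlogis(yadj)
  terms <- covariates
  if (!is.null(interactions)) {
    terms <- c(terms, vapply(interactions, function(p) {
      stopifnot(length(p) == 2L, all(p %in% covariates))
      paste(p, collapse = ":")
    }, character(1)))
  }
  fml <- stats::reformulate(terms, response = ".logit_y")
  fit <- stats::lm(fml, data = data)
  structure(
    list(coefficients = summary(fit)$coefficients,
         r_squared = summary(fit)$r.squared,
         aic = stats::AIC(fit), bic = stats::BIC(fit), n = n, model = fit),
    class = "logit_prop_fit"
  )
}

#' @export
print.logit_prop_fit <- function(x, ...) {
  cat(sprintf("<logit_prop_fit> n = %d, R^2 = %.3f, AIC = %.1f, BIC = %.1f\n",
              x$n, x$r_squared, x$aic, x$bic))
  stats::printCoefmat(x$coefficients, digits = 3)
  invisible(x)
}
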