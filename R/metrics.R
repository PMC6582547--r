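#' Specify a heterogeneity metric
#'
#' A metric turns the contents of one neighbourhood (or one coarse cell) into
#' a single number describing environmental heterogeneity. Built-in metrics:
#' `"shannon_evenness"` for categorical grids; `"variance"`, `"range"` and
#' `"mean"` for continuous grids; `"user_defined"` applies a caller-supplied
#' reduction. The short aliases `"shannon"` and `"var"` are accepted.
#'
#' For categorical metrics, `class_universe` fixes the set of classes `S`
#' entering Shannon evenness regardless of which classes occur locally, and
#' `include_classes` restricts the calculation to a subset of classes (cells
#' of other classes are dropped before computing proportions; a neighbourhood
#' with no retained cells yields a missing value). This supports analyses such
#' as evenness of broadleaf vs. coniferous forest with all other land covers
#' excluded.
#'
#' @param name metric name (see above).
#' @param class_universe optional integer vector of class codes defining `S`.
#' @param include_classes optional integer vector of class codes to retain;
#'   must be a subset of `class_universe` when both are given.
#' @param fn reduction function for `name = "user_defined"`; called with the
#'   numeric vector of (retained, non-missing) neighbourhood values.
#' @return An object of class `metric_spec`.
#' @examples
#' metric_spec("shannon", class_universe = 0:4)
#' metric_spec("var")
#' @export
metric_spec <- function(name, class_universe = NULL, include_classes = NULL,
                        fn = NULL) {
  aliases <- c(shannon = "shannon_evenness", var = "variance")
  if (name %in% names(aliases)) name <- aliases[[name]]
  name <- match.arg(name, c("shannon_evenness", "variance", "range", "mean",
                            "user_defined"))
  if (name == "user_defined" && !is.function(fn)) {
    stop("a user-defined metric needs `fn`", call. = FALSE)
  }
  if (name != "user_defined" && !is.null(fn)) {
    stop("`fn` is only used with name = \"user_defined\"", call. = FALSE)
  }
  if (!is.null(class_universe)) {
    if (any(class_universe < 0) || any(class_universe != round(class_universe)))
      stop("`class_universe` must hold non-negative integer class codes",
           call. = FALSE)
    class_universe <- sort(unique(as.integer(class_universe)))
  }
  if (!is.null(include_classes)) {
    include_classes <- sort(unique(as.integer(include_classes)))
    if (!is.null(class_universe) && !all(include_classes %in% class_universe))
      stop("`include_classes` must be a subset of `class_universe`",
           call. = FALSE)
  }
  structure(list(name = name, class_universe = class_universe,
                 include_classes = include_classes, fn = fn),
            class = "metric_spec")
}

metric_kind <- function(spec) {
  switch(spec$name,
         shannon_evenness = "categorical",
         variance = , range = , mean = "continuous",
         user_defined = "any")
}

#' Shannon evenness of class proportions
#'
#' Computes `J' = -sum(p_i * log(p_i)) / log(S)` where `p_i` is the proportion
#' of class `i` among the retained values and `S` is the number of classes:
#' the size of `class_universe` when given, otherwise the number of distinct
#' classes present. Zero proportions contribute nothing; when `S = 1` the
#' result is defined as 0 (a single class carries no diversity). Returns `NA`
#' when no values remain after filtering.
#'
#' @param values vector of integer class codes (`NA` allowed; dropped).
#' @param class_universe optional class set fixing `S`.
#' @param include_classes optional classes to retain before computing
#'   proportions.
#' @return Evenness in `[0, 1]`, or `NA`.
#' @examples
#' shannon_evenness(c(0, 0, 1, 1))            # 1: perfectly even
#' shannon_evenness(rep(2, 5), class_universe = c(1, 2)) # 0: one class of two
#' @export
shannon_evenness <- function(values, class_universe = NULL,
                             include_classes = NULL) {
  values <- values[!is.na(values)]
  if (length(values) && (any(values < 0) || any(values != round(values)))) {
    stop("shannon_evenness needs integer class codes, not continuous values",
         call. = FALSE)
  }
  if (!is.null(include_classes)) values <- values[values %in% include_classes]
  if (!length(values)) return(NA_real_)
  tab <- table(values)
  s <- if (!is.null(class_universe)) length(unique(class_universe))
       else length(tab)
  if (s <= 1L) return(0)
  p <- as.numeric(tab) / length(values)
  -sum(p * log(p)) / log(s)
}

#' Population variance
#'
#' Variance with divisor `N`: the neighbourhood is treated as the entire
#' population of cells, not a sample from one.
#'
#' @param values numeric vector (`NA` dropped).
#' @return Non-negative variance; `NA` for an empty input.
#' @examples
#' pop_var(c(0, 1)) # 0.25
#' @export
pop_var <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) return(NA_real_)
  m <- mean(values)
  mean((values - m)^2)
}

#' Range (max minus min)
#'
#' @param values numeric vector (`NA` dropped).
#' @return `max - min`; `NA` for an empty input.
#' @examples
#' value_range(c(0.2, 0.9, 0.4)) # 0.7
#' @export
value_range <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) return(NA_real_)
  max(values) - min(values)
}

# Evaluate a metric_spec on one collection of cell values. `where` labels the
# neighbourhood in error messages from user-defined metrics.
compute_metric <- function(values, spec, where = NULL) {
  stopifnot(inherits(spec, "metric_spec"))
  switch(spec$name,
    shannon_evenness = shannon_evenness(values, spec$class_universe,
                                        spec$include_classes),
    variance = pop_var(values),
    range = value_range(values),
    mean = if (all(is.na(values))) NA_real_ else mean(values, na.rm = TRUE),
    user_defined = {
      v <- values[!is.na(values)]
      if (!is.null(spec$include_classes)) v <- v[v %in% spec$include_classes]
      if (!length(v)) return(NA_real_)
      out <- tryCatch(spec$fn(v), error = function(e) {
        loc <- if (is.null(where)) "" else paste0(" at ", where)
        stop(sprintf("user metric failed%s: %s", loc, conditionMessage(e)),
             call. = FALSE)
      })
      as.numeric(out)
    })
}
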