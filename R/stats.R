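#' Paired t-test between two per-subplot series
#'
#' Compares two metrics measured on the same subplots (e.g. PD under two
#' chronograms): t = mean(d) / (sd(d) / sqrt(n)) on the paired differences
#' d = x - y, df = n - 1, two-sided p.
#'
#' @param data Data frame holding both series.
#' @param x,y Column names (strings) of the two series.
#' @return A one-row tibble: `estimate` (mean difference), `t`, `df`,
#'   `p_value`, `n`, `degenerate` (`TRUE` when the differences have zero
#'   variance, in which case `t` is `NA`).
#' @export
paired_t <- function(data, x, y) {
  xv <- data[[x]]
  yv <- data[[y]]
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]
  yv <- yv[ok]
  n <- length(xv)
  if (n < 3) abort("paired t-test needs at least 3 complete pairs")
  d <- xv - yv
  if (sd(d) == 0) {
    return(tibble(
      estimate = mean(d), t = NA_real_, df = n - 1,
      p_value = 1, n = n, degenerate = TRUE
    ))
  }
  ht <- t.test(xv, yv, paired = TRUE)
  tibble(
    estimate = unname(ht$estimate), t = unname(ht$statistic),
    df = unname(ht$parameter), p_value = ht$p.value, n = n,
    degenerate = FALSE
  )
}

#' Pearson product-moment correlation
#'
#' Sample correlation with the usual two-sided t-based p-value
#' (t = r sqrt((n-2)/(1-r^2)), df = n - 2).
#'
#' @param data Data frame holding both variables.
#' @param x,y Column names (strings).
#' @return A one-row tibble: `r`, `t`, `df`, `p_value`, `n`, `degenerate`.
#' @export
pearson <- function(data, x, y) {
  xv <- data[[x]]
  yv <- data[[y]]
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]
  yv <- yv[ok]
  n <- length(xv)
  if (n < 3) abort("correlation needs at least 3 complete pairs")
  if (sd(xv) == 0 || sd(yv) == 0) {
    return(tibble(
      r = NA_real_, t = NA_real_, df = n - 2, p_value = 1,
      n = n, degenerate = TRUE
    ))
  }
  ht <- cor.test(xv, yv, method = "pearson")
  tibble(
    r = unname(ht$estimate), t = unname(ht$statistic),
    df = unname(ht$parameter), p_value = ht$p.value, n = n,
    degenerate = FALSE
  )
}

#' Correlations between topography and community-structure metrics
#'
#' Pearson tests of every environmental variable against every metric,
#' emitted as a long table (one row per pair), the shape used for
#' topography-vs-diversity summaries.
#'
#' @param data Data frame containing all columns (join of a topography
#'   table and a metric table).
#' @param env Character vector of environmental columns (default
#'   `c("elevation", "slope", "convexity")`).
#' @param metrics Character vector of metric columns (default
#'   `c("pd", "nri", "nti")`).
#' @return A tibble with columns `variable`, `metric`, `r`, `p_value`,
#'   `n`.
#' @export
correlate_metrics <- function(data,
                              env = c("elevation", "slope", "convexity"),
                              metrics = c("pd", "nri", "nti")) {
  missing <- setdiff(c(env, metrics), names(data))
  if (length(missing) > 0) {
    abort(paste0("columns not found: ", paste(missing, collapse = ", ")))
  }
  tidyr::expand_grid(variable = env, metric = metrics) |>
    dplyr::mutate(res = purrr::map2(
      .data$variable, .data$metric,
      ~ pearson(data, .x, .y)[, c("r", "p_value", "n")]
    )) |>
    tidyr::unnest("res")
}
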