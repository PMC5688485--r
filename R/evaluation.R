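# Model evaluation: fit metrics (R-squared, Pearson correlation, RMSE),
# correlation classification, proxy comparison, and the relative-impact
# arithmetic used to contrast mortality-model runs.

#' Fit metrics for predicted vs observed coverage
#'
#' Computes the three evaluation metrics on matched vectors:
#' \itemize{
#' \item `rmse` — root mean square error, `sqrt(mean((obs - pred)^2))`;
#' \item `pearson_rho` — sample Pearson correlation;
#' \item `r_squared` — coefficient of determination
#'   `1 - SS_res / SS_tot` about the observed mean. Computed on
#'   prediction pairs (not in-model), it can be negative for a model
#'   worse than the mean.
#' }
#' The squared correlation is also returned (`r_squared_corr`) since
#' both conventions circulate; `r_squared` is the primary definition.
#' A constant observed vector leaves the correlation undefined: it is
#' returned as `NA` with `rho_defined = FALSE`, never silently as 0.
#'
#' @param observed numeric vector of observed coverage.
#' @param predicted numeric vector of predicted coverage, same length
#'   (at least 2, no missing values).
#' @return list of class `eval_metrics`: `r_squared`, `pearson_rho`,
#'   `rmse`, `n`, `r_squared_corr`, `rho_defined`.
#' @export
compute_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  if (length(observed) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (any(!is.finite(observed)) || any(!is.finite(predicted))) {
    stop("missing or non-finite values in inputs", call. = FALSE)
  }
  res <- observed - predicted
  ss_res <- sum(res^2)
  ss_tot <- sum((observed - mean(observed))^2)
  rho_defined <- sd(observed) > 0 && sd(predicted) > 0
  rho <- if (rho_defined) cor(observed, predicted) else NA_real_
  structure(list(
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    pearson_rho = rho,
    rmse = sqrt(mean(res^2)),
    n = length(observed),
    r_squared_corr = if (rho_defined) rho^2 else NA_real_,
    rho_defined = rho_defined
  ), class = "eval_metrics")
}

#' Classify a correlation coefficient
#'
#' Correlations above 0.8 indicate strong association, those in the
#' 0.5–0.8 range (inclusive) moderate association, anything below 0.5
#' weak.
#'
#' @param rho correlation coefficient(s) in `[-1, 1]`.
#' @return character vector: `"strong"`, `"moderate"` or `"weak"`.
#' @export
classify_correlation <- function(rho) {
  if (any(!is.finite(rho)) || any(abs(rho) > 1)) {
    stop("rho must lie in [-1, 1]", call. = FALSE)
  }
  ifelse(rho > 0.8, "strong", ifelse(rho >= 0.5, "moderate", "weak"))
}

#' Compare coverage estimates with default proxies
#'
#' Joins two coverage tables on (country, intervention) and reports the
#' per-key difference `proxy - estimate` in percentage points, together
#' with the range of differences.
#'
#' @param estimates,proxies data frames with columns `country`,
#'   `intervention`, `value` (proportions on `[0, 1]`); keys must match
#'   one-to-one.
#' @return tibble with `country`, `intervention`, `estimate`, `proxy`,
#'   `diff_pp` (percentage points); attribute `range` holds
#'   `c(min, max)` of `diff_pp`.
#' @export
compare_to_proxy <- function(estimates, proxies) {
  est <- tibble::as_tibble(estimates)
  prx <- tibble::as_tibble(proxies)
  keys <- c("country", "intervention")
  joined <- dplyr::full_join(
    dplyr::rename(est[c(keys, "value")], estimate = "value"),
    dplyr::rename(prx[c(keys, "value")], proxy = "value"),
    by = keys)
  if (anyNA(joined$estimate) || anyNA(joined$proxy)) {
    stop("estimates and proxies must share identical (country, intervention) keys",
         call. = FALSE)
  }
  joined$diff_pp <- 100 * (joined$proxy - joined$estimate)
  attr(joined, "range") <- c(min(joined$diff_pp), max(joined$diff_pp))
  joined
}

#' Relative impact of two mortality-model runs
#'
#' Expresses an updated impact estimate (e.g. maternal lives saved under
#' revised baseline coverage) as a percentage of the impact under the
#' current baseline: `100 * updated / current`. Reported values are
#' rounded half-up to the nearest integer percent; the unrounded value
#' is returned alongside.
#'
#' @param updated_impact impact count under updated baseline coverage.
#' @param current_impact impact count under current baseline coverage
#'   (must be positive).
#' @return list with `percent` (unrounded) and `percent_rounded`.
#' @export
#' @examples
#' impact_ratio(84, 177)$percent_rounded   # 47
impact_ratio <- function(updated_impact, current_impact) {
  if (any(current_impact <= 0)) stop("current_impact must be positive", call. = FALSE)
  pct <- 100 * updated_impact / current_impact
  list(percent = pct, percent_rounded = round_half_up(pct))
}
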