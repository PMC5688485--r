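# Household care-seeking: eligibility filtering, weighted ANC4+ coverage,
# its distribution across care-source strata (c_s), and the country-level
# ANC covariate rates fed to the predictive models.

#' Restrict household records to the recall window
#'
#' Keeps births within the last 36 months (half-open window
#' `[0, 36)` completed months), the restriction used to limit recall
#' bias relative to the 5-year window of the underlying questionnaire.
#' Records with negative `months_since_birth` are rejected and counted
#' separately from window exclusions.
#'
#' @param records household data frame with a `months_since_birth`
#'   column (integer months).
#' @param window_months exclusive upper bound of the recall window.
#' @return the eligible subset, with attributes `n_excluded` (outside
#'   the window) and `n_rejected` (negative recall values).
#' @export
filter_eligible <- function(records, window_months = 36) {
  rec <- tibble::as_tibble(records)
  if (!nrow(rec)) {
    out <- rec
    attr(out, "n_excluded") <- 0L
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  bad <- !is.finite(rec$months_since_birth) | rec$months_since_birth < 0
  if (any(bad)) {
    message(sprintf("filter_eligible: rejected %d record(s) with invalid months_since_birth",
                    sum(bad)))
  }
  keep <- !bad & rec$months_since_birth < window_months
  out <- rec[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!bad & !keep)
  attr(out, "n_rejected") <- sum(bad)
  out
}

check_weights <- function(records, caller) {
  if (!nrow(records)) stop(sprintf("%s: no records supplied", caller), call. = FALSE)
  if (any(!is.finite(records$weight) | records$weight <= 0)) {
    stop(sprintf("%s: sampling weights must be positive", caller), call. = FALSE)
  }
  if (anyDuplicated(records$woman_id)) {
    stop(sprintf("%s: duplicate woman_id; expected one record per woman", caller),
         call. = FALSE)
  }
  invisible(records)
}

#' Weighted ANC4+ coverage
#'
#' The weighted proportion of eligible women who attended four or more
#' antenatal care visits for the index birth.
#'
#' @param records eligible household records with `anc_visits` and
#'   `weight` columns.
#' @return proportion in `[0, 1]`.
#' @export
anc4_coverage <- function(records) {
  check_weights(records, "anc4_coverage")
  weighted_prop(records$anc_visits >= 4, records$weight)
}

#' Distribution of ANC4+ coverage across care-source strata
#'
#' Computes `c_s`: the weighted share of ALL eligible women who attended
#' ANC4+ and sought care from a source in stratum `s` (source facility
#' type x managing authority x residence). ANC4+ women reporting a
#' non-facility source (or a missing source) form an explicit
#' non-facility bucket: they are counted, reported via the
#' `non_facility_share` attribute, and excluded from the facility
#' strata, because facility readiness is undefined for them. The shares
#' therefore satisfy `sum(c_s) + non_facility_share = anc4_coverage`.
#'
#' @param records eligible household records.
#' @return tibble keyed by `facility_type`, `authority`, `location` with
#'   columns `c_s` (share of all eligible women) and `n_women`
#'   (unweighted count); attributes `anc4` (overall ANC4+ coverage) and
#'   `non_facility_share`.
#' @export
stratum_careseeking <- function(records) {
  check_weights(records, "stratum_careseeking")
  rec <- tibble::as_tibble(records)
  w_total <- sum(rec$weight)
  anc4 <- rec$anc_visits >= 4
  nonfac <- anc4 & (is.na(rec$source_type) | is.na(rec$source_authority) |
                      rec$source_type == "non_facility")
  fac <- rec[anc4 & !nonfac, , drop = FALSE]
  if (nrow(fac)) {
    out <- fac |>
      dplyr::group_by(facility_type = .data$source_type,
                      authority = .data$source_authority,
                      location = .data$residence) |>
      dplyr::summarise(c_s = sum(.data$weight) / w_total,
                       n_women = dplyr::n(), .groups = "drop")
  } else {
    out <- tibble::tibble(facility_type = character(), authority = character(),
                          location = character(), c_s = numeric(),
                          n_women = integer())
  }
  attr(out, "anc4") <- weighted_prop(anc4, rec$weight)
  attr(out, "non_facility_share") <- sum(rec$weight[nonfac]) / w_total
  out
}

#' Country-level ANC covariate rates
#'
#' Weighted proportions of eligible women with: four or more ANC visits
#' (`anc4_rate`); each ANC component received — blood sample collected,
#' urine sample collected, blood pressure measured (`blood_sample_rate`,
#' `urine_sample_rate`, `bp_rate`); and early ANC enrolment, defined as
#' a first visit within the first 4 months of pregnancy
#' (`early_anc_rate`, `first_visit_month <= 4`; women with no ANC do not
#' qualify).
#'
#' By default the denominator is all eligible women, so ANC
#' non-attenders contribute zeros — the convention under which these
#' rates serve as country-level predictors alongside `anc4_rate`. Set
#' `denominator = "anc_attenders"` to restrict the component and
#' early-enrolment rates to women with at least one ANC visit.
#'
#' @param records eligible household records.
#' @param denominator `"all"` (default) or `"anc_attenders"`.
#' @return one-row tibble with columns `anc4_rate`, `blood_sample_rate`,
#'   `urine_sample_rate`, `bp_rate`, `early_anc_rate`.
#' @export
covariate_rates <- function(records, denominator = c("all", "anc_attenders")) {
  denominator <- match.arg(denominator)
  check_weights(records, "covariate_rates")
  rec <- tibble::as_tibble(records)
  w <- rec$weight
  in_denom <- if (denominator == "all") rep(TRUE, nrow(rec)) else rec$anc_visits >= 1
  if (!any(in_denom)) stop("covariate_rates: empty denominator", call. = FALSE)
  sub <- rec[in_denom, , drop = FALSE]
  wp <- function(flag) weighted_prop(!is.na(flag) & flag, sub$weight)
  tibble::tibble(
    anc4_rate = weighted_prop(rec$anc_visits >= 4, w),
    blood_sample_rate = wp(sub$blood_sample),
    urine_sample_rate = wp(sub$urine_sample),
    bp_rate = wp(sub$blood_pressure),
    early_anc_rate = wp(sub$first_visit_month <= 4)
  )
}
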