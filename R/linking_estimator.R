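# Stratum-level linking: availability coverage = sum over strata of the
# care-seeking share c_s times the facility readiness proportion r_s.

#' Match care-seeking strata to readiness strata
#'
#' Joins the two stratum tables on (facility type, managing authority,
#' location). Care-seeking strata without an exact readiness match fall
#' back along a collapsing cascade: readiness is re-aggregated (weighted
#' by stratum facility weight) first dropping location, then dropping
#' authority as well. Facility type is never collapsed — it is the
#' strongest determinant of service availability. Strata unmatched after
#' the cascade are reported, never imputed.
#'
#' @param careseeking stratum care-seeking table from
#'   [stratum_careseeking()].
#' @param readiness stratum readiness table from [stratum_readiness()].
#' @return list with `matched` (care-seeking rows joined to readiness
#'   columns plus a `match_level` of `"exact"`, `"type_authority"` or
#'   `"type"`) and `unmatched` (care-seeking rows with no readiness
#'   information at any level).
#' @export
match_strata <- function(careseeking, readiness) {
  cs <- tibble::as_tibble(careseeking)
  rd <- tibble::as_tibble(readiness)
  ready_cols <- grep("^ready_", names(rd), value = TRUE)
  if (!length(ready_cols)) stop("readiness table has no ready_* columns", call. = FALSE)

  collapse <- function(keys) {
    rd |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(
        dplyr::across(dplyr::all_of(ready_cols),
                      ~ sum(.x * .data$wt_total) / sum(.data$wt_total)),
        .groups = "drop")
  }

  levels <- list(
    exact = list(keys = STRATUM_KEYS, tab = rd[c(STRATUM_KEYS, ready_cols)]),
    type_authority = list(keys = c("facility_type", "authority"),
                          tab = collapse(c("facility_type", "authority"))),
    type = list(keys = "facility_type", tab = collapse("facility_type"))
  )

  remaining <- cs
  matched <- list()
  for (lv in names(levels)) {
    if (!nrow(remaining)) break
    hit <- dplyr::inner_join(remaining, levels[[lv]]$tab,
                             by = levels[[lv]]$keys,
                             suffix = c("", ".rd"))
    if (nrow(hit)) {
      hit$match_level <- lv
      matched[[lv]] <- hit
      remaining <- dplyr::anti_join(remaining, levels[[lv]]$tab,
                                    by = levels[[lv]]$keys)
    }
  }
  list(matched = dplyr::bind_rows(matched), unmatched = remaining)
}

#' Linked availability coverage for one intervention
#'
#' The stratum-product estimator: over care-seeking strata matched to a
#' readiness value (see [match_strata()]),
#' \deqn{\widehat{AC} = \sum_s c_s \, r_s .} The result is the
#' proportion of women who attended ANC four or more times AND sought
#' care at a facility ready to deliver the intervention — availability
#' coverage. It can never exceed the ANC4+ facility-sourced share
#' `sum(c_s)`, hence never exceeds ANC4+ coverage. Care-seeking shares
#' that find no readiness match contribute zero and are reported.
#'
#' @inheritParams match_strata
#' @param intervention intervention name (a `ready_<intervention>`
#'   column must exist in `readiness`).
#' @return a `coverage_estimate`: list with `intervention`, `value`,
#'   `method = "linked"`, `n_strata_used`, `unmatched_careseeking_share`.
#' @export
link_coverage <- function(careseeking, readiness, intervention) {
  col <- paste0("ready_", intervention)
  if (!col %in% names(readiness)) {
    stop(sprintf("no readiness column for intervention '%s'", intervention),
         call. = FALSE)
  }
  mm <- match_strata(careseeking, readiness)
  if (!nrow(mm$matched)) {
    stop("linking failed: no care-seeking stratum matched any readiness stratum",
         call. = FALSE)
  }
  coverage_estimate(
    intervention = intervention,
    value = sum(mm$matched$c_s * mm$matched[[col]]),
    method = "linked",
    n_strata_used = nrow(mm$matched),
    unmatched_careseeking_share = sum(mm$unmatched$c_s)
  )
}

#' Construct a coverage estimate
#'
#' @param intervention intervention name.
#' @param value coverage proportion in `[0, 1]`.
#' @param method provenance: `"linked"`, `"proxy"` or `"predicted"`.
#' @param n_strata_used strata contributing to a linked estimate.
#' @param unmatched_careseeking_share care-seeking share with no
#'   readiness match (contributes zero to `value`).
#' @return object of class `coverage_estimate`.
#' @export
coverage_estimate <- function(intervention, value,
                              method = c("linked", "proxy", "predicted"),
                              n_strata_used = NA_integer_,
                              unmatched_careseeking_share = 0) {
  method <- match.arg(method)
  stopifnot(value >= 0, value <= 1,
            unmatched_careseeking_share >= 0, unmatched_careseeking_share <= 1)
  structure(list(intervention = intervention, value = value, method = method,
                 n_strata_used = as.integer(n_strata_used),
                 unmatched_careseeking_share = unmatched_careseeking_share),
            class = "coverage_estimate")
}

#' @export
print.coverage_estimate <- function(x, ...) {
  cat(sprintf("<coverage_estimate> %s: %.4f (%s, %d strata, unmatched share %.4f)\n",
              x$intervention, x$value, x$method, x$n_strata_used,
              x$unmatched_careseeking_share))
  invisible(x)
}
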