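# Facility readiness: score each facility's ability to deliver each ANC
# intervention from item-availability flags, then aggregate to weighted
# stratum-level readiness proportions r_s.

#' Default readiness checklists
#'
#' Returns the conjunctive item checklists used to score facility
#' readiness for the five ANC interventions. An intervention is scored
#' ready at a facility only when every listed item (test, drug,
#' equipment) was observed at the facility on the day of assessment:
#' e.g. syphilis detection and treatment requires a valid syphilis test
#' AND a drug to treat syphilis.
#'
#' The exact item sets used by national facility assessments vary; these
#' defaults are a transparent, editable stand-in. Supply a YAML file of
#' the same shape (intervention name mapping to a list of item names) to
#' override.
#'
#' @param path optional path to a YAML checklist; defaults to the
#'   checklist shipped with the package.
#' @return named list mapping intervention to a character vector of
#'   required item names.
#' @export
#' @examples
#' default_checklist()$syphilis
default_checklist <- function(path = NULL) {
  path <- path %||% system.file("extdata", "checklist_default.yaml",
                                package = "anclink")
  cl <- yaml::read_yaml(path)
  validate_checklist(cl)
}

validate_checklist <- function(cl) {
  if (!is.list(cl) || is.null(names(cl)) || any(names(cl) == "")) {
    stop("checklist must be a named list of item vectors", call. = FALSE)
  }
  cl <- lapply(cl, function(x) as.character(unlist(x)))
  empty <- names(cl)[lengths(cl) == 0]
  if (length(empty)) {
    stop(sprintf("checklist error: intervention(s) with no required items: %s",
                 paste(empty, collapse = ", ")), call. = FALSE)
  }
  cl
}

#' Score one facility against a readiness checklist
#'
#' @param record a one-row data frame (or named list) of a facility with
#'   one logical column/entry per item named in the checklist. A missing
#'   (`NA`) item flag is treated as "not available".
#' @param checklist named list of required item names per intervention,
#'   as returned by [default_checklist()].
#' @return named integer vector (one element per intervention): 1 if all
#'   required items are available, 0 otherwise.
#' @export
score_facility <- function(record, checklist) {
  checklist <- validate_checklist(checklist)
  rec <- as.list(record)
  out <- vapply(checklist, function(items) {
    missing_items <- setdiff(items, names(rec))
    if (length(missing_items)) {
      stop(sprintf("schema error: checklist item(s) not present in facility record: %s",
                   paste(missing_items, collapse = ", ")), call. = FALSE)
    }
    avail <- vapply(items, function(it) isTRUE(as.logical(rec[[it]][1])), logical(1))
    as.integer(all(avail))
  }, integer(1))
  out
}

#' Weighted stratum-level readiness proportions
#'
#' Scores every facility against the checklist and aggregates to the
#' stratum level (facility type x managing authority x location) as the
#' weighted proportion of facilities ready to deliver each intervention:
#' \deqn{r_s = \sum_i w_i \, ready_i / \sum_i w_i} over facilities
#' \eqn{i} in stratum \eqn{s}. Strata with no contributing facilities are
#' absent from the table, not zero-filled.
#'
#' Facilities with a missing stratum classifier or a non-positive weight
#' are excluded; the exclusions are counted in the `rejections`
#' attribute. Missing item flags score as "not available".
#'
#' @param facilities data frame with columns `facility_id`,
#'   `facility_type`, `authority`, `location`, `weight`, plus one logical
#'   column per checklist item.
#' @param checklist named list per [default_checklist()].
#' @return tibble with one row per stratum: the three stratum keys,
#'   `n_facilities`, `wt_total`, and one `ready_<intervention>` column
#'   per intervention holding \eqn{r_s}. Attribute `rejections` is a
#'   tibble of excluded facility ids and reasons.
#' @export
stratum_readiness <- function(facilities, checklist = default_checklist()) {
  checklist <- validate_checklist(checklist)
  if (!nrow(facilities)) stop("no facility records supplied", call. = FALSE)

  fac <- tibble::as_tibble(facilities)
  reasons <- character(nrow(fac))
  bad_class <- !complete.cases(fac[STRATUM_KEYS])
  bad_weight <- !is.finite(fac$weight) | fac$weight <= 0
  reasons[bad_class] <- "missing stratum classifier"
  reasons[bad_weight & !bad_class] <- "non-positive weight"
  drop <- bad_class | bad_weight
  rejections <- tibble::tibble(
    facility_id = fac$facility_id[drop],
    reason = reasons[drop]
  )
  if (any(drop)) {
    message(sprintf("stratum_readiness: excluded %d facility record(s) (%s)",
                    sum(drop),
                    paste(sprintf("%s: %d", names(table(rejections$reason)),
                                  as.integer(table(rejections$reason))),
                          collapse = "; ")))
  }
  fac <- fac[!drop, , drop = FALSE]
  if (!nrow(fac)) stop("all facility records were rejected", call. = FALSE)

  scores <- facility_scores(fac, checklist)
  dat <- dplyr::bind_cols(fac[c(STRATUM_KEYS, "weight")], scores)
  out <- dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(STRATUM_KEYS))) |>
    dplyr::summarise(
      n_facilities = dplyr::n(),
      wt_total = sum(.data$weight),
      dplyr::across(dplyr::all_of(paste0("ready_", names(checklist))),
                    ~ sum(.x * .data$weight) / sum(.data$weight)),
      .groups = "drop"
    )
  attr(out, "rejections") <- rejections
  out
}

# Vectorised scoring of many facilities; NA item flags count as absent.
facility_scores <- function(fac, checklist) {
  all_items <- unique(unlist(checklist))
  missing_items <- setdiff(all_items, names(fac))
  if (length(missing_items)) {
    stop(sprintf("schema error: checklist item(s) not present in facility table: %s",
                 paste(missing_items, collapse = ", ")), call. = FALSE)
  }
  n_na <- sum(vapply(fac[all_items], function(x) sum(is.na(x)), numeric(1)))
  if (n_na > 0) {
    message(sprintf("stratum_readiness: %d missing item flag(s) treated as 'not available'", n_na))
  }
  cols <- lapply(checklist, function(items) {
    m <- vapply(fac[items], function(x) !is.na(x) & as.logical(x), logical(nrow(fac)))
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(fac))
    as.numeric(rowSums(m) == length(items))
  })
  names(cols) <- paste0("ready_", names(checklist))
  tibble::as_tibble(cols)
}
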