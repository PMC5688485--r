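#' anclink: stratum-level linking of household and facility surveys
#'
#' Tools to estimate availability coverage of antenatal care (ANC)
#' interventions by combining care-seeking shares from household surveys
#' with facility readiness proportions from facility assessments, to fit
#' fractional-logit predictive models of coverage, and to compare the
#' results against the tiered / flat-5% default proxy rules used by the
#' Lives Saved Tool (LiST).
#'
#' @keywords internal
#' @importFrom rlang .data %||%
#' @importFrom stats plogis qlogis rbinom rpois rlnorm rnorm rbeta runif
#'   pnorm sd cor setNames complete.cases lm.wfit
#' @importFrom utils head
"_PACKAGE"

# The five ANC interventions handled throughout the package, in the fixed
# order used for deterministic iteration and for the item-rate solver.
INTERVENTIONS <- c("syphilis", "diabetes", "hypertensive", "malaria",
                   "preeclampsia")

# Country-level covariate names, in the fixed tie-breaking order used by
# stepwise selection (blood, urine, bp, early, anc4).
COVARIATE_NAMES <- c("blood_sample_rate", "urine_sample_rate", "bp_rate",
                     "early_anc_rate", "anc4_rate")

STRATUM_KEYS <- c("facility_type", "authority", "location")

logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)

#' Round half-up
#'
#' Rounds 0.5 away from zero toward positive infinity (the convention used
#' for reported integer percentages), unlike [base::round()]'s banker's
#' rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

weighted_prop <- function(flag, w) {
  stopifnot(length(flag) == length(w))
  sum(w * as.numeric(flag)) / sum(w)
}

# Derive a bounded sub-seed from a master seed and a stream label, so the
# household, facility, and panel streams are reproducible yet independent.
sub_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 1009 + offs) %% .Machine$integer.max)
}

assert_probability <- function(x, field) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("configuration error: `%s` must lie in [0, 1]", field),
         call. = FALSE)
  }
  invisible(x)
}

stratum_label <- function(facility_type, authority, location) {
  paste(facility_type, authority, location, sep = ":")
}

split_stratum_label <- function(label) {
  parts <- strsplit(label, ":", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad)) {
    stop(sprintf("malformed stratum label(s): %s",
                 paste(label[bad], collapse = ", ")), call. = FALSE)
  }
  tibble::tibble(
    facility_type = vapply(parts, `[[`, "", 1),
    authority     = vapply(parts, `[[`, "", 2),
    location      = vapply(parts, `[[`, "", 3)
  )
}
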