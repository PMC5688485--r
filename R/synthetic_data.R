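# Seeded synthetic microdata: DHS-style household records with ANC
# histories and SPA/SARA-style facility rosters, with a closed-form
# ground-truth availability coverage so the downstream estimator can be
# validated without any external data.

#' Simulation configuration for one country's surveys
#'
#' Describes the stated world the generator draws from: a two-stage
#' clustered household sample of women with a recent live birth, and a
#' weighted facility roster whose item availability is consistent with a
#' configured stratum-by-intervention readiness matrix.
#'
#' @param n_clusters number of household-survey clusters.
#' @param women_per_cluster women sampled per cluster.
#' @param n_facilities number of assessed facilities (must be at least
#'   the number of facility strata).
#' @param strata character vector of stratum labels
#'   `"type:authority:location"`; may include `"non_facility"` for ANC
#'   sought outside formal facilities.
#' @param careseeking_shares named probability vector over `strata`:
#'   the care-source distribution of ANC4+ women. Must sum to 1.
#' @param p_anc4 probability a woman attends 4+ ANC visits.
#' @param visit_count_law distribution of visit counts: a zero-inflated
#'   Poisson split at the ANC4+ margin — with probability `p_anc4`,
#'   `visits = 4 + Poisson(lambda_hi)`; otherwise 0 with probability
#'   `pi0`, else `min(1 + Poisson(lambda_low), 3)`.
#' @param p_early probability the first visit falls in pregnancy months
#'   1–4, given any ANC.
#' @param component_probs named probabilities of receiving each ANC
#'   component (`blood_pressure`, `urine_sample`, `blood_sample`,
#'   `weight`, `height`) among women with any ANC.
#' @param readiness_rates numeric matrix (rows = facility strata,
#'   columns = interventions) of per-intervention readiness
#'   probabilities; row names must appear in `strata`.
#' @param weight_law sampling-weight distribution,
#'   `list(dist = "lognormal", meanlog, sdlog)` or
#'   `list(dist = "constant", value)`.
#' @param p_within36 if non-`NULL`, the fraction of births falling
#'   inside the 36-month recall window; `NULL` draws months-since-birth
#'   uniformly on 0–59 (giving 0.6 inside the window).
#' @param couple_components if `TRUE`, ANC4+ facility-sourced women
#'   receive components at `component_probs` and all other ANC
#'   attenders at half those rates, coupling component receipt to
#'   facility care-seeking; default `FALSE` (independence).
#' @param checklist readiness checklist used to translate the readiness
#'   matrix into item-availability probabilities.
#' @param seed master seed; household, facility and panel streams use
#'   independent sub-seeds derived from it.
#' @return validated object of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 400,
                       women_per_cluster = 25,
                       n_facilities = 400,
                       strata = default_strata(),
                       careseeking_shares = default_careseeking_shares(),
                       p_anc4 = 0.55,
                       visit_count_law = list(dist = "anc_zip", lambda_hi = 1.5,
                                              pi0 = 0.3, lambda_low = 1.0),
                       p_early = 0.45,
                       component_probs = c(blood_pressure = 0.85,
                                           urine_sample = 0.70,
                                           blood_sample = 0.70,
                                           weight = 0.90, height = 0.60),
                       readiness_rates = default_readiness_rates(strata),
                       weight_law = list(dist = "lognormal", meanlog = 0, sdlog = 0.3),
                       p_within36 = NULL,
                       couple_components = FALSE,
                       checklist = default_checklist(),
                       seed = 1L) {
  cfg <- list(n_clusters = as.integer(n_clusters),
              women_per_cluster = as.integer(women_per_cluster),
              n_facilities = as.integer(n_facilities),
              strata = strata, careseeking_shares = careseeking_shares,
              p_anc4 = p_anc4, visit_count_law = visit_count_law,
              p_early = p_early, component_probs = component_probs,
              readiness_rates = readiness_rates, weight_law = weight_law,
              p_within36 = p_within36, couple_components = couple_components,
              checklist = validate_checklist(checklist),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_clusters >= 1, cfg$women_per_cluster >= 1, cfg$n_facilities >= 1)
  cs <- cfg$careseeking_shares
  if (is.null(names(cs)) || !all(names(cs) %in% cfg$strata)) {
    stop("configuration error: `careseeking_shares` must be named by entries of `strata`",
         call. = FALSE)
  }
  assert_probability(cs, "careseeking_shares")
  if (abs(sum(cs) - 1) > 1e-12) {
    stop("configuration error: `careseeking_shares` must sum to 1 (within 1e-12)",
         call. = FALSE)
  }
  assert_probability(cfg$p_anc4, "p_anc4")
  assert_probability(cfg$p_early, "p_early")
  assert_probability(cfg$component_probs, "component_probs")
  if (!is.null(cfg$p_within36)) assert_probability(cfg$p_within36, "p_within36")
  rr <- cfg$readiness_rates
  if (!is.matrix(rr) || is.null(rownames(rr)) || is.null(colnames(rr))) {
    stop("configuration error: `readiness_rates` must be a matrix with stratum rownames and intervention colnames",
         call. = FALSE)
  }
  assert_probability(as.vector(rr), "readiness_rates")
  unknown <- setdiff(rownames(rr), cfg$strata)
  if (length(unknown)) {
    stop(sprintf("configuration error: readiness_rates strata not in `strata`: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  fac_strata <- setdiff(cfg$strata, "non_facility")
  if (!all(fac_strata %in% rownames(rr))) {
    stop("configuration error: every facility stratum needs a readiness_rates row",
         call. = FALSE)
  }
  cfg
}

#' @rdname sim_config
#' @export
default_strata <- function() {
  grid <- expand.grid(location = c("urban", "rural"),
                      authority = c("public", "non_public"),
                      facility_type = c("hospital", "health_center", "health_post"),
                      stringsAsFactors = FALSE)
  c(stratum_label(grid$facility_type, grid$authority, grid$location),
    "non_facility")
}

#' @rdname sim_config
#' @export
default_careseeking_shares <- function() {
  c("hospital:public:urban" = 0.16, "hospital:public:rural" = 0.08,
    "hospital:non_public:urban" = 0.05, "hospital:non_public:rural" = 0.02,
    "health_center:public:urban" = 0.14, "health_center:public:rural" = 0.22,
    "health_center:non_public:urban" = 0.04, "health_center:non_public:rural" = 0.04,
    "health_post:public:urban" = 0.04, "health_post:public:rural" = 0.14,
    "health_post:non_public:urban" = 0.01, "health_post:non_public:rural" = 0.02,
    "non_facility" = 0.04)
}

#' @rdname sim_config
#' @export
default_readiness_rates <- function(strata = default_strata()) {
  fac <- setdiff(strata, "non_facility")
  keys <- split_stratum_label(fac)
  base <- rbind(hospital      = c(0.75, 0.70, 0.80, 0.75, 0.55),
                health_center = c(0.55, 0.45, 0.65, 0.60, 0.30),
                health_post   = c(0.30, 0.20, 0.40, 0.35, 0.10))
  colnames(base) <- INTERVENTIONS
  m <- base[keys$facility_type, , drop = FALSE]
  adj <- 0.05 * (keys$authority == "non_public") + 0.05 * (keys$location == "urban")
  m <- pmin(pmax(m + adj, 0.02), 0.98)
  rownames(m) <- fac
  m
}

draw_weights <- function(n, law) {
  switch(law$dist,
         lognormal = rlnorm(n, law$meanlog %||% 0, law$sdlog %||% 0.3),
         constant = rep(law$value %||% 1, n),
         stop(sprintf("unknown weight_law '%s'", law$dist), call. = FALSE))
}

#' Generate a household survey
#'
#' Draws `n_clusters * women_per_cluster` woman records (most recent
#' live birth) under the configured world: recall months, ANC visit
#' counts split at the ANC4+ margin, first-visit timing, component
#' receipt, and — for ANC4+ women only — a care-source stratum drawn
#' from `careseeking_shares` (women below 4 visits get a null source,
#' since only ANC4+ care-seeking enters the analysis). Deterministic
#' given the config's seed.
#'
#' @param config a [sim_config()].
#' @return tibble of woman records with columns `woman_id`,
#'   `cluster_id`, `months_since_birth`, `anc_visits`,
#'   `first_visit_month`, the component flags (`blood_pressure`,
#'   `urine_sample`, `blood_sample`, `weight_measured`,
#'   `height_measured`), `source_type`, `source_authority`, `residence`,
#'   `weight`.
#' @export
generate_household_survey <- function(config) {
  config <- validate_sim_config(config)
  set.seed(sub_seed(config$seed, "household"))
  n <- config$n_clusters * config$women_per_cluster

  months <- if (is.null(config$p_within36)) {
    sample(0:59, n, replace = TRUE)
  } else {
    recent <- runif(n) < config$p_within36
    ifelse(recent, sample(0:35, n, replace = TRUE), sample(36:59, n, replace = TRUE))
  }

  law <- config$visit_count_law
  is_anc4 <- runif(n) < config$p_anc4
  lo <- ifelse(runif(n) < (law$pi0 %||% 0.3), 0L,
               pmin(1L + rpois(n, law$lambda_low %||% 1), 3L))
  visits <- ifelse(is_anc4, 4L + rpois(n, law$lambda_hi %||% 1.5), lo)

  any_anc <- visits >= 1
  early <- runif(n) < config$p_early
  first_month <- ifelse(any_anc,
                        ifelse(early, sample(1:4, n, replace = TRUE),
                               sample(5:9, n, replace = TRUE)), NA_integer_)

  # care source: ANC4+ women only; others carry a null source
  shares <- config$careseeking_shares
  src <- rep(NA_character_, n)
  src[is_anc4] <- sample(names(shares), sum(is_anc4), replace = TRUE, prob = shares)
  fac_src <- !is.na(src) & src != "non_facility"
  src_keys <- tibble::tibble(facility_type = rep(NA_character_, n),
                             authority = rep(NA_character_, n),
                             location = rep(NA_character_, n))
  if (any(fac_src)) src_keys[fac_src, ] <- split_stratum_label(src[fac_src])
  src_type <- ifelse(!is.na(src) & src == "non_facility", "non_facility",
                     src_keys$facility_type)

  # residence: from the care-source stratum where one exists, otherwise
  # the marginal urban share implied by the facility care-seeking mix
  fac_shares <- shares[names(shares) != "non_facility"]
  urban_share <- sum(fac_shares[grepl(":urban$", names(fac_shares))]) / sum(fac_shares)
  residence <- ifelse(runif(n) < urban_share, "urban", "rural")
  residence[fac_src] <- src_keys$location[fac_src]

  cp <- config$component_probs
  mult <- if (config$couple_components) ifelse(fac_src, 1, 0.5) else rep(1, n)
  draw_comp <- function(p) any_anc & (runif(n) < p * mult)

  tibble::tibble(
    woman_id = sprintf("w%06d", seq_len(n)),
    cluster_id = sprintf("c%04d", rep(seq_len(config$n_clusters),
                                      each = config$women_per_cluster)),
    months_since_birth = as.integer(months),
    anc_visits = as.integer(visits),
    first_visit_month = as.integer(first_month),
    blood_pressure = draw_comp(cp[["blood_pressure"]]),
    urine_sample = draw_comp(cp[["urine_sample"]]),
    blood_sample = draw_comp(cp[["blood_sample"]]),
    weight_measured = draw_comp(cp[["weight"]]),
    height_measured = draw_comp(cp[["height"]]),
    source_type = src_type,
    source_authority = src_keys$authority,
    residence = residence,
    weight = draw_weights(n, config$weight_law)
  )
}

# Per-item availability probabilities consistent with the configured
# per-intervention readiness rates. Items are drawn independently within
# a facility, so P(all checklist items present) = prod(q_item); q is
# solved checklist by checklist in the fixed intervention order,
# conditioning on items already assigned (shared items induce
# cross-intervention correlation but keep every marginal rate exact,
# unless infeasible — then capped at 1 with a warning).
solve_item_rates <- function(r, checklist) {
  q <- c()
  for (iv in intersect(INTERVENTIONS, names(checklist))) {
    items <- checklist[[iv]]
    known <- intersect(items, names(q))
    rem <- setdiff(items, names(q))
    pk <- prod(q[known])
    # a zero shared-item rate already forces readiness 0; any remaining
    # rate is then feasible only for a zero target
    target <- if (pk == 0) (if (r[[iv]] > 0) Inf else 1) else r[[iv]] / pk
    if (!length(rem)) {
      if (abs(target - 1) > 1e-8) {
        warning(sprintf("readiness rate for '%s' fully determined by shared items; configured value ignored", iv),
                call. = FALSE)
      }
      next
    }
    if (target > 1) {
      warning(sprintf("readiness rate for '%s' infeasible given shared-item rates; capped", iv),
              call. = FALSE)
      target <- 1
    }
    q[rem] <- target^(1 / length(rem))
  }
  q
}

#' Generate a facility assessment
#'
#' Allocates `n_facilities` deterministically across the facility strata
#' (equal shares, remainder to the first strata, so every stratum
#' receives at least one facility) and draws per-item availability flags
#' whose implied per-intervention readiness matches the configured
#' `readiness_rates` exactly in expectation. Deterministic given the
#' config's seed.
#'
#' @param config a [sim_config()].
#' @return tibble of facility records: `facility_id`, `facility_type`,
#'   `authority`, `location`, one logical column per checklist item,
#'   `weight`.
#' @export
generate_facility_survey <- function(config) {
  config <- validate_sim_config(config)
  fac_strata <- rownames(config$readiness_rates)
  k <- length(fac_strata)
  if (config$n_facilities < k) {
    stop(sprintf("configuration error: n_facilities (%d) < number of facility strata (%d)",
                 config$n_facilities, k), call. = FALSE)
  }
  set.seed(sub_seed(config$seed, "facility"))
  n_per <- rep(config$n_facilities %/% k, k) +
    c(rep(1L, config$n_facilities %% k), rep(0L, k - config$n_facilities %% k))
  stratum_of <- rep(fac_strata, n_per)
  n <- length(stratum_of)

  items <- unique(unlist(config$checklist))
  qmat <- t(vapply(fac_strata, function(s) {
    q <- solve_item_rates(config$readiness_rates[s, ], config$checklist)
    q[items]
  }, numeric(length(items))))
  colnames(qmat) <- items

  flags <- lapply(items, function(it) {
    runif(n) < qmat[stratum_of, it]
  })
  names(flags) <- items

  keys <- split_stratum_label(stratum_of)
  tibble::as_tibble(c(
    list(facility_id = sprintf("f%05d", seq_len(n))),
    as.list(keys),
    flags,
    list(weight = draw_weights(n, config$weight_law))
  ))
}

#' Ground-truth availability coverage under the generator
#'
#' The closed form of the linked estimand in the simulated world:
#' \deqn{p_{ANC4+} \sum_s c^{shares}_s \, r_{s,int}} summed over facility
#' strata (a non-facility care-source share contributes zero, since
#' readiness is undefined there). Always lies in `[0, p_anc4]`.
#'
#' @param config a [sim_config()].
#' @param intervention one of the interventions named in
#'   `readiness_rates`.
#' @return proportion in `[0, 1]`.
#' @export
true_availability_coverage <- function(config, intervention) {
  config <- validate_sim_config(config)
  rr <- config$readiness_rates
  if (!intervention %in% colnames(rr)) {
    stop(sprintf("unknown intervention '%s'", intervention), call. = FALSE)
  }
  shares <- config$careseeking_shares
  fac <- intersect(names(shares), rownames(rr))
  config$p_anc4 * sum(shares[fac] * rr[fac, intervention])
}

#' Multi-country panel configuration
#'
#' World for the predictive-modelling stage: country-level covariate
#' rates drawn from Beta laws and observed coverage generated by a
#' fractional-logit process, `coverage = logit^{-1}(x'beta + e)` with
#' `e ~ N(0, noise_sd^2)`.
#'
#' @param n_countries number of countries (at least 3).
#' @param true_beta named list mapping intervention to a named
#'   coefficient vector (first element the intercept, remaining names
#'   drawn from the covariate set). Defaults to the published
#'   coefficient set ([published_models()]).
#' @param covariate_law named list mapping each covariate to
#'   `c(shape1, shape2)` Beta parameters.
#' @param noise_sd logit-scale noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return object of class `panel_config`.
#' @export
panel_config <- function(n_countries = 20,
                         true_beta = published_beta(),
                         covariate_law = list(
                           blood_sample_rate = c(5, 2.5),
                           urine_sample_rate = c(4, 2.5),
                           bp_rate = c(6, 2),
                           early_anc_rate = c(4, 4),
                           anc4_rate = c(5, 3)),
                         noise_sd = 0.15,
                         seed = 1L) {
  if (n_countries < 3) stop("configuration error: n_countries must be >= 3", call. = FALSE)
  if (noise_sd < 0) stop("configuration error: noise_sd must be >= 0", call. = FALSE)
  stopifnot(all(names(covariate_law) %in% COVARIATE_NAMES))
  for (iv in names(true_beta)) {
    b <- true_beta[[iv]]
    terms <- names(b)[-1]
    if (!all(terms %in% names(covariate_law))) {
      stop(sprintf("configuration error: true_beta['%s'] uses covariates without a law", iv),
           call. = FALSE)
    }
  }
  structure(list(n_countries = as.integer(n_countries), true_beta = true_beta,
                 covariate_law = covariate_law, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "panel_config")
}

#' Generate a country panel with a known fractional-logit process
#'
#' @param config a [panel_config()].
#' @return tibble with one row per country x intervention: `country`,
#'   the covariate columns, `intervention`, `coverage` in (0, 1).
#' @export
generate_country_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(sub_seed(config$seed, "panel"))
  n <- config$n_countries
  covs <- tibble::as_tibble(lapply(config$covariate_law, function(sh) {
    rbeta(n, sh[1], sh[2])
  }))
  covs <- dplyr::bind_cols(tibble::tibble(country = sprintf("C%03d", seq_len(n))), covs)

  rows <- lapply(names(config$true_beta), function(iv) {
    b <- config$true_beta[[iv]]
    eta <- rep(b[[1]], n)
    for (term in names(b)[-1]) eta <- eta + b[[term]] * covs[[term]]
    eps <- if (config$noise_sd > 0) rnorm(n, 0, config$noise_sd) else 0
    dplyr::bind_cols(covs,
                     tibble::tibble(intervention = iv,
                                    coverage = inv_logit(eta + eps)))
  })
  dplyr::bind_rows(rows)
}
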