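# End-to-end orchestration: simulate a multi-country world, summarise
# facility readiness and household care-seeking, link, fit predictive
# models on the resulting panel, and evaluate against default proxies.

#' Configuration for an end-to-end pipeline run
#'
#' @param out_dir directory for stage outputs (created if needed).
#' @param seed master seed; recorded, with the config, in
#'   `config_resolved.yaml` and threaded to every random stream.
#' @param n_countries number of simulated countries.
#' @param base_sim a [sim_config()] whose parameters are perturbed per
#'   country (see [simulate_countries()]); its sample sizes set the
#'   per-country survey sizes.
#' @param checklist readiness checklist (see [default_checklist()]).
#' @param stages stages to run, a subset of
#'   `c("simulate", "readiness", "careseeking", "link", "fit",
#'   "evaluate")`; later stages are skipped automatically when a stage
#'   they depend on is disabled.
#' @param keep_microdata write the simulated household/facility
#'   microdata CSVs (large) in addition to the stratum summaries.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("anclink_run_"),
                       seed = 1L,
                       n_countries = 20L,
                       base_sim = sim_config(n_clusters = 100,
                                             women_per_cluster = 20,
                                             n_facilities = 150,
                                             seed = seed),
                       checklist = default_checklist(),
                       stages = c("simulate", "readiness", "careseeking",
                                  "link", "fit", "evaluate"),
                       keep_microdata = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_countries = as.integer(n_countries), base_sim = base_sim,
                 checklist = validate_checklist(checklist), stages = stages,
                 keep_microdata = keep_microdata),
            class = "run_config")
}

#' Simulate a set of countries around a base configuration
#'
#' Draws one [sim_config()] per country by perturbing the base
#' configuration with a country-level latent "health system quality"
#' factor `u ~ N(0, 1)` that shifts both component-receipt
#' probabilities and facility readiness on the logit scale (plus
#' independent cell-level noise), and jitters the ANC4+ rate, early
#' enrolment rate and care-seeking mix. The shared factor induces the
#' real-world feature the predictive models exploit: countries where
#' ANC components are commonly delivered also tend to have ready
#' facilities.
#'
#' @param base a [sim_config()].
#' @param n_countries number of countries.
#' @param seed master seed for the country-level draws.
#' @return named list of `sim_config` objects (`C001`, `C002`, ...).
#' @export
simulate_countries <- function(base, n_countries, seed = base$seed) {
  set.seed(sub_seed(seed, "countries"))
  jitter_logit <- function(p, shift, sd = 0) {
    inv_logit(logit(pmin(pmax(p, 0.02), 0.98)) + shift +
                if (sd > 0) rnorm(length(p), 0, sd) else 0)
  }
  out <- lapply(seq_len(n_countries), function(i) {
    u <- rnorm(1)
    cfg <- base
    cfg$seed <- sub_seed(seed, paste0("country", i))
    cfg$p_anc4 <- inv_logit(logit(base$p_anc4) + 0.4 * u + rnorm(1, 0, 0.5))
    cfg$p_early <- jitter_logit(base$p_early, rnorm(1, 0, 0.5))
    cfg$component_probs <- vapply(base$component_probs, function(p) {
      jitter_logit(p, 0.8 * u + rnorm(1, 0, 0.4))
    }, numeric(1))
    rr <- base$readiness_rates
    for (iv in colnames(rr)) {
      rr[, iv] <- jitter_logit(rr[, iv], 0.8 * u + rnorm(1, 0, 0.3), sd = 0.2)
    }
    cfg$readiness_rates <- rr
    shares <- base$careseeking_shares * exp(rnorm(length(base$careseeking_shares), 0, 0.3))
    cfg$careseeking_shares <- shares / sum(shares)
    validate_sim_config(cfg)
  })
  names(out) <- sprintf("C%03d", seq_len(n_countries))
  out
}

#' Run the linking pipeline end to end
#'
#' Executes the five analysis steps on simulated data: (1) facility
#' readiness by stratum, (2) household care-seeking by stratum plus
#' country covariate rates, (3) the stratum-product linking estimator
#' per intervention, (4) stepwise fractional-logit predictive models on
#' the resulting country panel, (5) evaluation: fit metrics of the
#' predictions against the linked estimates, and comparison of linked
#' estimates with the default proxy rules. All numeric outputs are
#' written as CSV/JSON under `config$out_dir` and are identical across
#' reruns with the same config and seed.
#'
#' @param config a [run_config()].
#' @return the run report (invisibly written to `report.json`): list of
#'   per-stage record counts, exclusions, unmatched shares, convergence
#'   flags, and file paths.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, stages_run = character(),
                 status = "incomplete")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$status <<- sprintf("failed at stage '%s'", name)
      jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                           auto_unbox = TRUE, pretty = TRUE, force = TRUE)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  on <- function(name) name %in% config$stages
  write_cfg_yaml(config)

  households <- facilities <- NULL
  if (on("simulate")) {
    stage("simulate", {
      countries <- simulate_countries(config$base_sim, config$n_countries,
                                      seed = config$seed)
      households <- lapply(countries, generate_household_survey)
      facilities <- lapply(countries, generate_facility_survey)
      truth <- dplyr::bind_rows(lapply(names(countries), function(cc) {
        tibble::tibble(country = cc, intervention = INTERVENTIONS,
                       true_coverage = vapply(INTERVENTIONS, function(iv) {
                         true_availability_coverage(countries[[cc]], iv)
                       }, numeric(1)))
      }))
      readr::write_csv(truth, file.path(config$out_dir, "true_coverage.csv"))
      if (config$keep_microdata) {
        md <- file.path(config$out_dir, "microdata")
        dir.create(md, showWarnings = FALSE)
        for (cc in names(countries)) {
          readr::write_csv(households[[cc]], file.path(md, paste0(cc, "_household.csv")))
          readr::write_csv(facilities[[cc]], file.path(md, paste0(cc, "_facility.csv")))
        }
      }
      report$stages_run <- c(report$stages_run, "simulate")
      report$simulate <- list(n_countries = length(countries),
                              n_women = sum(vapply(households, nrow, numeric(1))),
                              n_facilities = sum(vapply(facilities, nrow, numeric(1))))
    })
  }

  readiness_tabs <- NULL
  if (on("readiness") && !is.null(facilities)) {
    stage("readiness", {
      readiness_tabs <- lapply(facilities, stratum_readiness,
                               checklist = config$checklist)
      combined <- dplyr::bind_rows(readiness_tabs, .id = "country")
      readr::write_csv(combined, file.path(config$out_dir, "stratum_readiness.csv"))
      report$stages_run <- c(report$stages_run, "readiness")
      report$readiness <- list(
        n_strata = nrow(combined),
        n_rejected = sum(vapply(readiness_tabs,
                                function(t) nrow(attr(t, "rejections")), numeric(1))))
    })
  }

  careseeking_tabs <- covariates <- NULL
  if (on("careseeking") && !is.null(households)) {
    stage("careseeking", {
      eligible <- lapply(households, filter_eligible)
      careseeking_tabs <- lapply(eligible, stratum_careseeking)
      covariates <- dplyr::bind_rows(lapply(eligible, covariate_rates),
                                     .id = "country")
      combined <- dplyr::bind_rows(careseeking_tabs, .id = "country")
      readr::write_csv(combined, file.path(config$out_dir, "stratum_careseeking.csv"))
      readr::write_csv(covariates, file.path(config$out_dir, "covariates.csv"))
      report$stages_run <- c(report$stages_run, "careseeking")
      report$careseeking <- list(
        n_eligible = sum(vapply(eligible, nrow, numeric(1))),
        n_excluded = sum(vapply(eligible,
                                function(t) attr(t, "n_excluded"), numeric(1))),
        anc4_mean = mean(vapply(careseeking_tabs,
                                function(t) attr(t, "anc4"), numeric(1))))
    })
  }

  panel <- NULL
  if (on("link") && !is.null(careseeking_tabs) && !is.null(readiness_tabs)) {
    stage("link", {
      rows <- lapply(names(careseeking_tabs), function(cc) {
        dplyr::bind_rows(lapply(INTERVENTIONS, function(iv) {
          est <- link_coverage(careseeking_tabs[[cc]], readiness_tabs[[cc]], iv)
          tibble::tibble(country = cc, intervention = iv, value = est$value,
                         method = est$method, n_strata_used = est$n_strata_used,
                         unmatched_share = est$unmatched_careseeking_share)
        }))
      })
      panel <- dplyr::bind_rows(rows) |>
        dplyr::left_join(covariates, by = "country")
      readr::write_csv(panel, file.path(config$out_dir, "coverage_panel.csv"))
      report$stages_run <- c(report$stages_run, "link")
      report$link <- list(n_estimates = nrow(panel),
                          max_unmatched_share = max(panel$unmatched_share))
    })
  }

  models <- predictions <- NULL
  if (on("fit") && !is.null(panel)) {
    stage("fit", {
      models <- lapply(INTERVENTIONS, function(iv) {
        sub <- panel[panel$intervention == iv, ]
        fit <- stepwise_select(sub$value, sub[COVARIATE_NAMES])
        fit$intervention <- iv
        fit
      })
      names(models) <- INTERVENTIONS
      jsonlite::write_json(
        lapply(models, function(m) {
          list(intervention = m$intervention, terms = m$terms,
               beta = as.list(m$beta), se = as.list(m$se),
               p_values = as.list(m$p_values), n_obs = m$n_obs,
               converged = m$converged)
        }),
        file.path(config$out_dir, "models.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
      predictions <- dplyr::bind_rows(lapply(INTERVENTIONS, function(iv) {
        sub <- panel[panel$intervention == iv, ]
        tibble::tibble(country = sub$country, intervention = iv,
                       value = vapply(seq_len(nrow(sub)), function(j) {
                         predict_coverage(models[[iv]], sub[j, COVARIATE_NAMES])
                       }, numeric(1)))
      }))
      readr::write_csv(predictions, file.path(config$out_dir, "predictions.csv"))
      report$stages_run <- c(report$stages_run, "fit")
      report$fit <- list(
        converged = vapply(models, function(m) m$converged, logical(1)),
        n_terms = vapply(models, function(m) length(m$terms), numeric(1)))
    })
  }

  if (on("evaluate") && !is.null(panel)) {
    stage("evaluate", {
      proxies <- panel |>
        dplyr::transmute(.data$country, .data$intervention,
                         value = vapply(seq_len(nrow(panel)), function(j) {
                           default_proxy(panel$intervention[j],
                                         100 * panel$anc4_rate[j])
                         }, numeric(1)))
      linked <- panel[c("country", "intervention", "value")]
      comparison <- compare_to_proxy(linked, proxies)
      readr::write_csv(comparison, file.path(config$out_dir, "proxy_comparison.csv"))
      report$evaluate <- list(
        proxy_diff_range_pp = as.numeric(attr(comparison, "range")))
      if (!is.null(predictions)) {
        metrics <- lapply(INTERVENTIONS, function(iv) {
          obs <- linked$value[linked$intervention == iv]
          prd <- predictions$value[predictions$intervention == iv]
          m <- compute_metrics(obs, prd)
          list(r_squared = m$r_squared, pearson_rho = m$pearson_rho,
               rmse = m$rmse, n = m$n,
               correlation_class = if (m$rho_defined)
                 classify_correlation(m$pearson_rho) else NA)
        })
        names(metrics) <- INTERVENTIONS
        jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
        report$evaluate$metrics <- metrics
      }
      report$stages_run <- c(report$stages_run, "evaluate")
    })
  }

  report$status <- "complete"
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  report
}

write_cfg_yaml <- function(config) {
  cfg <- list(seed = config$seed, n_countries = config$n_countries,
              stages = config$stages,
              base_sim = list(
                n_clusters = config$base_sim$n_clusters,
                women_per_cluster = config$base_sim$women_per_cluster,
                n_facilities = config$base_sim$n_facilities,
                p_anc4 = config$base_sim$p_anc4,
                p_early = config$base_sim$p_early,
                component_probs = as.list(config$base_sim$component_probs),
                careseeking_shares = as.list(config$base_sim$careseeking_shares),
                readiness_rates = apply(config$base_sim$readiness_rates, 1,
                                        as.list, simplify = FALSE)))
  yaml::write_yaml(cfg, file.path(config$out_dir, "config_resolved.yaml"))
}
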