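# Fractional-logit predictive models of intervention coverage, stepwise
# covariate selection, prediction from fitted or published coefficient
# sets, and the default proxy rules they are compared against.

#' Fit a fractional logit model
#'
#' Quasi-likelihood regression for a fractional outcome `y` on `[0, 1]`:
#' maximises the Bernoulli quasi-log-likelihood
#' \deqn{\sum_i w_i [ y_i \log\mu_i + (1-y_i)\log(1-\mu_i) ], \quad
#'   \mu_i = logit^{-1}(x_i'\beta)}
#' by iteratively reweighted least squares (IRLS). Outcomes exactly 0 or
#' 1 are admitted without clipping — the quasi-likelihood is finite
#' there for finite coefficients. Because fractional outcomes violate
#' the binomial variance function, inference uses robust sandwich (HC1)
#' standard errors, with two-sided p-values from the normal reference
#' distribution.
#'
#' Covariates are expected on the proportion (0–1) scale; coefficient
#' magnitudes are only interpretable on that scale.
#'
#' @param y numeric outcome vector in `[0, 1]`.
#' @param X covariate data frame or matrix (no intercept column — one is
#'   added), columns named.
#' @param weights optional positive observation weights (default 1).
#' @param max_iter maximum IRLS iterations.
#' @param tol convergence tolerance on the maximum relative coefficient
#'   change.
#' @return object of class `fraclogit`: `intervention` (optional
#'   label), `terms`, `beta` (intercept first), `se` (HC1), `p_values`,
#'   `vcov`, `n_obs`, `converged`, `iterations`, `fitted`.
#' @export
fit_fractional_logit <- function(y, X = NULL, weights = NULL,
                                 max_iter = 100L, tol = 1e-10) {
  y <- as.numeric(y)
  if (any(!is.finite(y)) || any(y < 0) || any(y > 1)) {
    stop("outcome must lie in [0, 1] with no missing values", call. = FALSE)
  }
  n <- length(y)
  if (is.null(X)) {
    Xm <- matrix(numeric(0), nrow = n, ncol = 0)
    terms <- character()
  } else {
    Xm <- as.matrix(X)
    if (is.null(colnames(Xm))) colnames(Xm) <- paste0("x", seq_len(ncol(Xm)))
    terms <- colnames(Xm)
  }
  Xd <- cbind(`(Intercept)` = 1, Xm)
  p <- ncol(Xd)
  if (n <= p) stop("more parameters than observations", call. = FALSE)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  stopifnot(length(w) == n, all(w > 0))

  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  eps <- 1e-10
  for (iter in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- pmin(pmax(inv_logit(eta), eps), 1 - eps)
    v <- mu * (1 - mu)             # logit link: variance = d mu / d eta
    z <- eta + (y - mu) / v        # working response
    ww <- w * v
    fit <- tryCatch(
      lm.wfit(Xd, z, ww),
      error = function(e) NULL
    )
    if (is.null(fit) || anyNA(fit$coefficients)) {
      return(fraclogit_failure(terms, n, iter,
                               "singular weighted least-squares system"))
    }
    beta_new <- fit$coefficients
    delta <- max(abs(beta_new - beta) / pmax(abs(beta_new), 1e-8))
    beta <- beta_new
    if (!all(is.finite(beta)) || max(abs(beta)) > 1e6) {
      return(fraclogit_failure(terms, n, iter,
                               "divergent coefficients (possible separation)"))
    }
    if (delta < tol) { converged <- TRUE; break }
  }

  eta <- drop(Xd %*% beta)
  mu <- pmin(pmax(inv_logit(eta), eps), 1 - eps)
  v <- mu * (1 - mu)
  # sandwich: bread from the expected information, meat from the outer
  # product of scores; HC1 small-sample factor n / (n - p)
  A <- crossprod(Xd * sqrt(w * v))
  u <- Xd * (w * (y - mu))
  B <- crossprod(u)
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ainv)) {
    return(fraclogit_failure(terms, n, iter, "singular information matrix"))
  }
  V <- Ainv %*% B %*% Ainv * n / (n - p)
  se <- sqrt(diag(V))
  zstat <- beta / se
  structure(list(
    intervention = NULL,
    terms = terms,
    beta = setNames(beta, colnames(Xd)),
    se = setNames(se, colnames(Xd)),
    p_values = setNames(2 * pnorm(-abs(zstat)), colnames(Xd)),
    vcov = V,
    n_obs = n,
    converged = converged,
    iterations = iter,
    fitted = inv_logit(eta)
  ), class = "fraclogit")
}

fraclogit_failure <- function(terms, n, iter, reason) {
  structure(list(intervention = NULL, terms = terms,
                 beta = NULL, se = NULL, p_values = NULL, vcov = NULL,
                 n_obs = n, converged = FALSE, iterations = iter,
                 diagnostics = reason, fitted = NULL),
            class = "fraclogit")
}

#' @export
print.fraclogit <- function(x, ...) {
  cat("<fraclogit>", if (!is.null(x$intervention)) x$intervention else "",
      sprintf("n = %d, converged = %s (%d iterations)\n",
              x$n_obs, x$converged, x$iterations))
  if (!is.null(x$beta)) {
    print(data.frame(estimate = x$beta, robust_se = x$se, p = x$p_values))
  } else {
    cat("  fit failed:", x$diagnostics, "\n")
  }
  invisible(x)
}

#' Stepwise covariate selection for a fractional logit model
#'
#' Forward selection with backward pruning: at each forward step the
#' candidate with the smallest robust p-value below `p_exit` enters
#' (ties broken by the fixed candidate ordering blood, urine, blood
#' pressure, early enrolment, ANC4+); after each addition any included
#' term with p-value at or above `p_exit` is removed; iterated to a
#' fixed point. The model never exceeds `max_terms` covariates
#' (excluding the intercept) — a small-sample cap. If no candidate ever
#' enters, the intercept-only model is returned, flagged via its empty
#' `terms`.
#'
#' @param y fractional outcome vector.
#' @param candidates data frame of candidate covariates (columns on the
#'   0–1 scale).
#' @param p_exit entry/exit p-value threshold.
#' @param max_terms maximum number of covariates retained.
#' @param weights optional observation weights.
#' @return a `fraclogit` fit on the selected terms.
#' @export
stepwise_select <- function(y, candidates, p_exit = 0.1, max_terms = 2L,
                            weights = NULL) {
  cand <- tibble::as_tibble(candidates)
  if (!ncol(cand)) stop("no candidate covariates supplied", call. = FALSE)
  order_ref <- c(intersect(COVARIATE_NAMES, names(cand)),
                 setdiff(names(cand), COVARIATE_NAMES))
  cand <- cand[order_ref]
  selected <- character()
  repeat {
    changed <- FALSE
    # forward step
    if (length(selected) < max_terms) {
      pool <- setdiff(names(cand), selected)
      best <- NULL; best_p <- p_exit
      for (term in pool) {
        f <- fit_fractional_logit(y, cand[c(selected, term)], weights = weights)
        if (!f$converged || is.null(f$p_values)) next
        pv <- f$p_values[[term]]
        if (pv < best_p) { best <- term; best_p <- pv }
      }
      if (!is.null(best)) { selected <- c(selected, best); changed <- TRUE }
    }
    # backward step
    if (length(selected)) {
      f <- fit_fractional_logit(y, cand[selected], weights = weights)
      pv <- f$p_values[selected]
      worst <- names(pv)[which.max(pv)]
      if (max(pv) >= p_exit) {
        selected <- setdiff(selected, worst)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  fit_fractional_logit(y, if (length(selected)) cand[selected] else NULL,
                       weights = weights)
}

#' Published coefficient set for the five ANC interventions
#'
#' The multivariate fractional-logit coefficients reported for the
#' five interventions, on the logit scale with covariates as proportions
#' on `[0, 1]`:
#' \itemize{
#' \item syphilis detection and treatment: intercept -1.22, blood sample
#'   3.36, early ANC enrolment -5.23;
#' \item diabetes case management: intercept -3.21, blood sample 2.61;
#' \item hypertensive disorders case management: intercept -1.62, urine
#'   sample 2.50 — note the source table labels this slope "urine sample
#'   taken" while the accompanying prose attributes the association to
#'   blood-pressure measurement; the table value is transcribed here and
#'   the discrepancy is NOT silently resolved;
#' \item malaria case management: intercept -1.64, blood sample 2.92;
#' \item management of pre-eclampsia: intercept -6.44, blood sample
#'   4.91, ANC4+ 2.56.
#' }
#'
#' @return named list (one entry per intervention) of objects of class
#'   `published_model`: `intervention`, `beta` (named, intercept first),
#'   and an optional `note`.
#' @export
published_models <- function() {
  mk <- function(iv, beta, note = NULL) {
    structure(list(intervention = iv, beta = beta, note = note),
              class = "published_model")
  }
  list(
    syphilis = mk("syphilis",
                  c("(Intercept)" = -1.22, blood_sample_rate = 3.36,
                    early_anc_rate = -5.23)),
    diabetes = mk("diabetes",
                  c("(Intercept)" = -3.21, blood_sample_rate = 2.61)),
    hypertensive = mk("hypertensive",
                      c("(Intercept)" = -1.62, urine_sample_rate = 2.50),
                      note = paste("slope labeled 'urine sample taken' in the",
                                   "source table; prose attributes it to",
                                   "blood-pressure measurement")),
    malaria = mk("malaria",
                 c("(Intercept)" = -1.64, blood_sample_rate = 2.92)),
    preeclampsia = mk("preeclampsia",
                      c("(Intercept)" = -6.44, blood_sample_rate = 4.91,
                        anc4_rate = 2.56))
  )
}

#' @rdname published_models
#' @return `published_beta()`: the same set as a named list of plain
#'   coefficient vectors, convenient as `true_beta` for
#'   [panel_config()].
#' @export
published_beta <- function() {
  lapply(published_models(), function(m) m$beta)
}

#' Predict coverage from a fitted or published model
#'
#' Applies the inverse logit to the linear predictor: coverage
#' `= logit^{-1}(b0 + sum_j b_j x_j)`, always strictly inside (0, 1).
#'
#' @param model a `fraclogit` fit or a `published_model` entry.
#' @param covariates named list / one-row data frame holding every
#'   covariate the model's terms name, on the 0–1 proportion scale.
#' @return predicted proportion(s) in (0, 1).
#' @export
predict_coverage <- function(model, covariates) {
  beta <- if (inherits(model, "fraclogit")) {
    if (is.null(model$beta)) stop("model did not converge; no coefficients", call. = FALSE)
    model$beta
  } else if (inherits(model, "published_model")) {
    model$beta
  } else stop("model must be a 'fraclogit' or 'published_model'", call. = FALSE)
  covs <- as.list(covariates)
  terms <- names(beta)[-1]
  missing_terms <- setdiff(terms, names(covs))
  if (length(missing_terms)) {
    stop(sprintf("missing covariate(s) for prediction: %s",
                 paste(missing_terms, collapse = ", ")), call. = FALSE)
  }
  eta <- beta[[1]]
  for (term in terms) eta <- eta + beta[[term]] * as.numeric(covs[[term]])
  inv_logit(eta)
}

#' Default proxy coverage rules
#'
#' The rules currently used to impute baseline coverage of the ANC
#' interventions from ANC4+ coverage when no better data exist:
#' \itemize{
#' \item syphilis detection and treatment — a tiered multiplier of
#'   ANC4+: 20% of ANC4+ when ANC4+ < 40; 50% when 40 <= ANC4+ < 75;
#'   70% when 75 <= ANC4+ < 95; 100% when ANC4+ >= 95;
#' \item diabetes, hypertensive disorders, malaria and pre-eclampsia
#'   case management — a flat 5% of ANC4+.
#' }
#' ANC4+ enters on the percent scale as the rules are stated; the result
#' is returned on the proportion scale used everywhere else in the
#' package. The proxy can never exceed ANC4+ itself.
#'
#' @param intervention one of `"syphilis"`, `"diabetes"`,
#'   `"hypertensive"`, `"malaria"`, `"preeclampsia"`.
#' @param anc4_percent ANC4+ coverage in percent, on `[0, 100]`
#'   (vectorised).
#' @return proxy coverage as a proportion in `[0, 1]`.
#' @export
#' @examples
#' default_proxy("syphilis", 30)   # 0.20 * 30% = 0.06
#' default_proxy("diabetes", 60)   # 0.05 * 60% = 0.03
default_proxy <- function(intervention, anc4_percent) {
  intervention <- match.arg(intervention, INTERVENTIONS)
  if (any(!is.finite(anc4_percent)) || any(anc4_percent < 0) ||
      any(anc4_percent > 100)) {
    stop("anc4_percent must lie in [0, 100]", call. = FALSE)
  }
  mult <- if (intervention == "syphilis") {
    syphilis_tier_multiplier(anc4_percent)
  } else {
    0.05
  }
  mult * anc4_percent / 100
}

#' @rdname default_proxy
#' @return `syphilis_tier_multiplier()`: the tier multiplier (0.20,
#'   0.50, 0.70 or 1.00) applied to ANC4+ under the tiered rule.
#' @export
syphilis_tier_multiplier <- function(anc4_percent) {
  ifelse(anc4_percent < 40, 0.20,
         ifelse(anc4_percent < 75, 0.50,
                ifelse(anc4_percent < 95, 0.70, 1.00)))
}
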