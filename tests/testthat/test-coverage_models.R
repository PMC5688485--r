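test_that("the intercept-only fractional logit has the closed-form solution", {
  set.seed(12)
  y <- runif(30)
  f <- fit_fractional_logit(y)
  expect_equal(unname(f$beta[1]), qlogis(mean(y)), tolerance = 1e-10)
  expect_true(f$converged)
  # weighted version: logit of the weighted mean
  w <- rlnorm(30)
  fw <- fit_fractional_logit(y, weights = w)
  expect_equal(unname(fw$beta[1]), qlogis(sum(w * y) / sum(w)), tolerance = 1e-10)
})

test_that("coefficients agree with the reference GLM on a fixed 20-row panel", {
  fx <- fixture_panel_20()
  f <- fit_fractional_logit(fx$y, fx$X)
  g <- stats::glm(fx$y ~ blood_sample_rate + anc4_rate, data = fx$X,
                  family = stats::quasibinomial())
  expect_lt(max(abs(f$beta - stats::coef(g))), 1e-6)
  expect_true(f$converged)
  # robust (HC1 sandwich) standard errors against an independent route
  expect_equal(unname(f$se), unname(glm_hc1_se(g)), tolerance = 1e-6)
  expect_true(all(f$p_values >= 0 & f$p_values <= 1))
})

test_that("outcomes exactly at 0 and 1 are admitted without clipping", {
  set.seed(33)
  x <- runif(40)
  y <- c(0, 1, plogis(-1 + 2 * x[-(1:2)] + rnorm(38, 0, 0.3)))
  f <- fit_fractional_logit(y, data.frame(x = x))
  g <- suppressWarnings(stats::glm(y ~ x, family = stats::quasibinomial()))
  expect_lt(max(abs(f$beta - stats::coef(g))), 1e-6)
})

test_that("the estimator is invariant to observation order", {
  fx <- fixture_panel_20()
  f1 <- fit_fractional_logit(fx$y, fx$X)
  perm <- sample(seq_along(fx$y))
  f2 <- fit_fractional_logit(fx$y[perm], fx$X[perm, ])
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
})

test_that("degenerate fits fail loudly rather than silently", {
  # perfectly separated binary outcome: divergence is flagged
  x <- c(rep(0, 10), rep(1, 10))
  y <- x
  f <- fit_fractional_logit(y, data.frame(x = x))
  expect_false(f$converged)
  expect_error(fit_fractional_logit(c(0.2, -0.1, 0.5)), "\\[0, 1\\]")
  expect_error(fit_fractional_logit(runif(3),
                                    data.frame(a = runif(3), b = runif(3),
                                               c = runif(3))),
               "more parameters")
})

test_that("parameter recovery improves with panel size", {
  truth <- c(-6.44, 4.91, 2.56)
  sizes <- c(50, 200, 800)
  reps <- 100
  bias <- sapply(sizes, function(n) {
    est <- vapply(seq_len(reps), function(r) {
      pc <- panel_config(n_countries = n, noise_sd = 0.15, seed = n * 1000 + r,
                         true_beta = list(preeclampsia = c(
                           "(Intercept)" = -6.44, blood_sample_rate = 4.91,
                           anc4_rate = 2.56)))
      sub <- generate_country_panel(pc)
      fit_fractional_logit(sub$coverage,
                           sub[c("blood_sample_rate", "anc4_rate")])$beta
    }, numeric(3))
    rowMeans(est) - truth
  })
  # bias shrinks toward zero from the smallest to the largest panel
  expect_true(all(abs(bias[, 3]) <= abs(bias[, 1]) + 0.02))
  expect_true(all(abs(bias[, 3]) < 0.1))
})

test_that("stepwise selection honors signal, noise, and the two-term cap", {
  set.seed(101)
  n <- 200
  cand <- tibble::as_tibble(setNames(
    lapply(COVARIATE_NAMES, function(nm) runif(n)), COVARIATE_NAMES))
  # one overwhelming signal among pure noise
  y_sig <- plogis(-2 + 4 * cand$bp_rate + rnorm(n, 0, 0.2))
  f_sig <- stepwise_select(y_sig, cand)
  expect_equal(f_sig$terms[1], "bp_rate")  # the signal enters first
  expect_lte(length(f_sig$terms), 2L)
  # three strong candidates: the cap binds at exactly two terms
  y3 <- plogis(-3 + 2.5 * cand$blood_sample_rate + 2.5 * cand$urine_sample_rate +
                 2.5 * cand$anc4_rate + rnorm(n, 0, 0.15))
  f3 <- stepwise_select(y3, cand)
  expect_equal(length(f3$terms), 2L)
  f4 <- stepwise_select(y3, cand, max_terms = 3)
  expect_equal(length(f4$terms), 3L)
})

test_that("a pure-noise fixture yields the intercept-only model", {
  # fixed dataset where every single-term robust p-value exceeds 0.1,
  # verified through the reference GLM + sandwich route
  set.seed(7)
  n <- 40
  cand <- tibble::as_tibble(setNames(
    lapply(COVARIATE_NAMES, function(nm) runif(n)), COVARIATE_NAMES))
  y <- plogis(qlogis(0.3) + rnorm(n, 0, 0.4))
  for (nm in COVARIATE_NAMES) {
    g <- stats::glm(y ~ cand[[nm]], family = stats::quasibinomial())
    z <- stats::coef(g)[2] / glm_hc1_se(g)[2]
    expect_gt(2 * stats::pnorm(-abs(z)), 0.1)
  }
  f <- stepwise_select(y, cand)
  expect_equal(f$terms, character(0))
  expect_equal(unname(f$beta[1]), qlogis(mean(y)), tolerance = 1e-10)
})

test_that("published coefficient set matches its stated structure", {
  pm <- published_models()
  expect_setequal(names(pm), INTERVENTIONS)
  slopes <- vapply(pm, function(m) length(m$beta) - 1L, integer(1))
  expect_equal(slopes[["preeclampsia"]], 2L)
  expect_equal(slopes[["syphilis"]], 2L)
  expect_equal(slopes[["diabetes"]], 1L)
  expect_equal(slopes[["hypertensive"]], 1L)
  expect_equal(slopes[["malaria"]], 1L)
  # the hypertensive slope carries the transcription-discrepancy note
  expect_match(pm$hypertensive$note, "urine")
  expect_true("urine_sample_rate" %in% names(pm$hypertensive$beta))
})

test_that("predictions apply the inverse logit to the linear predictor", {
  # zero linear predictor -> 0.5
  f0 <- structure(list(beta = c("(Intercept)" = 0), terms = character()),
                  class = "fraclogit")
  expect_equal(predict_coverage(f0, list()), 0.5)
  pm <- published_models()
  expect_equal(predict_coverage(pm$preeclampsia,
                                list(blood_sample_rate = 0.9, anc4_rate = 0.6)),
               0.3810721, tolerance = 1e-6)
  expect_equal(predict_coverage(pm$diabetes, list(blood_sample_rate = 0)),
               0.0388, tolerance = 1e-3)
  expect_error(predict_coverage(pm$preeclampsia, list(blood_sample_rate = 0.9)),
               "anc4_rate")
  # predictions strictly inside (0,1) and monotone in positive-slope covariates
  p_lo <- predict_coverage(pm$malaria, list(blood_sample_rate = 0.1))
  p_hi <- predict_coverage(pm$malaria, list(blood_sample_rate = 0.9))
  expect_true(p_lo > 0 && p_hi < 1 && p_hi > p_lo)
})

test_that("default proxy rules reproduce the tier table and the flat 5% rule", {
  # syphilis tiers, hand-computed on the percent scale
  expect_equal(default_proxy("syphilis", 30), 0.20 * 0.30)
  expect_equal(default_proxy("syphilis", 60), 0.50 * 0.60)
  expect_equal(default_proxy("syphilis", 80), 0.70 * 0.80)
  expect_equal(default_proxy("syphilis", 96), 0.96)
  # boundary conventions: 40 and 75 open the next tier, 95 the top
  expect_equal(syphilis_tier_multiplier(c(39.999, 40, 74.999, 75, 94.999, 95)),
               c(0.20, 0.50, 0.50, 0.70, 0.70, 1.00))
  # flat 5% of ANC4+ for the case-management interventions
  expect_equal(default_proxy("diabetes", 60), 0.03)
  for (iv in c("diabetes", "hypertensive", "malaria", "preeclampsia")) {
    expect_equal(default_proxy(iv, 80), 0.04)
  }
  expect_error(default_proxy("syphilis", 120), "\\[0, 100\\]")
})

test_that("the proxy never exceeds ANC4+ and is monotone for syphilis", {
  grid <- seq(0, 100, by = 0.5)
  for (iv in INTERVENTIONS) {
    expect_true(all(default_proxy(iv, grid) <= grid / 100 + 1e-15))
  }
  syph <- default_proxy("syphilis", grid)
  expect_true(all(diff(syph) >= -1e-15))
})
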