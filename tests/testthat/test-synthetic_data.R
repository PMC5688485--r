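test_that("household generation is deterministic under the seed", {
  cfg <- tiny_config(seed = 5)
  expect_identical(generate_household_survey(cfg), generate_household_survey(cfg))
  expect_identical(generate_facility_survey(cfg), generate_facility_survey(cfg))
  expect_identical(generate_country_panel(panel_config(seed = 9)),
                   generate_country_panel(panel_config(seed = 9)))
  # different seeds move the data
  expect_false(identical(generate_household_survey(tiny_config(seed = 5)),
                         generate_household_survey(tiny_config(seed = 6))))
})

test_that("degenerate visit laws pin the ANC4+ margin", {
  all4 <- generate_household_survey(tiny_config(seed = 2, p_anc4 = 1))
  expect_true(all(all4$anc_visits >= 4))
  none <- generate_household_survey(tiny_config(seed = 2, p_anc4 = 0))
  expect_true(all(none$anc_visits < 4))
  expect_true(all(is.na(none$source_type)))
})

test_that("generated ANC4+ coverage matches the configured rate at n = 10,000", {
  cfg <- tiny_config(seed = 31, p_anc4 = 0.6,
                     weight_law = list(dist = "constant", value = 1))
  cfg$n_clusters <- 500L; cfg$women_per_cluster <- 20L
  hh <- generate_household_survey(cfg)
  el <- filter_eligible(hh)
  se <- sqrt(0.6 * 0.4 / nrow(el))
  expect_lt(abs(anc4_coverage(el) - 0.6), 3 * se)
})

test_that("record-level invariants hold on generated data", {
  hh <- generate_household_survey(tiny_config(seed = 8))
  expect_true(all(hh$weight > 0))
  expect_true(all(hh$months_since_birth >= 0 & hh$months_since_birth <= 59))
  no_anc <- hh$anc_visits == 0
  expect_true(all(is.na(hh$first_visit_month[no_anc])))
  expect_true(all(!hh$blood_pressure[no_anc] & !hh$blood_sample[no_anc] &
                    !hh$urine_sample[no_anc]))
  anc4 <- hh$anc_visits >= 4
  expect_true(all(!is.na(hh$source_type[anc4])))
  expect_true(all(is.na(hh$source_type[!anc4])))
  # facility-sourced residence agrees with the drawn stratum location
  fac <- anc4 & hh$source_type != "non_facility"
  expect_true(all(hh$residence %in% c("urban", "rural")))
  ff <- generate_facility_survey(tiny_config(seed = 8))
  expect_true(all(ff$weight > 0))
  expect_setequal(unique(stratum_label(ff$facility_type, ff$authority, ff$location)),
                  rownames(tiny_config(seed = 8)$readiness_rates))
})

test_that("degenerate readiness laws propagate to stratum readiness", {
  strata <- "hospital:public:urban"
  mk <- function(rate) {
    rr <- matrix(rate, 1, 5, dimnames = list(strata, INTERVENTIONS))
    sim_config(n_clusters = 2, women_per_cluster = 2, n_facilities = 30,
               strata = strata, careseeking_shares = setNames(1, strata),
               readiness_rates = rr, seed = 3)
  }
  up <- stratum_readiness(generate_facility_survey(mk(1)), default_checklist())
  expect_true(all(as.matrix(up[paste0("ready_", INTERVENTIONS)]) == 1))
  down <- stratum_readiness(generate_facility_survey(mk(0)), default_checklist())
  expect_true(all(as.matrix(down[paste0("ready_", INTERVENTIONS)]) == 0))
})

test_that("observed readiness share matches the configured rate at 1,000 facilities", {
  strata <- "hospital:public:urban"
  rr <- matrix(0.7, 1, 5, dimnames = list(strata, INTERVENTIONS))
  cfg <- sim_config(n_clusters = 2, women_per_cluster = 2, n_facilities = 1000,
                    strata = strata, careseeking_shares = setNames(1, strata),
                    readiness_rates = rr,
                    weight_law = list(dist = "constant", value = 1), seed = 17)
  ff <- generate_facility_survey(cfg)
  rd <- stratum_readiness(ff, cfg$checklist)
  se <- sqrt(0.7 * 0.3 / 1000)
  for (iv in INTERVENTIONS) {
    expect_lt(abs(rd[[paste0("ready_", iv)]] - 0.7), 3 * se)
  }
})

test_that("closed-form true availability coverage follows the stratum product", {
  one <- "hospital:public:urban"
  mk <- function(p_anc4, shares, rates) {
    rr <- matrix(rates, nrow = length(rates), ncol = 5,
                 dimnames = list(setdiff(names(shares), "non_facility"), INTERVENTIONS))
    sim_config(n_clusters = 2, women_per_cluster = 2,
               n_facilities = length(rates) * 2,
               strata = names(shares), careseeking_shares = shares,
               p_anc4 = p_anc4, readiness_rates = rr, seed = 1)
  }
  # single stratum: p_anc4 = 1, share 1, readiness 0.5 -> 0.5
  expect_equal(true_availability_coverage(mk(1, setNames(1, one), 0.5), "malaria"), 0.5)
  # readiness all 1 -> exactly p_anc4
  expect_equal(true_availability_coverage(mk(0.73, setNames(1, one), 1), "syphilis"), 0.73)
  # two strata, hand arithmetic: 0.6 * (0.5*0.2 + 0.5*1.0) = 0.36
  shares <- c("hospital:public:urban" = 0.5, "health_center:public:rural" = 0.5)
  expect_equal(true_availability_coverage(mk(0.6, shares, c(0.2, 1.0)), "diabetes"), 0.36)
  expect_error(true_availability_coverage(tiny_config(), "nonexistent"),
               "unknown intervention")
})

test_that("configuration errors name the offending field", {
  expect_error(tiny_config(careseeking_shares = c("hospital:public:urban" = 0.5,
                                                  "health_center:public:rural" = 0.4)),
               "careseeking_shares")
  expect_error(tiny_config(p_anc4 = 1.2), "p_anc4")
  expect_error(tiny_config(component_probs = c(blood_pressure = -0.1,
                                               urine_sample = 0.7, blood_sample = 0.7,
                                               weight = 0.9, height = 0.6)),
               "component_probs")
  expect_error(tiny_config(n_facilities = 1), "n_facilities")
  expect_error(panel_config(n_countries = 2), "n_countries")
  expect_error(panel_config(noise_sd = -1), "noise_sd")
})

test_that("country panel follows the configured fractional-logit process", {
  pc <- panel_config(n_countries = 10, noise_sd = 0, seed = 4)
  pan <- generate_country_panel(pc)
  for (iv in names(pc$true_beta)) {
    b <- pc$true_beta[[iv]]
    sub <- pan[pan$intervention == iv, ]
    eta <- rep(b[[1]], nrow(sub))
    for (term in names(b)[-1]) eta <- eta + b[[term]] * sub[[term]]
    expect_equal(sub$coverage, plogis(eta), tolerance = 1e-12)
  }
  # intercept-only zero coefficient: all coverages exactly 0.5
  pc0 <- panel_config(n_countries = 5, noise_sd = 0,
                      true_beta = list(malaria = c("(Intercept)" = 0)), seed = 4)
  expect_true(all(generate_country_panel(pc0)$coverage == 0.5))
  expect_true(all(pan$coverage > 0 & pan$coverage < 1))
})

test_that("refitting the panel recovers the generating coefficients", {
  # 200 countries, logit noise 0.2: coefficient estimates should lie
  # within two robust standard errors of truth in at least 90% of
  # (replicate, coordinate) cases. Exact nominal 95% coverage is not
  # expected: logit-scale noise makes the quasi-ML estimand a slightly
  # attenuated version of the generating coefficients.
  truth <- c(-6.44, 4.91, 2.56)
  reps <- 30
  hits <- matrix(NA, reps, 3)
  for (r in seq_len(reps)) {
    pc <- panel_config(n_countries = 200, noise_sd = 0.2, seed = 1000 + r,
                       true_beta = list(preeclampsia = c("(Intercept)" = -6.44,
                                                         blood_sample_rate = 4.91,
                                                         anc4_rate = 2.56)))
    sub <- generate_country_panel(pc)
    f <- fit_fractional_logit(sub$coverage, sub[c("blood_sample_rate", "anc4_rate")])
    hits[r, ] <- abs(f$beta - truth) <= 2 * f$se
  }
  expect_gte(mean(hits), 0.9)
})

test_that("the linked estimate converges to the closed-form truth as n grows", {
  sizes <- list(c(cl = 20, wpc = 20, fac = 60),
                c(cl = 40, wpc = 40, fac = 240),
                c(cl = 80, wpc = 80, fac = 960))
  err <- sapply(seq_along(sizes), function(k) {
    s <- sizes[[k]]
    mean(sapply(1:20, function(r) {
      cfg <- tiny_config(seed = 100 * k + r)
      cfg$n_clusters <- as.integer(s["cl"])
      cfg$women_per_cluster <- as.integer(s["wpc"])
      cfg$n_facilities <- as.integer(s["fac"])
      cs <- stratum_careseeking(filter_eligible(generate_household_survey(cfg)))
      rd <- stratum_readiness(generate_facility_survey(cfg), cfg$checklist)
      est <- link_coverage(cs, rd, "preeclampsia")
      abs(est$value - true_availability_coverage(cfg, "preeclampsia"))
    }))
  })
  expect_true(err[2] < err[1] && err[3] < err[2])
})
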