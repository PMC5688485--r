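# Shared fixtures, built in code. All randomness is seeded.

# internals used by fixtures/tests
INTERVENTIONS <- anclink:::INTERVENTIONS
COVARIATE_NAMES <- anclink:::COVARIATE_NAMES
stratum_label <- anclink:::stratum_label

# A small two-stratum world with no non-facility care source.
tiny_config <- function(seed = 1, ...) {
  strata <- c("hospital:public:urban", "health_center:public:rural")
  rr <- matrix(c(0.8, 0.4,
                 0.7, 0.3,
                 0.9, 0.5,
                 0.8, 0.4,
                 0.6, 0.2),
               nrow = 2, dimnames = list(strata, INTERVENTIONS))
  sim_config(n_clusters = 10, women_per_cluster = 10, n_facilities = 40,
             strata = strata,
             careseeking_shares = c("hospital:public:urban" = 0.4,
                                    "health_center:public:rural" = 0.6),
             readiness_rates = rr, seed = seed, ...)
}

# Hand-specified woman records (equal weights unless stated).
make_women <- function(anc_visits,
                       weight = rep(1, length(anc_visits)),
                       months_since_birth = rep(0L, length(anc_visits)),
                       first_visit_month = ifelse(anc_visits >= 1, 3L, NA_integer_),
                       source_type = rep(NA_character_, length(anc_visits)),
                       source_authority = rep(NA_character_, length(anc_visits)),
                       residence = rep("urban", length(anc_visits)),
                       blood_pressure = anc_visits >= 1,
                       urine_sample = anc_visits >= 1,
                       blood_sample = anc_visits >= 1) {
  n <- length(anc_visits)
  tibble::tibble(
    woman_id = sprintf("w%03d", seq_len(n)),
    cluster_id = "c1",
    months_since_birth = as.integer(months_since_birth),
    anc_visits = as.integer(anc_visits),
    first_visit_month = as.integer(first_visit_month),
    blood_pressure = blood_pressure,
    urine_sample = urine_sample,
    blood_sample = blood_sample,
    weight_measured = anc_visits >= 1,
    height_measured = anc_visits >= 1,
    source_type = source_type,
    source_authority = source_authority,
    residence = residence,
    weight = weight)
}

# Hand-specified facility records against a simple one/two-item checklist.
simple_checklist <- function() {
  list(syphilis = c("syphilis_test", "syphilis_treatment_drug"))
}

make_facilities <- function(n, facility_type = "hospital", authority = "public",
                            location = "urban", weight = rep(1, n),
                            syphilis_test = rep(TRUE, n),
                            syphilis_treatment_drug = rep(TRUE, n)) {
  tibble::tibble(
    facility_id = sprintf("f%03d", seq_len(n)),
    facility_type = facility_type, authority = authority, location = location,
    syphilis_test = syphilis_test,
    syphilis_treatment_drug = syphilis_treatment_drug,
    weight = weight)
}

# A fixed 20-row panel with a known fractional-logit signal, used to
# cross-check the in-package IRLS against stats::glm.
fixture_panel_20 <- function(seed = 42) {
  set.seed(seed)
  n <- 20
  X <- data.frame(blood_sample_rate = rbeta(n, 5, 2.5),
                  anc4_rate = rbeta(n, 5, 3))
  y <- plogis(-6.44 + 4.91 * X$blood_sample_rate + 2.56 * X$anc4_rate +
                rnorm(n, 0, 0.15))
  list(y = y, X = X)
}

# HC1 sandwich standard errors computed from a stats::glm quasibinomial
# fit — the independent route for robust-inference checks.
glm_hc1_se <- function(fit) {
  X <- model.matrix(fit)
  mu <- fitted(fit)
  y <- fit$y
  v <- mu * (1 - mu)
  A <- crossprod(X * sqrt(v))
  u <- X * (y - mu)
  B <- crossprod(u)
  n <- nrow(X); p <- ncol(X)
  V <- solve(A) %*% B %*% solve(A) * n / (n - p)
  sqrt(diag(V))
}
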