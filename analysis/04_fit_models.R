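#!/usr/bin/env Rscript
# Stage 4 driver: fractional-logit predictive models of linked coverage
# on country-level ANC covariates, selected stepwise (entry/exit at
# p = 0.1, at most two covariates). Predictions from the fitted models
# and from the published coefficient set are both written out.
suppressMessages(library(anclink))
suppressMessages(library(dplyr))
suppressMessages(library(readr))

interventions <- c("syphilis", "diabetes", "hypertensive", "malaria",
                   "preeclampsia")
covariate_names <- c("blood_sample_rate", "urine_sample_rate", "bp_rate",
                     "early_anc_rate", "anc4_rate")
panel <- read_csv("results/coverage_panel.csv", show_col_types = FALSE)

models <- lapply(interventions, function(iv) {
  sub <- filter(panel, intervention == iv)
  fit <- stepwise_select(sub$value, sub[covariate_names])
  fit$intervention <- iv
  fit
})
names(models) <- interventions

jsonlite::write_json(
  lapply(models, function(m) list(intervention = m$intervention,
                                  terms = m$terms, beta = as.list(m$beta),
                                  se = as.list(m$se),
                                  p_values = as.list(m$p_values),
                                  n_obs = m$n_obs, converged = m$converged)),
  "results/models.json", auto_unbox = TRUE, pretty = TRUE, digits = NA)

published <- published_models()
predictions <- bind_rows(lapply(interventions, function(iv) {
  sub <- filter(panel, intervention == iv)
  bind_rows(
    tibble::tibble(country = sub$country, intervention = iv, method = "fitted",
                   value = vapply(seq_len(nrow(sub)), function(j)
                     predict_coverage(models[[iv]], sub[j, covariate_names]),
                     numeric(1))),
    tibble::tibble(country = sub$country, intervention = iv, method = "published",
                   value = vapply(seq_len(nrow(sub)), function(j)
                     predict_coverage(published[[iv]], sub[j, covariate_names]),
                     numeric(1))))
}))
write_csv(predictions, "results/predictions.csv")

for (iv in interventions) {
  m <- models[[iv]]
  cat(sprintf("%-13s terms: %-40s converged: %s\n", iv,
              if (length(m$terms)) paste(sprintf("%s (p=%.3g)", m$terms,
                                                 m$p_values[m$terms]),
                                         collapse = ", ")
              else "(intercept only)",
              m$converged))
}
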