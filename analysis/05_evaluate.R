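#!/usr/bin/env Rscript
# Stage 5 driver: model fit metrics (R-squared, Pearson correlation,
# RMSE) of the predictions against the linked estimates; comparison of
# linked estimates with the current default proxy rules; and the
# worked relative-impact ratios for a mortality-model scale-up run.
suppressMessages(library(anclink))
suppressMessages(library(dplyr))
suppressMessages(library(readr))

interventions <- c("syphilis", "diabetes", "hypertensive", "malaria",
                   "preeclampsia")
panel <- read_csv("results/coverage_panel.csv", show_col_types = FALSE)
predictions <- read_csv("results/predictions.csv", show_col_types = FALSE)

metrics <- lapply(interventions, function(iv) {
  obs <- filter(panel, intervention == iv)
  prd <- filter(predictions, intervention == iv, method == "fitted")
  m <- compute_metrics(obs$value, prd$value[match(obs$country, prd$country)])
  list(r_squared = m$r_squared, pearson_rho = m$pearson_rho, rmse = m$rmse,
       n = m$n, correlation_class = classify_correlation(m$pearson_rho))
})
names(metrics) <- interventions
jsonlite::write_json(metrics, "results/metrics.json", auto_unbox = TRUE,
                     pretty = TRUE, digits = NA)

proxies <- panel |>
  rowwise() |>
  mutate(value = default_proxy(intervention, 100 * anc4_rate)) |>
  ungroup() |>
  select(country, intervention, value)
comparison <- compare_to_proxy(panel[c("country", "intervention", "value")],
                               proxies)
write_csv(comparison, "results/proxy_comparison.csv")

# worked relative-impact arithmetic for a pre-eclampsia scale-up run:
# impact under updated baselines as a share of impact under proxies
impact <- tibble::tribble(
  ~setting, ~outcome, ~updated, ~current,
  "Ghana", "maternal_lives_saved", 84, 177,
  "Ghana", "stillbirths_prevented", 532, 885,
  "Burkina Faso", "maternal_lives_saved", 263, 273,
  "Burkina Faso", "stillbirths_prevented", 425, 435)
impact$ratio_percent <- vapply(seq_len(nrow(impact)), function(i)
  impact_ratio(impact$updated[i], impact$current[i])$percent_rounded, numeric(1))
impact$relative_difference_percent <- round_half_up(
  100 * (1 - impact$updated / impact$current), 1)
write_csv(impact, "results/impact_ratios.csv")

for (iv in interventions) {
  m <- metrics[[iv]]
  cat(sprintf("%-13s R2 = %5.2f  rho = %.2f (%s)  RMSE = %.3f\n", iv,
              m$r_squared, m$pearson_rho, m$correlation_class, m$rmse))
}
rng <- attr(comparison, "range")
cat(sprintf("proxy minus linked differences span %.1f to %.1f percentage points\n",
            rng[1], rng[2]))
cat(sprintf("Ghana maternal impact under updated baselines: %d%% of the proxy-based run\n",
            as.integer(impact$ratio_percent[1])))
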