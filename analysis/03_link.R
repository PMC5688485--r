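#!/usr/bin/env Rscript
# Stage 3 driver: the linking estimator. For each country and
# intervention, availability coverage = sum over strata of the
# care-seeking share times the readiness proportion. Compared against
# the generator's closed-form ground truth.
suppressMessages(library(anclink))
suppressMessages(library(dplyr))
suppressMessages(library(readr))

interventions <- c("syphilis", "diabetes", "hypertensive", "malaria",
                   "preeclampsia")
rd_all <- read_csv("results/stratum_readiness.csv", show_col_types = FALSE)
cs_all <- read_csv("results/stratum_careseeking.csv", show_col_types = FALSE)
cov <- read_csv("results/covariates.csv", show_col_types = FALSE)

panel <- bind_rows(lapply(unique(cs_all$country), function(cc) {
  cs <- filter(cs_all, country == cc)
  rd <- filter(rd_all, country == cc)
  bind_rows(lapply(interventions, function(iv) {
    est <- link_coverage(cs, rd, iv)
    tibble::tibble(country = cc, intervention = iv, value = est$value,
                   n_strata_used = est$n_strata_used,
                   unmatched_share = est$unmatched_careseeking_share)
  }))
})) |>
  left_join(cov, by = "country")
write_csv(panel, "results/coverage_panel.csv")

truth <- read_csv("results/true_coverage.csv", show_col_types = FALSE)
chk <- inner_join(panel, truth, by = c("country", "intervention"))
cat(sprintf("linked %d country-intervention estimates\n", nrow(panel)))
cat(sprintf("mean |linked - truth| = %.4f (max %.4f)\n",
            mean(abs(chk$value - chk$true_coverage)),
            max(abs(chk$value - chk$true_coverage))))
cat(sprintf("care-seeking share left unmatched: max %.4f\n",
            max(panel$unmatched_share)))
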