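#!/usr/bin/env Rscript
# Stage 1 driver: simulate a 20-country world of household surveys and
# facility assessments with known ground-truth availability coverage.
# Microdata go to scratch/ (large, regenerable); the ground truth and the
# resolved configuration go to results/.
suppressMessages(library(anclink))
suppressMessages(library(readr))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 2017L

dir.create("results", showWarnings = FALSE)
dir.create("scratch/sim", recursive = TRUE, showWarnings = FALSE)

base <- sim_config(n_clusters = 100, women_per_cluster = 20,
                   n_facilities = 200, seed = seed)
countries <- simulate_countries(base, n_countries = 20, seed = seed)

truth <- do.call(rbind, lapply(names(countries), function(cc) {
  data.frame(country = cc,
             intervention = c("syphilis", "diabetes", "hypertensive",
                              "malaria", "preeclampsia"))
}))
truth$true_coverage <- mapply(function(cc, iv) {
  true_availability_coverage(countries[[cc]], iv)
}, truth$country, truth$intervention)
write_csv(truth, "results/true_coverage.csv")

for (cc in names(countries)) {
  write_csv(generate_household_survey(countries[[cc]]),
            file.path("scratch/sim", paste0(cc, "_household.csv")))
  write_csv(generate_facility_survey(countries[[cc]]),
            file.path("scratch/sim", paste0(cc, "_facility.csv")))
}
yaml::write_yaml(list(seed = seed, n_countries = 20,
                      women_per_country = 2000, facilities_per_country = 200),
                 "results/sim_config.yaml")

cat(sprintf("simulated %d countries (seed %d): %d women and %d facilities each\n",
            length(countries), seed, 2000, 200))
cat(sprintf("true availability coverage ranges %.3f-%.3f across country-interventions\n",
            min(truth$true_coverage), max(truth$true_coverage)))
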