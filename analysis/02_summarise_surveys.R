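#!/usr/bin/env Rscript
# Stage 2 driver: per country, score facility readiness by stratum
# (facility type x authority x location) and summarise household
# care-seeking: ANC4+ coverage, its distribution across care-source
# strata, and the country-level ANC covariate rates.
suppressMessages(library(anclink))
suppressMessages(library(dplyr))
suppressMessages(library(readr))

countries <- sub("_household.csv", "",
                 basename(list.files("scratch/sim", "_household\\.csv$")))
stopifnot(length(countries) > 0)
checklist <- default_checklist()

readiness <- careseeking <- covariates <- list()
for (cc in countries) {
  hh <- read_csv(file.path("scratch/sim", paste0(cc, "_household.csv")),
                 show_col_types = FALSE)
  ff <- read_csv(file.path("scratch/sim", paste0(cc, "_facility.csv")),
                 show_col_types = FALSE)
  eligible <- filter_eligible(hh)
  readiness[[cc]] <- stratum_readiness(ff, checklist)
  cst <- stratum_careseeking(eligible)
  careseeking[[cc]] <- mutate(cst, anc4 = attr(cst, "anc4"),
                              non_facility_share = attr(cst, "non_facility_share"))
  covariates[[cc]] <- covariate_rates(eligible)
}

write_csv(bind_rows(readiness, .id = "country"), "results/stratum_readiness.csv")
write_csv(bind_rows(careseeking, .id = "country"), "results/stratum_careseeking.csv")
cov <- bind_rows(covariates, .id = "country")
write_csv(cov, "results/covariates.csv")

cat(sprintf("summarised %d countries\n", length(countries)))
cat(sprintf("ANC4+ coverage across countries: %.2f-%.2f (median %.2f)\n",
            min(cov$anc4_rate), max(cov$anc4_rate), median(cov$anc4_rate)))
cat(sprintf("early ANC enrolment rates: %.2f-%.2f\n",
            min(cov$early_anc_rate), max(cov$early_anc_rate)))
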