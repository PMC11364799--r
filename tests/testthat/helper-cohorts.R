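# Shared generator configurations for tests. The step-hazard configuration
# mirrors the canonical three-group staging truth used throughout: change
# points at 8 and 12 mm with reference-coded hazard ratios (1, 3.5, 4.5),
# under roughly 40% censoring.

step_config <- function(n = 600, seed = 1,
                        log_hrs = log(c(1, 3.5, 4.5)),
                        cutoffs = c(8, 12), ...) {
  synthetic_config(n_subjects = n, seed = seed,
                   censor_dist = c(min = 60, max = 180),
                   step_hazard = list(cutoffs = cutoffs, log_hrs = log_hrs),
                   ...)
}

# All true covariates, for oracle-adjusted searches.
all_covariates <- c("age", "sex_female", "smoking", "alcohol", "betel",
                    "pN_stage", "margin_positive", "extranodal_extension")

# A small complete cohort (no missingness) for fast structural tests.
complete_config <- function(n = 120, seed = 1, ...) {
  ms <- lapply(stagecraft::synthetic_config()$missingness, function(m) {
    m$prob <- 0
    m
  })
  synthetic_config(n_subjects = n, seed = seed, missingness = ms, ...)
}
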