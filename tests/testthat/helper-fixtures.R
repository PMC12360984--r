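# Shared fixtures: scaled study rosters and small synthetic stacks, all
# generated in code at test time.

# default roster rescaled to a total sample size
scaled_configs <- function(n_total, roster = "absence_6m") {
  cfgs <- default_study_configs(roster)
  f <- n_total / sum(vapply(cfgs, `[[`, 0L, "n"))
  lapply(cfgs, function(cf) {
    cf$n <- max(10L, as.integer(round(cf$n * f)))
    cf
  })
}

# k identical small studies (handy for degenerate / homogeneous cases)
equal_configs <- function(k, n_each, ...) {
  lapply(seq_len(k), function(i)
    study_config(paste0("S", i), n_each, ...))
}

# reference profile: categorical predictors at reference, continuous at zero
reference_profile <- function() {
  list(age = 0, sex = "male", multisite_pain = "single", pain_score = 0,
       pain_duration = "<3 months", job_type = "professional/managerial",
       anxiety_depression = 0L, comorbidity = 0L, prior_absence_6m = 0L,
       baseline_presenteeism = 0)
}

# the worked example profile used for scorer arithmetic
worked_profile <- function() {
  list(age = 50, sex = "female", multisite_pain = "single", pain_score = 6,
       pain_duration = ">12 months", job_type = "manual",
       anxiety_depression = 0L, comorbidity = 0L, prior_absence_6m = 1L,
       baseline_presenteeism = 5)
}

# brute-force concordance oracle: enumerate all event/non-event pairs
brute_force_c <- function(y, p) {
  cases <- p[y == 1]; controls <- p[y == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}
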