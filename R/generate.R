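# Synthetic multi-study IPD generator.
#
# Emulates the statistical structure of the six primary-care MSD cohorts:
# study-specific predictor marginals, outcomes drawn from a multilevel
# (random-intercept) logistic or linear model, and both sporadic and
# study-level systematically missing predictors.

# evaluate `code` under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a child seed (< 2^31) deterministically
child_seeds <- function(seed, n) with_seed(seed, sample.int(2147483646L, n))

#' Configuration of one synthetic study
#'
#' Bundles the participant count, predictor marginal parameters, recorded
#' outcome set and an optional Gaussian-copula correlation matrix for one
#' study.  Continuous scores (pain, presenteeism) are drawn as rounded,
#' 0-10-clipped Gaussians; age is Gaussian truncated to the working-age range
#' 16-75.
#'
#' @param study_id Study label.
#' @param n Number of participants (\eqn{\ge 1}).
#' @param age_mean,age_sd Age distribution (years).
#' @param prop_female,prop_multisite,prop_anxiety,prop_comorbidity,prop_prior_absence
#'   Proportions in `[0, 1]`.
#' @param pain_mean,pain_sd,presenteeism_mean,presenteeism_sd Latent Gaussian
#'   parameters of the two 0-10 scores before rounding/clipping.
#' @param duration_probs Probabilities of the four pain-duration categories
#'   (must sum to 1).
#' @param job_probs Probabilities of the three job-type classes (sum to 1).
#' @param outcome_set Outcomes this study records.
#' @param copula Optional 10x10 correlation matrix (dictionary predictor
#'   order) inducing rank correlation between predictors; default identity
#'   (independent sampling).
#' @return An object of class `study_config`.
#' @export
study_config <- function(study_id, n,
                         age_mean = 50.6, age_sd = 11.7,
                         prop_female = 0.56, prop_multisite = 0.32,
                         pain_mean = 6, pain_sd = 2.97,
                         duration_probs = c(0.26, 0.13, 0.12, 0.49),
                         job_probs = c(0.64, 0.11, 0.25),
                         prop_anxiety = 0.22, prop_comorbidity = 0.50,
                         prop_prior_absence = 0.30,
                         presenteeism_mean = 5, presenteeism_sd = 3.71,
                         outcome_set = "absence_6m", copula = NULL) {
  stopifnot(n >= 1, age_sd > 0, pain_sd > 0, presenteeism_sd > 0)
  props <- c(prop_female, prop_multisite, prop_anxiety, prop_comorbidity,
             prop_prior_absence)
  if (any(props < 0 | props > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  for (pr in list(duration_probs, job_probs)) {
    if (any(pr < 0) || abs(sum(pr) - 1) > 1e-6)
      stop("categorical proportions must be non-negative and sum to 1",
           call. = FALSE)
  }
  if (!is.null(copula)) {
    stopifnot(is.matrix(copula), nrow(copula) == 10, ncol(copula) == 10)
    if (any(abs(copula - t(copula)) > 1e-8) || any(abs(diag(copula) - 1) > 1e-8))
      stop("copula must be a correlation matrix", call. = FALSE)
  }
  structure(list(study_id = study_id, n = as.integer(n),
                 age_mean = age_mean, age_sd = age_sd,
                 prop_female = prop_female, prop_multisite = prop_multisite,
                 pain_mean = pain_mean, pain_sd = pain_sd,
                 duration_probs = duration_probs / sum(duration_probs),
                 job_probs = job_probs / sum(job_probs),
                 prop_anxiety = prop_anxiety,
                 prop_comorbidity = prop_comorbidity,
                 prop_prior_absence = prop_prior_absence,
                 presenteeism_mean = presenteeism_mean,
                 presenteeism_sd = presenteeism_sd,
                 outcome_set = outcome_set, copula = copula),
            class = "study_config")
}

#' Default study rosters mirroring the development populations
#'
#' Returns study configurations whose sizes and predictor marginals mirror
#' the published study-population summaries: five studies for the 6-month
#' absence models (total n = 2179), three for 6-month presenteeism
#' (n = 1218) and two for 12-month absence (n = 408).  Where a study did not
#' record a predictor, the pooled modelling-population value is used; the
#' "any comorbidity" prevalence is derived from the reported component
#' conditions (diabetes, respiratory, heart, other) assuming independence.
#'
#' @param roster Which modelling population to mirror.
#' @return A list of [study_config()] objects.
#' @export
default_study_configs <- function(roster = c("absence_6m", "presenteeism_6m",
                                             "absence_12m")) {
  roster <- match.arg(roster)
  iqr_sd <- function(lq, uq) (uq - lq) / 1.349
  cfg <- list(
    BEEP = study_config("BEEP", 214, age_mean = 56.4, age_sd = 7.1,
      prop_female = 0.49, prop_multisite = 0.93,
      pain_mean = 4, pain_sd = iqr_sd(3, 5.5),
      duration_probs = c(0.10, 0.08, 0.13, 0.69),  # only ">1 year" (69%) reported
      job_probs = c(0.71, 0.10, 0.19), prop_anxiety = 0.22,
      prop_comorbidity = 0.53, prop_prior_absence = 0.30,
      presenteeism_mean = 5, presenteeism_sd = iqr_sd(2, 7)),
    KAPS = study_config("KAPS", 747, age_mean = 49.6, age_sd = 11.3,
      prop_female = 0.58, prop_multisite = 0.45,
      pain_mean = 5, pain_sd = iqr_sd(3, 7),
      duration_probs = c(0.23, 0.14, 0.14, 0.49),
      job_probs = c(0.65, 0.12, 0.23), prop_anxiety = 0.16,
      prop_comorbidity = 0.48, prop_prior_absence = 0.40,
      presenteeism_mean = 5, presenteeism_sd = iqr_sd(2, 7)),
    STEMS = study_config("STEMS", 432, age_mean = 49.6, age_sd = 11.6,
      prop_female = 0.53, prop_multisite = 0.34,
      pain_mean = 7, pain_sd = iqr_sd(7, 9),
      duration_probs = c(0.42, 0.12, 0.11, 0.21) / 0.86,
      job_probs = c(0.61, 0.13, 0.27) / 1.01, prop_anxiety = 0.29,
      prop_comorbidity = 0.65, prop_prior_absence = 0.30,
      presenteeism_mean = 5, presenteeism_sd = iqr_sd(2, 7),
      outcome_set = c("absence_6m", "presenteeism_6m", "absence_12m")),
    SWAP = study_config("SWAP", 338, age_mean = 48.7, age_sd = 10.3,
      prop_female = 0.58, prop_multisite = 0.65,
      pain_mean = 7, pain_sd = iqr_sd(6, 8),
      duration_probs = c(0.33, 0.12, 0.14, 0.39) / 0.98,
      job_probs = c(0.56, 0.15, 0.28) / 0.99, prop_anxiety = 0.31,
      prop_comorbidity = 0.50, prop_prior_absence = 0.30,
      presenteeism_mean = 6, presenteeism_sd = iqr_sd(5, 9),
      outcome_set = "absence_12m"),
    STarT_MSK_pilot = study_config("STarT MSK-pilot", 232,
      age_mean = 51.2, age_sd = 12.4,
      prop_female = 0.60, prop_multisite = 0.08,
      pain_mean = 6, pain_sd = iqr_sd(5, 8),
      duration_probs = c(0.28, 0.13, 0.14, 0.45),
      job_probs = c(0.69, 0.09, 0.22), prop_anxiety = 0.19,
      prop_comorbidity = 0.48, prop_prior_absence = 0.28,
      presenteeism_mean = 5, presenteeism_sd = iqr_sd(2, 7),
      outcome_set = c("absence_6m", "presenteeism_6m")),
    STarT_MSK_MT = study_config("STarT MSK-MT", 554,
      age_mean = 50.2, age_sd = 12.7,
      prop_female = 0.57, prop_multisite = 0.08,
      pain_mean = 7, pain_sd = iqr_sd(5, 8),
      duration_probs = c(0.24, 0.18, 0.14, 0.44),
      job_probs = c(0.64, 0.11, 0.25) / 1.00, prop_anxiety = 0.25,
      prop_comorbidity = 0.44, prop_prior_absence = 0.32,
      presenteeism_mean = 5, presenteeism_sd = iqr_sd(2, 7),
      outcome_set = c("absence_6m", "presenteeism_6m"))
  )
  switch(roster,
    absence_6m = cfg[c("BEEP", "KAPS", "STEMS", "STarT_MSK_pilot",
                       "STarT_MSK_MT")],
    presenteeism_6m = cfg[c("STEMS", "STarT_MSK_pilot", "STarT_MSK_MT")],
    absence_12m = {
      # 12-month roster restricted to participants still employed at 12 months
      out <- cfg[c("STEMS", "SWAP")]
      out$STEMS$n <- 70L
      out
    })
}

# draw n profiles from a config's marginals (optionally rank-correlated
# through a Gaussian copula)
draw_profiles <- function(config, n) {
  if (is.null(config$copula)) {
    U <- matrix(stats::runif(n * 10), n, 10)
  } else {
    L <- chol(config$copula)
    Z <- matrix(stats::rnorm(n * 10), n, 10) %*% L
    U <- stats::pnorm(Z)
  }
  colnames(U) <- names(msd_dictionary()$predictors)
  q_trunc_norm <- function(u, mean, sd, lo, hi) {
    plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
    stats::qnorm(plo + u * (phi - plo), mean, sd)
  }
  score <- function(u, mean, sd)
    pmin(10, pmax(0, round(stats::qnorm(u, mean, sd))))
  cat_from_u <- function(u, probs, levels, ordered = FALSE) {
    idx <- findInterval(u, cumsum(probs), left.open = TRUE) + 1L
    factor(levels[idx], levels = levels, ordered = ordered)
  }
  dict <- msd_dictionary()$predictors
  data.frame(
    age = q_trunc_norm(U[, "age"], config$age_mean, config$age_sd, 16, 75),
    sex = cat_from_u(U[, "sex"], c(1 - config$prop_female, config$prop_female),
                     dict$sex$levels),
    multisite_pain = cat_from_u(U[, "multisite_pain"],
                                c(1 - config$prop_multisite, config$prop_multisite),
                                dict$multisite_pain$levels),
    pain_score = score(U[, "pain_score"], config$pain_mean, config$pain_sd),
    pain_duration = cat_from_u(U[, "pain_duration"], config$duration_probs,
                               dict$pain_duration$levels, ordered = TRUE),
    job_type = cat_from_u(U[, "job_type"], config$job_probs,
                          dict$job_type$levels),
    anxiety_depression = as.integer(U[, "anxiety_depression"] < config$prop_anxiety),
    comorbidity = as.integer(U[, "comorbidity"] < config$prop_comorbidity),
    prior_absence_6m = as.integer(U[, "prior_absence_6m"] < config$prop_prior_absence),
    baseline_presenteeism = score(U[, "baseline_presenteeism"],
                                  config$presenteeism_mean,
                                  config$presenteeism_sd)
  )
}

#' Generate one synthetic study
#'
#' Draws `config$n` participants from the study's predictor marginals, then
#' draws the outcome from the true model's linear predictor plus the average
#' intercept and the supplied study intercept deviation (logistic family:
#' Bernoulli on the inverse-logit; linear family: Gaussian with the model's
#' residual SD, clipped to the 0-10 instrument range with the clipping
#' fraction recorded as attribute `clip_fraction`).  Missingness is not
#' applied at this stage; see [apply_missingness()].
#'
#' @param config A [study_config()].
#' @param truth A [true_model()].
#' @param study_intercept_deviation Deviation of this study's intercept from
#'   the average intercept.
#' @param seed Integer seed; output is reproducible for a fixed seed.
#' @return An [ipd_stack()] containing exactly `config$n` rows of one study.
#' @export
generate_study <- function(config, truth, study_intercept_deviation = 0,
                           seed = 1L) {
  stopifnot(inherits(config, "study_config"), inherits(truth, "true_model"))
  with_seed(seed, {
    df <- draw_profiles(config, config$n)
    df <- cbind(study_id = config$study_id, df)
    X <- encode_predictors(df, names(truth$coefficients))
    lp <- truth$intercept + study_intercept_deviation +
      drop(X %*% truth$coefficients)
    clip_frac <- 0
    if (truth$outcome %in% config$outcome_set) {
      if (truth$family == "logistic") {
        df[[truth$outcome]] <- stats::rbinom(config$n, 1L, stats::plogis(lp))
      } else {
        y <- stats::rnorm(config$n, lp, truth$residual_sd)
        clip_frac <- mean(y < 0 | y > 10)
        df[[truth$outcome]] <- pmin(10, pmax(0, y))
      }
    } else {
      df[[truth$outcome]] <- rep(NA, config$n)
    }
    out <- ipd_stack(df)
    attr(out, "clip_fraction") <- clip_frac
    out
  })
}

#' Generate a multi-study IPD stack
#'
#' Study intercept deviations are drawn independently from a zero-mean
#' Gaussian with SD equal to the true model's between-study
#' `random_intercept_sd`; each study is then generated with a derived
#' sub-seed, so output is byte-identical for a fixed seed.
#'
#' @param configs List of [study_config()] objects (\eqn{\ge 2} for the
#'   between-study SD to be identifiable downstream).
#' @param truth A [true_model()].
#' @param seed Integer seed.
#' @return An [ipd_stack()] with one block of rows per study; study intercept
#'   deviations are recorded in attribute `study_deviations`.
#' @export
generate_multistudy <- function(configs, truth, seed = 1L) {
  stopifnot(length(configs) >= 1)
  if (length(configs) == 1 && truth$random_intercept_sd > 0)
    warning("single study with random_intercept_sd > 0: ",
            "the between-study SD is not identifiable downstream")
  ids <- vapply(configs, `[[`, "", "study_id")
  if (anyDuplicated(ids)) stop("study_ids must be distinct")
  k <- length(configs)
  devs <- with_seed(seed, stats::rnorm(k, 0, truth$random_intercept_sd))
  seeds <- child_seeds(seed + 1L, k)
  parts <- mapply(function(cf, dv, sd) generate_study(cf, truth, dv, sd),
                  configs, devs, seeds, SIMPLIFY = FALSE)
  out <- as_ipd_stack(do.call(rbind, lapply(parts, as.data.frame)), parts[[1]])
  out$study_id <- factor(out$study_id, levels = ids)
  attr(out, "study_deviations") <- stats::setNames(devs, ids)
  out
}

#' Specification of predictor missingness
#'
#' @param sporadic Named vector of per-predictor sporadic missingness
#'   probabilities in `[0, 1)`.  A rate of 1 is rejected: a fully missing
#'   column must be declared systematic.
#' @param mechanism `"MCAR"`, or `mar_mechanism()` for missingness at random
#'   driven by an observed predictor.
#' @param systematic Data frame with columns `study_id` and `predictor`
#'   listing (study, predictor) pairs that are fully missing.
#' @return An object of class `missingness_spec`.
#' @export
missingness_spec <- function(sporadic = numeric(0), mechanism = "MCAR",
                             systematic = NULL) {
  if (length(sporadic)) {
    stopifnot(!is.null(names(sporadic)))
    if (any(sporadic < 0 | sporadic >= 1))
      stop("sporadic rates must lie in [0, 1); declare fully missing ",
           "predictors as systematic", call. = FALSE)
  }
  if (!identical(mechanism, "MCAR") && !inherits(mechanism, "mar_mechanism"))
    stop("mechanism must be \"MCAR\" or mar_mechanism()", call. = FALSE)
  if (!is.null(systematic))
    stopifnot(is.data.frame(systematic),
              all(c("study_id", "predictor") %in% names(systematic)))
  structure(list(sporadic = sporadic, mechanism = mechanism,
                 systematic = systematic), class = "missingness_spec")
}

#' @rdname missingness_spec
#' @param driver Predictor whose value drives missingness of the others.
#' @param slope Log-odds increase in missingness per unit of the driver.
#' @export
mar_mechanism <- function(driver, slope) {
  structure(list(type = "MAR", driver = driver, slope = slope),
            class = "mar_mechanism")
}

#' Mask predictor cells according to a missingness specification
#'
#' Sporadic cells are masked independently per predictor: under MCAR with the
#' configured probability; under MAR with probability
#' `plogis(a + slope * driver)` where the intercept `a` is calibrated so the
#' marginal rate matches the configured rate.  Systematic (study, predictor)
#' pairs have the predictor masked for every participant of that study.  The
#' input stack is not mutated.
#'
#' @param stack An [ipd_stack()].
#' @param spec A [missingness_spec()].
#' @param seed Integer seed.
#' @return A new [ipd_stack()] with `NA` in the masked cells.
#' @export
apply_missingness <- function(stack, spec, seed = 1L) {
  stopifnot(inherits(stack, "ipd_stack"), inherits(spec, "missingness_spec"))
  preds <- names(msd_dictionary()$predictors)
  bad <- setdiff(names(spec$sporadic), preds)
  if (length(bad))
    stop("unknown predictor(s) in sporadic spec: ", paste(bad, collapse = ", "))
  mar <- inherits(spec$mechanism, "mar_mechanism")
  if (mar) {
    if (!spec$mechanism$driver %in% preds)
      stop("MAR driver must be a predictor")
    if (isTRUE(spec$sporadic[spec$mechanism$driver] > 0))
      stop("the MAR driver itself cannot be sporadically missing")
  }
  if (!is.null(spec$systematic)) {
    if (!all(spec$systematic$study_id %in% study_ids(stack)))
      stop("systematic spec references unknown study")
    if (!all(spec$systematic$predictor %in% preds))
      stop("systematic spec references unknown predictor")
  }
  out <- as.data.frame(stack)
  with_seed(seed, {
    for (p in names(spec$sporadic)) {
      rate <- spec$sporadic[[p]]
      if (rate <= 0) next
      n <- nrow(out)
      if (mar) {
        x <- as.numeric(encode_predictors(
          out, intersect(model_terms("absence_6m"),
                         switch(spec$mechanism$driver,
                                sex = "female",
                                multisite_pain = "multisite_pain",
                                spec$mechanism$driver))))
        slope <- spec$mechanism$slope
        a <- stats::uniroot(function(a) mean(stats::plogis(a + slope * x)) - rate,
                            c(-40, 40))$root
        pr <- stats::plogis(a + slope * x)
      } else {
        pr <- rep(rate, n)
      }
      mask <- stats::runif(n) < pr
      out[[p]][mask] <- NA
    }
    NULL
  })
  if (!is.null(spec$systematic)) {
    for (i in seq_len(nrow(spec$systematic))) {
      s <- spec$systematic$study_id[i]; p <- spec$systematic$predictor[i]
      out[[p]][out$study_id == s] <- NA
    }
  }
  as_ipd_stack(out, stack)
}
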