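truth6 <- published_truth("absence_6m")

test_that("generate_study honours the count contract and is deterministic", {
  cfg <- study_config("A", 500)
  d1 <- generate_study(cfg, truth6, 0, seed = 1)
  d2 <- generate_study(cfg, truth6, 0, seed = 1)
  expect_equal(nrow(d1), 500)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- generate_study(cfg, truth6, 0, seed = 2)
  expect_false(identical(d1$absence_6m, d3$absence_6m))
})

test_that("null-coefficient truth reproduces the inverse-logit of the constant", {
  null_truth <- true_model("logistic",
                           coefficients = setNames(rep(0, 13),
                                                   model_terms("absence_6m")),
                           intercept = -3.493, random_intercept_sd = 0)
  n <- 60000
  d <- generate_study(study_config("A", n), null_truth, 0, seed = 8)
  p0 <- 1 / (1 + exp(3.493))          # 0.0295
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(mean(d$absence_6m) - p0), 3 * se)
})

test_that("empirical marginals converge to the configured marginals", {
  n <- 50000
  cfg <- study_config("A", n)          # pooled 6-month marginals
  d <- generate_study(cfg, truth6, 0, seed = 9)
  bin_se <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(d$sex == "female") - 0.56), 3 * bin_se(0.56))
  expect_lt(abs(mean(d$multisite_pain == "multisite") - 0.32), 3 * bin_se(0.32))
  expect_lt(abs(mean(d$prior_absence_6m) - 0.30), 3 * bin_se(0.30))
  expect_lt(abs(mean(d$pain_duration == ">12 months") - 0.49), 3 * bin_se(0.49))
  expect_lt(abs(mean(d$job_type == "manual") - 0.25), 3 * bin_se(0.25))
  # age: compare against the truncated-normal mean (truncation to [16, 75]
  # shifts the mean below the latent 50.6)
  a <- (16 - 50.6) / 11.7; b <- (75 - 50.6) / 11.7
  mu_trunc <- 50.6 + 11.7 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  expect_lt(abs(mean(d$age) - mu_trunc), 3 * 11.7 / sqrt(n))
  expect_true(all(d$pain_score >= 0 & d$pain_score <= 10))
  expect_true(all(d$age >= 16 & d$age <= 75))
})

test_that("multistudy generation draws study intercepts with the configured SD", {
  cfgs <- scaled_configs(1000)
  stk <- generate_multistudy(cfgs, truth6, seed = 3)
  expect_equal(length(unique(stk$study_id)), 5)
  expect_identical(as.data.frame(stk),
                   as.data.frame(generate_multistudy(cfgs, truth6, seed = 3)))

  # degenerate: zero between-study SD gives exactly zero deviations
  t0 <- truth6; t0$random_intercept_sd <- 0
  stk0 <- generate_multistudy(cfgs, t0, seed = 3)
  expect_equal(unname(attr(stk0, "study_deviations")), rep(0, 5))

  expect_warning(generate_multistudy(cfgs[1], truth6, seed = 1),
                 "not identifiable")
})

test_that("between-study spread of empirical logit event rates matches a direct
           Monte-Carlo oracle", {
  cfgs <- equal_configs(5, 800)
  reps <- 30
  # package path
  sd_pkg <- vapply(seq_len(reps), function(r) {
    stk <- generate_multistudy(cfgs, truth6, seed = 100 + r)
    rates <- tapply(stk$absence_6m, stk$study_id, mean)
    stats::sd(qlogis(pmin(pmax(rates, 1e-4), 1 - 1e-4)))
  }, 0)
  # independent oracle: same model simulated directly from its definition
  set.seed(999)
  sd_ora <- vapply(seq_len(reps), function(r) {
    rates <- vapply(seq_len(5), function(j) {
      u <- rnorm(1, 0, truth6$random_intercept_sd)
      d <- generate_study(study_config("X", 800), true_model(
        "logistic", truth6$coefficients, truth6$intercept, 0), u,
        seed = 5000 + 10 * r + j)
      mean(d$absence_6m)
    }, 0)
    stats::sd(qlogis(rates))
  }, 0)
  # the two routes must agree within Monte-Carlo error of the difference
  se_diff <- sqrt(stats::var(sd_pkg) / reps + stats::var(sd_ora) / reps)
  expect_lt(abs(mean(sd_pkg) - mean(sd_ora)), 3 * se_diff)
  # and both must be in the neighbourhood of the generating SD (0.794)
  expect_gt(mean(sd_pkg), 0.4)
  expect_lt(mean(sd_pkg), 1.2)
})

test_that("null truth across studies yields homogeneous outcome rates", {
  null_truth <- true_model("logistic",
                           coefficients = setNames(rep(0, 13),
                                                   model_terms("absence_6m")),
                           intercept = -1.5, random_intercept_sd = 0)
  cfgs <- equal_configs(5, 400)
  n_nonsig <- 0
  n_seeds <- 50
  for (s in seq_len(n_seeds)) {
    stk <- generate_multistudy(cfgs, null_truth, seed = 400 + s)
    tab <- table(stk$study_id, stk$absence_6m)
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    n_nonsig <- n_nonsig + (p > 0.01)
  }
  expect_gte(n_nonsig / n_seeds, 0.95)
})

test_that("gaussian copula hook induces the requested rank correlation", {
  R <- diag(10)
  R[4, 10] <- R[10, 4] <- 0.6    # pain_score with baseline_presenteeism
  cfg <- study_config("A", 20000, copula = R)
  d <- generate_study(cfg, truth6, 0, seed = 12)
  rho <- cor(d$pain_score, d$baseline_presenteeism, method = "spearman")
  expect_gt(rho, 0.45); expect_lt(rho, 0.7)
  d0 <- generate_study(study_config("A", 20000), truth6, 0, seed = 12)
  expect_lt(abs(cor(d0$pain_score, d0$baseline_presenteeism)), 0.03)
})

test_that("configuration errors are rejected", {
  expect_error(study_config("A", 100, prop_female = 1.2), "proportions")
  expect_error(study_config("A", 100, duration_probs = c(0.5, 0.2, 0.2, 0.2)),
               "sum to 1")
  expect_error(true_model("logistic", c(nonsense = 1), intercept = 0),
               "unknown coefficient")
  expect_error(true_model("linear", setNames(0.1, "age"), 0,
                          residual_sd = NULL), "residual_sd")
})

test_that("sporadic missingness masks at the configured rate and MAR slope is
           recoverable", {
  stk <- generate_multistudy(scaled_configs(10000), truth6, seed = 14)

  # identity when nothing is masked
  id <- apply_missingness(stk, missingness_spec(), seed = 1)
  expect_identical(as.data.frame(id), as.data.frame(stk))

  mcar <- apply_missingness(stk, missingness_spec(
    sporadic = c(pain_score = 0.2)), seed = 2)
  expect_lt(abs(mean(is.na(mcar$pain_score)) - 0.2),
            3 * sqrt(0.2 * 0.8 / nrow(stk)))
  expect_false(anyNA(stk$pain_score))   # input not mutated

  mar <- apply_missingness(stk, missingness_spec(
    sporadic = c(comorbidity = 0.25),
    mechanism = mar_mechanism("pain_score", 0.5)), seed = 3)
  fit <- glm(is.na(mar$comorbidity) ~ mar$pain_score, family = binomial())
  est <- coef(fit)[2]; se <- sqrt(vcov(fit)[2, 2])
  expect_lt(abs(est - 0.5), 3 * se)
  expect_lt(abs(mean(is.na(mar$comorbidity)) - 0.25), 0.02)
})

test_that("systematic missingness masks whole study columns and nothing else", {
  stk <- generate_multistudy(scaled_configs(600), truth6, seed = 15)
  out <- apply_missingness(stk, missingness_spec(
    systematic = data.frame(study_id = "KAPS", predictor = "prior_absence_6m")),
    seed = 1)
  expect_true(all(is.na(out$prior_absence_6m[out$study_id == "KAPS"])))
  expect_false(anyNA(out$prior_absence_6m[out$study_id != "KAPS"]))
})

test_that("degenerate missingness specifications are rejected", {
  stk <- generate_multistudy(scaled_configs(200), truth6, seed = 16)
  expect_error(missingness_spec(sporadic = c(pain_score = 1)), "systematic")
  expect_error(apply_missingness(stk, missingness_spec(
    sporadic = c(made_up = 0.1)), 1), "unknown predictor")
  expect_error(apply_missingness(stk, missingness_spec(
    systematic = data.frame(study_id = "nope", predictor = "age")), 1),
    "unknown study")
  expect_error(apply_missingness(stk, missingness_spec(
    sporadic = c(pain_score = 0.2),
    mechanism = mar_mechanism("pain_score", 0.5)), 1),
    "driver itself")
})
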