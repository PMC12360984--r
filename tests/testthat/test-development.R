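truth6 <- published_truth("absence_6m")

test_that("multilevel fit recovers generating coefficients at moderate size", {
  stk <- generate_multistudy(scaled_configs(6000), truth6, seed = 51)
  fit <- fit_multilevel(stk, "absence_6m")
  expect_s3_class(fit, "wa_model")
  expect_equal(fit$terms$term, model_terms("absence_6m"))
  z <- (fit$terms$estimate - truth6$coefficients[fit$terms$term]) /
    fit$terms$se
  expect_lt(max(abs(z)), 4)          # 13 comparisons at moderate n
  expect_gt(fit$loglik_model, fit$loglik_null)
  expect_equal(fit$p_df, 13)
})

test_that("single-study input and missing predictor cells are refused", {
  one <- generate_study(study_config("A", 300), truth6, 0, seed = 1)
  expect_error(fit_multilevel(one, "absence_6m"), "two studies")
  stk <- generate_multistudy(scaled_configs(400), truth6, seed = 2)
  holes <- apply_missingness(stk, missingness_spec(
    sporadic = c(pain_score = 0.2)), seed = 3)
  expect_error(fit_multilevel(holes, "absence_6m"), "impute")
})

test_that("heuristic shrinkage follows the chi-square arithmetic", {
  mock <- msdwork:::new_wa_model(
    family = "logistic", outcome = "absence_6m",
    terms = data.frame(term = model_terms("absence_6m"), estimate = 0, se = 1),
    intercept = 0, intercept_se = 1, random_intercept_sd = 0,
    n_obs = 100L, n_events = 10L,
    loglik_model = -100, loglik_null = -150, p_df = 10)
  # chi-square = 100, p = 10 -> S = 0.90
  expect_equal(heuristic_shrinkage(mock), 0.9)
  mock$loglik_model <- mock$loglik_null + 5   # chi-square = p
  expect_warning(S0 <- heuristic_shrinkage(mock), "no better than chance")
  expect_equal(S0, 0)
  mock$loglik_model <- mock$loglik_null + 2   # chi-square < p
  expect_warning(Sn <- heuristic_shrinkage(mock), "no better than chance")
  expect_lt(Sn, 0)
})

test_that("shrinkage application halves coefficients for S = 0.5 and is
           guarded against double application", {
  stk <- generate_multistudy(scaled_configs(2500), truth6, seed = 52)
  fit <- fit_multilevel(stk, "absence_6m")
  shr <- apply_shrinkage_and_reestimate(fit, 0.5, stk)
  expect_equal(shr$terms$estimate, 0.5 * fit$terms$estimate)
  expect_true(shr$shrunken)
  expect_error(apply_shrinkage_and_reestimate(shr, 0.9, stk),
               "already shrunken")
  expect_error(apply_shrinkage_and_reestimate(fit, 0, stk), "0, 1.5")
  expect_error(apply_shrinkage_and_reestimate(fit, 1.7, stk), "0, 1.5")
})

test_that("S = 1 leaves the multilevel intercept unchanged and the marginal
           intercept restores the event rate exactly", {
  stk <- generate_multistudy(scaled_configs(2500), truth6, seed = 53)
  fit <- fit_multilevel(stk, "absence_6m")
  same <- apply_shrinkage_and_reestimate(fit, 1, stk)
  expect_equal(same$terms$estimate, fit$terms$estimate)
  expect_lt(abs(same$intercept - fit$intercept), 1e-4)

  S <- heuristic_shrinkage(fit)
  marg <- apply_shrinkage_and_reestimate(fit, S, stk,
                                         intercept_method = "marginal")
  pred <- predict(marg, as.data.frame(stk))
  expect_lt(abs(mean(pred) - mean(stk$absence_6m)), 1e-6)
})

test_that("pooling across imputations follows Rubin's rules and ignores order", {
  stk <- generate_multistudy(scaled_configs(1500), truth6, seed = 54)
  fit <- fit_multilevel(stk, "absence_6m")
  m2 <- fit
  m2$terms$estimate <- fit$terms$estimate + 0.1
  m2$intercept <- fit$intercept - 0.2
  m2$shrinkage <- 0.8; fit$shrinkage <- 0.9

  pooled <- pool_across_imputations(list(fit, m2))
  expect_equal(pooled$terms$estimate,
               (fit$terms$estimate + m2$terms$estimate) / 2)
  expect_equal(pooled$shrinkage, 0.85)
  i <- 1
  hand <- rubin_pool(c(fit$terms$estimate[i], m2$terms$estimate[i]),
                     c(fit$terms$se[i]^2, m2$terms$se[i]^2))
  expect_equal(pooled$terms$se[i], hand$se)

  flipped <- pool_across_imputations(list(m2, fit))
  expect_equal(flipped$terms$estimate, pooled$terms$estimate)
  expect_equal(flipped$terms$se, pooled$terms$se)

  same <- pool_across_imputations(list(fit, fit))
  expect_equal(same$terms$estimate, fit$terms$estimate)
  expect_equal(same$terms$se, fit$terms$se)   # B = 0

  broken <- m2; broken$terms <- broken$terms[-1, ]
  expect_error(pool_across_imputations(list(fit, broken)), "share")
})

test_that("fractional-polynomial closed test keeps linear truths linear and
           finds quadratic departures", {
  stk <- generate_multistudy(scaled_configs(2179), truth6, seed = 55)
  for (v in c("age", "pain_score", "baseline_presenteeism")) {
    fp <- select_fractional_polynomial(stk, v, "absence_6m")
    expect_equal(fp$form, "linear")
  }

  big <- generate_multistudy(scaled_configs(10000), truth6, seed = 56)
  df <- as.data.frame(big)
  z <- as.numeric(scale(df$pain_score))
  set.seed(57)
  df$absence_6m <- rbinom(nrow(df), 1, plogis(-3 + 0.15 * z^2))
  quad <- ipd_stack(df)
  fp2 <- select_fractional_polynomial(quad, "pain_score", "absence_6m")
  expect_true(fp2$form %in% c("FP1", "FP2"))

  const <- df; const$pain_score <- 5
  expect_error(select_fractional_polynomial(ipd_stack(const), "pain_score",
                                            "absence_6m"), "constant")
  expect_error(select_fractional_polynomial(
    ipd_stack(df[1:60, ]), "pain_score", "absence_6m"), "100 complete cases")
})

test_that("Riley criteria reproduce hand-computed sample sizes", {
  # criterion 3 at prevalence 0.0987: (1.96/0.05)^2 * 0.0987 * 0.9013 = 136.7
  r <- riley_max_parameters("logistic", n = 5000, outcome_summary = 0.0987,
                            anticipated_R2cs = 0.05)
  expect_equal(unname(r$required_n["outcome_proportion"]), 137)

  # criterion 1 at p = 16, S = 0.9, R2cs = 0.05: 16 / (0.1 |ln(1 - 0.05/0.9)|)
  n1_hand <- 16 / ((0.9 - 1) * log(1 - 0.05 / 0.9))
  expect_equal(ceiling(n1_hand), 2800)
  expect_lt(abs(n1_hand - 2799.25), 0.5)
  r16 <- riley_max_parameters("logistic", n = ceiling(n1_hand),
                              outcome_summary = 0.0987,
                              anticipated_R2cs = 0.05)
  expect_gte(r16$max_parameters, 16)

  # doubling n never decreases the parameter allowance
  ns <- c(200, 400, 800, 1600, 3200, 6400)
  ps <- vapply(ns, function(n)
    riley_max_parameters("logistic", n, 0.1, 0.05)$max_parameters, 0L)
  expect_true(all(diff(ps) >= 0))

  lin <- riley_max_parameters("linear", n = 1218, outcome_summary = 2.5,
                              anticipated_R2cs = 0.2)
  expect_gt(lin$max_parameters, 20)
  expect_equal(unname(lin$required_n["residual_variance"]),
               234 + lin$max_parameters)
})

test_that("fitted models serialise to JSON and back bit-exactly", {
  stk <- generate_multistudy(scaled_configs(1200), truth6, seed = 58)
  fit <- fit_multilevel(stk, "absence_6m")
  path <- tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_identical(back$terms$estimate, fit$terms$estimate)
  expect_identical(back$terms$se, fit$terms$se)
  expect_identical(back$intercept, fit$intercept)
  expect_identical(back$random_intercept_sd, fit$random_intercept_sd)
  unlink(path)
})
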