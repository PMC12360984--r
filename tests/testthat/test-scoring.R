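test_that("published payloads carry the frozen constants and shrinkage", {
  m6 <- load_published_model("absence_6m")
  cf <- coef(m6)
  expect_identical(unname(cf["prior_absence_6m"]), 1.465)
  expect_identical(unname(cf["baseline_presenteeism"]), 0.250)
  expect_identical(m6$intercept, -3.493)
  expect_identical(m6$random_intercept_sd, 0.794)
  expect_identical(m6$shrinkage, 0.9464)
  expect_length(cf, 13)
  expect_identical(m6$provenance, "published")

  mp <- load_published_model("presenteeism_6m")
  expect_identical(mp$intercept, 0.309)
  expect_identical(mp$shrinkage, 0.9746)
  expect_identical(mp$family, "linear")

  expect_message(m12 <- load_published_model("absence_12m"), "not ready")
  expect_identical(m12$shrinkage, 0.7832)
  expect_length(coef(m12), 11)
  expect_false(any(c("comorbidity", "prior_absence_6m") %in%
                     m12$terms$term))
  expect_match(m12$caveat, "not ready")

  expect_error(load_published_model("nonsense"), "valid names")
})

test_that("predict_risk reproduces independent hand arithmetic", {
  m6 <- load_published_model("absence_6m")
  inv_logit <- function(x) 1 / (1 + exp(-x))

  suppressWarnings(ref <- predict_risk(m6, reference_profile()))
  expect_equal(ref$linear_predictor, -3.493, tolerance = 1e-12)
  expect_equal(ref$risk, inv_logit(-3.493), tolerance = 1e-12)

  wk <- predict_risk(m6, worked_profile())
  lp_hand <- -3.493 + (-0.016) * 50 + (-0.307) + 0.127 * 6 + 0.432 +
    (-0.315) + 1.465 + 0.250 * 5
  expect_equal(lp_hand, -1.006, tolerance = 1e-9)
  expect_equal(wk$linear_predictor, lp_hand, tolerance = 1e-12)
  expect_equal(wk$risk, inv_logit(lp_hand), tolerance = 1e-12)
  expect_equal(round(wk$risk, 3), 0.268)

  mp <- load_published_model("presenteeism_6m")
  suppressWarnings(refp <- predict_risk(mp, reference_profile()))
  expect_equal(refp$expected_score, 0.309, tolerance = 1e-12)
})

test_that("predictions are deterministic, monotone in continuous predictors,
           and strictly inside (0, 1)", {
  m6 <- load_published_model("absence_6m")
  base <- worked_profile()
  r0 <- predict_risk(m6, base)$risk
  expect_identical(predict_risk(m6, base)$risk, r0)
  for (v in 0:10) {
    pr <- base; pr$baseline_presenteeism <- v
    r <- predict_risk(m6, pr)$risk
    if (v > 0) expect_gte(r, last_r)   # coefficient +0.250
    expect_true(r > 0 && r < 1)
    last_r <- r
  }
})

test_that("incomplete or out-of-range profiles are refused with the
           offending predictor named", {
  m6 <- load_published_model("absence_6m")
  for (p in names(msd_dictionary()$predictors)) {
    broken <- worked_profile()
    broken[[p]] <- NULL
    expect_error(predict_risk(m6, broken), p)
  }
  bad <- worked_profile(); bad$pain_score <- 12
  expect_error(predict_risk(m6, bad), "pain_score")
  bad2 <- worked_profile(); bad2$pain_duration <- "forever"
  expect_error(predict_risk(m6, bad2), "pain_duration")
  old <- worked_profile(); old$age <- 80
  expect_warning(predict_risk(m6, old), "working-age")
})

test_that("categorical inputs are accepted as labels or integer codes", {
  m6 <- load_published_model("absence_6m")
  lab <- predict_risk(m6, worked_profile())
  coded <- worked_profile()
  coded$sex <- 2L; coded$multisite_pain <- 1L
  coded$pain_duration <- 4L; coded$job_type <- 3L
  expect_equal(predict_risk(m6, coded)$risk, lab$risk)
})

test_that("the linear scorer clips to the instrument range and flags it", {
  mp <- load_published_model("presenteeism_6m")
  hi <- list(age = 20, sex = "male", multisite_pain = "multisite",
             pain_score = 10, pain_duration = ">12 months",
             job_type = "manual", anxiety_depression = 1L, comorbidity = 1L,
             prior_absence_6m = 1L, baseline_presenteeism = 10)
  out <- predict_risk(mp, hi)
  expect_lte(out$expected_score, 10)
  expect_identical(out$clipped, out$linear_predictor > 10)
})

test_that("batch scoring collects row errors and carries identifiers", {
  m6 <- load_published_model("absence_6m")
  good <- as.data.frame(worked_profile(), stringsAsFactors = FALSE)
  df <- rbind(good, good, good)
  df$id <- c("a", "b", "c")
  df$pain_score[2] <- 99
  suppressMessages(res <- score_batch(m6, df))
  expect_equal(res$n_scored, 2)
  expect_equal(res$n_failed, 1)
  expect_equal(res$errors$id, "b")
  expect_match(res$errors$message, "pain_score")
  expect_identical(res$predictions$risk[1], res$predictions$risk[2])

  # empty data section: empty predictions with a header
  suppressMessages(res0 <- score_batch(m6, df[0, ]))
  expect_equal(nrow(res0$predictions), 0)
  expect_true(all(c("id", "risk") %in% names(res0$predictions)))

  # CSV round trip
  fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".csv")
  write.csv(df, fin, row.names = FALSE)
  suppressMessages(res2 <- score_batch("absence_6m", fin, fout))
  expect_true(file.exists(fout))
  back <- read.csv(fout)
  expect_equal(nrow(back), 2)
  expect_equal(back$risk, res$predictions$risk, tolerance = 1e-12)
  unlink(c(fin, fout))
  expect_error(suppressWarnings(suppressMessages(score_batch(m6, tempfile()))),
               "malformed CSV")
})

test_that("published models survive a JSON round trip bit-exactly", {
  for (nm in c("absence_6m", "presenteeism_6m", "absence_12m")) {
    m <- suppressMessages(load_published_model(nm))
    path <- tempfile(fileext = ".json")
    write_model_json(m, path)
    back <- read_model_json(path)
    expect_identical(back$terms$estimate, m$terms$estimate)
    expect_identical(back$intercept, m$intercept)
    expect_identical(back$random_intercept_sd, m$random_intercept_sd)
    expect_identical(back$shrinkage, m$shrinkage)
    expect_s3_class(back, "published_model")
    unlink(path)
  }
})

test_that("the alternative loader reading multiplies by the stored shrinkage", {
  plain <- load_published_model("absence_6m")
  alt <- load_published_model("absence_6m", apply_shrinkage = TRUE)
  expect_equal(alt$terms$estimate, 0.9464 * plain$terms$estimate)
})

test_that("the command-line scorer runs end to end", {
  cli <- system.file("exec", "msdwork", package = "msdwork")
  expect_true(nzchar(cli))
  df <- as.data.frame(worked_profile(), stringsAsFactors = FALSE)
  df <- rbind(df, df); df$id <- c("r1", "r2")
  fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".csv")
  write.csv(df, fin, row.names = FALSE)
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(rscript, c(cli, "score", "--model",
                                             "absence_6m", "--in", fin,
                                             "--out", fout),
                                  stdout = TRUE, stderr = TRUE))
  expect_true(file.exists(fout))
  preds <- read.csv(fout)
  expect_equal(nrow(preds), 2)
  expect_equal(round(preds$risk[1], 3), 0.268)
  unlink(c(fin, fout))
})
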