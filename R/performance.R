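# Validation statistics for risk-prediction models: discrimination
# (C-statistic), calibration (slope, calibration-in-the-large, O/E ratio,
# smooth calibration curves) and Rubin's-rules pooling across imputations.

new_performance_estimate <- function(metric, estimate, se, scale = "natural",
                                     study_id = "pooled", n = NA_integer_,
                                     events = NA_integer_, flags = character(0)) {
  structure(list(metric = metric, estimate = estimate, se = se, scale = scale,
                 study_id = study_id, n = n, events = events, flags = flags),
            class = "performance_estimate")
}

#' @export
print.performance_estimate <- function(x, ...) {
  cat(sprintf("%s [%s]: %.4f (SE %.4f, scale %s, n=%s, events=%s)%s\n",
              x$metric, x$study_id, x$estimate, x$se, x$scale, x$n, x$events,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' @export
as.data.frame.performance_estimate <- function(x, ...) {
  data.frame(study_id = x$study_id, metric = x$metric, estimate = x$estimate,
             se = x$se, scale = x$scale, n = x$n, events = x$events,
             flags = paste(x$flags, collapse = ";"))
}

#' Concordance statistic with DeLong standard error
#'
#' The probability that a randomly chosen event receives a higher predicted
#' risk than a randomly chosen non-event, with tied predictions counted one
#' half.  The standard error uses the DeLong pairwise-placement variance.
#'
#' @param outcomes Binary 0/1 vector.
#' @param risks Predicted risks (any strictly increasing transform of the
#'   linear predictor gives the same value).
#' @return A `performance_estimate` with `metric = "c_statistic"`.
#' @export
c_statistic <- function(outcomes, risks) {
  stopifnot(length(outcomes) == length(risks))
  ok <- !is.na(outcomes) & !is.na(risks)
  y <- outcomes[ok]; p <- risks[ok]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("undefined discrimination: both outcome classes must be present",
         call. = FALSE)
  r <- rank(p)                     # midranks: ties count 1/2
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # DeLong placements via midranks
  v10 <- (r[y == 1] - rank(p[y == 1])) / n0
  v01 <- 1 - (r[y == 0] - rank(p[y == 0])) / n1
  var_auc <- stats::var(v10) / n1 + stats::var(v01) / n0
  new_performance_estimate("c_statistic", auc, sqrt(var_auc),
                           n = n1 + n0, events = n1)
}

#' Calibration slope
#'
#' Binary family: slope of a logistic regression of the outcome on the
#' linear predictor (intercept free).  Linear family: slope of a regression
#' of observed on predicted scores.  A slope of 1 indicates correctly spread
#' predictions; below 1 indicates overfitting.
#'
#' @param outcomes Observed outcomes.
#' @param linear_predictors Model linear predictors (binary family) or
#'   predicted scores (linear family).
#' @param family `"logistic"` or `"linear"`.
#' @return A `performance_estimate` with `metric = "calibration_slope"`.
#' @export
calibration_slope <- function(outcomes, linear_predictors,
                              family = c("logistic", "linear")) {
  family <- match.arg(family)
  if (stats::var(linear_predictors) < 1e-12)
    stop("slope unidentifiable: constant linear predictor", call. = FALSE)
  if (family == "logistic") {
    fit <- stats::glm(outcomes ~ linear_predictors, family = stats::binomial())
    est <- unname(stats::coef(fit)[2]); se <- sqrt(stats::vcov(fit)[2, 2])
    ev <- sum(outcomes == 1)
  } else {
    fit <- stats::lm(outcomes ~ linear_predictors)
    est <- unname(stats::coef(fit)[2]); se <- sqrt(stats::vcov(fit)[2, 2])
    ev <- NA_integer_
  }
  new_performance_estimate("calibration_slope", est, se,
                           n = length(outcomes), events = ev)
}

#' Calibration-in-the-large
#'
#' Binary family: intercept of a logistic regression of the outcome with the
#' linear predictor as fixed offset.  Linear family: mean of observed minus
#' predicted.  Zero indicates correct average risk.
#'
#' @inheritParams calibration_slope
#' @return A `performance_estimate` with `metric = "citl"`.
#' @export
citl <- function(outcomes, linear_predictors,
                 family = c("logistic", "linear")) {
  family <- match.arg(family)
  if (family == "logistic") {
    fit <- stats::glm(outcomes ~ 1 + offset(linear_predictors),
                      family = stats::binomial())
    est <- unname(stats::coef(fit)[1]); se <- sqrt(stats::vcov(fit)[1, 1])
    ev <- sum(outcomes == 1)
  } else {
    d <- outcomes - linear_predictors
    est <- mean(d); se <- stats::sd(d) / sqrt(length(d))
    ev <- NA_integer_
  }
  new_performance_estimate("citl", est, se, n = length(outcomes), events = ev)
}

#' Observed / expected outcome ratio
#'
#' Ratio of the observed event count to the sum of predicted risks; 1
#' indicates correct overall expected risk.  The standard error is computed
#' on the log scale as `sqrt((1 - mean(y)) / sum(y))`.
#'
#' @param outcomes Binary 0/1 vector.
#' @param risks Predicted probabilities; their sum must be positive.
#' @return A `performance_estimate` with `metric = "oe_ratio"` and
#'   `scale = "log"` for the SE.
#' @export
oe_ratio <- function(outcomes, risks) {
  stopifnot(length(outcomes) == length(risks), sum(risks) > 0)
  O <- sum(outcomes); E <- sum(risks)
  if (O == 0)
    return(new_performance_estimate("oe_ratio", 0, NA_real_, scale = "log",
                                    n = length(outcomes), events = 0L,
                                    flags = "zero_observed_events"))
  se_log <- sqrt((1 - mean(outcomes)) / O)
  new_performance_estimate("oe_ratio", O / E, se_log, scale = "log",
                           n = length(outcomes), events = as.integer(O))
}

#' Grouped and smoothed calibration curve
#'
#' Decile-grouped observed vs mean predicted risk, plus a locally weighted
#' (loess, span 0.75) smooth on the probability scale evaluated on a
#' 100-point grid of predicted risk, with a pointwise 95% band.  With fewer
#' than 50 observations only the grouped points are returned, with a
#' warning.
#'
#' @param outcomes Binary 0/1 vector.
#' @param risks Predicted probabilities.
#' @param groups Number of risk groups (default 10).
#' @param span Loess span (default 0.75).
#' @param grid_size Number of grid points for the smooth (default 100).
#' @return A list of class `calibration_curve` with plot-ready data frames
#'   `groups` (predicted, observed, n, events) and `smooth` (predicted,
#'   observed, lower, upper), the latter `NULL` for small samples.
#' @export
calibration_curve <- function(outcomes, risks, groups = 10, span = 0.75,
                              grid_size = 100) {
  n <- length(outcomes)
  stopifnot(length(risks) == n)
  if (stats::var(risks) < 1e-12) {
    g <- data.frame(group = 1L, predicted = mean(risks),
                    observed = mean(outcomes), n = n,
                    events = sum(outcomes == 1))
    return(structure(list(groups = g, smooth = NULL), class = "calibration_curve"))
  }
  br <- unique(stats::quantile(risks, probs = seq(0, 1, length.out = groups + 1)))
  gi <- cut(risks, br, include.lowest = TRUE, labels = FALSE)
  g <- do.call(rbind, lapply(sort(unique(gi)), function(k) {
    data.frame(group = k, predicted = mean(risks[gi == k]),
               observed = mean(outcomes[gi == k]), n = sum(gi == k),
               events = sum(outcomes[gi == k] == 1))
  }))
  smooth <- NULL
  if (n < 50) {
    warning("fewer than 50 observations: grouped points only, no smooth")
  } else {
    lo <- stats::loess(outcomes ~ risks, span = span, degree = 2,
                       family = "gaussian")
    grid <- seq(min(risks), max(risks), length.out = grid_size)
    pr <- stats::predict(lo, newdata = data.frame(risks = grid), se = TRUE)
    smooth <- data.frame(predicted = grid,
                         observed = pmin(1, pmax(0, pr$fit)),
                         lower = pmin(1, pmax(0, pr$fit - 1.96 * pr$se.fit)),
                         upper = pmin(1, pmax(0, pr$fit + 1.96 * pr$se.fit)))
  }
  structure(list(groups = g, smooth = smooth), class = "calibration_curve")
}

#' Rubin's rules for pooling across imputations
#'
#' Pools `m` estimates as their mean with total variance
#' `W + (1 + 1/m) B`, where `W` is the mean within-imputation variance and
#' `B` the between-imputation sample variance; the 95% interval uses a t
#' distribution with Barnard-Rubin degrees of freedom.
#'
#' @param estimates Numeric vector of per-imputation estimates.
#' @param variances Per-imputation (squared-SE) variances, all \eqn{\ge 0}.
#' @return A list of class `rubin_pooled` with elements `estimate`, `W`,
#'   `B`, `variance`, `se`, `df`, `ci` and `m`.
#' @export
rubin_pool <- function(estimates, variances) {
  stopifnot(length(estimates) == length(variances), all(variances >= 0, na.rm = TRUE))
  m <- length(estimates)
  if (m == 1) {
    warning("single imputation: pass-through, no between-imputation variance")
    return(structure(list(estimate = estimates, W = variances, B = 0,
                          variance = variances, se = sqrt(variances),
                          df = Inf,
                          ci = estimates + c(-1.96, 1.96) * sqrt(variances),
                          m = 1L), class = "rubin_pooled"))
  }
  est <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  Tvar <- W + (1 + 1 / m) * B
  df <- if (B <= 0) Inf else (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
  tq <- if (is.finite(df)) stats::qt(0.975, df) else 1.96
  structure(list(estimate = est, W = W, B = B, variance = Tvar,
                 se = sqrt(Tvar), df = df,
                 ci = est + c(-tq, tq) * sqrt(Tvar), m = m),
            class = "rubin_pooled")
}

#' @export
print.rubin_pooled <- function(x, ...) {
  cat(sprintf("Rubin-pooled estimate %.4f (T = %.4f, W = %.4f, B = %.4f, m = %d)\n",
              x$estimate, x$variance, x$W, x$B, x$m))
  invisible(x)
}

# transform a performance estimate to its pooling scale and back.
# C-statistics pool on the logit scale, O/E on the log scale,
# slope/CITL on the natural scale.
pooling_transform <- function(metric) {
  switch(metric,
    c_statistic = list(
      fwd = function(est, se) list(est = stats::qlogis(est),
                                   se = se / (est * (1 - est))),
      bwd = stats::plogis),
    oe_ratio = list(
      fwd = function(est, se) list(est = log(est), se = se),  # SE already log-scale
      bwd = exp),
    list(fwd = function(est, se) list(est = est, se = se),
         bwd = identity))
}
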