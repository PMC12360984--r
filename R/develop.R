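# Model development: multilevel mixed-effects fits, functional-form checks,
# heuristic shrinkage with intercept re-estimation, Rubin's-rules pooling of
# fitted models, and Riley minimum-sample-size criteria.

new_wa_model <- function(family, outcome, terms, intercept, intercept_se,
                         random_intercept_sd, n_obs, n_events, loglik_model,
                         loglik_null, p_df, shrinkage = NULL,
                         shrunken = FALSE, provenance = "developed",
                         m = 1L, caveat = NULL) {
  structure(list(family = family, outcome = outcome, terms = terms,
                 intercept = intercept, intercept_se = intercept_se,
                 random_intercept_sd = random_intercept_sd, n_obs = n_obs,
                 n_events = n_events, loglik_model = loglik_model,
                 loglik_null = loglik_null, p_df = p_df,
                 shrinkage = shrinkage, shrunken = shrunken,
                 provenance = provenance, m = m, caveat = caveat),
            class = "wa_model")
}

#' @export
print.wa_model <- function(x, ...) {
  cat(sprintf("%s %s model for %s (%d terms, n = %s%s)%s\n",
              x$provenance, x$family, x$outcome, nrow(x$terms), x$n_obs,
              if (!is.na(x$n_events)) paste0(", events = ", x$n_events) else "",
              if (x$shrunken) sprintf(" [shrunken, S = %.4f]", x$shrinkage) else ""))
  df <- x$terms
  df$estimate <- sprintf("% .4f", df$estimate)
  df$se <- ifelse(is.na(df$se), "", sprintf("%.4f", df$se))
  print(df, row.names = FALSE)
  cat(sprintf("constant: %.4f   sd(constant): %.4f\n",
              x$intercept, x$random_intercept_sd))
  if (!is.null(x$caveat)) cat("caveat:", x$caveat, "\n")
  invisible(x)
}

#' Model coefficients as a named vector
#' @param object A `wa_model`.
#' @param ... Unused.
#' @return Named numeric vector of term coefficients (no intercept).
#' @export
coef.wa_model <- function(object, ...)
  stats::setNames(object$terms$estimate, object$terms$term)

# linear predictor with the study random effect set to zero
model_lp <- function(model, data) {
  X <- encode_predictors(data, model$terms$term)
  model$intercept + drop(X %*% model$terms$estimate)
}

#' Predict from a fitted work-outcome model
#'
#' Predictions for new individuals use the average intercept (study random
#' effect set to zero).
#'
#' @param object A `wa_model`.
#' @param newdata Data frame with the model's predictor columns.
#' @param type `"link"` for the linear predictor, `"response"` for the risk
#'   (logistic) or expected score (linear).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.wa_model <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  lp <- model_lp(object, newdata)
  if (type == "link" || object$family == "linear") lp else stats::plogis(lp)
}

#' Fit a multilevel (random-intercept) prediction model
#'
#' Binary outcomes are fitted by multilevel logistic regression (maximum
#' likelihood with adaptive Gauss-Hermite quadrature); the continuous
#' presenteeism outcome by multilevel linear regression fitted by REML.
#' Both include a random intercept per study.  Predictors are internally
#' standardised for numerical stability and coefficients back-transformed to
#' the natural scale.
#'
#' @param stack An [ipd_stack()] with at least two studies, no missing
#'   predictor cells, and the outcome observed in every included study.
#' @param outcome Outcome column name.
#' @param terms Design-matrix terms; default [model_terms()] for the outcome.
#' @param nAGQ Number of adaptive quadrature points for the logistic family
#'   (default 7).
#' @return A `wa_model` with coefficient estimates and SEs, the average
#'   intercept, the random-intercept SD, and the fixed-effects model and
#'   null log-likelihoods used for heuristic shrinkage.
#' @export
fit_multilevel <- function(stack, outcome, terms = model_terms(outcome),
                           nAGQ = 7) {
  dict <- attr(stack, "dictionary")
  if (is.null(dict)) dict <- msd_dictionary()
  family <- dict$outcomes[[outcome]]$family
  if (is.null(family)) stop("unknown outcome: ", outcome, call. = FALSE)
  df <- as.data.frame(stack)
  df <- df[!is.na(df[[outcome]]), , drop = FALSE]
  study <- droplevels(factor(df$study_id))
  if (nlevels(study) < 2)
    stop("at least two studies are required for a multilevel fit",
         call. = FALSE)
  X <- encode_predictors(df, terms)
  if (anyNA(X))
    stop("missing predictor cells: impute first (see impute_joint)",
         call. = FALSE)
  y <- df[[outcome]]
  p <- length(terms)

  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-9] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  dat <- data.frame(.y = y, Z, .study = study, check.names = FALSE)
  fml <- stats::reformulate(c(sprintf("`%s`", terms), "(1 | .study)"),
                            response = ".y")

  if (family == "logistic") {
    fit <- suppressMessages(lme4::glmer(fml, data = dat,
                                        family = stats::binomial(),
                                        nAGQ = nAGQ))
    null <- suppressMessages(lme4::glmer(.y ~ 1 + (1 | .study), data = dat,
                                         family = stats::binomial(),
                                         nAGQ = nAGQ))
    check_lme4_convergence(fit, terms)
    ll_model <- as.numeric(stats::logLik(fit))
    ll_null <- as.numeric(stats::logLik(null))
    n_events <- sum(y == 1)
  } else {
    fit <- suppressMessages(lme4::lmer(fml, data = dat, REML = TRUE))
    check_lme4_convergence(fit, terms)
    fit_ml <- suppressMessages(lme4::lmer(fml, data = dat, REML = FALSE))
    null_ml <- suppressMessages(lme4::lmer(.y ~ 1 + (1 | .study), data = dat, REML = FALSE))
    ll_model <- as.numeric(stats::logLik(fit_ml))
    ll_null <- as.numeric(stats::logLik(null_ml))
    n_events <- NA_integer_
  }

  b <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  # back-transform standardised coefficients to the natural scale
  q <- p + 1L
  Tm <- diag(c(1, 1 / scl))
  Tm[1, -1] <- -ctr / scl
  est_nat <- drop(Tm %*% b)
  V_nat <- Tm %*% V %*% t(Tm)
  se_nat <- sqrt(diag(V_nat))

  new_wa_model(
    family = family, outcome = outcome,
    terms = data.frame(term = terms, estimate = est_nat[-1], se = se_nat[-1]),
    intercept = est_nat[1], intercept_se = se_nat[1],
    random_intercept_sd = sqrt(unname(unlist(lme4::VarCorr(fit))[1])),
    n_obs = nrow(dat), n_events = n_events,
    loglik_model = ll_model, loglik_null = ll_null, p_df = p)
}

check_lme4_convergence <- function(fit, terms) {
  conv <- fit@optinfo$conv
  if (!is.null(conv$opt) && conv$opt != 0)
    stop("multilevel fit did not converge (optimizer code ", conv$opt, "): ",
         paste(unlist(conv$lme4$messages), collapse = "; "), call. = FALSE)
  msgs <- unlist(conv$lme4$messages)
  if (any(grepl("failed to converge", msgs)))
    stop("multilevel fit failed to converge: ",
         paste(msgs, collapse = "; "), call. = FALSE)
  b <- lme4::fixef(fit)[-1]
  if (any(abs(b) > 15))
    stop("possible complete separation on term(s): ",
         paste(terms[abs(b) > 15], collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Van Houwelingen-le Cessie heuristic shrinkage factor
#'
#' Computes `S = (chisq - p) / chisq`, where `chisq` is twice the difference
#' between the model and null (intercept plus random intercept only)
#' log-likelihoods of the fixed-effects structure, and `p` is the number of
#' predictor degrees of freedom.  Values below 1 quantify expected
#' overfitting; the factor is applied uniformly to all coefficients.
#'
#' @param model A `wa_model` from [fit_multilevel()].
#' @return The scalar shrinkage factor.  If `chisq <= p` the returned value
#'   is \eqn{\le 0} and a warning is raised (model no better than chance
#'   after the degrees-of-freedom correction).
#' @export
heuristic_shrinkage <- function(model) {
  stopifnot(inherits(model, "wa_model"))
  chisq <- 2 * (model$loglik_model - model$loglik_null)
  p <- model$p_df
  S <- (chisq - p) / chisq
  if (chisq <= p)
    warning("model chi-square (", round(chisq, 2), ") <= ", p,
            " df: model no better than chance after df correction; S <= 0")
  S
}

#' Apply uniform shrinkage and re-estimate the intercept
#'
#' Multiplies every predictor coefficient by the shrinkage factor `S`, then
#' re-estimates the average intercept (and random-intercept SD) by refitting
#' the random-intercept model with the shrunken linear predictor entered as
#' a fixed offset, so that predictions remain correct on average.
#'
#' @param model A `wa_model` (not already shrunken).
#' @param S Shrinkage factor in (0, 1.5].
#' @param stack The development data ([ipd_stack()]) used to re-estimate the
#'   intercept.
#' @param nAGQ Quadrature points for the logistic offset refit.
#' @param intercept_method `"multilevel"` (default) keeps the conditional
#'   intercept of the random-intercept offset refit; `"marginal"` replaces
#'   it with the population-averaged intercept from a pooled offset fit, so
#'   that predictions made with the study random effect at zero are correct
#'   on average over the development data.  The random-intercept SD is
#'   re-estimated from the multilevel refit in both cases.
#' @return The shrunken `wa_model` (flagged; applying twice is an error).
#' @export
apply_shrinkage_and_reestimate <- function(model, S, stack, nAGQ = 7,
                                           intercept_method = c("multilevel",
                                                                "marginal")) {
  intercept_method <- match.arg(intercept_method)
  stopifnot(inherits(model, "wa_model"))
  if (model$shrunken)
    stop("model is already shrunken: refusing to apply shrinkage twice",
         call. = FALSE)
  if (!(S > 0 && S <= 1.5))
    stop("shrinkage factor must lie in (0, 1.5]", call. = FALSE)
  df <- as.data.frame(stack)
  df <- df[!is.na(df[[model$outcome]]), , drop = FALSE]
  X <- encode_predictors(df, model$terms$term)
  off <- S * drop(X %*% model$terms$estimate)
  dat <- data.frame(.y = df[[model$outcome]], .off = off,
                    .study = droplevels(factor(df$study_id)))
  if (model$family == "logistic") {
    fit <- suppressMessages(lme4::glmer(.y ~ 1 + (1 | .study) + offset(.off),
                                        data = dat, family = stats::binomial(),
                                        nAGQ = nAGQ))
  } else {
    fit <- suppressMessages(lme4::lmer(.y ~ 1 + (1 | .study) + offset(.off),
                                       data = dat, REML = TRUE))
  }
  out <- model
  out$terms$estimate <- S * model$terms$estimate
  out$terms$se <- S * model$terms$se
  if (intercept_method == "marginal") {
    mf <- if (model$family == "logistic")
      stats::glm(.y ~ 1 + offset(.off), data = dat, family = stats::binomial())
    else stats::lm(.y ~ 1 + offset(.off), data = dat)
    out$intercept <- unname(stats::coef(mf)[1])
    out$intercept_se <- sqrt(as.matrix(stats::vcov(mf))[1, 1])
  } else {
    out$intercept <- unname(lme4::fixef(fit)[1])
    out$intercept_se <- sqrt(as.matrix(stats::vcov(fit))[1, 1])
  }
  out$random_intercept_sd <- sqrt(unname(unlist(lme4::VarCorr(fit))[1]))
  out$shrinkage <- S
  out$shrunken <- TRUE
  out
}

#' Pool fitted models across imputations by Rubin's rules
#'
#' Each coefficient (and the intercept) is pooled as the across-imputation
#' mean with Rubin total variance; the shrinkage factor and random-intercept
#' SD are pooled as across-imputation means.
#'
#' @param models List of `wa_model` objects sharing family and term set.
#' @return A pooled `wa_model` (`m` set to the number of imputations).
#' @export
pool_across_imputations <- function(models) {
  stopifnot(length(models) >= 1, all(vapply(models, inherits, TRUE, "wa_model")))
  m <- length(models)
  if (m == 1) return(models[[1]])
  t1 <- models[[1]]$terms$term
  for (mod in models) {
    if (!identical(mod$terms$term, t1) || mod$family != models[[1]]$family)
      stop("models must share family and term set", call. = FALSE)
  }
  pool_one <- function(est, v) rubin_pool(est, v)
  terms <- models[[1]]$terms
  for (i in seq_len(nrow(terms))) {
    r <- pool_one(vapply(models, function(x) x$terms$estimate[i], 0),
                  vapply(models, function(x) x$terms$se[i]^2, 0))
    terms$estimate[i] <- r$estimate
    terms$se[i] <- r$se
  }
  ri <- pool_one(vapply(models, `[[`, 0, "intercept"),
                 vapply(models, function(x) x$intercept_se^2, 0))
  shr <- vapply(models, function(x) if (is.null(x$shrinkage)) NA_real_ else x$shrinkage, 0)
  out <- models[[1]]
  out$terms <- terms
  out$intercept <- ri$estimate
  out$intercept_se <- ri$se
  out$random_intercept_sd <- mean(vapply(models, `[[`, 0, "random_intercept_sd"))
  out$loglik_model <- mean(vapply(models, `[[`, 0, "loglik_model"))
  out$loglik_null <- mean(vapply(models, `[[`, 0, "loglik_null"))
  out$shrinkage <- if (all(is.na(shr))) NULL else mean(shr)
  out$m <- m
  out
}

# fractional-polynomial basis for powers in {-2,-1,-0.5,0,0.5,1,2,3};
# power 0 is log(x); a repeated power p gives x^p and x^p*log(x)
fp_basis <- function(x, powers) {
  f <- function(p) if (p == 0) log(x) else x^p
  if (length(powers) == 1) return(matrix(f(powers[1]), ncol = 1))
  if (powers[1] == powers[2])
    cbind(f(powers[1]), f(powers[1]) * log(x))
  else
    cbind(f(powers[1]), f(powers[2]))
}

#' Closed-test selection of a fractional-polynomial functional form
#'
#' Tests fractional-polynomial transforms up to second order for a
#' continuous predictor, in a complete-case analysis adjusted for the
#' remaining model terms (and fixed study effects), using the standard
#' closed test on deviance differences over the power set
#' \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}: best FP2 vs linear (3 df), then best
#' FP2 vs best FP1 (2 df), each at `alpha`.
#'
#' @param stack An [ipd_stack()] (complete cases are used).
#' @param variable Continuous predictor term to test.
#' @param outcome Outcome column.
#' @param adjustment Other design-matrix terms to adjust for; default all
#'   remaining terms of the outcome's model.
#' @param alpha Significance level of the closed test (default 0.05).
#' @return A list with `form` (`"linear"`, `"FP1"` or `"FP2"`), the selected
#'   `powers`, the applied `shift`, and the closed-test `tests` table.
#' @export
select_fractional_polynomial <- function(stack, variable, outcome,
                                         adjustment = NULL, alpha = 0.05) {
  dict <- msd_dictionary()
  family <- dict$outcomes[[outcome]]$family
  terms <- model_terms(outcome)
  if (!variable %in% terms) stop("unknown term: ", variable, call. = FALSE)
  if (is.null(adjustment)) adjustment <- setdiff(terms, variable)
  df <- as.data.frame(stack)
  X <- encode_predictors(df, c(variable, adjustment))
  keep <- stats::complete.cases(X) & !is.na(df[[outcome]])
  X <- X[keep, , drop = FALSE]
  y <- df[[outcome]][keep]
  study <- droplevels(factor(df$study_id[keep]))
  if (nrow(X) < 100) stop("need at least 100 complete cases", call. = FALSE)
  x <- X[, variable]
  if (stats::var(x) < 1e-12) stop("variable is constant", call. = FALSE)
  shift <- if (min(x) > 0) 0 else -min(x) + min(diff(sort(unique(x))))
  xs <- x + shift
  A <- cbind(X[, adjustment, drop = FALSE],
             stats::model.matrix(~study)[, -1, drop = FALSE])
  glm_family <- if (family == "logistic") stats::binomial() else stats::gaussian()
  dev_of <- function(B) {
    stats::deviance(stats::glm.fit(cbind(1, B, A), y, family = glm_family))
  }
  powers <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)
  dev1 <- vapply(powers, function(p) dev_of(fp_basis(xs, p)), 0)
  best1 <- powers[which.min(dev1)]
  pairs <- expand.grid(p1 = powers, p2 = powers)
  pairs <- pairs[pairs$p1 <= pairs$p2, ]
  dev2 <- mapply(function(p1, p2) dev_of(fp_basis(xs, c(p1, p2))),
                 pairs$p1, pairs$p2)
  best2 <- unlist(pairs[which.min(dev2), ])
  d_lin <- dev_of(matrix(xs, ncol = 1))
  p_fp2_lin <- stats::pchisq(d_lin - min(dev2), df = 3, lower.tail = FALSE)
  p_fp2_fp1 <- stats::pchisq(min(dev1) - min(dev2), df = 2, lower.tail = FALSE)
  tests <- data.frame(
    comparison = c("FP2 vs linear", "FP2 vs FP1"),
    chisq = c(d_lin - min(dev2), min(dev1) - min(dev2)),
    df = c(3, 2), p = c(p_fp2_lin, p_fp2_fp1))
  if (p_fp2_lin >= alpha)
    res <- list(form = "linear", powers = 1)
  else if (p_fp2_fp1 < alpha)
    res <- list(form = "FP2", powers = unname(best2))
  else
    res <- list(form = "FP1", powers = best1)
  c(res, list(shift = shift, tests = tests))
}

#' Riley minimum-sample-size criteria for prediction models
#'
#' For a binary outcome the three criteria are: (1) expected uniform
#' shrinkage at least `target_shrinkage` via
#' `n = p / ((S - 1) ln(1 - R2cs / S))`; (2) small optimism (0.05) in
#' apparent vs adjusted Nagelkerke R-squared, via the same formula with
#' `S = R2cs / (R2cs + 0.05 * max R2cs)`; (3) precise estimation of the
#' overall outcome proportion, `n >= (1.96 / 0.05)^2 phi (1 - phi)`.  For a
#' continuous outcome the analogues are the shrinkage criterion, optimism
#' `<= 0.05` in adjusted R-squared (`n >= p (1 - R2) / 0.05 + p + 1`), and
#' precise residual-variance estimation (`n >= 234 + p`).
#'
#' @param family `"logistic"` or `"linear"`.
#' @param n Available sample size.
#' @param outcome_summary Outcome prevalence (binary) or outcome SD
#'   (continuous; enters only through the reported assumptions).
#' @param anticipated_R2cs Anticipated Cox-Snell R-squared in (0, 1).
#' @param target_shrinkage Target expected shrinkage in (0.5, 1), default 0.9.
#' @return A list of class `sample_size_result` with `max_parameters` (the
#'   largest parameter count satisfying every criterion at `n`), the
#'   per-criterion required `n` evaluated at `max_parameters`, and the
#'   assumptions.
#' @export
riley_max_parameters <- function(family = c("logistic", "linear"), n,
                                 outcome_summary, anticipated_R2cs,
                                 target_shrinkage = 0.9) {
  family <- match.arg(family)
  stopifnot(anticipated_R2cs > 0, anticipated_R2cs < 1,
            target_shrinkage > 0.5, target_shrinkage < 1, n >= 1)
  R2 <- anticipated_R2cs; S <- target_shrinkage
  n1_of_p <- function(p, s) p / ((s - 1) * log(1 - R2 / s))
  if (family == "logistic") {
    phi <- outcome_summary
    stopifnot(phi > 0, phi < 1)
    maxR2 <- 1 - exp(2 * (phi * log(phi) + (1 - phi) * log(1 - phi)))
    S2 <- R2 / (R2 + 0.05 * maxR2)
    n3 <- (1.96 / 0.05)^2 * phi * (1 - phi)
    pmax1 <- floor(n * (S - 1) * log(1 - R2 / S))
    pmax2 <- floor(n * (S2 - 1) * log(1 - R2 / S2))
    max_p <- if (n < n3) 0L else max(0L, min(pmax1, pmax2))
    crit <- c(shrinkage = ceiling(n1_of_p(max(max_p, 1), S)),
              optimism = ceiling(n1_of_p(max(max_p, 1), S2)),
              outcome_proportion = ceiling(n3))
  } else {
    pmax1 <- floor(n * (S - 1) * log(1 - R2 / S))
    pmax2 <- floor((n - 1) / (1 + (1 - R2) / 0.05))
    pmax3 <- floor(n - 234)
    max_p <- max(0L, min(pmax1, pmax2, pmax3))
    crit <- c(shrinkage = ceiling(n1_of_p(max(max_p, 1), S)),
              optimism = ceiling(max(max_p, 1) * (1 - R2) / 0.05 + max(max_p, 1) + 1),
              residual_variance = 234 + max(max_p, 1))
  }
  structure(list(family = family, n = as.integer(n),
                 max_parameters = as.integer(max_p),
                 required_n = crit, required_n_overall = max(crit),
                 assumptions = list(anticipated_R2cs = R2,
                                    target_shrinkage = S,
                                    outcome_summary = outcome_summary)),
            class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat(sprintf("Riley criteria (%s outcome), n = %d: up to %d predictor parameters\n",
              x$family, x$n, x$max_parameters))
  cat("required n by criterion at that p:\n")
  print(x$required_n)
  invisible(x)
}
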