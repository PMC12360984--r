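# Internal-external cross-validation (IECV): leave one study out, run the
# full development procedure (multilevel fit, cycle-specific heuristic
# shrinkage, intercept re-estimation, Rubin pooling across imputations) on
# the remaining studies, validate in the omitted study, and pool per-cycle
# performance by random-effects meta-analysis.

# normalise input: an ipd_stack becomes a single-"imputation" set
as_imputation_list <- function(x) {
  if (inherits(x, "imputation_set")) return(x$completed)
  if (inherits(x, "ipd_stack")) return(list(x))
  stop("expected an ipd_stack or imputation_set", call. = FALSE)
}

# full development procedure on a list of completed stacks (one per
# imputation): per-imputation fit and shrinkage, Rubin pooling, uniform
# shrinkage of the pooled coefficients, per-imputation intercept
# re-estimation with the shrunken linear predictor as offset, pooling of the
# re-estimated intercepts
develop_model <- function(completed, outcome, terms = model_terms(outcome),
                          nAGQ = 7) {
  fits <- lapply(completed, fit_multilevel, outcome = outcome, terms = terms,
                 nAGQ = nAGQ)
  shr <- vapply(fits, heuristic_shrinkage, 0)
  S <- mean(shr)
  pooled <- pool_across_imputations(fits)
  # the deployed cycle/final models are scored with the random effect at
  # zero, so their constant is the population-averaged (marginal) intercept
  refits <- lapply(seq_along(completed), function(i) {
    base <- pooled
    base$shrunken <- FALSE
    apply_shrinkage_and_reestimate(base, S, completed[[i]], nAGQ = nAGQ,
                                   intercept_method = "marginal")
  })
  final <- pooled
  final$terms$estimate <- S * pooled$terms$estimate
  final$terms$se <- S * pooled$terms$se
  if (length(refits) == 1) {
    final$intercept <- refits[[1]]$intercept
    final$intercept_se <- refits[[1]]$intercept_se
  } else {
    ri <- rubin_pool(vapply(refits, `[[`, 0, "intercept"),
                     vapply(refits, function(x) x$intercept_se^2, 0))
    final$intercept <- ri$estimate
    final$intercept_se <- ri$se
  }
  final$random_intercept_sd <-
    mean(vapply(refits, `[[`, 0, "random_intercept_sd"))
  final$shrinkage <- S
  final$shrunken <- TRUE
  final$m <- length(completed)
  final
}

# evaluate a model on validation rows of each completed stack and Rubin-pool
# the metrics across imputations on their pooling scales
evaluate_model <- function(model, completed, rows, outcome, study_label) {
  metrics <- if (model$family == "logistic")
    c("c_statistic", "calibration_slope", "citl", "oe_ratio")
  else c("calibration_slope", "citl")
  # a metric that cannot be computed in a validation set (e.g. no events)
  # is reported as missing and later excluded from the meta-analysis
  safe <- function(expr) tryCatch(expr, error = function(e)
    new_performance_estimate("unavailable", NA_real_, NA_real_))
  per_imp <- lapply(completed, function(stk) {
    df <- as.data.frame(stk)[rows, , drop = FALSE]
    df <- df[!is.na(df[[outcome]]), , drop = FALSE]
    y <- df[[outcome]]
    lp <- model_lp(model, df)
    ests <- list()
    if (model$family == "logistic") {
      p <- stats::plogis(lp)
      ests$c_statistic <- safe(c_statistic(y, p))
      ests$calibration_slope <- safe(calibration_slope(y, lp, "logistic"))
      ests$citl <- safe(citl(y, lp, "logistic"))
      ests$oe_ratio <- safe(oe_ratio(y, p))
    } else {
      ests$calibration_slope <- safe(calibration_slope(y, lp, "linear"))
      ests$citl <- safe(citl(y, lp, "linear"))
    }
    ests
  })
  n <- per_imp[[1]][[1]]$n
  events <- per_imp[[1]][[1]]$events
  out <- lapply(metrics, function(mt) {
    tr <- pooling_transform(mt)
    vals <- lapply(per_imp, function(e) {
      x <- e[[mt]]
      if (is.na(x$se) || (mt == "c_statistic" && (x$estimate <= 0 || x$estimate >= 1)))
        return(c(NA_real_, NA_real_))
      t <- tr$fwd(x$estimate, x$se)
      c(t$est, t$se)
    })
    V <- do.call(rbind, vals)
    if (anyNA(V)) {
      return(data.frame(study_id = study_label, metric = mt,
                        estimate = per_imp[[1]][[mt]]$estimate,
                        se = NA_real_, est_trans = NA_real_,
                        se_trans = NA_real_,
                        scale = if (mt %in% c("c_statistic")) "logit"
                                else if (mt == "oe_ratio") "log" else "natural",
                        n = n, events = events))
    }
    rp <- if (nrow(V) == 1)
      list(estimate = V[1, 1], se = V[1, 2])
    else suppressWarnings(rubin_pool(V[, 1], V[, 2]^2))
    data.frame(study_id = study_label, metric = mt,
               estimate = tr$bwd(rp$estimate), se = rp$se,
               est_trans = rp$estimate, se_trans = rp$se,
               scale = if (mt == "c_statistic") "logit"
                       else if (mt == "oe_ratio") "log" else "natural",
               n = n, events = events)
  })
  do.call(rbind, out)
}

#' Internal-external cross-validation with performance meta-analysis
#'
#' Omits one study in turn, runs the full development procedure on the
#' remaining studies, and validates the cycle model in the omitted study
#' using the average intercept (study random effect set to zero).  With
#' multiply imputed input, per-imputation metrics are pooled by Rubin's
#' rules within each cycle; per-cycle statistics are then combined by
#' random-effects meta-analysis.  Apparent performance (the final model
#' applied back to the full development data, ignoring clustering) is also
#' computed.  With only two studies, IECV is refused and apparent
#' performance alone is returned.
#'
#' @param x An [ipd_stack()] without missing predictor cells, or an
#'   `imputation_set` from [impute_joint()].
#' @param outcome Outcome column name.
#' @param terms Design-matrix terms (default [model_terms()]).
#' @param nAGQ Quadrature points for logistic fits.
#' @param meta_method Between-study variance estimator for the performance
#'   meta-analysis (`"REML"` default, `"DL"` optional).
#' @param min_events Held-out studies with fewer events are flagged
#'   `unstable` (binary outcomes; cycles are still computed).
#' @return An object of class `iecv_result` with elements `cycles` (per
#'   held-out study: cycle model and pooled metrics), `metrics` (per-cycle
#'   metric table), `pooled` (per metric: [random_effects_meta()] result),
#'   `apparent` (metric table for apparent performance) and `final_model`.
#' @export
run_iecv <- function(x, outcome, terms = model_terms(outcome), nAGQ = 7,
                     meta_method = c("REML", "DL"), min_events = 10) {
  meta_method <- match.arg(meta_method)
  completed <- as_imputation_list(x)
  first <- completed[[1]]
  has_outcome <- tapply(!is.na(first[[outcome]]), first$study_id, any)
  cycle_studies <- names(has_outcome)[has_outcome]
  k <- length(cycle_studies)
  if (k < 2) stop("IECV requires at least two studies with the outcome")

  all_rows <- as.character(first$study_id) %in% cycle_studies
  sub <- function(stk, keep) as_ipd_stack(as.data.frame(stk)[keep, , drop = FALSE], stk)
  dev_all <- lapply(completed, sub, keep = all_rows)
  final_model <- develop_model(dev_all, outcome, terms, nAGQ)
  apparent <- evaluate_model(final_model, dev_all,
                             rows = rep(TRUE, sum(all_rows)), outcome,
                             study_label = "apparent")
  apparent$flags <- "apparent"

  if (k == 2) {
    message("only two studies record ", outcome,
            ": IECV not performed, returning apparent performance only")
    return(structure(list(outcome = outcome, cycles = NULL, metrics = NULL,
                          pooled = NULL, apparent = apparent,
                          final_model = final_model, k = k),
                     class = "iecv_result"))
  }

  cycles <- list(); metric_rows <- list()
  for (s in cycle_studies) {
    dev_keep <- all_rows & as.character(first$study_id) != s
    val_rows_local <- as.character(first$study_id) == s
    dev <- lapply(completed, sub, keep = dev_keep)
    cyc_model <- develop_model(dev, outcome, terms, nAGQ)
    mt <- evaluate_model(cyc_model, completed, rows = val_rows_local,
                         outcome, study_label = s)
    flags <- character(0)
    if (final_model$family == "logistic" &&
        isTRUE(mt$events[1] < min_events)) flags <- "unstable"
    mt$flags <- paste(flags, collapse = ";")
    cycles[[s]] <- list(model = cyc_model, performance = mt)
    metric_rows[[s]] <- mt
  }
  metrics <- do.call(rbind, c(metric_rows, make.row.names = FALSE))

  pooled <- list()
  for (mt in unique(metrics$metric)) {
    rows <- metrics[metrics$metric == mt & !is.na(metrics$se_trans), ]
    dropped <- setdiff(cycle_studies, rows$study_id)
    if (length(dropped))
      message(mt, ": cycle(s) ", paste(dropped, collapse = ", "),
              " excluded from meta-analysis (metric unavailable)")
    pooled[[mt]] <- random_effects_meta(rows$est_trans, rows$se_trans,
                                        method = meta_method, metric = mt)
  }
  structure(list(outcome = outcome, cycles = cycles, metrics = metrics,
                 pooled = pooled, apparent = apparent,
                 final_model = final_model, k = k),
            class = "iecv_result")
}

#' @export
print.iecv_result <- function(x, ...) {
  cat(sprintf("IECV of the %s model: %d studies\n", x$outcome, x$k))
  if (!is.null(x$pooled)) {
    for (mt in names(x$pooled)) {
      p <- x$pooled[[mt]]
      tr <- pooling_transform(mt)
      cat(sprintf("  pooled %s: %.3f (95%% CI %.3f-%.3f, tau^2 = %.4f)\n",
                  mt, tr$bwd(p$pooled), tr$bwd(p$ci_low), tr$bwd(p$ci_high),
                  p$tau2))
    }
  } else cat("  apparent performance only (two studies)\n")
  invisible(x)
}

#' Random-effects meta-analysis of a performance statistic
#'
#' Pools per-cycle performance estimates with between-study variance
#' \eqn{\tau^2} estimated by REML (DerSimonian-Laird available as an
#' option); the pooled value is the inverse-variance weighted mean with
#' weights \eqn{1/(se^2 + \tau^2)} and the 95% CI uses the Hartung-Knapp
#' adjustment with a t(k-1) reference (a plain Wald interval under
#' `"DL"`).
#'
#' @param estimates Per-cycle estimates (already on the pooling scale).
#' @param ses Their standard errors (positive).
#' @param method `"REML"` (default) or `"DL"`.
#' @param metric Optional metric label carried through.
#' @param hartung_knapp Use the Hartung-Knapp CI adjustment (default TRUE
#'   for REML, FALSE for DL to match the classical estimator).
#' @return A list of class `meta_result`: `metric`, `pooled`, `ci_low`,
#'   `ci_high`, `se`, `tau2`, `k`, `q_stat`, `method`.  With `k = 1` the
#'   single estimate is passed through with an infinite-width CI flag.
#' @export
random_effects_meta <- function(estimates, ses, method = c("REML", "DL"),
                                metric = NULL, hartung_knapp = NULL) {
  method <- match.arg(method)
  if (is.null(hartung_knapp)) hartung_knapp <- method == "REML"
  stopifnot(length(estimates) == length(ses))
  k <- length(estimates)
  if (k == 1) {
    warning("k = 1: pass-through with infinite-width CI")
    return(structure(list(metric = metric, pooled = estimates, se = ses,
                          ci_low = -Inf, ci_high = Inf, tau2 = NA_real_,
                          k = 1L, q_stat = NA_real_, method = method,
                          flags = "single_cycle"), class = "meta_result"))
  }
  stopifnot(all(ses > 0))
  if (stats::var(estimates) < 1e-14) {
    # identical inputs: tau^2 is exactly 0, pooled is the common value
    pooled <- estimates[1]
    se <- sqrt(1 / sum(1 / ses^2))
    tq <- if (hartung_knapp) stats::qt(0.975, k - 1) else 1.96
    return(structure(list(metric = metric, pooled = pooled, se = se,
                          ci_low = pooled - tq * se, ci_high = pooled + tq * se,
                          tau2 = 0, k = as.integer(k),
                          q_stat = 0, method = method, flags = character(0)),
                     class = "meta_result"))
  }
  fit <- withCallingHandlers(
    metafor::rma(yi = estimates, sei = ses, method = method,
                 test = if (hartung_knapp) "knha" else "z"),
    warning = function(w) {
      # informational note from metafor when the REML profile is flat and
      # tau^2 is set to 0; the result is still valid
      if (grepl("Fisher scoring|local maximum", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(metric = metric, pooled = as.numeric(fit$b),
                 se = fit$se, ci_low = fit$ci.lb, ci_high = fit$ci.ub,
                 tau2 = fit$tau2, k = as.integer(k), q_stat = fit$QE,
                 method = method, flags = character(0)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta (%s%s): pooled %.4f [%.4f, %.4f], tau^2 = %.4f, k = %d\n",
              x$method, if (!is.null(x$metric)) paste0(", ", x$metric) else "",
              x$pooled, x$ci_low, x$ci_high, x$tau2, x$k))
  invisible(x)
}

#' Forest-plot data for one IECV metric
#'
#' Per-cycle estimates with 95% CIs plus the pooled row with \eqn{\tau^2},
#' back-transformed to the natural scale for metrics pooled on the logit
#' (C-statistic) or log (O/E) scale.
#'
#' @param result An `iecv_result`.
#' @param metric Metric name present in every cycle.
#' @return Data frame with columns `study_id`, `estimate`, `ci_low`,
#'   `ci_high`, `pooled` (logical) and `tau2` (pooled row only).
#' @export
forest_data <- function(result, metric) {
  stopifnot(inherits(result, "iecv_result"))
  if (is.null(result$metrics)) stop("no IECV cycles available")
  mt <- result$metrics[result$metrics$metric == metric, ]
  if (!nrow(mt)) stop("metric not found: ", metric)
  tr <- pooling_transform(metric)
  rows <- data.frame(study_id = mt$study_id,
                     estimate = mt$estimate,
                     ci_low = tr$bwd(mt$est_trans - 1.96 * mt$se_trans),
                     ci_high = tr$bwd(mt$est_trans + 1.96 * mt$se_trans),
                     pooled = FALSE, tau2 = NA_real_)
  p <- result$pooled[[metric]]
  rbind(rows, data.frame(study_id = "pooled", estimate = tr$bwd(p$pooled),
                         ci_low = tr$bwd(p$ci_low), ci_high = tr$bwd(p$ci_high),
                         pooled = TRUE, tau2 = p$tau2))
}

#' Apparent performance of a model on its development data
#'
#' Applies the model directly back to the pooled development data, without
#' any adjustment for optimism and ignoring the clustering of participants
#' within studies.
#'
#' @param model A `wa_model`.
#' @param stack Development data ([ipd_stack()] or `imputation_set`).
#' @param outcome Outcome column name.
#' @return Metric table (data frame) flagged `"apparent"`.
#' @export
apparent_performance <- function(model, stack, outcome = model$outcome) {
  completed <- as_imputation_list(stack)
  if (!nrow(completed[[1]])) stop("empty stack", call. = FALSE)
  out <- evaluate_model(model, completed, rows = rep(TRUE, nrow(completed[[1]])),
                        outcome, study_label = "apparent")
  out$flags <- "apparent"
  out
}
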