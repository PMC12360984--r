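#' Outcome-generating ("true") model for synthetic cohorts
#'
#' Defines the data-generating model used by [generate_study()] and
#' [generate_multistudy()]: a fixed-effect coefficient vector over
#' design-matrix terms, an average intercept, a between-study random-intercept
#' SD, and the outcome family.
#'
#' @param family `"logistic"` (binary outcome) or `"linear"` (continuous).
#' @param coefficients Named numeric vector; names must be design-matrix terms
#'   produced by [model_terms()] / [encode_predictors()].
#' @param intercept Average intercept (constant term).
#' @param random_intercept_sd Between-study SD of the study intercepts
#'   (\eqn{\ge 0}).
#' @param residual_sd Residual SD, required for the linear family.
#' @param outcome Name of the outcome column the model generates.
#' @return An object of class `true_model`.
#' @seealso [published_truth()] for the three published coefficient sets.
#' @export
true_model <- function(family = c("logistic", "linear"), coefficients,
                       intercept, random_intercept_sd = 0, residual_sd = NULL,
                       outcome = "absence_6m") {
  family <- match.arg(family)
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            random_intercept_sd >= 0)
  known <- c(model_terms("absence_6m"))
  unknown <- setdiff(names(coefficients), known)
  if (length(unknown))
    stop("unknown coefficient term(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (family == "linear") {
    if (is.null(residual_sd) || residual_sd <= 0)
      stop("linear family requires residual_sd > 0", call. = FALSE)
  }
  structure(list(family = family, coefficients = coefficients,
                 intercept = intercept,
                 random_intercept_sd = random_intercept_sd,
                 residual_sd = residual_sd, outcome = outcome),
            class = "true_model")
}

#' @export
print.true_model <- function(x, ...) {
  cat(sprintf("true_model (%s) for %s: %d terms, intercept %.3f, RE SD %.3f\n",
              x$family, x$outcome, length(x$coefficients), x$intercept,
              x$random_intercept_sd))
  invisible(x)
}

# Published coefficient sets: models to predict any work absence over
# 6 months, presenteeism at 6 months, and any absence over 12 months.
# Constants and random-effect terms were re-estimated after shrinkage, so the
# stored coefficients are final (post-shrinkage) values.
.published <- local({
  terms13 <- c("age", "female", "multisite_pain", "pain_score",
               "pain_duration_3_6m", "pain_duration_7_12m",
               "pain_duration_gt12m", "job_intermediate", "job_manual",
               "anxiety_depression", "comorbidity", "prior_absence_6m",
               "baseline_presenteeism")
  terms11 <- setdiff(terms13, c("comorbidity", "prior_absence_6m"))
  list(
    absence_6m = list(
      family = "logistic",
      coefficients = stats::setNames(
        c(-0.016, -0.307, -0.141, 0.127, 0.308, 0.008, 0.432, -0.015, -0.315,
          0.370, -0.024, 1.465, 0.250), terms13),
      intercept = -3.493, random_intercept_sd = 0.794, shrinkage = 0.9464,
      caveat = NULL),
    presenteeism_6m = list(
      family = "linear",
      coefficients = stats::setNames(
        c(-0.016, -0.124, -0.028, 0.198, 0.067, 0.186, 0.722, 0.212, 0.387,
          0.317, 0.424, 0.252, 0.375), terms13),
      intercept = 0.309, random_intercept_sd = 0.118, shrinkage = 0.9746,
      caveat = NULL),
    absence_12m = list(
      family = "logistic",
      coefficients = stats::setNames(
        c(-0.005, 0.003, 0.172, 0.101, -0.760, -0.308, 0.061, 0.534, 0.452,
          0.457, 0.129), terms11),
      intercept = -2.533, random_intercept_sd = 0.613, shrinkage = 0.7832,
      caveat = paste("Developed on 408 participants from two studies, below",
                     "the minimum sample size; poorly calibrated on",
                     "validation and not ready for use in practice."))
  )
})

#' Published outcome models as data-generating truth
#'
#' Returns one of the three published coefficient sets as a [true_model()],
#' for use in simulation studies (parameter recovery, IECV self-consistency).
#' For the linear presenteeism model a residual SD must be assumed because
#' the publication does not report one; the default of 2.5 is consistent with
#' the spread of observed 6-month presenteeism scores (median 3, IQR 1-6)
#' after accounting for the predictors.
#'
#' @param name `"absence_6m"`, `"presenteeism_6m"` or `"absence_12m"`.
#' @param residual_sd Residual SD for the linear family (default 2.5).
#' @return A [true_model()].
#' @export
published_truth <- function(name = c("absence_6m", "presenteeism_6m",
                                     "absence_12m"), residual_sd = 2.5) {
  name <- match.arg(name)
  p <- .published[[name]]
  true_model(family = p$family, coefficients = p$coefficients,
             intercept = p$intercept,
             random_intercept_sd = p$random_intercept_sd,
             residual_sd = if (p$family == "linear") residual_sd else NULL,
             outcome = name)
}
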