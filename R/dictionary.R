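#' Data dictionary for the MSD work-outcome IPD
#'
#' Returns the canonical description of the ten baseline predictors and the
#' three work outcomes used throughout the package: column names, types,
#' units, level codes and admissible ranges.  The dictionary is attached to
#' every [ipd_stack()] and drives CSV round-trips, input validation and the
#' design-matrix encoding.
#'
#' Predictors are: age (years); sex; multisite pain; baseline pain score
#' (0-10 numerical rating scale); pain duration (four ordered categories);
#' job type (NS-SEC three-class); anxiety/depression; any other comorbidity;
#' work absence in the previous 6 months; and baseline presenteeism (0-10).
#'
#' @return A named list with components `predictors`, `outcomes` (each a named
#'   list of variable descriptors) and `version`.
#' @export
#' @examples
#' names(msd_dictionary()$predictors)
msd_dictionary <- function() {
  cont <- function(unit, range) list(type = "continuous", unit = unit, range = range)
  catg <- function(levels, type = "nominal") list(type = type, levels = levels)
  flag <- list(type = "binary", levels = c("no", "yes"), codes = c(0L, 1L))
  list(
    predictors = list(
      age                   = cont("years", c(16, 75)),
      sex                   = catg(c("male", "female")),
      multisite_pain        = catg(c("single", "multisite")),
      pain_score            = cont("0-10 NRS", c(0, 10)),
      pain_duration         = catg(c("<3 months", "3-6 months", "7-12 months",
                                     ">12 months"), type = "ordinal"),
      job_type              = catg(c("professional/managerial", "intermediate",
                                     "manual")),
      anxiety_depression    = flag,
      comorbidity           = flag,
      prior_absence_6m      = flag,
      baseline_presenteeism = cont("0-10 scale", c(0, 10))
    ),
    outcomes = list(
      absence_6m       = list(type = "binary", levels = c("no", "yes"),
                              codes = c(0L, 1L), family = "logistic"),
      presenteeism_6m  = list(type = "continuous", unit = "0-10 scale",
                              range = c(0, 10), family = "linear"),
      absence_12m      = list(type = "binary", levels = c("no", "yes"),
                              codes = c(0L, 1L), family = "logistic")
    ),
    version = "1"
  )
}

#' Predictor sets and design-matrix terms for each outcome model
#'
#' The 6-month absence and presenteeism models use all ten predictors
#' (13 design-matrix parameters); the 12-month absence model omits
#' comorbidity and prior absence, which were not consistently recorded
#' (8 predictors, 11 parameters).
#'
#' @param outcome One of `"absence_6m"`, `"presenteeism_6m"`, `"absence_12m"`.
#' @return For `model_predictors()`, predictor column names; for
#'   `model_terms()`, design-matrix column names in canonical order.
#' @export
model_predictors <- function(outcome = c("absence_6m", "presenteeism_6m",
                                         "absence_12m")) {
  outcome <- match.arg(outcome)
  p <- names(msd_dictionary()$predictors)
  if (outcome == "absence_12m")
    p <- setdiff(p, c("comorbidity", "prior_absence_6m"))
  p
}

#' @rdname model_predictors
#' @export
model_terms <- function(outcome = c("absence_6m", "presenteeism_6m",
                                    "absence_12m")) {
  outcome <- match.arg(outcome)
  terms <- c(
    age                   = "age",
    sex                   = "female",
    multisite_pain        = "multisite_pain",
    pain_score            = "pain_score",
    pain_duration         = NA, # expands to 3 dummies
    job_type              = NA, # expands to 2 dummies
    anxiety_depression    = "anxiety_depression",
    comorbidity           = "comorbidity",
    prior_absence_6m      = "prior_absence_6m",
    baseline_presenteeism = "baseline_presenteeism"
  )
  out <- character(0)
  for (p in model_predictors(outcome)) {
    out <- c(out, switch(p,
      pain_duration = c("pain_duration_3_6m", "pain_duration_7_12m",
                        "pain_duration_gt12m"),
      job_type = c("job_intermediate", "job_manual"),
      unname(terms[p])))
  }
  out
}

#' Encode predictor columns as a design matrix
#'
#' Expands the predictor columns of an IPD data frame into the canonical
#' design matrix used by all models.  Reference levels are: male sex,
#' single-site pain, pain duration under 3 months, professional/managerial
#' job, and absence of each binary flag.  Continuous predictors enter on
#' their natural scale.
#'
#' @param data A data frame containing the predictor columns.
#' @param terms Design-matrix columns to produce; default all 13.
#' @return A numeric matrix with one row per row of `data` and one column per
#'   term.  Rows with missing predictor values yield `NA` entries.
#' @export
encode_predictors <- function(data, terms = model_terms("absence_6m")) {
  lev <- function(col, level) {
    x <- data[[col]]
    if (is.null(x)) stop("missing predictor column: ", col, call. = FALSE)
    as.numeric(x == level)
  }
  num <- function(col) {
    x <- data[[col]]
    if (is.null(x)) stop("missing predictor column: ", col, call. = FALSE)
    as.numeric(x)
  }
  builders <- list(
    age                   = function() num("age"),
    female                = function() lev("sex", "female"),
    multisite_pain        = function() lev("multisite_pain", "multisite"),
    pain_score            = function() num("pain_score"),
    pain_duration_3_6m    = function() lev("pain_duration", "3-6 months"),
    pain_duration_7_12m   = function() lev("pain_duration", "7-12 months"),
    pain_duration_gt12m   = function() lev("pain_duration", ">12 months"),
    job_intermediate      = function() lev("job_type", "intermediate"),
    job_manual            = function() lev("job_type", "manual"),
    anxiety_depression    = function() num("anxiety_depression"),
    comorbidity           = function() num("comorbidity"),
    prior_absence_6m      = function() num("prior_absence_6m"),
    baseline_presenteeism = function() num("baseline_presenteeism")
  )
  unknown <- setdiff(terms, names(builders))
  if (length(unknown))
    stop("unknown design-matrix term(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  X <- vapply(terms, function(t) builders[[t]](), numeric(nrow(data)))
  if (nrow(data) == 1L) X <- matrix(X, nrow = 1L, dimnames = list(NULL, terms))
  colnames(X) <- terms
  X
}

#' Validate predictor values against the data dictionary
#'
#' Checks that each supplied predictor column has admissible values: factors
#' or labels within the declared level sets, binary flags coded 0/1, and
#' continuous scores within their instrument range.  `NA` cells are permitted
#' (they represent missing data).
#'
#' @param data Data frame of predictor columns.
#' @param predictors Predictor names to check (default: those present).
#' @return Invisibly `TRUE`; errors describe the first offending column.
#' @export
validate_predictors <- function(data, predictors = NULL) {
  dict <- msd_dictionary()$predictors
  if (is.null(predictors))
    predictors <- intersect(names(dict), names(data))
  for (p in predictors) {
    d <- dict[[p]]
    x <- data[[p]]
    if (is.null(x)) stop("missing predictor column: ", p, call. = FALSE)
    x <- x[!is.na(x)]
    if (!length(x)) next
    if (d$type %in% c("nominal", "ordinal")) {
      bad <- !(as.character(x) %in% d$levels)
      if (any(bad))
        stop("invalid level(s) for ", p, ": ",
             paste(unique(as.character(x)[bad]), collapse = ", "),
             call. = FALSE)
    } else if (d$type == "binary") {
      if (!all(x %in% c(0, 1)))
        stop("binary predictor ", p, " must be coded 0/1", call. = FALSE)
    } else {
      if (!is.numeric(x))
        stop("predictor ", p, " must be numeric", call. = FALSE)
      if (p != "age" && (any(x < d$range[1]) || any(x > d$range[2])))
        stop("predictor ", p, " outside [", d$range[1], ", ", d$range[2], "]",
             call. = FALSE)
    }
  }
  invisible(TRUE)
}
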