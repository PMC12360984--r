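# Frozen published coefficient sets as scorers, with strict input
# validation, batch scoring, and JSON serialisation of fitted models.

#' Load a published prognostic model
#'
#' Returns one of the three published coefficient sets as a frozen scorer.
#' The stored coefficients are final (post-shrinkage) values: the constants
#' and random-effect terms were re-estimated after adjustment for optimism,
#' so no shrinkage multiplication happens at scoring time (set
#' `apply_shrinkage = TRUE` to explore the alternative reading in
#' sensitivity analyses).  The 12-month absence model carries a caveat: it
#' was developed on data below the minimum sample size, is poorly
#' calibrated, and is not ready for use in practice.
#'
#' @param name `"absence_6m"`, `"presenteeism_6m"` or `"absence_12m"`.
#' @param apply_shrinkage Multiply the stored coefficients by the stored
#'   shrinkage factor (default `FALSE`; the stored values are already
#'   shrunken).
#' @return A `published_model` (also a `wa_model`).
#' @export
load_published_model <- function(name = c("absence_6m", "presenteeism_6m",
                                          "absence_12m"),
                                 apply_shrinkage = FALSE) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown model \"", name[1], "\"; valid names: absence_6m, ",
         "presenteeism_6m, absence_12m", call. = FALSE))
  p <- .published[[name]]
  est <- if (apply_shrinkage) p$shrinkage * p$coefficients else p$coefficients
  model <- new_wa_model(
    family = p$family, outcome = name,
    terms = data.frame(term = names(p$coefficients), estimate = unname(est),
                       se = NA_real_),
    intercept = p$intercept, intercept_se = NA_real_,
    random_intercept_sd = p$random_intercept_sd,
    n_obs = NA_integer_, n_events = NA_integer_,
    loglik_model = NA_real_, loglik_null = NA_real_,
    p_df = length(p$coefficients), shrinkage = p$shrinkage,
    shrunken = TRUE, provenance = "published", caveat = p$caveat)
  if (!is.null(p$caveat)) message("note: ", p$caveat)
  class(model) <- c("published_model", class(model))
  model
}

# predictor columns required by a model's term set
required_predictors <- function(model) {
  terms <- model$terms$term
  preds <- character(0)
  map <- c(age = "age", female = "sex", multisite_pain = "multisite_pain",
           pain_score = "pain_score", pain_duration_3_6m = "pain_duration",
           pain_duration_7_12m = "pain_duration",
           pain_duration_gt12m = "pain_duration",
           job_intermediate = "job_type", job_manual = "job_type",
           anxiety_depression = "anxiety_depression",
           comorbidity = "comorbidity", prior_absence_6m = "prior_absence_6m",
           baseline_presenteeism = "baseline_presenteeism")
  unique(unname(map[terms]))
}

# canonicalise one or more profiles: accept level labels or integer codes
canonicalise_profiles <- function(profile, predictors) {
  df <- as.data.frame(profile, stringsAsFactors = FALSE)
  dict <- msd_dictionary()$predictors
  missing_cols <- setdiff(predictors, names(df))
  if (length(missing_cols))
    stop("missing predictor(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (p in predictors) {
    d <- dict[[p]]
    x <- df[[p]]
    if (anyNA(x))
      stop("missing value for predictor: ", p, call. = FALSE)
    if (d$type %in% c("nominal", "ordinal")) {
      if (is.numeric(x)) {
        if (any(x < 1 | x > length(d$levels)))
          stop("out-of-range code for ", p, call. = FALSE)
        x <- d$levels[x]
      }
      if (!all(as.character(x) %in% d$levels))
        stop("invalid level for ", p, ": ",
             paste(setdiff(as.character(x), d$levels), collapse = ", "),
             call. = FALSE)
      df[[p]] <- factor(as.character(x), levels = d$levels,
                        ordered = d$type == "ordinal")
    } else if (d$type == "binary") {
      if (is.character(x)) x <- match(x, d$levels) - 1L
      if (!all(x %in% c(0, 1)))
        stop("binary predictor ", p, " must be 0/1 or no/yes", call. = FALSE)
      df[[p]] <- as.integer(x)
    } else {
      x <- as.numeric(x)
      if (p == "age") {
        if (any(x < d$range[1] | x > d$range[2]))
          warning("age outside [", d$range[1], ", ", d$range[2],
                  "]: extrapolating beyond the working-age development data")
      } else if (any(x < d$range[1] | x > d$range[2])) {
        stop(p, " outside [", d$range[1], ", ", d$range[2], "]",
             call. = FALSE)
      }
      df[[p]] <- x
    }
  }
  df
}

#' Predict risk or expected score for individual profiles
#'
#' Computes the linear predictor of a model for complete patient profiles
#' and returns the predicted probability (logistic models) or expected
#' presenteeism score clipped to the 0-10 instrument range (linear model).
#' New individuals are scored with the average intercept (study random
#' effect zero).  Profiles must be complete for the model's predictors and
#' within the data dictionary's ranges; categorical values may be given as
#' level labels or 1-based integer codes.
#'
#' @param model A `wa_model` or `published_model`.
#' @param profile A named list or data frame of predictor values (one or
#'   more rows).
#' @return Data frame with `linear_predictor` and `risk` (logistic) or
#'   `expected_score` with a `clipped` flag (linear).
#' @export
predict_risk <- function(model, profile) {
  stopifnot(inherits(model, "wa_model"))
  preds <- required_predictors(model)
  df <- canonicalise_profiles(profile, preds)
  lp <- model_lp(model, df)
  if (model$family == "logistic")
    data.frame(linear_predictor = lp, risk = stats::plogis(lp))
  else
    data.frame(linear_predictor = lp,
               expected_score = pmin(10, pmax(0, lp)),
               clipped = lp < 0 | lp > 10)
}

#' Batch-score a CSV (or data frame) of profiles
#'
#' Validates each row against the data dictionary, scores the valid rows,
#' and collects row-level validation errors without aborting the batch.  An
#' identifier column (`id`, if present, else the row number) is carried
#' through.
#'
#' @param model A `wa_model`/`published_model` or a published-model name.
#' @param input Path to a CSV conforming to the data dictionary, or a data
#'   frame.
#' @param output Optional path for the predictions CSV.
#' @return A list with `predictions` (data frame), `errors` (data frame of
#'   row, message) and `n_scored` / `n_failed` counts.
#' @export
score_batch <- function(model, input, output = NULL) {
  if (is.character(model)) model <- load_published_model(model)
  if (is.character(input)) {
    df <- tryCatch(
      utils::read.csv(input, stringsAsFactors = FALSE, na.strings = ""),
      error = function(e) stop("malformed CSV ", input, ": ",
                               conditionMessage(e), call. = FALSE))
  } else df <- as.data.frame(input)
  id <- if ("id" %in% names(df)) df$id else seq_len(nrow(df))
  preds <- required_predictors(model)
  rows <- vector("list", nrow(df)); errs <- list()
  for (i in seq_len(nrow(df))) {
    res <- tryCatch(
      withCallingHandlers(
        predict_risk(model, df[i, , drop = FALSE]),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(row = i, id = as.character(id[i]),
                                              message = conditionMessage(res))
    } else {
      rows[[i]] <- cbind(data.frame(id = id[i]), res)
    }
  }
  predictions <- if (any(!vapply(rows, is.null, TRUE)))
    do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  else {
    cols <- c("id", "linear_predictor",
              if (model$family == "logistic") "risk"
              else c("expected_score", "clipped"))
    as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  errors <- if (length(errs)) do.call(rbind, errs)
  else data.frame(row = integer(0), id = character(0), message = character(0))
  if (!is.null(output))
    utils::write.csv(predictions, output, row.names = FALSE, na = "")
  message(sprintf("scored %d of %d rows (%d failed validation)",
                  nrow(predictions), nrow(df), nrow(errors)))
  list(predictions = predictions, errors = errors,
       n_scored = nrow(predictions), n_failed = nrow(errors))
}

# small polynomial rolling hash of the dictionary JSON, recorded in
# serialised models so a scorer and a data set can be checked for
# dictionary agreement
dictionary_hash <- function(dict = msd_dictionary()) {
  s <- jsonlite::toJSON(dict, auto_unbox = TRUE)
  h <- 7
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Serialise / restore a fitted model as JSON
#'
#' Writes family, ordered terms with estimates and SEs, intercept,
#' random-intercept SD, shrinkage, provenance and a data-dictionary hash.
#' The round trip restores every numeric field bit-exactly.
#'
#' @param model A `wa_model`.
#' @param path File path for the model JSON.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` returns the restored `wa_model`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "wa_model"))
  payload <- list(
    family = model$family, outcome = model$outcome,
    terms = model$terms, intercept = model$intercept,
    intercept_se = model$intercept_se,
    random_intercept_sd = model$random_intercept_sd,
    shrinkage = model$shrinkage, shrunken = model$shrunken,
    provenance = model$provenance, p_df = model$p_df,
    n_obs = model$n_obs, n_events = model$n_events,
    loglik_model = model$loglik_model, loglik_null = model$loglik_null,
    m = model$m, caveat = model$caveat,
    dictionary_hash = dictionary_hash())
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(p$dictionary_hash) && p$dictionary_hash != dictionary_hash())
    warning("model was serialised under a different data dictionary")
  nn <- function(x, cast = identity) if (is.null(x)) NULL else cast(x)
  model <- new_wa_model(
    family = p$family, outcome = p$outcome,
    terms = data.frame(term = p$terms$term, estimate = p$terms$estimate,
                       se = p$terms$se),
    intercept = p$intercept, intercept_se = nn(p$intercept_se, as.numeric),
    random_intercept_sd = p$random_intercept_sd,
    n_obs = nn(p$n_obs, as.integer), n_events = nn(p$n_events, as.integer),
    loglik_model = nn(p$loglik_model, as.numeric),
    loglik_null = nn(p$loglik_null, as.numeric),
    p_df = p$p_df, shrinkage = nn(p$shrinkage, as.numeric),
    shrunken = isTRUE(p$shrunken), provenance = p$provenance,
    m = nn(p$m, as.integer), caveat = nn(p$caveat, as.character))
  if (identical(model$provenance, "published"))
    class(model) <- c("published_model", class(model))
  model
}
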