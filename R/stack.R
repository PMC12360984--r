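#' Multi-study IPD stack
#'
#' An `ipd_stack` is a data frame of per-participant rows from two or more
#' studies sharing one data dictionary: a `study_id` factor, the ten baseline
#' predictor columns, and whichever outcome columns the constituent studies
#' recorded.  Missing cells are `NA`; a predictor that is `NA` for every row
#' of a study is systematically missing in that study.
#'
#' @param data Data frame with a `study_id` column, predictor columns and at
#'   least one outcome column.
#' @param dictionary Data dictionary, by default [msd_dictionary()].
#' @return An object of class `ipd_stack` (also a `data.frame`).
#' @export
ipd_stack <- function(data, dictionary = msd_dictionary()) {
  stopifnot(is.data.frame(data))
  if (is.null(data$study_id)) stop("`data` must have a study_id column")
  data$study_id <- factor(data$study_id, levels = unique(as.character(data$study_id)))
  pred <- intersect(names(dictionary$predictors), names(data))
  if (length(pred) < length(dictionary$predictors))
    stop("missing predictor column(s): ",
         paste(setdiff(names(dictionary$predictors), pred), collapse = ", "))
  out <- intersect(names(dictionary$outcomes), names(data))
  if (!length(out)) stop("at least one outcome column is required")
  validate_predictors(data)
  rownames(data) <- NULL
  structure(data, class = c("ipd_stack", "data.frame"),
            dictionary = dictionary)
}

#' @export
print.ipd_stack <- function(x, ...) {
  tab <- table(x$study_id)
  cat(sprintf("ipd_stack: %d participants in %d studies\n", nrow(x), length(tab)))
  cat("  studies: ", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  outs <- intersect(names(attr(x, "dictionary")$outcomes), names(x))
  cat("  outcomes:", paste(outs, collapse = ", "), "\n")
  miss <- vapply(intersect(names(attr(x, "dictionary")$predictors), names(x)),
                 function(p) mean(is.na(x[[p]])), numeric(1))
  if (any(miss > 0))
    cat("  missing predictor cells: ",
        paste(sprintf("%s %.1f%%", names(miss)[miss > 0], 100 * miss[miss > 0]),
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.ipd_stack <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Study labels of an IPD stack
#' @param stack An [ipd_stack()].
#' @return Character vector of study labels in stack order.
#' @export
study_ids <- function(stack) levels(stack$study_id)

#' Outcome columns present in an IPD stack
#' @inheritParams study_ids
#' @return Character vector of outcome column names.
#' @export
stack_outcomes <- function(stack)
  intersect(names(attr(stack, "dictionary")$outcomes), names(stack))

#' Write / read an IPD stack as stacked CSV plus JSON data dictionary
#'
#' The stacked CSV has one row per participant with a `study_id` column;
#' missing cells are written as empty fields.  `write_ipd()` also writes one
#' CSV per study and a machine-readable dictionary JSON naming each column,
#' its type, unit and level codes.
#'
#' @param stack An [ipd_stack()].
#' @param dir Output directory (created if needed).
#' @return `write_ipd()` returns the directory invisibly; `read_ipd()`
#'   returns an [ipd_stack()].
#' @export
write_ipd <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame(stack)
  utils::write.csv(df, file.path(dir, "ipd_stacked.csv"), row.names = FALSE,
                   na = "")
  for (s in study_ids(stack))
    utils::write.csv(df[df$study_id == s, , drop = FALSE],
                     file.path(dir, paste0("study_", gsub("[^A-Za-z0-9_-]", "_", s), ".csv")),
                     row.names = FALSE, na = "")
  dict <- attr(stack, "dictionary")
  jsonlite::write_json(dict, file.path(dir, "dictionary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_ipd
#' @param path Path to a stacked CSV written by `write_ipd()`.
#' @export
read_ipd <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "ipd_stacked.csv")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  dict <- msd_dictionary()
  for (p in names(dict$predictors)) {
    d <- dict$predictors[[p]]
    if (is.null(df[[p]])) next
    if (d$type %in% c("nominal", "ordinal"))
      df[[p]] <- factor(df[[p]], levels = d$levels,
                        ordered = d$type == "ordinal")
  }
  ipd_stack(df, dict)
}

# internal: rebuild the class/attributes after data-frame surgery
as_ipd_stack <- function(df, template) {
  structure(as.data.frame(df), class = c("ipd_stack", "data.frame"),
            dictionary = attr(template, "dictionary"))
}
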