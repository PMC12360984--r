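# Multilevel joint-model multiple imputation.
#
# A latent-Gaussian joint model over all predictors (and the available
# outcome columns, included for congeniality with the analysis models):
# continuous variables are modelled directly after standardisation;
# binary and ordinal variables through latent normals with fixed thresholds.
# Study-level random effects on the variable means account for clustering
# and allow between-study heterogeneity; a predictor that is systematically
# missing in a study is imputed by borrowing information across studies
# through the random-effect distribution.  Estimation is by a Gibbs sampler
# with conjugate inverse-Wishart updates for the residual and random-effect
# covariances; completed data sets are taken at thinned intervals after
# burn-in.

# variable schema for the latent joint model
impute_schema <- function(stack) {
  dict <- attr(stack, "dictionary")
  if (is.null(dict)) dict <- msd_dictionary()
  vars <- list()
  add <- function(name, kind, levels = NULL, round_out = FALSE, clip = NULL) {
    vars[[name]] <<- list(name = name, kind = kind, levels = levels,
                          round_out = round_out, clip = clip)
  }
  for (p in names(dict$predictors)) {
    d <- dict$predictors[[p]]
    if (d$type == "continuous")
      add(p, "cont", round_out = p != "age",
          clip = if (p == "age") c(16, 75) else d$range)
    else if (d$type == "binary") add(p, "cat", levels = c("0", "1"))
    else add(p, "cat", levels = d$levels)
  }
  for (o in intersect(names(dict$outcomes), names(stack))) {
    d <- dict$outcomes[[o]]
    if (d$type == "continuous") add(o, "cont", clip = d$range)
    else add(o, "cat", levels = c("0", "1"))
  }
  vars
}

# numeric category codes (1-based) or standardized values; returns list with
# matrix Y (NA = missing), and per-variable centre/scale for continuous
code_variables <- function(stack, schema) {
  n <- nrow(stack)
  q <- length(schema)
  Y <- matrix(NA_real_, n, q, dimnames = list(NULL, names(schema)))
  centre <- scale <- stats::setNames(rep(NA_real_, q), names(schema))
  for (v in names(schema)) {
    s <- schema[[v]]
    x <- stack[[v]]
    if (s$kind == "cont") {
      x <- as.numeric(x)
      mu <- mean(x, na.rm = TRUE); sd <- stats::sd(x, na.rm = TRUE)
      if (!is.finite(sd) || sd < 1e-9) sd <- 1
      centre[v] <- mu; scale[v] <- sd
      Y[, v] <- (x - mu) / sd
    } else {
      if (is.factor(x)) x <- as.integer(x)
      else x <- as.integer(x) + 1L  # 0/1 flags -> 1/2
      Y[, v] <- x
    }
  }
  list(Y = Y, centre = centre, scale = scale)
}

# interior thresholds for an L-level latent variable: 0, 1, ..., L-2
cat_cuts <- function(L) if (L == 2) 0 else seq(0, L - 2)

riwish <- function(nu, S) {
  W <- stats::rWishart(1, nu, chol2inv(chol(S)))[, , 1]
  chol2inv(chol(W))
}

# truncated-normal draws, vectorised, with numerical guards
rtruncnorm_vec <- function(mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  plo <- pmin(pmax(plo, 0), 1 - 1e-12)
  phi <- pmax(pmin(phi, 1), plo + 1e-12)
  u <- stats::runif(length(mean), plo, phi)
  stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12), mean, sd)
}

#' Multilevel joint-model multiple imputation
#'
#' Imputes missing predictor cells of a multi-study IPD stack under a joint
#' latent-Gaussian model with study-level random effects (see the package
#' vignette for the model).  Outcome columns present in the stack enter the
#' joint model as additional variables so that imputations condition on the
#' outcome.  A predictor that is systematically missing in a study is
#' imputed by borrowing information across studies; a predictor missing in
#' every study is unidentifiable and raises an error.
#'
#' @param stack An [ipd_stack()].
#' @param m Number of imputations (default 10, \eqn{\ge 2}).
#' @param burn_in Gibbs burn-in iterations (default 1000).
#' @param thin Iterations between retained completed data sets (default 100).
#' @param seed Integer seed; the sampler is reproducible for a fixed seed.
#' @return An object of class `imputation_set`: list with `completed` (a
#'   list of `m` completed [ipd_stack()]s sharing the row order of the
#'   input), `m`, and `sampler_trace` (per-iteration summaries of the
#'   variable means and residual variances).
#' @export
impute_joint <- function(stack, m = 10, burn_in = 1000, thin = 100,
                         seed = 1L) {
  stopifnot(inherits(stack, "ipd_stack"), m >= 2, burn_in >= 1, thin >= 1)
  dict <- attr(stack, "dictionary")
  preds <- intersect(names(msd_dictionary()$predictors), names(stack))
  n_missing <- vapply(preds, function(p) sum(is.na(stack[[p]])), 0)
  all_missing <- preds[vapply(preds, function(p) all(is.na(stack[[p]])), TRUE)]
  if (length(all_missing))
    stop("predictor(s) missing in every study are unidentifiable: ",
         paste(all_missing, collapse = ", "), call. = FALSE)
  input_na <- lapply(stats::setNames(preds, preds),
                     function(p) is.na(stack[[p]]))
  if (sum(n_missing) == 0) {
    return(structure(list(completed = rep(list(stack), m), m = as.integer(m),
                          sampler_trace = NULL, seed = seed,
                          input_na = input_na),
                     class = "imputation_set"))
  }

  schema <- impute_schema(stack)
  cd <- code_variables(stack, schema)
  Y <- cd$Y
  n <- nrow(Y); q <- ncol(Y)
  vn <- colnames(Y)
  kinds <- vapply(schema, `[[`, "", "kind")
  cuts <- lapply(schema, function(s)
    if (s$kind == "cat") cat_cuts(length(s$levels)) else NULL)
  study <- as.integer(droplevels(factor(stack$study_id)))
  J <- max(study)
  obs <- !is.na(Y)

  # latent matrix initialisation: category c starts at its cell midpoint
  # (c - 1.5 under cuts 0..L-2); missing cells start at 0
  Z <- Y
  for (k in seq_len(q)) {
    init <- if (kinds[k] == "cat") Y[, k] - 1.5 else Y[, k]
    Z[, k] <- ifelse(obs[, k], init, 0)
  }

  mu <- colMeans(Z)
  U <- matrix(0, J, q)
  Sigma <- diag(q); Psi <- diag(0.1, q)
  nu0 <- q + 2; S0 <- diag(q)
  nu0p <- q + 2; S0p <- diag(0.1, q)

  n_iter <- burn_in + m * thin
  keep_at <- burn_in + seq_len(m) * thin
  completed <- vector("list", m)
  trace <- matrix(NA_real_, floor(n_iter / 10), 1 + 2 * q)
  tr_row <- 0L

  restore_pd <- function(M) {
    ok <- tryCatch({ chol(M); TRUE }, error = function(e) FALSE)
    if (!ok) {
      message("non-positive-definite working covariance: jittered restart")
      M <- M + diag(1e-6 * max(diag(M)), nrow(M))
    }
    M
  }

  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      Sigma <- restore_pd(Sigma)
      Urow <- U[study, , drop = FALSE]
      # (a) latent / missing cells, column by column
      for (k in seq_len(q)) {
        Skk <- Sigma[k, k]
        Bk <- solve(Sigma[-k, -k, drop = FALSE], Sigma[-k, k])
        vk <- max(Skk - sum(Sigma[k, -k] * Bk), 1e-10)
        Rk <- sweep(Z[, -k, drop = FALSE], 2, mu[-k]) - Urow[, -k, drop = FALSE]
        mk <- mu[k] + Urow[, k] + drop(Rk %*% Bk)
        if (kinds[k] == "cont") {
          miss <- !obs[, k]
          if (any(miss))
            Z[miss, k] <- stats::rnorm(sum(miss), mk[miss], sqrt(vk))
        } else {
          ck <- c(-Inf, cuts[[k]], Inf)
          o <- obs[, k]
          if (any(o)) {
            cat_idx <- Y[o, k]
            Z[o, k] <- rtruncnorm_vec(mk[o], sqrt(vk),
                                      ck[cat_idx], ck[cat_idx + 1L])
          }
          if (any(!o))
            Z[!o, k] <- stats::rnorm(sum(!o), mk[!o], sqrt(vk))
        }
      }
      # (b) study random effects
      SigInv <- chol2inv(chol(Sigma))
      PsiInv <- chol2inv(chol(restore_pd(Psi)))
      for (j in seq_len(J)) {
        rows <- study == j
        nj <- sum(rows)
        Prec <- nj * SigInv + PsiInv
        ch <- chol(Prec)
        rhs <- SigInv %*% colSums(sweep(Z[rows, , drop = FALSE], 2, mu))
        mean_j <- backsolve(ch, forwardsolve(t(ch), rhs))
        U[j, ] <- mean_j + backsolve(ch, stats::rnorm(q))
      }
      Urow <- U[study, , drop = FALSE]
      # (c) grand means (flat prior)
      E0 <- Z - Urow
      mu <- colMeans(E0) + drop(stats::rnorm(q) %*% chol(Sigma)) / sqrt(n)
      # (d) residual covariance
      E <- sweep(E0, 2, mu)
      Sigma <- riwish(nu0 + n, S0 + crossprod(E))
      # (e) random-effect covariance
      Psi <- riwish(nu0p + J, S0p + crossprod(U))

      if (it %% 10 == 0 && tr_row < nrow(trace)) {
        tr_row <- tr_row + 1L
        trace[tr_row, ] <- c(it, mu, diag(Sigma))
      }
      ki <- match(it, keep_at)
      if (!is.na(ki)) {
        completed[[ki]] <- complete_from_latent(stack, schema, cd, Z, obs)
      }
    }
    NULL
  })
  trace <- as.data.frame(trace[seq_len(tr_row), , drop = FALSE])
  names(trace) <- c("iteration", paste0("mu_", vn), paste0("var_", vn))
  structure(list(completed = completed, m = as.integer(m),
                 sampler_trace = trace, seed = seed, input_na = input_na),
            class = "imputation_set")
}

# map latent matrix back to a completed stack; observed cells are copied
# from the input bit-exactly
complete_from_latent <- function(stack, schema, cd, Z, obs) {
  out <- as.data.frame(stack)
  for (v in names(schema)) {
    s <- schema[[v]]
    miss <- !obs[, v]
    if (!any(miss) || !v %in% names(out)) next
    if (!v %in% names(msd_dictionary()$predictors)) next  # outcomes left as-is
    if (s$kind == "cont") {
      x <- cd$centre[v] + cd$scale[v] * Z[miss, v]
      if (s$round_out) x <- round(x)
      if (!is.null(s$clip)) x <- pmin(s$clip[2], pmax(s$clip[1], x))
      out[[v]][miss] <- x
    } else {
      ck <- cat_cuts(length(s$levels))
      idx <- findInterval(Z[miss, v], ck) + 1L
      if (is.factor(out[[v]]))
        out[[v]][miss] <- levels(out[[v]])[idx]
      else
        out[[v]][miss] <- as.integer(idx - 1L)
    }
  }
  as_ipd_stack(out, stack)
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("imputation_set: m = %d completed data sets, %d participants\n",
              x$m, nrow(x$completed[[1]])))
  invisible(x)
}

#' Missingness-mechanism diagnostics
#'
#' For every predictor with both missing and observed cells, fits a logistic
#' regression of the missingness indicator on all other observed predictors
#' (complete-case in those predictors) and reports coefficient, SE and
#' p-value per driver term.  Large systematic associations flag violations
#' of the missing-completely-at-random assumption.
#'
#' @param stack An [ipd_stack()].
#' @return Data frame with columns `predictor`, `driver`, `estimate`, `se`,
#'   `p`, `status` (`"ok"` or `"insufficient"` for predictors with fewer
#'   than 10 missing or 10 observed cells).  Fully observed stacks give an
#'   empty table.
#' @export
missingness_diagnostics <- function(stack) {
  preds <- intersect(names(msd_dictionary()$predictors), names(stack))
  out <- list()
  for (p in preds) {
    miss <- is.na(stack[[p]])
    if (!any(miss) || all(miss)) next
    if (sum(miss) < 10 || sum(!miss) < 10) {
      out[[p]] <- data.frame(predictor = p, driver = NA_character_,
                             estimate = NA_real_, se = NA_real_, p = NA_real_,
                             status = "insufficient")
      next
    }
    others <- setdiff(preds, p)
    terms <- unlist(lapply(others, function(o) switch(o,
      sex = "female", multisite_pain = "multisite_pain",
      pain_duration = c("pain_duration_3_6m", "pain_duration_7_12m",
                        "pain_duration_gt12m"),
      job_type = c("job_intermediate", "job_manual"), o)))
    X <- encode_predictors(as.data.frame(stack), terms)
    keep <- stats::complete.cases(X)
    d <- data.frame(.miss = as.numeric(miss[keep]), X[keep, , drop = FALSE],
                    check.names = FALSE)
    fit <- stats::glm(stats::reformulate(sprintf("`%s`", terms), ".miss"),
                      data = d, family = stats::binomial())
    sm <- summary(fit)$coefficients[-1, , drop = FALSE]
    out[[p]] <- data.frame(predictor = p, driver = terms,
                           estimate = unname(sm[, 1]), se = unname(sm[, 2]),
                           p = unname(sm[, 4]), status = "ok")
  }
  if (!length(out))
    return(data.frame(predictor = character(0), driver = character(0),
                      estimate = numeric(0), se = numeric(0), p = numeric(0),
                      status = character(0)))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Imputation consistency report
#'
#' Compares imputed against observed cells, per predictor, study and
#' imputation: mean and SD (continuous) or proportion-type summaries
#' (categorical, via numeric level codes), together with a standardized
#' difference, and exports plot-ready histogram tables for comparing
#' distributions across imputations and back to the observed values.
#'
#' @param imps An `imputation_set` from [impute_joint()].
#' @return A list of class `imputation_consistency` with `summaries` (one
#'   row per predictor x study x imputation having imputed cells, plus the
#'   observed reference rows) and `histograms` (shared-break counts for
#'   observed cells and each imputation).
#' @export
imputation_consistency <- function(imps) {
  stopifnot(inherits(imps, "imputation_set"))
  first <- imps$completed[[1]]
  preds <- intersect(names(msd_dictionary()$predictors), names(first))
  num <- function(x) as.numeric(x)  # factors -> level codes
  masks <- imps$input_na            # which cells were imputed
  studies <- as.character(first$study_id)
  rows <- list(); hists <- list()
  for (p in preds) {
    x_all <- lapply(imps$completed, function(s) num(s[[p]]))
    imputed_any <- masks[[p]]
    obs_mask <- !imputed_any
    for (s in unique(studies)) {
      in_s <- studies == s
      ob <- x_all[[1]][in_s & obs_mask]
      if (length(ob)) {
        rows[[length(rows) + 1L]] <- data.frame(
          predictor = p, study_id = s, imputation = 0L, source = "observed",
          n = length(ob), mean = mean(ob), sd = stats::sd(ob),
          std_diff = 0)
      }
      for (i in seq_len(imps$m)) {
        im <- x_all[[i]][in_s & imputed_any]
        if (!length(im)) next
        sd_ref <- stats::sd(ob)
        if (!isTRUE(sd_ref > 0)) sd_ref <- stats::sd(x_all[[i]][in_s])
        rows[[length(rows) + 1L]] <- data.frame(
          predictor = p, study_id = s, imputation = i, source = "imputed",
          n = length(im), mean = mean(im), sd = stats::sd(im),
          std_diff = if (isTRUE(sd_ref > 0)) (mean(im) - mean(ob)) / sd_ref
                     else NA_real_)
      }
    }
    if (any(imputed_any)) {
      all_vals <- unlist(x_all)
      br <- pretty(all_vals, n = 12)
      ob <- x_all[[1]][obs_mask]
      hb <- if (length(ob)) graphics::hist(ob, breaks = br, plot = FALSE)$counts else
        rep(0L, length(br) - 1)
      hh <- data.frame(predictor = p, source = "observed", imputation = 0L,
                       bin_lo = br[-length(br)], bin_hi = br[-1], count = hb)
      for (i in seq_len(imps$m)) {
        hc <- graphics::hist(x_all[[i]][imputed_any], breaks = br, plot = FALSE)$counts
        hh <- rbind(hh, data.frame(predictor = p, source = "imputed",
                                   imputation = i, bin_lo = br[-length(br)],
                                   bin_hi = br[-1], count = hc))
      }
      hists[[p]] <- hh
    }
  }
  structure(list(
    summaries = if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
                else data.frame(),
    histograms = if (length(hists)) do.call(rbind, c(hists, make.row.names = FALSE))
                 else data.frame()),
    class = "imputation_consistency")
}
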