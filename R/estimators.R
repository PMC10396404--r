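analysis_frame <- function(data, spec) {
  if (inherits(data, "masked_data")) data <- data$data
  vars <- c(spec$outcome, spec$exposure, spec$covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop("analysis variable(s) not in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  data[vars]
}

ols_fit <- function(y, X) {
  fit <- lm.fit(X, y)
  if (fit$rank < ncol(X))
    stop("singular design matrix in least-squares fit", call. = FALSE)
  rss <- sum(fit$residuals^2)
  df <- length(y) - ncol(X)
  sigma2 <- rss / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  list(coef = fit$coefficients, vcov = sigma2 * XtXinv, sigma2 = sigma2,
       df = df, rss = rss, XtXinv = XtXinv)
}

design_matrix <- function(data, predictors) {
  cbind(`(Intercept)` = 1, as.matrix(data[predictors]))
}

#' Complete-records regression analysis
#'
#' Ordinary least squares of the outcome on exposure and covariates (main
#' effects only), restricted to records with every analysis variable
#' observed.
#'
#' @param data a `masked_data` or a data frame with `NA`s.
#' @param spec a regression `estimand` (see [estimand_regression()]) naming
#'   outcome, exposure and covariates.
#' @return a `cra_fit`: list with `estimate` (exposure coefficient), `se`,
#'   `ci_low`, `ci_high` (normal-approximation 95% CI), `n_complete`, and
#'   the full coefficient vector.
#' @export
fit_cra <- function(data, spec) {
  df <- analysis_frame(data, spec)
  keep <- complete.cases(df)
  p <- 1L + length(spec$covariates)  # regressors: exposure + covariates
  if (sum(keep) < p + 2L)
    stop("insufficient complete records (", sum(keep), ") for ", p,
         " regressors", call. = FALSE)
  df <- df[keep, , drop = FALSE]
  X <- design_matrix(df, c(spec$exposure, spec$covariates))
  fit <- ols_fit(df[[spec$outcome]], X)
  est <- unname(fit$coef[spec$exposure])
  se <- sqrt(fit$vcov[spec$exposure, spec$exposure])
  structure(list(estimate = est, se = se,
                 ci_low = est - qnorm(0.975) * se,
                 ci_high = est + qnorm(0.975) * se,
                 n_complete = nrow(df), coefficients = fit$coef,
                 df_residual = fit$df),
            class = "cra_fit")
}

#' @export
print.cra_fit <- function(x, ...) {
  cat(sprintf(
    "complete-records analysis: estimate %.4f (95%% CI %.4f, %.4f), n = %d\n",
    x$estimate, x$ci_low, x$ci_high, x$n_complete))
  invisible(x)
}

#' Specify the imputation procedure
#'
#' Settings for fully conditional specification imputation. `deltas` are
#' pattern-mixture sensitivity offsets: after each posterior draw for a
#' variable, `deltas[variable]` is added to the values imputed for records
#' where that variable is missing, encoding the assumed mean difference
#' between unobserved and observed values conditional on the predictors.
#' Deltas apply to gaussian variables only: for a binary variable an offset
#' would need an explicit scale (log-odds vs probability) and is rejected
#' rather than guessed.
#'
#' @param n_imputations number of completed datasets (default 20).
#' @param n_cycles chained-equation cycles per imputation (default 10).
#' @param variable_models optional named character vector, incomplete
#'   variable -> `"gaussian"` or `"binary"`; unlisted variables are
#'   auto-declared (binary when the observed values are all 0/1).
#' @param deltas named numeric vector of offsets, default all zero.
#' @param predictors optional named list, variable -> predictor set;
#'   defaults to all other variables (analysis variables plus declared
#'   auxiliaries present in the data).
#' @param seed integer seed.
#' @return an `imputation_spec`.
#' @export
imputation_spec <- function(n_imputations = 20L, n_cycles = 10L,
                            variable_models = NULL, deltas = numeric(0),
                            predictors = NULL, seed = 1L) {
  stopifnot(n_imputations >= 1L, n_cycles >= 1L)
  structure(list(n_imputations = as.integer(n_imputations),
                 n_cycles = as.integer(n_cycles),
                 variable_models = variable_models,
                 deltas = deltas, predictors = predictors,
                 seed = as.integer(seed)),
            class = "imputation_spec")
}

declare_family <- function(col) {
  obs <- col[!is.na(col)]
  if (all(obs %in% c(0, 1))) "binary" else "gaussian"
}

# Proper gaussian imputation: posterior draw of (beta, sigma^2) under the
# noninformative prior, then predictive draws for the missing rows.
draw_gaussian <- function(y_obs, X_obs, X_mis) {
  fit <- ols_fit(y_obs, X_obs)
  sigma2 <- fit$rss / rchisq(1L, fit$df)
  R <- chol(fit$XtXinv)
  beta <- fit$coef + sqrt(sigma2) * drop(crossprod(R, rnorm(ncol(X_obs))))
  drop(X_mis %*% beta) + rnorm(nrow(X_mis), 0, sqrt(sigma2))
}

# Proper binary imputation: large-sample normal draw of the logistic
# coefficients, then bernoulli draws.
draw_binary <- function(y_obs, X_obs, X_mis, label) {
  fit <- tryCatch(
    suppressWarnings(glm.fit(X_obs, y_obs, family = binomial())),
    error = function(e)
      stop("imputation-model failure for '", label, "': ",
           conditionMessage(e), call. = FALSE))
  if (!fit$converged || fit$rank < ncol(X_obs))
    stop("imputation model for '", label,
         "' did not converge (separation or singular fit)", call. = FALSE)
  Xw <- X_obs * sqrt(fit$weights)
  V <- chol2inv(chol(crossprod(Xw)))
  R <- chol(V)
  beta <- fit$coefficients + drop(crossprod(R, rnorm(ncol(X_obs))))
  p <- plogis(drop(X_mis %*% beta))
  rbinom(nrow(X_mis), 1L, p)
}

#' Multiple imputation by fully conditional specification
#'
#' Chained-equations imputation with proper parameter draws, optionally
#' delta-adjusted (not-at-random FCS). Missing cells are initialized by
#' random draws from the observed marginals; the procedure then cycles
#' through the incomplete variables, refitting each conditional model on the
#' currently completed data, drawing imputation-model parameters from their
#' posterior (gaussian) or large-sample (logistic) distribution, and drawing
#' new values for the missing cells. For a variable with a nonzero delta the
#' offset is added to every value imputed for its missing records. Observed
#' cells are never altered; a fixed seed reproduces the output exactly.
#'
#' @param data a `masked_data` or data frame with `NA`s.
#' @param ispec an [imputation_spec()].
#' @return list of `n_imputations` completed data frames, with the spec
#'   attached as attribute `ispec`.
#' @export
fcs_impute <- function(data, ispec = imputation_spec()) {
  df <- if (inherits(data, "masked_data")) data$data else data
  df <- as.data.frame(df)
  incomplete <- names(df)[vapply(df, anyNA, logical(1))]
  m <- ispec$n_imputations
  if (length(incomplete) == 0L)
    return(structure(lapply(seq_len(m), function(i) df), ispec = ispec))

  fam <- vapply(incomplete, function(v) {
    f <- ispec$variable_models[[v]]
    if (is.null(f)) declare_family(df[[v]]) else
      match.arg(f, c("gaussian", "binary"))
  }, character(1))
  deltas <- setNames(rep(0, length(incomplete)), incomplete)
  for (v in names(ispec$deltas)) {
    if (!v %in% names(df))
      stop("delta names unknown variable '", v, "'", call. = FALSE)
    if (!v %in% incomplete) next
    if (fam[[v]] == "binary" && ispec$deltas[[v]] != 0)
      stop("delta adjustment for binary variable '", v, "' is not ",
           "supported: the offset scale (log-odds vs probability) is ",
           "ambiguous; deltas apply to gaussian variables only",
           call. = FALSE)
    deltas[[v]] <- ispec$deltas[[v]]
  }
  preds <- lapply(setNames(incomplete, incomplete), function(v) {
    p <- if (!is.null(ispec$predictors) && !is.null(ispec$predictors[[v]]))
      ispec$predictors[[v]] else setdiff(names(df), v)
    bad <- setdiff(p, names(df))
    if (length(bad))
      stop("predictor(s) for '", v, "' not in data: ",
           paste(bad, collapse = ", "), call. = FALSE)
    p
  })
  mis_idx <- lapply(setNames(incomplete, incomplete),
                    function(v) which(is.na(df[[v]])))

  set.seed(ispec$seed)
  out <- vector("list", m)
  for (imp in seq_len(m)) {
    cur <- df
    for (v in incomplete) {
      obs_vals <- df[[v]][!is.na(df[[v]])]
      cur[[v]][mis_idx[[v]]] <- sample(obs_vals, length(mis_idx[[v]]),
                                       replace = TRUE)
    }
    for (cycle in seq_len(ispec$n_cycles)) {
      for (v in incomplete) {
        mi <- mis_idx[[v]]
        obs <- setdiff(seq_len(nrow(df)), mi)
        X <- design_matrix(cur, preds[[v]])
        drawn <- tryCatch({
          if (fam[[v]] == "gaussian")
            draw_gaussian(df[[v]][obs], X[obs, , drop = FALSE],
                          X[mi, , drop = FALSE])
          else
            draw_binary(df[[v]][obs], X[obs, , drop = FALSE],
                        X[mi, , drop = FALSE], v)
        }, error = function(e)
          stop("imputation failed for variable '", v, "' in cycle ", cycle,
               ": ", conditionMessage(e), call. = FALSE))
        if (deltas[[v]] != 0) drawn <- drawn + deltas[[v]]
        cur[[v]][mi] <- drawn
      }
    }
    out[[imp]] <- cur
  }
  structure(out, ispec = ispec)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' The pooled estimate is the mean of the per-imputation estimates; the
#' total variance combines the mean within-imputation variance with the
#' between-imputation variance inflated by `(1 + 1/m)`. The confidence
#' interval uses a t reference with the small-sample (Barnard-Rubin)
#' degrees-of-freedom adjustment when a complete-data df is supplied.
#'
#' @param estimates numeric vector of per-imputation point estimates.
#' @param variances numeric vector of per-imputation squared standard
#'   errors, same length.
#' @param df_com complete-data residual degrees of freedom (`Inf` for the
#'   large-sample formula).
#' @return a `pooled_estimate`: estimate, within/between/total variance,
#'   95% CI, degrees of freedom, number of imputations.
#' @export
pool_rubin <- function(estimates, variances, df_com = Inf) {
  m <- length(estimates)
  if (m == 0L) stop("no estimates to pool", call. = FALSE)
  if (length(variances) != m)
    stop("estimates and variances must have equal length", call. = FALSE)
  qbar <- mean(estimates)
  within <- mean(variances)
  between <- if (m == 1L) 0 else var(estimates)
  total <- within + (1 + 1 / m) * between
  if (between > 0 && m > 1L) {
    lambda <- (1 + 1 / m) * between / total
    df_old <- (m - 1) / lambda^2
    df <- if (is.finite(df_com)) {
      df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
      1 / (1 / df_old + 1 / df_obs)
    } else df_old
  } else {
    df <- if (is.finite(df_com)) df_com else Inf
  }
  halfw <- qt(0.975, df) * sqrt(total)
  structure(list(estimate = qbar, within_variance = within,
                 between_variance = between, total_variance = total,
                 ci_low = qbar - halfw, ci_high = qbar + halfw,
                 degrees_of_freedom = df, n_imputations_used = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "pooled estimate %.4f (95%% CI %.4f, %.4f), m = %d, df = %.1f\n",
    x$estimate, x$ci_low, x$ci_high, x$n_imputations_used,
    x$degrees_of_freedom))
  invisible(x)
}

fit_analysis_model <- function(completed, spec) {
  X <- design_matrix(completed, c(spec$exposure, spec$covariates))
  fit <- ols_fit(completed[[spec$outcome]], X)
  c(estimate = unname(fit$coef[spec$exposure]),
    variance = fit$vcov[spec$exposure, spec$exposure],
    df = fit$df)
}

#' Multiple-imputation analysis with Rubin pooling
#'
#' Imputes with [fcs_impute()], fits the main-effects linear analysis model
#' on each completed dataset, and pools.
#'
#' @inheritParams fit_cra
#' @param ispec an [imputation_spec()].
#' @return a `pooled_estimate`.
#' @export
mi_analysis <- function(data, spec, ispec = imputation_spec()) {
  completed <- fcs_impute(data, ispec)
  fits <- vapply(completed, fit_analysis_model, numeric(3), spec = spec)
  pool_rubin(fits["estimate", ], fits["variance", ],
             df_com = fits["df", 1L])
}

#' Delta-adjusted sensitivity analysis over a grid of offsets
#'
#' Runs a not-at-random FCS imputation once per grid value, applying the
#' delta to the imputed values of the outcome, refits the analysis model on
#' each completed dataset and pools. All grid values share the same seed, so
#' results differ only through the delta.
#'
#' @inheritParams mi_analysis
#' @param delta_grid nonempty numeric vector of outcome-scale offsets.
#' @return list of `pooled_estimate`s, one per delta, in input order, with
#'   the grid attached as attribute `delta_grid`.
#' @export
delta_adjusted_analysis <- function(data, spec,
                                    ispec = imputation_spec(), delta_grid) {
  if (length(delta_grid) == 0L)
    stop("delta_grid must be nonempty", call. = FALSE)
  out <- lapply(delta_grid, function(d) {
    ispec_d <- ispec
    ispec_d$deltas <- c(ispec$deltas[names(ispec$deltas) != spec$outcome],
                        setNames(d, spec$outcome))
    mi_analysis(data, spec, ispec_d)
  })
  attr(out, "delta_grid") <- delta_grid
  out
}
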