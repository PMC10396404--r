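#' Specify a generative model consistent with an m-DAG
#'
#' Structural equations for the substantive and latent nodes plus logistic
#' missingness mechanisms for the indicator nodes. Every coefficient must
#' name an actual graph parent and every graph parent must receive a
#' (possibly zero) coefficient, so the model can never introduce dependence
#' absent from the graph.
#'
#' @param g an `mdag`.
#' @param equations named list, one entry per substantive/latent node:
#'   `list(family = "gaussian"|"bernoulli", intercept =, coefs = named
#'   numeric over the node's parents, sd = (gaussian only, > 0), clip =
#'   optional c(lo, hi) bounds applied after the draw)`.
#' @param mechanisms named list, one entry per missingness node:
#'   `list(intercept =, coefs = named numeric over the node's parents)`,
#'   interpreted on the logit scale.
#' @param n default sample size.
#' @param seed default random seed.
#' @return a `generative_model`.
#' @export
generative_model <- function(g, equations, mechanisms = list(), n = 1000L,
                             seed = 1L) {
  kinds <- vapply(g$nodes, `[[`, character(1), "kind")
  subst <- names(kinds)[kinds != "missingness"]
  miss <- names(kinds)[kinds == "missingness"]
  if (!setequal(names(equations), subst))
    stop("equations must cover exactly the substantive/latent nodes; ",
         "mismatch: ",
         paste(c(setdiff(subst, names(equations)),
                 setdiff(names(equations), subst)), collapse = ", "),
         call. = FALSE)
  if (!setequal(names(mechanisms), miss))
    stop("mechanisms must cover exactly the missingness nodes; mismatch: ",
         paste(c(setdiff(miss, names(mechanisms)),
                 setdiff(names(mechanisms), miss)), collapse = ", "),
         call. = FALSE)
  check_coefs <- function(v, spec, what) {
    pa <- setdiff(parents(g, v), character(0))
    cf <- spec$coefs
    if (is.null(cf)) cf <- setNames(numeric(0), character(0))
    extra <- setdiff(names(cf), pa)
    if (length(extra))
      stop(what, " for '", v, "' references non-parent(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
    missing_pa <- setdiff(pa, names(cf))
    if (length(missing_pa))
      stop(what, " for '", v, "' must give a (possibly zero) coefficient ",
           "for every parent; missing: ",
           paste(missing_pa, collapse = ", "), call. = FALSE)
    cf
  }
  for (v in subst) {
    eq <- equations[[v]]
    eq$family <- match.arg(eq$family, c("gaussian", "bernoulli"))
    if (is.null(eq$intercept)) eq$intercept <- 0
    eq$coefs <- check_coefs(v, eq, "equation")
    if (eq$family == "gaussian") {
      if (is.null(eq$sd) || !(eq$sd > 0))
        stop("gaussian equation for '", v, "' needs noise sd > 0",
             call. = FALSE)
    }
    equations[[v]] <- eq
  }
  for (v in miss) {
    mech <- mechanisms[[v]]
    if (is.null(mech$intercept)) mech$intercept <- 0
    mech$coefs <- check_coefs(v, mech, "mechanism")
    mechanisms[[v]] <- mech
  }
  structure(list(graph = g, equations = equations, mechanisms = mechanisms,
                 n = as.integer(n), seed = as.integer(seed)),
            class = "generative_model")
}

#' @export
print.generative_model <- function(x, ...) {
  cat("generative model on", length(x$equations), "variables,",
      length(x$mechanisms), "missingness mechanisms; n =", x$n, "\n")
  invisible(x)
}

linear_pred <- function(intercept, coefs, data, n = nrow(data)) {
  lp <- rep(intercept, n)
  for (p in names(coefs))
    if (coefs[[p]] != 0) lp <- lp + coefs[[p]] * data[[p]]
  lp
}

#' Simulate complete data from a generative model
#'
#' Nodes are generated in topological order; gaussian nodes as
#' intercept + sum(coef * parent) + noise, bernoulli nodes as draws with
#' logit-linear probability. A single random stream is consumed in
#' topological node order, so a fixed seed reproduces the table exactly.
#'
#' @param m a `generative_model`.
#' @param n sample size (defaults to the model's).
#' @param seed random seed (defaults to the model's). Pass `NA` to use the
#'   current RNG state without reseeding.
#' @return data frame of the substantive and latent variables.
#' @export
simulate_complete <- function(m, n = m$n, seed = m$seed) {
  stopifnot(inherits(m, "generative_model"))
  if (!is.na(seed)) set.seed(seed)
  ord <- topological_order(m$graph)
  ord <- ord[ord %in% names(m$equations)]
  dat <- list()
  for (v in ord) {
    eq <- m$equations[[v]]
    lp <- linear_pred(eq$intercept, eq$coefs, dat, n = n)
    x <- if (eq$family == "gaussian") lp + rnorm(n, 0, eq$sd)
         else rbinom(n, 1L, plogis(lp))
    if (!is.null(eq$clip)) x <- pmin(pmax(x, eq$clip[1L]), eq$clip[2L])
    dat[[v]] <- x
  }
  as.data.frame(dat, optional = TRUE)
}

#' Draw missingness indicators from the model's logistic mechanisms
#'
#' Each indicator is drawn independently per record with probability
#' `plogis(intercept + sum(coef * parent value))`, parents restricted to the
#' indicator's parents in the m-DAG.
#'
#' @param m a `generative_model`.
#' @param data complete data table from [simulate_complete()].
#' @param seed random seed; `NA` continues the current stream.
#' @return data frame of 0/1 indicator columns, one per missingness node.
#' @export
simulate_missingness <- function(m, data, seed = NA) {
  stopifnot(inherits(m, "generative_model"))
  if (!is.na(seed)) set.seed(seed)
  n <- nrow(data)
  ind <- list()
  for (v in sort(names(m$mechanisms))) {
    mech <- m$mechanisms[[v]]
    p <- plogis(linear_pred(mech$intercept, mech$coefs, data))
    ind[[v]] <- rbinom(n, 1L, p)
  }
  as.data.frame(ind, optional = TRUE)
}

#' Assemble a masked dataset
#'
#' Applies the indicators to the complete table: a cell becomes `NA` exactly
#' where its indicator equals 1. The pre-masking values are retained as the
#' `shadow`, for evaluation only; masking never alters an observed cell.
#'
#' @param g the `mdag` (supplies the indicator-to-variable mapping via each
#'   missingness node's `indicator_of`).
#' @param complete complete data table.
#' @param indicators 0/1 indicator table with one column per missingness
#'   node.
#' @return a `masked_data` object: list with `data` (NAs in place),
#'   `indicators`, and `shadow`.
#' @export
mask_data <- function(g, complete, indicators) {
  stopifnot(all(unlist(indicators) %in% c(0L, 1L)))
  data <- complete
  for (v in names(indicators)) {
    target <- g$nodes[[v]]$indicator_of
    if (is.null(target) || !target %in% names(data))
      stop("indicator '", v, "' does not mark a variable in the data",
           call. = FALSE)
    data[[target]][indicators[[v]] == 1L] <- NA
  }
  structure(list(data = data, indicators = indicators, shadow = complete),
            class = "masked_data")
}

#' @export
print.masked_data <- function(x, ...) {
  pm <- vapply(x$data, function(col) mean(is.na(col)), numeric(1))
  cat("masked dataset: ", nrow(x$data), " records, ", ncol(x$data),
      " variables\n", sep = "")
  inc <- pm[pm > 0]
  if (length(inc))
    cat("  missing: ", paste0(names(inc), " ",
                              sprintf("%.1f%%", 100 * inc),
                              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Simulate a masked dataset in one seeded pass
#'
#' @param m a `generative_model`.
#' @param n sample size.
#' @param seed single seed governing both the structural draws and the
#'   missingness draws (one stream, consumed in topological node order).
#' @return a `masked_data`.
#' @export
simulate_masked <- function(m, n = m$n, seed = m$seed) {
  if (!is.na(seed)) set.seed(seed)
  complete <- simulate_complete(m, n, seed = NA)
  ind <- simulate_missingness(m, complete, seed = NA)
  mask_data(m$graph, complete, ind)
}

#' Calibrate mechanism intercepts to target missingness proportions
#'
#' Adjusts each missingness mechanism's intercept by stochastic root-finding
#' so the realized marginal proportion missing matches the target: the
#' marginal probability is estimated by Monte Carlo over a large simulated
#' complete table and the intercept solved by bisection on that empirical
#' expectation.
#'
#' @param m a `generative_model`.
#' @param targets named numeric vector, indicator node -> desired marginal
#'   proportion, each in (0, 1).
#' @param n Monte Carlo sample size for the calibration draw.
#' @param seed seed for the calibration draw.
#' @param tol acceptable absolute deviation of the realized proportion.
#' @return the model with calibrated intercepts.
#' @export
calibrate_intercepts <- function(m, targets, n = 200000L, seed = m$seed,
                                 tol = 0.005) {
  stopifnot(inherits(m, "generative_model"))
  bad <- names(targets)[!(targets > 0 & targets < 1)]
  if (length(bad) || any(!names(targets) %in% names(m$mechanisms)))
    stop("calibration targets must be in (0, 1) and name missingness ",
         "nodes", call. = FALSE)
  set.seed(seed)
  complete <- simulate_complete(m, n = n, seed = NA)
  for (v in names(targets)) {
    mech <- m$mechanisms[[v]]
    lp0 <- linear_pred(0, mech$coefs, complete)
    f <- function(a) mean(plogis(a + lp0)) - targets[[v]]
    root <- tryCatch(uniroot(f, c(-40, 40), tol = 1e-10),
                     error = function(e)
                       stop("calibration failed for '", v, "': ",
                            conditionMessage(e), call. = FALSE))
    m$mechanisms[[v]]$intercept <- root$root
  }
  ind <- simulate_missingness(m, complete, seed = NA)
  realized <- colMeans(ind)[names(targets)]
  resid <- abs(realized - unlist(targets))
  if (any(resid > max(tol, 4 * sqrt(0.25 / n))))
    stop("calibration did not converge; residuals: ",
         paste(sprintf("%s=%.4f", names(targets), resid), collapse = ", "),
         call. = FALSE)
  m
}

#' Write / read a masked dataset as CSV
#'
#' Missing cells are written empty; indicator columns keep their node names
#' (conventionally `M_<variable>`). The shadow table is only written when a
#' path is supplied, since it exists for evaluation and must not leak into
#' an analysis.
#'
#' @param md a `masked_data`.
#' @param path output CSV path for the observed data plus indicators.
#' @param shadow_path optional CSV path for the pre-masking table.
#' @export
write_masked_csv <- function(md, path, shadow_path = NULL) {
  out <- cbind(md$data, md$indicators)
  write.csv(out, path, row.names = FALSE, na = "")
  if (!is.null(shadow_path))
    write.csv(md$shadow, shadow_path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_masked_csv
#' @param g the `mdag` the file's indicator columns refer to.
#' @return `read_masked_csv` returns a `masked_data` (its shadow equals the
#'   observed data with NAs: the true values are unknown for a real file).
#' @export
read_masked_csv <- function(path, g) {
  raw <- read.csv(path)
  kinds <- vapply(g$nodes, `[[`, character(1), "kind")
  miss <- names(kinds)[kinds == "missingness"]
  have <- intersect(miss, names(raw))
  ind <- raw[have]
  data <- raw[setdiff(names(raw), miss)]
  for (v in have) {
    target <- g$nodes[[v]]$indicator_of
    if (!is.null(target) && target %in% names(data))
      data[[target]][ind[[v]] == 1L] <- NA
  }
  structure(list(data = data, indicators = ind, shadow = data),
            class = "masked_data")
}
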