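#' The case-study m-DAGs
#'
#' Point-exposure study graphs emulating a cohort analysis of the effect of
#' maternal mental illness (binary exposure X) on child behaviour measured by
#' a bounded 0-40 questionnaire score (continuous outcome Y), adjusted for a
#' complete confounder set (collapsed node C) and an incomplete confounder
#' set (collapsed node Z: maternal alcohol use, maternal smoking, child
#' physical functioning). One missingness indicator per incomplete variable,
#' with a single indicator for missingness in any of the incomplete
#' confounders. Variant `"a"`: exposure and incomplete confounders cause
#' missingness, the outcome does not. Variant `"b"` adds an arrow from the
#' outcome to each indicator. Variant `"pm"` is the pattern-mixture probe
#' graph: only the outcome is incomplete and only the exposure drives its
#' missingness.
#'
#' @param variant `"a"`, `"b"` or `"pm"`.
#' @return an `mdag` with a `roles` attribute giving the canonical role
#'   assignment.
#' @export
case_study_mdag <- function(variant = c("a", "b", "pm")) {
  variant <- match.arg(variant)
  zn <- node("Z", role = "confounder",
             group_members = c("mat_alcohol", "mat_smoking", "child_phys"))
  base_nodes <- list(
    node("C", role = "confounder"), zn,
    node("X", role = "exposure"), node("Y", role = "outcome"))
  core <- list(c("C", "Z"), c("C", "X"), c("C", "Y"), c("Z", "X"),
               c("Z", "Y"), c("X", "Y"))
  if (variant == "pm") {
    nodes <- c(base_nodes, list(node("M_Y", kind = "missingness",
                                     indicator_of = "Y")))
    edges <- c(core, list(c("X", "M_Y")))
    roles <- c(C = "C", Z = "Z", X = "X", Y = "Y", M_Y = "M_Y")
  } else {
    nodes <- c(base_nodes, list(
      node("M_X", kind = "missingness", indicator_of = "X"),
      node("M_Y", kind = "missingness", indicator_of = "Y"),
      node("M_Z", kind = "missingness", indicator_of = "Z")))
    ind <- c("M_X", "M_Y", "M_Z")
    edges <- c(core,
               lapply(ind, function(mi) c("X", mi)),
               lapply(ind, function(mi) c("Z", mi)))
    if (variant == "b")
      edges <- c(edges, lapply(ind, function(mi) c("Y", mi)))
    roles <- c(C = "C", Z = "Z", X = "X", Y = "Y",
               M_X = "M_X", M_Y = "M_Y", M_Z = "M_Z")
  }
  g <- mdag(nodes, edges)
  attr(g, "roles") <- roles
  g
}

#' The case-study role assignment
#' @return named character vector suitable for [extract_key_arrows()].
#' @export
case_study_roles <- function() {
  c(C = "C", Z = "Z", X = "X", Y = "Y",
    M_X = "M_X", M_Y = "M_Y", M_Z = "M_Z")
}

# Default structural parameters. The outcome is near-gaussian on the 0-40
# questionnaire scale, with mean/sd chosen so boundary clipping touches
# well under 1% of draws; the true adjusted exposure effect is b_x.
CASE_STUDY_PARAMS <- list(
  b_x = 0.6,        # true exposure coefficient (outcome units)
  y_intercept = 16, y_sd = 5, conf_coef = 1.5,
  x_intercept = -1.6, x_conf_coef = 0.4,
  miss_x_coef = 0.5, miss_z_coef = 0.5, # log-odds per unit X / Z
  miss_y_sd_units = 1,                  # variant b: log-odds per SD of Y
  pm_x_coef = 0.7,                      # pm variant: log-odds, exposed vs not
  miss_targets = c(M_X = 0.15, M_Y = 0.23, M_Z = 0.19)
)

#' Build the calibrated case-study generative model
#'
#' Structural equations: C and Z standard-normal confounder blocks (Z partly
#' caused by C), a logistic binary exposure, and a gaussian outcome clipped
#' to the 0-40 questionnaire range (clipping affects < 1% of draws at the
#' default parameters). Missingness mechanisms follow the variant's graph;
#' intercepts are calibrated so marginal missingness matches 15% (exposure),
#' 23% (outcome) and 19% (incomplete confounders). In variant `"b"` the
#' outcome enters each mechanism with log-odds `outcome_effect` per standard
#' deviation of the outcome. In variant `"pm"` only the outcome is
#' incomplete, its mechanism depends on the exposure alone, the outcome is
#' not clipped, and after masking the unobserved outcomes are shifted by
#' `pattern_delta`, giving a pattern-mixture mechanism with known
#' sensitivity parameter.
#'
#' @param variant `"a"`, `"b"` or `"pm"`.
#' @param seed seed for the calibration draws.
#' @param outcome_effect variant `"b"` outcome-to-indicator strength,
#'   log-odds per outcome SD.
#' @param pattern_delta variant `"pm"` shift applied to unobserved outcomes
#'   (outcome units).
#' @param n_calibrate Monte Carlo size for intercept calibration.
#' @return a `generative_model` with attributes `truth` (the true adjusted
#'   exposure coefficient, accounting for the pattern-mixture shift),
#'   `variant`, and `pattern_delta`.
#' @export
case_study_model <- function(variant = c("a", "b", "pm"), seed = 1L,
                             outcome_effect = 1, pattern_delta = 0,
                             n_calibrate = 200000L) {
  variant <- match.arg(variant)
  p <- CASE_STUDY_PARAMS
  g <- case_study_mdag(variant)
  eqs <- list(
    C = list(family = "gaussian", intercept = 0, coefs = c(), sd = 1),
    Z = list(family = "gaussian", intercept = 0, coefs = c(C = 0.3), sd = 1),
    X = list(family = "bernoulli", intercept = p$x_intercept,
             coefs = c(C = p$x_conf_coef, Z = p$x_conf_coef)),
    Y = list(family = "gaussian", intercept = p$y_intercept,
             coefs = c(X = p$b_x, C = p$conf_coef, Z = p$conf_coef),
             sd = p$y_sd,
             clip = if (variant == "pm") NULL else c(0, 40)))
  if (variant == "pm") {
    mechs <- list(M_Y = list(intercept = 0, coefs = c(X = p$pm_x_coef)))
    targets <- p$miss_targets["M_Y"]
  } else {
    base <- c(X = p$miss_x_coef, Z = p$miss_z_coef)
    if (variant == "b") {
      # outcome SD implied by the linear model (before clipping)
      var_z <- 0.3^2 + 1
      px <- 0.18  # approximate exposure prevalence for the variance term
      var_y <- p$b_x^2 * px * (1 - px) +
        p$conf_coef^2 * (1 + var_z) + 2 * p$conf_coef^2 * 0.3 + p$y_sd^2
      y_coef <- outcome_effect / sqrt(var_y)
      base <- c(base, Y = y_coef)
    }
    mechs <- list(M_X = list(intercept = 0, coefs = base),
                  M_Y = list(intercept = 0, coefs = base),
                  M_Z = list(intercept = 0, coefs = base))
    targets <- p$miss_targets
  }
  m <- generative_model(g, eqs, mechs, n = 4882L, seed = as.integer(seed))
  m <- calibrate_intercepts(m, targets, n = n_calibrate, seed = seed)
  truth <- p$b_x
  if (variant == "pm" && pattern_delta != 0) {
    a <- m$mechanisms$M_Y$intercept
    truth <- truth + pattern_delta *
      (plogis(a + p$pm_x_coef) - plogis(a))
  }
  attr(m, "truth") <- truth
  attr(m, "variant") <- variant
  attr(m, "pattern_delta") <- pattern_delta
  m
}

#' Generate a synthetic case-study dataset
#'
#' Emulates the case-study structure: binary exposure with ~15% missing,
#' continuous 0-40 outcome with ~23% missing, a complete confounder block
#' and an incomplete confounder block with ~19% missing, default n = 4882.
#'
#' @param seed integer seed governing model calibration and data generation.
#' @param n sample size (>= 100).
#' @param variant which case-study m-DAG drives the missingness.
#' @param model optionally a prebuilt [case_study_model()] to reuse across
#'   replicates (skips recalibration).
#' @param ... passed to [case_study_model()].
#' @return list with `graphs` (both study m-DAGs, named `a` and `b`),
#'   `model`, `data` (a `masked_data`), `truth` (true adjusted exposure
#'   coefficient), and `roles`.
#' @export
case_study_generator <- function(seed = 1L, n = 4882L, variant = "a",
                                 model = NULL, ...) {
  if (n < 100) stop("n must be at least 100", call. = FALSE)
  if (is.null(model)) model <- case_study_model(variant, seed = seed, ...)
  md <- simulate_masked(model, n = n, seed = seed)
  pd <- attr(model, "pattern_delta")
  if (!is.null(pd) && pd != 0) {
    mis <- md$indicators$M_Y == 1L
    md$shadow$Y[mis] <- md$shadow$Y[mis] + pd
  }
  list(graphs = list(a = case_study_mdag("a"), b = case_study_mdag("b")),
       model = model, data = md, truth = attr(model, "truth"),
       roles = case_study_roles())
}
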