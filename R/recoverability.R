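#' Define the target estimand
#'
#' The catalogued targets for a point-exposure study: the marginal mean of
#' the exposure or outcome, and the exposure coefficient in a main-effects
#' linear regression of the outcome on the exposure and confounders.
#'
#' @param variable node name whose marginal mean is targeted.
#' @param of whether `variable` plays the exposure or the outcome role in
#'   the study (determines the catalogue row consulted).
#' @return an `estimand` object.
#' @export
estimand_marginal_mean <- function(variable, of = c("exposure", "outcome")) {
  of <- match.arg(of)
  structure(list(target = "marginal_mean", variable = variable, of = of),
            class = "estimand")
}

#' @rdname estimand_marginal_mean
#' @param outcome,exposure node names of the outcome and exposure.
#' @param covariates character vector of adjustment covariate node names
#'   (must exclude exposure and outcome).
#' @export
estimand_regression <- function(outcome, exposure, covariates = character(0)) {
  covariates <- as.character(covariates)
  if (exposure %in% covariates || outcome %in% covariates)
    stop("exposure and outcome must not appear among covariates",
         call. = FALSE)
  if (identical(outcome, exposure))
    stop("outcome and exposure must differ", call. = FALSE)
  structure(list(target = "regression_coefficient", outcome = outcome,
                 exposure = exposure, covariates = covariates),
            class = "estimand")
}

#' @export
print.estimand <- function(x, ...) {
  if (x$target == "marginal_mean")
    cat("estimand: marginal mean of ", x$variable, " (", x$of, ")\n",
        sep = "")
  else
    cat("estimand: coefficient of ", x$exposure, " in regression of ",
        x$outcome, " on {", paste(c(x$exposure, x$covariates),
                                  collapse = ", "), "}\n", sep = "")
  invisible(x)
}

check_estimand <- function(g, e) {
  vars <- if (e$target == "marginal_mean") e$variable else
    c(e$outcome, e$exposure, e$covariates)
  for (v in vars) {
    if (!v %in% node_names(g))
      stop("estimand names unknown node '", v, "'", call. = FALSE)
    if (g$nodes[[v]]$kind != "substantive")
      stop("estimand node '", v, "' is not substantive", call. = FALSE)
  }
  invisible(TRUE)
}

ROLE_SYMBOLS <- c("X", "Y", "Z", "C", "M_X", "M_Y", "M_Z")
KEY_SOURCES <- c("X", "Y", "Z")
KEY_TARGETS <- c("M_X", "M_Y", "M_Z")

check_roles <- function(g, roles) {
  roles <- unlist(roles)
  bad <- setdiff(names(roles), node_names(g))
  if (length(bad))
    stop("role assignment names unknown node(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unname(roles), ROLE_SYMBOLS)
  if (length(bad))
    stop("unknown role symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(unname(roles)))
    stop("each role symbol may be assigned to at most one node",
         call. = FALSE)
  if (!all(c("X", "Y") %in% roles))
    stop("role assignment must cover the exposure (X) and outcome (Y)",
         call. = FALSE)
  ind <- vapply(names(roles), function(v) g$nodes[[v]]$kind, character(1))
  m_roles <- grepl("^M_", unname(roles))
  if (any(ind[m_roles] != "missingness"))
    stop("M_* roles must be assigned to missingness nodes", call. = FALSE)
  if (any(ind[!m_roles] != "substantive"))
    stop("X/Y/Z/C roles must be assigned to substantive nodes",
         call. = FALSE)
  kinds_all <- vapply(g$nodes, `[[`, character(1), "kind")
  all_m <- names(kinds_all)[kinds_all == "missingness"]
  unassigned <- setdiff(all_m, names(roles)[m_roles])
  if (length(unassigned))
    stop("role assignment must cover every missingness indicator; missing: ",
         paste(unassigned, collapse = ", "), call. = FALSE)
  roles
}

#' Extract the key arrows of a study m-DAG
#'
#' The canonical catalogue is indexed by the "key arrows": arrows from each
#' incomplete variable (exposure X, outcome Y, incomplete confounders Z) into
#' each missingness indicator (M_X, M_Y, M_Z). This maps the study graph
#' through an explicit role assignment and records exactly which key arrows
#' it contains. Arrows from complete confounders (role C) into indicators are
#' noted in the justification but are not key arrows.
#'
#' @param g an admissible `mdag` (no [validate_mdag()] violations).
#' @param roles named character vector mapping node names to role symbols
#'   among `X, Y, Z, C, M_X, M_Y, M_Z`; must cover X, Y and every
#'   missingness indicator in the graph. Roles are always explicit input and
#'   never inferred from node names.
#' @return a `key_arrow_set`: list with `arrows` (character vector of
#'   `"X->M_Y"`-style labels, sorted), `outcome_causes_missingness`, and a
#'   `justification` trail.
#' @export
extract_key_arrows <- function(g, roles) {
  rep_ <- validate_mdag(g)
  if (length(rep_$violations))
    stop("graph violates the overarching assumptions; see validate_mdag()",
         call. = FALSE)
  roles <- check_roles(g, roles)
  sym_of <- setNames(unname(roles), names(roles))
  arrows <- character(0)
  notes <- character(0)
  for (i in seq_len(nrow(g$edges))) {
    from <- g$edges[i, 1L]; to <- g$edges[i, 2L]
    fs <- sym_of[from]; ts <- sym_of[to]
    if (is.na(fs) || is.na(ts)) next
    if (ts %in% KEY_TARGETS) {
      if (fs %in% KEY_SOURCES)
        arrows <- c(arrows, paste0(fs, "->", ts))
      else if (fs == "C")
        notes <- c(notes, paste0("edge ", from, " -> ", to,
                                 " (complete confounders into indicator) ",
                                 "recorded; not a key arrow"))
    }
  }
  arrows <- sort(unique(arrows))
  structure(list(
    arrows = arrows,
    outcome_causes_missingness = any(startsWith(arrows, "Y->")),
    justification = c(
      paste0("key arrows present: ",
             if (length(arrows)) paste(arrows, collapse = ", ") else
               "(none)"),
      notes)),
    class = "key_arrow_set")
}

full_grid <- function() {
  sort(as.vector(outer(KEY_SOURCES, KEY_TARGETS, paste, sep = "->")))
}

arrow_signature <- function(arrows) {
  if (length(arrows) == 0L) return("none")
  parts <- character(0)
  for (s in KEY_SOURCES) {
    tg <- sort(sub("^.*->M_", "", arrows[startsWith(arrows, paste0(s, "->"))]))
    if (length(tg) == 0L) next
    parts <- c(parts, paste0(
      s, "_", if (length(tg) == 3L) "all" else
        paste0("M", tg, collapse = "+")))
  }
  paste(parts, collapse = ",")
}

#' Map a key-arrow set to its canonical m-DAG label
#'
#' The full grid of key arrows (every incomplete variable into every
#' indicator) is canonical type J; the grid without any outcome arrows
#' (exposure and incomplete-confounder arrows only) is type E. Any other set
#' is labelled `"other:<signature>"` and carries a nesting note naming the
#' smallest catalogued superset, because every canonical graph also stands
#' for the nested sub-graphs reachable by deleting arrows.
#'
#' @param k a `key_arrow_set` from [extract_key_arrows()].
#' @return a `canonical_label`: character scalar with attributes `nested_in`
#'   (for `"other"` labels) and `note`.
#' @export
classify_canonical <- function(k) {
  stopifnot(inherits(k, "key_arrow_set"))
  a <- k$arrows
  e_set <- sort(c(paste0("X->", KEY_TARGETS), paste0("Z->", KEY_TARGETS)))
  if (setequal(a, full_grid())) {
    lab <- "J"
    attr(lab, "note") <- "all key arrows present: canonical type J"
  } else if (setequal(a, e_set)) {
    lab <- "E"
    attr(lab, "note") <-
      "exposure and incomplete-confounder arrows, no outcome arrows: type E"
  } else {
    nested <- if (all(a %in% e_set)) "E" else "J"
    lab <- paste0("other:", arrow_signature(a))
    attr(lab, "nested_in") <- nested
    attr(lab, "note") <- paste0(
      "arrow set is a strict subset of canonical type ", nested,
      " (smallest catalogued superset); nested graphs share the canonical ",
      "graph's recoverability results where those establish recoverability")
  }
  class(lab) <- c("canonical_label", class(lab))
  lab
}

#' @export
print.canonical_label <- function(x, ...) {
  cat("canonical m-DAG label: ", unclass(x)[1L], "\n", sep = "")
  if (!is.null(attr(x, "nested_in")))
    cat("  nested within: ", attr(x, "nested_in"), "\n", sep = "")
  cat("  ", attr(x, "note"), "\n", sep = "")
  invisible(x)
}

estimand_key <- function(e) {
  if (e$target == "regression_coefficient") "regression_coefficient"
  else paste0("marginal_mean_", e$of)
}

#' The canonical recoverability catalogue
#'
#' Verdicts for (canonical label, estimand) pairs in point-exposure studies.
#' Only the cells this package can vouch for are populated as authoritative:
#' the regression-adjusted exposure effect is recoverable under type E and
#' not recoverable under type J (where a delta-adjusted analysis is
#' required). All other cells ship as `undetermined` placeholders that the
#' user may fill in from the companion catalogue of canonical m-DAGs via
#' `overrides`.
#'
#' @param overrides optional data frame with columns `label`, `estimand`,
#'   `status` used to fill in or replace entries (e.g. from the companion
#'   catalogue). `estimand` takes values `regression_coefficient`,
#'   `marginal_mean_exposure`, `marginal_mean_outcome`; `status` one of
#'   `recoverable`, `not_recoverable`, `undetermined`.
#' @return data frame with columns `label`, `estimand`, `status`, `source`.
#' @export
canonical_catalogue <- function(overrides = NULL) {
  labels <- LETTERS[1:10]
  keys <- c("marginal_mean_exposure", "marginal_mean_outcome",
            "regression_coefficient")
  cat_ <- expand.grid(label = labels, estimand = keys,
                      stringsAsFactors = FALSE)
  cat_$status <- "undetermined"
  cat_$source <- "placeholder: consult the companion canonical catalogue"
  set_entry <- function(d, lab, key, status, src) {
    i <- d$label == lab & d$estimand == key
    d$status[i] <- status
    d$source[i] <- src
    d
  }
  cat_ <- set_entry(cat_, "E", "regression_coefficient", "recoverable",
                    "authoritative")
  cat_ <- set_entry(cat_, "J", "regression_coefficient", "not_recoverable",
                    "authoritative")
  if (!is.null(overrides)) {
    stopifnot(all(c("label", "estimand", "status") %in% names(overrides)))
    for (i in seq_len(nrow(overrides)))
      cat_ <- set_entry(cat_, overrides$label[i], overrides$estimand[i],
                        overrides$status[i], "user override")
  }
  cat_
}

#' Look up recoverability of an estimand for a canonical label
#'
#' Exact canonical labels are read straight from the catalogue. An
#' `"other:*"` label nested within a catalogued label whose verdict is
#' `recoverable` inherits recoverability by the nesting rule (and, when the
#' set aligns with several canonical graphs, recoverability in any one of
#' them suffices). A nested label whose only catalogued superset is
#' non-recoverable stays `undetermined`: deleting arrows can only help, so a
#' negative verdict is never inherited downward.
#'
#' @param label a `canonical_label` from [classify_canonical()] (or a plain
#'   label string).
#' @param e an `estimand`.
#' @param catalogue catalogue table, see [canonical_catalogue()].
#' @return a `recoverability_verdict`: list with `status`,
#'   `canonical_label`, `cra_consistent` (filled by [assess_recoverability()])
#'   and a `justification` character vector.
#' @export
lookup_recoverability <- function(label, e, catalogue = canonical_catalogue()) {
  if (!inherits(e, "estimand"))
    stop("e must be an estimand object", call. = FALSE)
  key <- estimand_key(e)
  lab <- unclass(label)[1L]
  just <- character(0)
  if (!startsWith(lab, "other")) {
    row <- catalogue[catalogue$label == lab & catalogue$estimand == key, ]
    if (nrow(row) == 0L)
      stop("unknown canonical label '", lab, "'", call. = FALSE)
    status <- row$status[1L]
    just <- c(just, paste0("catalogue entry (", lab, ", ", key, "): ",
                           status, " [", row$source[1L], "]"))
  } else {
    nested <- attr(label, "nested_in")
    status <- "undetermined"
    just <- c(just, paste0("label ", lab, " not itself catalogued"))
    if (!is.null(nested)) {
      row <- catalogue[catalogue$label == nested & catalogue$estimand == key, ]
      if (nrow(row) && row$status[1L] == "recoverable") {
        status <- "recoverable"
        just <- c(just, paste0(
          "nested within catalogued type ", nested,
          " which is recoverable for this estimand; nesting rule applies"))
      } else {
        just <- c(just, paste0(
          "smallest catalogued superset ", nested, " has status ",
          if (nrow(row)) row$status[1L] else "unknown",
          "; non-recoverable verdicts are not inherited by nested graphs - ",
          "consult the companion catalogue"))
      }
    }
  }
  structure(list(status = status, canonical_label = lab,
                 cra_consistent = NA, justification = just),
            class = "recoverability_verdict")
}

#' @export
print.recoverability_verdict <- function(x, ...) {
  cat("recoverability verdict: ", x$status, " (canonical label ",
      x$canonical_label, ")\n", sep = "")
  if (!is.na(x$cra_consistent))
    cat("  complete-records analysis consistent: ", x$cra_consistent, "\n",
        sep = "")
  for (j in x$justification) cat("  - ", j, "\n", sep = "")
  invisible(x)
}

#' Graphical validity criterion for complete-records analysis
#'
#' For a regression estimand, complete-records analysis is consistent when
#' selection on complete records carries no information about the outcome
#' given the regressors, i.e. when the outcome is d-separated from every
#' missingness indicator given the exposure and covariates. Conditioning is
#' on the regressors actually fitted, not on auxiliaries.
#'
#' @param g an admissible `mdag`.
#' @param e a regression `estimand` (marginal means route through the
#'   catalogue instead and are rejected here).
#' @return list with `valid` (logical), `query` (the d-separation statement)
#'   and `justification`.
#' @export
cra_valid <- function(g, e) {
  if (!inherits(e, "estimand") || e$target != "regression_coefficient")
    stop("cra_valid applies to regression estimands only; use ",
         "lookup_recoverability() for marginal means", call. = FALSE)
  check_estimand(g, e)
  kinds <- vapply(g$nodes, `[[`, character(1), "kind")
  miss <- names(kinds)[kinds == "missingness"]
  cond <- c(e$exposure, e$covariates)
  valid <- if (length(miss) == 0L) TRUE else
    d_separated(g, e$outcome, miss, cond)
  query <- paste0("d_sep(", e$outcome, " ; {",
                  paste(miss, collapse = ", "), "} | {",
                  paste(cond, collapse = ", "), "})")
  list(valid = valid, query = query,
       justification = paste0(query, " = ", valid,
                              if (valid) ": complete-record selection is " else
                                ": complete-record selection is NOT ",
                              "uninformative about the outcome given the ",
                              "regressors"))
}

#' One-call graphical assessment of an m-DAG
#'
#' Runs validation, key-arrow extraction, canonical classification, the
#' catalogue lookup and (for regression estimands) the complete-records
#' validity criterion, and assembles the full verdict with its
#' justification trail. Re-running with the same inputs yields a
#' byte-identical trail.
#'
#' @inheritParams extract_key_arrows
#' @param e an `estimand`.
#' @param catalogue see [canonical_catalogue()].
#' @return a `recoverability_verdict` with `cra_consistent` filled for
#'   regression estimands.
#' @export
assess_recoverability <- function(g, e, roles,
                                  catalogue = canonical_catalogue()) {
  check_estimand(g, e)
  k <- extract_key_arrows(g, roles)
  lab <- classify_canonical(k)
  v <- lookup_recoverability(lab, e, catalogue)
  v$justification <- c(k$justification, attr(lab, "note"), v$justification)
  if (e$target == "regression_coefficient") {
    cv <- cra_valid(g, e)
    v$cra_consistent <- cv$valid
    v$justification <- c(v$justification, cv$justification)
  }
  v
}
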