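#' @importFrom stats lm.fit glm.fit coef vcov rnorm rbinom runif rchisq rt qt qnorm plogis sd var binomial uniroot setNames complete.cases
#' @importFrom utils head write.csv read.csv
NULL

NODE_KINDS <- c("substantive", "latent", "missingness")
NODE_ROLES <- c("exposure", "outcome", "confounder", "auxiliary", "none")
NAME_RE <- "^[A-Za-z_][A-Za-z0-9_]*$"

#' Create an m-DAG node
#'
#' Nodes are either substantive analysis variables, latent (unmeasured)
#' variables, or binary missingness indicators. A missingness node must name
#' the substantive node (or collapsed node-group) whose missingness it marks
#' via `indicator_of`. A node may stand for a collapsed set of variables
#' (e.g. "all incomplete confounders") through `group_members`; such nodes are
#' treated as atomic in every graph algorithm.
#'
#' @param name identifier string (letters, digits, underscore; not starting
#'   with a digit).
#' @param kind one of `"substantive"`, `"latent"`, `"missingness"`.
#' @param role analysis role, substantive nodes only: `"exposure"`,
#'   `"outcome"`, `"confounder"`, `"auxiliary"` or `"none"`.
#' @param indicator_of for missingness nodes, the name of the node whose
#'   missingness this indicator marks.
#' @param group_members optional character vector naming the collapsed
#'   variables this node represents.
#' @return a `node` object (named list).
#' @export
node <- function(name, kind = "substantive", role = "none",
                 indicator_of = NULL, group_members = NULL) {
  if (!is.character(name) || length(name) != 1L || !grepl(NAME_RE, name))
    stop("node name must be an identifier matching [A-Za-z_][A-Za-z0-9_]*: ",
         deparse(name), call. = FALSE)
  kind <- match.arg(kind, NODE_KINDS)
  role <- match.arg(role, NODE_ROLES)
  if (kind != "substantive" && role != "none")
    stop("role applies to substantive nodes only (node '", name, "')",
         call. = FALSE)
  has_ind <- !is.null(indicator_of) && nzchar(indicator_of)
  if (kind == "missingness" && !has_ind)
    stop("missingness node '", name, "' requires indicator_of", call. = FALSE)
  if (kind != "missingness" && has_ind)
    stop("indicator_of is only valid for missingness nodes (node '", name,
         "')", call. = FALSE)
  if (!is.null(group_members)) {
    if (kind == "latent")
      stop("group_members not allowed on latent nodes (node '", name, "')",
           call. = FALSE)
    if (length(group_members) == 0L)
      group_members <- NULL
  }
  structure(list(name = name, kind = kind, role = role,
                 indicator_of = if (has_ind) indicator_of else NULL,
                 group_members = group_members),
            class = "mdag_node")
}

#' Construct an m-DAG
#'
#' A missingness DAG: a directed acyclic graph over substantive, latent and
#' missingness-indicator nodes. Construction checks name uniqueness, that
#' every edge endpoint exists, that there are no self-loops, and acyclicity
#' (via topological sort; a violating cycle is reported).
#'
#' @param nodes list of [node()] objects.
#' @param edges list of length-2 character vectors `c(from, to)`, or a
#'   two-column character matrix.
#' @return an `mdag` object.
#' @seealso [parse_mdag()], [serialize_mdag()], [validate_mdag()],
#'   [d_separated()]
#' @examples
#' g <- mdag(list(node("a"), node("b")), list(c("a", "b")))
#' d_separated(g, "a", "b", character(0))
#' @export
mdag <- function(nodes = list(), edges = list()) {
  if (inherits(nodes, "mdag_node")) nodes <- list(nodes)
  nm <- vapply(nodes, function(n) {
    if (!inherits(n, "mdag_node")) stop("nodes must be node() objects",
                                        call. = FALSE)
    n$name
  }, character(1))
  if (anyDuplicated(nm))
    stop("duplicate node names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  if (is.matrix(edges)) edges <- split(edges, row(edges))
  em <- if (length(edges) == 0L) {
    matrix(character(0), ncol = 2L, dimnames = list(NULL, c("from", "to")))
  } else {
    e <- t(vapply(edges, function(e) {
      if (length(e) != 2L) stop("each edge must be a [from, to] pair",
                                call. = FALSE)
      as.character(e)
    }, character(2)))
    colnames(e) <- c("from", "to")
    e
  }
  bad <- setdiff(unique(c(em)), nm)
  if (length(bad))
    stop("edge endpoint(s) not among node names: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(em[, 1L] == em[, 2L]))
    stop("self-loop on node '", em[em[, 1L] == em[, 2L], 1L][1L], "'",
         call. = FALSE)
  key <- paste(em[, 1L], em[, 2L], sep = "\r")
  if (anyDuplicated(key)) em <- em[!duplicated(key), , drop = FALSE]
  # deterministic edge order
  if (nrow(em) > 1L)
    em <- em[order(em[, 1L], em[, 2L], method = "radix"), , drop = FALSE]
  names(nodes) <- nm
  nodes <- nodes[order(nm, method = "radix")]
  g <- structure(list(nodes = nodes, edges = em), class = "mdag")
  cyc <- find_cycle(g)
  if (!is.null(cyc))
    stop("graph is cyclic: ", paste(cyc, collapse = " -> "), call. = FALSE)
  g
}

#' Node names of an m-DAG (sorted)
#' @param g an `mdag`.
#' @return character vector.
#' @export
node_names <- function(g) names(g$nodes)

#' Parent / child / ancestor sets of a node
#' @param g an `mdag`.
#' @param v node name.
#' @return character vector of node names.
#' @export
parents <- function(g, v) unname(g$edges[g$edges[, 2L] == v, 1L])

#' @rdname parents
#' @export
children <- function(g, v) unname(g$edges[g$edges[, 1L] == v, 2L])

#' @rdname parents
#' @export
ancestors <- function(g, v) {
  seen <- character(0)
  frontier <- v
  while (length(frontier)) {
    p <- unique(unname(g$edges[g$edges[, 2L] %in% frontier, 1L]))
    p <- setdiff(p, seen)
    seen <- c(seen, p)
    frontier <- p
  }
  seen
}

# returns NULL for a DAG, or one cycle as a character vector
find_cycle <- function(g) {
  nm <- node_names(g)
  state <- setNames(integer(length(nm)), nm) # 0 unseen, 1 in stack, 2 done
  ch <- split(unname(g$edges[, 2L]), factor(g$edges[, 1L], levels = nm))
  path <- character(0)
  res <- NULL
  visit <- function(v) {
    if (!is.null(res)) return(invisible())
    if (state[[v]] == 1L) {
      i <- match(v, path)
      res <<- c(path[i:length(path)], v)
      return(invisible())
    }
    if (state[[v]] == 2L) return(invisible())
    state[[v]] <<- 1L
    path <<- c(path, v)
    for (w in ch[[v]]) visit(w)
    path <<- path[-length(path)]
    state[[v]] <<- 2L
  }
  for (v in nm) visit(v)
  res
}

#' Topological order of an m-DAG
#' @param g an `mdag`.
#' @return node names in an order with every edge pointing forward
#'   (deterministic: lexicographic among available nodes).
#' @export
topological_order <- function(g) {
  nm <- node_names(g)
  indeg <- setNames(integer(length(nm)), nm)
  tab <- table(g$edges[, 2L])
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  avail <- sort(nm[indeg == 0L])
  while (length(avail)) {
    v <- avail[1L]
    avail <- avail[-1L]
    out <- c(out, v)
    for (w in children(g, v)) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) avail <- sort(c(avail, w))
    }
  }
  out
}

#' @export
print.mdag <- function(x, ...) {
  kinds <- vapply(x$nodes, `[[`, character(1), "kind")
  cat("m-DAG with ", length(x$nodes), " nodes (",
      sum(kinds == "substantive"), " substantive, ",
      sum(kinds == "latent"), " latent, ",
      sum(kinds == "missingness"), " missingness) and ",
      nrow(x$edges), " edges\n", sep = "")
  if (nrow(x$edges))
    cat("  ", paste(x$edges[, 1L], "->", x$edges[, 2L], collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

node_to_list <- function(n) {
  out <- list(name = n$name, kind = n$kind, role = n$role)
  if (!is.null(n$indicator_of)) out$indicator_of <- n$indicator_of
  if (!is.null(n$group_members)) out$group_members <- as.list(n$group_members)
  out
}

#' Serialize an m-DAG to its canonical JSON form
#'
#' Nodes are emitted sorted by name and edges lexicographically, so the
#' output is byte-stable across runs and round-trips through [parse_mdag()].
#'
#' @param g an `mdag`.
#' @param path optional file to write to.
#' @return the JSON string, invisibly when `path` is given.
#' @export
serialize_mdag <- function(g, path = NULL) {
  doc <- list(
    nodes = lapply(unname(g$nodes), node_to_list),
    edges = lapply(seq_len(nrow(g$edges)),
                   function(i) as.list(unname(g$edges[i, ])))
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  txt <- paste0(as.character(txt), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Parse an m-DAG from its JSON graph format
#'
#' The format is a JSON document with top-level keys `nodes` (list of objects
#' with fields `name`, `kind`, `role`, `indicator_of`, `group_members`) and
#' `edges` (list of two-element `[from, to]` lists). Cyclic inputs are
#' rejected with an error naming one cycle.
#'
#' @param text a JSON string, or a path to a file containing one.
#' @return an `mdag`.
#' @export
parse_mdag <- function(text) {
  src <- if (length(text) == 1L && !grepl("[{\\[]", text) && file.exists(text))
    paste(readLines(text, warn = FALSE), collapse = "\n") else
    paste(text, collapse = "\n")
  doc <- tryCatch(jsonlite::fromJSON(src, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed graph document: ", conditionMessage(e),
                         call. = FALSE))
  if (!is.list(doc) || !all(c("nodes", "edges") %in% names(doc)))
    stop("malformed graph document: top-level keys 'nodes' and 'edges' ",
         "required", call. = FALSE)
  nodes <- lapply(seq_along(doc$nodes), function(i) {
    nd <- doc$nodes[[i]]
    if (is.null(nd$name))
      stop("malformed graph document: node ", i, " has no 'name' field",
           call. = FALSE)
    node(name = nd$name,
         kind = if (is.null(nd$kind)) "substantive" else nd$kind,
         role = if (is.null(nd$role)) "none" else nd$role,
         indicator_of = nd$indicator_of,
         group_members = if (is.null(nd$group_members)) NULL else
           unlist(nd$group_members))
  })
  edges <- lapply(seq_along(doc$edges), function(i) {
    e <- unlist(doc$edges[[i]])
    if (length(e) != 2L)
      stop("malformed graph document: edge ", i, " is not a [from, to] pair",
           call. = FALSE)
    e
  })
  mdag(nodes, edges)
}

#' Check an m-DAG against the overarching structural assumptions
#'
#' The canonical recoverability catalogue for point-exposure studies requires
#' (i) no unmeasured common causes of a variable and a missingness indicator,
#' (ii) no measured common causes of a variable and an indicator left out of
#' the graph, and (iii) no direct arrows out of missingness indicators.
#' Assumption (iii) is checked by scanning edges; assumption (i) by looking
#' for a latent node that parents both a non-missingness node and an
#' indicator. Assumption (ii) concerns variables *not* in the graph and
#' cannot be machine-checked; it is always emitted as a warning requiring
#' user attestation.
#'
#' @param g an `mdag`.
#' @return a `validation_report`: list with `violations` and `warnings`, each
#'   a list of `(code, message)` pairs. An empty `violations` list means the
#'   graph is admissible for canonical classification.
#' @export
validate_mdag <- function(g) {
  viol <- list()
  kinds <- vapply(g$nodes, `[[`, character(1), "kind")
  miss <- names(kinds)[kinds == "missingness"]
  lat <- names(kinds)[kinds == "latent"]
  for (i in seq_len(nrow(g$edges))) {
    if (g$edges[i, 1L] %in% miss)
      viol[[length(viol) + 1L]] <- list(
        code = "ASSUMPTION_III",
        message = paste0("edge ", g$edges[i, 1L], " -> ", g$edges[i, 2L],
                         ": missingness indicators must not cause other ",
                         "variables or indicators"))
  }
  for (u in lat) {
    ch <- children(g, u)
    if (any(ch %in% miss) && any(!(ch %in% miss)))
      viol[[length(viol) + 1L]] <- list(
        code = "ASSUMPTION_I",
        message = paste0("latent node ", u, " is a common cause of a ",
                         "variable and a missingness indicator"))
  }
  warns <- list(list(
    code = "ASSUMPTION_II",
    message = paste("assumption (ii) - no measured common causes of a",
                    "variable and a missingness indicator omitted from the",
                    "graph - cannot be machine-checked; user attestation",
                    "required")))
  structure(list(violations = viol, warnings = warns),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (length(x$violations) == 0L) cat("admissible: no violations\n")
  for (v in x$violations) cat("violation [", v$code, "] ", v$message, "\n",
                              sep = "")
  for (w in x$warnings) cat("warning   [", w$code, "] ", w$message, "\n",
                            sep = "")
  invisible(x)
}

is_admissible <- function(g) length(validate_mdag(g)$violations) == 0L
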