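#' Test d-separation in an m-DAG
#'
#' Decides whether every path between node sets `A` and `B` is blocked by the
#' conditioning set `Z` under the usual rules: a chain or fork is blocked when
#' its middle node is in `Z`; a collider blocks unless the collider or one of
#' its descendants is in `Z`. Implemented by the linear-time reachability
#' ("Bayes-ball") method rather than path enumeration. Collapsed node-groups
#' are atomic: a group node separates or connects exactly like a single node.
#'
#' @param g an `mdag`.
#' @param A,B,Z character vectors of node names; pairwise disjoint, `Z` may
#'   be empty.
#' @return `TRUE` if `A` and `B` are d-separated given `Z`.
#' @examples
#' g <- mdag(list(node("a"), node("b"), node("c")),
#'           list(c("a", "b"), c("b", "c")))
#' d_separated(g, "a", "c", "b")  # chain blocked by conditioning
#' @export
d_separated <- function(g, A, B, Z = character(0)) {
  nm <- node_names(g)
  A <- as.character(A); B <- as.character(B); Z <- as.character(Z)
  unknown <- setdiff(c(A, B, Z), nm)
  if (length(unknown))
    stop("unknown node name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(intersect(A, B)) || length(intersect(A, Z)) ||
      length(intersect(B, Z)))
    stop("A, B and Z must be pairwise disjoint", call. = FALSE)
  if (length(A) == 0L || length(B) == 0L) return(TRUE)

  idx <- seq_along(nm)
  names(idx) <- nm
  pa <- lapply(nm, function(v) unname(idx[parents(g, v)]))
  ch <- lapply(nm, function(v) unname(idx[children(g, v)]))
  in_z <- nm %in% Z
  anc_z <- in_z
  if (any(in_z)) anc_z[idx[ancestors(g, Z)]] <- TRUE
  in_b <- nm %in% B

  n <- length(nm)
  # visited[v, 1]: entered moving "up" (from a child); [v, 2]: "down"
  visited <- matrix(FALSE, n, 2L)
  stack_v <- unname(idx[A])
  stack_d <- rep(1L, length(stack_v))
  while (length(stack_v)) {
    v <- stack_v[length(stack_v)]; d <- stack_d[length(stack_d)]
    stack_v <- stack_v[-length(stack_v)]
    stack_d <- stack_d[-length(stack_d)]
    if (visited[v, d]) next
    visited[v, d] <- TRUE
    if (d == 1L) {            # arrived from a child (or is a source)
      if (!in_z[v]) {
        if (in_b[v]) return(FALSE)
        stack_v <- c(stack_v, pa[[v]], ch[[v]])
        stack_d <- c(stack_d, rep(1L, length(pa[[v]])),
                     rep(2L, length(ch[[v]])))
      }
    } else {                  # arrived from a parent
      if (!in_z[v]) {
        if (in_b[v]) return(FALSE)
        stack_v <- c(stack_v, ch[[v]])
        stack_d <- c(stack_d, rep(2L, length(ch[[v]])))
      }
      if (anc_z[v]) {         # collider at v is opened by Z
        stack_v <- c(stack_v, pa[[v]])
        stack_d <- c(stack_d, rep(1L, length(pa[[v]])))
      }
    }
  }
  TRUE
}
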