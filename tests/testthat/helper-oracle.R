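# Brute-force d-separation oracle: enumerate every simple path between two
# nodes on the skeleton and check the blocking rules explicitly. Kept
# independent of the package's reachability implementation.

# adjacency-matrix representation: amat[i, j] == 1 means i -> j
amat_of <- function(g) {
  nm <- node_names(g)
  A <- matrix(0L, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_len(nrow(g$edges)))
    A[g$edges[i, 1L], g$edges[i, 2L]] <- 1L
  A
}

descendants_of <- function(A, v) {
  nm <- rownames(A)
  seen <- v
  frontier <- v
  while (length(frontier)) {
    nxt <- nm[colSums(A[frontier, , drop = FALSE]) > 0]
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# all simple paths a..b on the skeleton, each as a list of (node, direction)
# where direction[k] is +1 if the edge path[k] -> path[k+1] points forward
enum_paths <- function(A, a, b) {
  nm <- rownames(A)
  sk <- (A + t(A)) > 0
  paths <- list()
  walk <- function(path, dirs) {
    v <- path[length(path)]
    if (v == b) {
      paths[[length(paths) + 1L]] <<- list(nodes = path, dirs = dirs)
      return(invisible())
    }
    for (w in nm[sk[v, ]]) {
      if (w %in% path) next
      walk(c(path, w), c(dirs, if (A[v, w] == 1L) 1L else -1L))
    }
  }
  walk(a, integer(0))
  paths
}

path_blocked <- function(A, path, Z, desc = NULL) {
  nodes <- path$nodes
  dirs <- path$dirs
  k <- length(nodes)
  if (k <= 2L) return(FALSE)      # direct edge: never blocked
  for (i in 2:(k - 1L)) {
    v <- nodes[i]
    collider <- dirs[i - 1L] == 1L && dirs[i] == -1L  # -> v <-
    if (collider) {
      dv <- if (is.null(desc)) descendants_of(A, v) else desc[[v]]
      if (!any(dv %in% Z)) return(TRUE)
    } else {
      if (v %in% Z) return(TRUE)
    }
  }
  FALSE
}

all_descendants <- function(A) {
  nm <- rownames(A)
  lapply(setNames(nm, nm), function(v) descendants_of(A, v))
}

dsep_oracle <- function(g, a, b, Z, A = amat_of(g), paths = NULL,
                        desc = NULL) {
  if (is.null(paths)) paths <- enum_paths(A, a, b)
  for (p in paths) if (!path_blocked(A, p, Z, desc)) return(FALSE)
  TRUE
}

# set version: A and B are d-separated iff every cross pair is
dsep_oracle_set <- function(g, A, B, Z) {
  Amat <- amat_of(g)
  for (a in A) for (b in B)
    if (!dsep_oracle(g, a, b, Z, A = Amat)) return(FALSE)
  TRUE
}

# build an mdag of plain substantive nodes from a 0/1 adjacency matrix
mdag_from_amat <- function(A) {
  nm <- rownames(A)
  idx <- which(A == 1L, arr.ind = TRUE)
  edges <- lapply(seq_len(nrow(idx)),
                  function(i) c(nm[idx[i, 1L]], nm[idx[i, 2L]]))
  mdag(lapply(nm, node), edges)
}

is_acyclic_amat <- function(A) {
  n <- nrow(A)
  B <- A
  for (k in seq_len(n)) {
    if (any(diag(B) > 0)) return(FALSE)
    B <- B %*% A
  }
  TRUE
}

# every DAG on n labelled nodes (feasible for n <= 4)
all_dags <- function(n) {
  nm <- paste0("v", seq_len(n))
  pos <- which(upper.tri(matrix(0, n, n)) | lower.tri(matrix(0, n, n)))
  out <- list()
  for (mask in 0:(2^length(pos) - 1L)) {
    A <- matrix(0L, n, n, dimnames = list(nm, nm))
    bits <- bitwAnd(bitwShiftR(mask, seq_along(pos) - 1L), 1L)
    A[pos] <- bits
    if (is_acyclic_amat(A)) out[[length(out) + 1L]] <- A
  }
  out
}

# random DAG: random topological order, independent edges forward
random_dag_amat <- function(n, p_edge = 0.4) {
  nm <- paste0("v", seq_len(n))
  ord <- sample(n)
  A <- matrix(0L, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (runif(1) < p_edge) A[ord[i], ord[j]] <- 1L
  A
}

all_subsets <- function(x) {
  out <- list(character(0))
  for (v in x) out <- c(out, lapply(out, function(s) c(s, v)))
  out
}
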