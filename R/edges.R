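#' Unique-edge index table for an n-node connectome
#'
#' Connectivity matrices are symmetric with a zero diagonal, so the unit of
#' analysis is the unique (unordered) node pair. Every function in this
#' package that vectorises a matrix into edges uses the same canonical
#' order: the upper triangle traversed row-wise, i.e. pairs `(i, j)` with
#' `i < j` sorted by `i` then `j`. Serialised models record this order so
#' that masks remain interpretable across sessions.
#'
#' @param n_nodes Number of nodes (k), giving `k * (k - 1) / 2` unique edges.
#' @param node_ids Optional node labels (length `n_nodes`); defaults to
#'   `1:n_nodes`.
#' @return A tibble with one row per unique edge: `edge` (1-based position
#'   in the canonical order), `i`, `j` (row/column positions, `i < j`),
#'   `node_i`, `node_j` (labels).
#' @examples
#' edge_index(4)
#' @export
edge_index <- function(n_nodes, node_ids = NULL) {
  stopifnot(n_nodes >= 2)
  if (is.null(node_ids)) node_ids <- seq_len(n_nodes)
  stopifnot(length(node_ids) == n_nodes)
  i <- rep.int(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
  j <- sequence((n_nodes - 1L):1L) + i
  tibble::tibble(
    edge = seq_along(i),
    i = i, j = j,
    node_i = node_ids[i], node_j = node_ids[j]
  )
}

#' Number of unique edges among k nodes
#'
#' @param k Number of nodes.
#' @return `k * (k - 1) / 2`.
#' @examples
#' n_unique_edges(268) # 35778
#' n_unique_edges(205) # 20910
#' @export
n_unique_edges <- function(k) {
  stopifnot(k >= 0)
  k * (k - 1) / 2
}

# Linear indices of the canonical edge order into an n x n matrix.
edge_linear_index <- function(n_nodes) {
  ei <- edge_index(n_nodes)
  (ei$j - 1L) * n_nodes + ei$i
}

#' Vectorise connectivity matrices into a subject-by-edge matrix
#'
#' Stacks one or more symmetric connectivity matrices into the
#' subjects x unique-edges matrix that edge selection operates on, using
#' the canonical edge order of [edge_index()].
#'
#' @param matrices A single connectivity matrix or a (possibly named) list
#'   of them, all sharing the same node roster.
#' @return A numeric matrix (subjects x edges) with subject names as row
#'   names and attributes `node_ids` (the shared roster) and `n_nodes`.
#' @export
edges_from_matrices <- function(matrices) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1)
  ids <- connectivity_node_ids(matrices[[1]])
  n <- length(ids)
  idx <- edge_linear_index(n)
  out <- matrix(NA_real_, nrow = length(matrices), ncol = length(idx))
  for (s in seq_along(matrices)) {
    m <- matrices[[s]]
    if (!identical(dim(m), c(n, n))) {
      stop("matrix ", s, " is not ", n, "x", n, call. = FALSE)
    }
    if (!identical(connectivity_node_ids(m), ids)) {
      stop("matrix ", s, " has a different node roster", call. = FALSE)
    }
    out[s, ] <- m[idx]
  }
  rownames(out) <- names(matrices)
  attr(out, "node_ids") <- ids
  attr(out, "n_nodes") <- n
  out
}

#' Rebuild a symmetric connectivity matrix from an edge vector
#'
#' Inverse of [edges_from_matrices()] for a single subject: places the
#' unique-edge values back into a symmetric zero-diagonal matrix.
#'
#' @param values Numeric vector of length `k * (k - 1) / 2` in canonical
#'   edge order.
#' @param node_ids Node labels (length k).
#' @return A k x k symmetric matrix with zero diagonal and `node_ids` as
#'   dimnames.
#' @export
matrix_from_edges <- function(values, node_ids) {
  n <- length(node_ids)
  if (length(values) != n_unique_edges(n)) {
    stop("expected ", n_unique_edges(n), " edge values for ", n,
         " nodes, got ", length(values), call. = FALSE)
  }
  m <- matrix(0, n, n, dimnames = list(node_ids, node_ids))
  m[edge_linear_index(n)] <- values
  m + t(m)
}

# Node labels of a connectivity matrix: dimnames if present, else 1..n.
connectivity_node_ids <- function(m) {
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  ids
}
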