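#' Neighbor-joining tree from a dissimilarity matrix
#'
#' Saitou–Nei agglomeration with the Studier–Keppler O(N^3) update: at each
#' step the pair (i, j) minimising
#' \eqn{Q_{ij} = (n-2) d_{ij} - r_i - r_j} (with \eqn{r_i = \sum_k d_{ik}})
#' is joined, branch lengths
#' \eqn{l_i = d_{ij}/2 + (r_i - r_j)/(2(n-2))}, \eqn{l_j = d_{ij} - l_i},
#' and distances to the new node \eqn{d_{uk} = (d_{ik} + d_{jk} - d_{ij})/2}.
#' On an additive (tree-metric) matrix this recovers the generating topology
#' and its branch lengths exactly.  Ties in Q are broken deterministically by
#' the smallest (row, column) index pair in the current matrix, so the result
#' is a function of the input alone.
#'
#' The returned tree is unrooted (stored with a trifurcating root, as usual
#' for `phylo`).  Negative branch-length estimates — possible on non-additive
#' data — are clamped to zero in `edge.length`; the raw estimates are kept in
#' `attr(tree, "raw.edge.length")` and the total clamped amount in
#' `attr(tree, "clamped")`.
#'
#' @param D Symmetric numeric matrix with zero diagonal, non-negative
#'   entries, unique `dimnames`; at least 3 taxa.
#' @return An [ape::phylo] tree with `N` leaves and `N - 2` internal nodes.
#' @export
#' @examples
#' D <- matrix(c(0,3,5,6, 3,0,6,7, 5,6,0,7, 6,7,7,0), 4, 4,
#'             dimnames = rep(list(c("A","B","C","D")), 2))
#' neighbor_joining(D)
neighbor_joining <- function(D) {
  if (!is.matrix(D) || !is.numeric(D) || nrow(D) != ncol(D))
    stop_usage("D must be a square numeric matrix")
  N <- nrow(D)
  if (N < 3L) stop_usage("neighbor-joining needs at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels) || anyDuplicated(labels))
    stop_usage("D must have unique row names")
  if (max(abs(D - t(D))) > 1e-8) stop_usage("D is not symmetric")
  if (any(D < 0)) stop_usage("D has negative entries")
  D <- (D + t(D)) / 2
  diag(D) <- 0

  n_internal <- N - 2L
  n_edge <- 2L * N - 3L
  parent <- integer(n_edge)
  child <- integer(n_edge)
  elen <- numeric(n_edge)
  ne <- 0L
  add_edge <- function(p, c, l) {
    ne <<- ne + 1L
    parent[ne] <<- p
    child[ne] <<- c
    elen[ne] <<- l
  }

  node_id <- seq_len(N)  # active cluster -> tree node id (tips 1..N)
  next_internal <- N
  n <- N
  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    next_internal <- next_internal + 1L
    add_edge(next_internal, node_id[i], li)
    add_edge(next_internal, node_id[j], lj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    D[i, ] <- dnew
    D[, i] <- dnew
    D[i, i] <- 0
    keep <- setdiff(seq_len(n), j)
    D <- D[keep, keep, drop = FALSE]
    node_id[i] <- next_internal
    node_id <- node_id[-j]
    n <- n - 1L
  }
  # final 3-star: closed-form lengths to the central node
  next_internal <- next_internal + 1L
  add_edge(next_internal, node_id[1L], (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  add_edge(next_internal, node_id[2L], (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  add_edge(next_internal, node_id[3L], (D[1, 3] + D[2, 3] - D[1, 2]) / 2)

  # renumber internals so the root (the central node, created last) is N+1
  # and edges point away from it, as ape expects
  root_tmp <- next_internal
  remap <- function(v) ifelse(v <= N, v, N + 1L + (root_tmp - v))
  tree <- structure(list(edge = cbind(remap(parent), remap(child)),
                         edge.length = elen,
                         tip.label = labels,
                         Nnode = n_internal),
                    class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")
  raw <- tree$edge.length
  tree$edge.length <- pmax(raw, 0)
  attr(tree, "raw.edge.length") <- raw
  attr(tree, "clamped") <- -sum(raw[raw < 0])
  tree
}

#' Root a tree on the edge separating an outgroup
#'
#' @param tree An [ape::phylo] tree.
#' @param outgroup Character vector of leaf labels; must be a proper,
#'   non-empty subset of the leaves and must form one side of a bipartition
#'   of the unrooted tree.
#' @return The tree rooted on that edge (topology otherwise unchanged).
#' @export
root_by_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  outgroup <- unique(as.character(outgroup))
  unknown <- setdiff(outgroup, tree$tip.label)
  if (length(unknown))
    stop_usage("outgroup leaves not in tree: ", paste(unknown, collapse = ", "))
  if (length(outgroup) == 0L || length(outgroup) >= length(tree$tip.label))
    stop_usage("outgroup must be a proper non-empty subset of the leaves")
  if (!is_monophyletic(tree, outgroup)) {
    stop_input("outgroup is not one side of any bipartition: ",
               paste(outgroup, collapse = ", "))
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}
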