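#' Test whether a set of leaves is monophyletic
#'
#' On an unrooted tree a taxon is monophyletic when some edge bipartitions
#' the leaves into exactly the taxon's members versus everything else — the
#' members "appear exclusively in one branch".  Singletons (and the full
#' leaf set) are trivially monophyletic.  With `rooted = TRUE` the tree's
#' stored rooting is respected and the members must form a clade.
#'
#' @param tree An [ape::phylo] tree.
#' @param leaves Character vector of leaf labels (or integer tip indices).
#' @param rooted Evaluate as a rooted clade instead of an unrooted
#'   bipartition side?  Default `FALSE`.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, leaves, rooted = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  N <- length(tree$tip.label)
  if (is.character(leaves)) {
    idx <- match(unique(leaves), tree$tip.label)
    if (anyNA(idx))
      stop_usage("unknown leaf in set: ",
                 paste(unique(leaves)[is.na(idx)], collapse = ", "))
  } else {
    idx <- unique(as.integer(leaves))
    if (any(idx < 1L | idx > N)) stop_usage("tip index out of range")
  }
  if (length(idx) == 0L) stop_usage("empty leaf set")
  k <- length(idx)
  if (k == 1L || k == N) return(TRUE)
  # complement is a single tip: the tip's own edge provides the bipartition
  if (!rooted && k == N - 1L) return(TRUE)
  target <- sort(idx)
  clades <- node_clades(tree)
  for (cl in clades) {
    if (length(cl) == k && all(cl == target)) return(TRUE)
    if (!rooted && length(cl) == N - k &&
        all(cl == setdiff(seq_len(N), target))) return(TRUE)
  }
  FALSE
}

# Tip-index sets below each internal node, each sorted; the root's full set
# is dropped.  Computed by one postorder sweep.
node_clades <- function(tree) {
  N <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", N + tree$Nnode)
  for (i in seq_len(N)) sets[[i]] <- i
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    c <- tree$edge[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[c]])
  }
  out <- lapply(sets[(N + 1L):(N + tree$Nnode)], sort)
  root <- N + 1L
  out[vapply(seq_along(out), function(i) i + N != root, NA)]
}

# Canonical keys for the non-trivial splits (bipartitions) of a tree: each
# split is represented by the side not containing tip-label `ref`, as a
# comma-joined sorted label string.  Label-based so trees with permuted tip
# numbering compare equal.
split_keys <- function(tree) {
  N <- length(tree$tip.label)
  labs <- tree$tip.label
  ref <- sort(labs)[1L]
  keys <- character(0)
  for (cl in node_clades(tree)) {
    side <- labs[cl]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) >= 2L && length(side) <= N - 2L)
      keys <- c(keys, paste(sort(side), collapse = ","))
  }
  unique(keys)
}

#' Robinson–Foulds distance between two unrooted trees
#'
#' Number of non-trivial bipartitions present in one tree but not the other.
#' Used throughout the test-suite to compare recovered and true topologies;
#' 0 means identical unrooted topology (for binary trees on the same leaves).
#'
#' @param t1,t2 [ape::phylo] trees on the same leaf set.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label))
    stop_usage("trees have different leaf sets")
  k1 <- split_keys(t1)
  k2 <- split_keys(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}
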