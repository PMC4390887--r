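#' Reference validation regime
#'
#' The package's frozen end-to-end validation setting: random 12-leaf trees
#' whose maximum tip-to-tip path is rescaled to a fixed divergence depth, and
#' proteomes large enough that composition-vector distances at K = 5 and 6
#' carry clear phylogenetic signal.  The depth cap matters because cosine
#' dissimilarity saturates near 0.5 once two genomes share essentially no
#' K-peptides; a maximum path of 0.2 expected substitutions per site keeps
#' every pair on the informative part of the curve while leaving internal
#' edges long enough to resolve.  These functions exist so that tests,
#' scripts and users exercise exactly the same conditions.
#'
#' @param n_leaves Number of leaves.
#' @param seed Integer seed.
#' @param depth Maximum tip-to-tip path length (expected substitutions per
#'   site at rate 1).
#' @param equal Use equal relative branch lengths (a deliberately
#'   well-separated tree, used for the bootstrap fixture) instead of
#'   uniform-random ones.
#' @return `validation_tree()`: an [ape::phylo] tree; `validation_params()`:
#'   a [sim_params()] object.
#' @export
validation_tree <- function(n_leaves = 12, seed = 1, depth = 0.2,
                            equal = FALSE) {
  tr <- random_tree(n_leaves, seed = seed,
                    len_min = if (equal) 1 else 0.5,
                    len_max = if (equal) 1 else 1.5)
  tr$edge.length <- tr$edge.length /
    max(as.matrix(stats::cophenetic(tr))) * depth
  tr
}

#' @rdname validation_tree
#' @export
validation_params <- function(seed = 1) {
  sim_params(n_proteins = 150, length_mean = 250, length_sd = 40,
             substitution_rate = 1, seed = seed)
}

#' Topology-recovery study under the validation regime
#'
#' For each replicate: draw a [validation_tree()], evolve proteomes with
#' [validation_params()], run the composition-vector pipeline at each K, and
#' record the Robinson–Foulds distance of the recovered tree to the truth.
#' K-mer tables are counted once per genome and shared across the requested
#' K values.
#'
#' @param n_rep Number of replicates.
#' @param K Integer vector of peptide lengths.
#' @param seed Base seed; replicate r uses seed `seed + r`.
#' @param n_leaves Leaves per replicate tree.
#' @return Integer matrix, `length(K)` rows (named `K5`, ...) by `n_rep`
#'   columns, of RF distances to the truth tree.
#' @export
recovery_study <- function(n_rep = 100, K = c(5L, 6L), seed = 0,
                           n_leaves = 12) {
  K <- as.integer(K)
  kmax <- max(K)
  out <- matrix(NA_integer_, length(K), n_rep,
                dimnames = list(paste0("K", K), NULL))
  for (r in seq_len(n_rep)) {
    rep_seed <- as.integer(seed) + r
    truth <- validation_tree(n_leaves, seed = rep_seed)
    sim <- simulate_proteomes(truth, validation_params(seed = rep_seed))
    tabs <- lapply(sim$proteomes, function(p)
      lapply(seq_len(kmax), function(k)
        if (k >= min(K) - 2L) count_kmers(p, k) else NULL))
    for (ki in seq_along(K)) {
      k <- K[ki]
      cvs <- lapply(tabs, function(tt)
        composition_vector(tt[[k]], tt[[k - 1L]], tt[[k - 2L]]))
      names(cvs) <- names(sim$proteomes)
      est <- neighbor_joining(distance_matrix(cvs))
      out[ki, r] <- rf_distance(est, truth)
    }
  }
  out
}
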