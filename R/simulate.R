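#' Simulation parameters for the synthetic proteome evolver
#'
#' @param n_proteins Number of proteins in the root proteome (>= 1).
#' @param length_mean,length_sd Protein length distribution (residues);
#'   lengths are drawn Normal and truncated below at `length_min`.
#' @param length_min Minimum protein length; must stay >= the largest K you
#'   intend to use (default 25 covers K up to 9 comfortably).
#' @param substitution_rate Expected substitutions per site per unit branch
#'   length; a site on a branch of length `l` substitutes with probability
#'   `1 - exp(-substitution_rate * l)`, to a uniformly chosen different
#'   residue.
#' @param loss_prob,dup_prob Per-protein, per-branch probabilities of whole
#'   protein loss and duplication (defaults 0).
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of (tree, params).
#' @return Object of class `"sim_params"`.
#' @export
sim_params <- function(n_proteins = 60, length_mean = 150, length_sd = 25,
                       length_min = 25, substitution_rate = 1,
                       loss_prob = 0, dup_prob = 0, seed = 1) {
  p <- list(n_proteins = as.integer(n_proteins),
            length_mean = length_mean, length_sd = length_sd,
            length_min = as.integer(length_min),
            substitution_rate = substitution_rate,
            loss_prob = loss_prob, dup_prob = dup_prob,
            seed = as.integer(seed))
  if (p$n_proteins < 1L) stop_usage("n_proteins must be >= 1")
  if (p$length_mean <= 0 || p$length_sd < 0 || p$length_min < 1L)
    stop_usage("bad length parameters")
  if (p$substitution_rate < 0) stop_usage("substitution_rate must be >= 0")
  if (p$loss_prob < 0 || p$loss_prob > 1 || p$dup_prob < 0 || p$dup_prob > 1)
    stop_usage("loss_prob and dup_prob must be in [0, 1]")
  structure(p, class = "sim_params")
}

#' Evolve synthetic proteomes along a known tree
#'
#' A root proteome of i.i.d. uniform amino-acid sequences is evolved along
#' each branch of `tree`: every site substitutes independently with
#' probability `1 - exp(-rate * branch_length)` to a uniformly random
#' different residue (a deliberately simple, analyzable model — no rate
#' matrix, no indels); whole proteins are lost or duplicated with the
#' configured per-branch probabilities.  A leaf that would lose all its
#' proteins keeps one, with a warning, so every leaf yields a valid
#' proteome.  The output is a deterministic function of `(tree, params)`.
#'
#' @param tree A rooted binary [ape::phylo] tree with positive branch
#'   lengths; leaf labels become genome ids.
#' @param params A [sim_params()] object.
#' @return List with `proteomes` (named list of [proteome()] objects, one
#'   per leaf) and `tree` (the truth tree, unchanged).
#' @export
simulate_proteomes <- function(tree, params = sim_params()) {
  stopifnot(inherits(tree, "phylo"), inherits(params, "sim_params"))
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0))
    stop_usage("tree must have positive branch lengths")
  set.seed(params$seed)
  N <- length(tree$tip.label)
  lens <- pmax(params$length_min,
               round(rnorm(params$n_proteins, params$length_mean,
                           params$length_sd)))
  root_prot <- lapply(lens, function(L) sample.int(20L, L, replace = TRUE))

  tree_pre <- ape::reorder.phylo(tree, "cladewise")  # parent before child
  root <- N + 1L
  state <- vector("list", N + tree$Nnode)
  state[[root]] <- root_prot
  leaf_prot <- vector("list", N)
  for (e in seq_len(nrow(tree_pre$edge))) {
    p <- tree_pre$edge[e, 1L]
    ch <- tree_pre$edge[e, 2L]
    evolved <- evolve_branch(state[[p]], tree_pre$edge.length[e], params)
    if (ch <= N) leaf_prot[[ch]] <- evolved else state[[ch]] <- evolved
  }
  proteomes <- lapply(seq_len(N), function(i) {
    proteome(tree$tip.label[i],
             vapply(leaf_prot[[i]], function(v)
               paste(AA20[v], collapse = ""), ""),
             source = "synthetic")
  })
  names(proteomes) <- tree$tip.label
  list(proteomes = proteomes, tree = tree)
}

evolve_branch <- function(prots, len, params) {
  p_sub <- 1 - exp(-params$substitution_rate * len)
  out <- list()
  for (prot in prots) {
    if (params$loss_prob > 0 && runif(1) < params$loss_prob) next
    copies <- 1L
    if (params$dup_prob > 0 && runif(1) < params$dup_prob) copies <- 2L
    for (cp in seq_len(copies)) {
      s <- prot
      if (p_sub > 0) {
        hit <- which(runif(length(s)) < p_sub)
        if (length(hit)) {
          # uniform over the 19 other residues
          shift <- sample.int(19L, length(hit), replace = TRUE)
          s[hit] <- ((s[hit] - 1L + shift) %% 20L) + 1L
        }
      }
      out[[length(out) + 1L]] <- s
    }
  }
  if (length(out) == 0L) {
    warning("branch lost every protein; keeping one resampled survivor")
    out <- list(prots[[sample.int(length(prots), 1L)]])
  }
  out
}

#' Assign clade-derived lineages to the leaves of a truth tree
#'
#' Gives every leaf a complete lineage whose taxa are clades of the tree:
#' the rank-r taxon of a leaf is named after its ancestor r steps below the
#' root (or the leaf itself when the path is shorter), so on the true
#' topology every taxon is monophyletic by construction.  Useful as ground
#' truth for the taxonomy layer.
#'
#' @param tree A rooted [ape::phylo] tree.
#' @return A `"lineage_table"` over the leaves.
#' @export
sim_lineages <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  N <- length(tree$tip.label)
  parent <- integer(N + tree$Nnode)
  for (e in seq_len(nrow(tree$edge)))
    parent[tree$edge[e, 2L]] <- tree$edge[e, 1L]
  root <- N + 1L
  lins <- lapply(seq_len(N), function(tip) {
    path <- tip
    nd <- tip
    while (nd != root) {
      nd <- parent[nd]
      path <- c(nd, path)
    }
    anc <- path[-1L]  # below the root, towards the tip
    nm <- vapply(seq_along(LINEAGE_RANKS), function(d) {
      nd <- anc[min(d, length(anc))]
      if (nd <= N) paste0("tax_", tree$tip.label[nd])
      else paste0("tax_n", nd)
    }, "")
    setNames(nm, LINEAGE_RANKS)
  })
  names(lins) <- tree$tip.label
  as_lineage_table(lins)
}

#' Inject Unclassified ranks into a lineage table
#'
#' Emulates incomplete public-database lineages: for a seeded random subset
#' of genomes (`fraction` of them), all ranks below a random cut point
#' (uniform over P..S) are replaced by `"Unclassified"`.
#'
#' @param lineages A `"lineage_table"`.
#' @param fraction Fraction of genomes to degrade, in `[0, 1]`.
#' @param seed Integer seed.
#' @return The modified `"lineage_table"`.
#' @export
inject_unclassified <- function(lineages, fraction, seed = 1) {
  if (!inherits(lineages, "lineage_table"))
    stop_usage("lineages must be a lineage_table")
  if (fraction < 0 || fraction > 1) stop_usage("fraction must be in [0, 1]")
  set.seed(as.integer(seed))
  n <- nrow(lineages)
  n_pick <- round(fraction * n)
  if (n_pick == 0L) return(lineages)
  pick <- sample.int(n, n_pick)
  cut_ranks <- LINEAGE_RANKS[-1L]  # never blank the domain
  for (i in pick) {
    cut <- sample.int(length(cut_ranks), 1L)
    blank <- cut_ranks[cut:length(cut_ranks)]
    lineages[i, blank] <- UNCLASSIFIED
  }
  mat <- as.matrix(lineages[, LINEAGE_RANKS, drop = FALSE])
  lineages$complete <- apply(mat, 1L, function(v) all(v != UNCLASSIFIED))
  lineages
}

#' Random binary tree for simulations
#'
#' A convenience wrapper: random topology via [ape::rtree()] with branch
#' lengths drawn uniformly from `[len_min, len_max]`, seeded.
#'
#' @param n_leaves Number of leaves.
#' @param seed Integer seed.
#' @param len_min,len_max Branch-length range (units of expected
#'   substitutions per site at rate 1).
#' @return A rooted binary [ape::phylo] tree with leaf labels `g01`, `g02`,
#'   ...
#' @export
random_tree <- function(n_leaves, seed = 1, len_min = 0.02, len_max = 0.10) {
  set.seed(as.integer(seed))
  tr <- ape::rtree(n_leaves,
                   tip.label = sprintf("g%02d", seq_len(n_leaves)))
  tr$edge.length <- runif(nrow(tr$edge), len_min, len_max)
  tr
}
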