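#' Bootstrap support by resampling whole protein products
#'
#' Composition-vector trees have no alignment columns to resample, so the
#' sampling pool is the genome's set of protein products: in each replicate
#' every genome's protein list is resampled with replacement to its original
#' size (independently per genome, seeded deterministically from
#' `(seed, replicate, genome)`), and the full composition-vector → distance
#' → neighbor-joining pipeline is rerun.  The support of an internal edge of
#' the point-estimate tree is the fraction of replicates whose tree contains
#' the same bipartition.
#'
#' A replicate that produces a degenerate proteome (no valid K-window) is
#' rejected and redrawn with a fresh sub-seed; the number of redraws is
#' reported in `attr(tree, "redrawn")`.
#'
#' @param proteomes Named list of [proteome()] objects (>= 4 for internal
#'   edges to exist).
#' @param K Peptide length.
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer master seed.
#' @param extended Extended composition-vector storage (see
#'   [composition_vector()]).
#' @param .identity Internal test hook: skip resampling so every replicate
#'   equals the original data.
#' @return The point-estimate [ape::phylo] tree with `node.label` set to the
#'   support fraction (empty for the root) and a numeric attribute
#'   `"support"` (NA for the root), plus `attr(,"redrawn")`.
#' @export
bootstrap_support <- function(proteomes, K = 6, B = 100, seed = 1,
                              extended = FALSE, .identity = FALSE) {
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop_usage("B must be an integer >= 1")
  seed <- as.integer(seed)
  labels <- names(proteomes)
  if (is.null(labels)) stop_usage("proteomes must be a named list")

  point <- cvtree(proteomes, K = K, extended = extended)$tree
  keys <- split_keys(point)
  hits <- setNames(integer(length(keys)), keys)
  redrawn <- 0L

  for (b in seq_len(B)) {
    attempt <- 0L
    repeat {
      rep_prot <- if (.identity) proteomes else
        resample_proteomes(proteomes, seed, b, attempt)
      tr <- tryCatch(cvtree(rep_prot, K = K, extended = extended)$tree,
                     cvtreer_degenerate_error = function(e) NULL)
      if (!is.null(tr)) break
      redrawn <- redrawn + 1L
      attempt <- attempt + 1L
      if (attempt > 100L)
        stop_degenerate("bootstrap replicate ", b,
                        " keeps producing degenerate proteomes")
    }
    rep_keys <- split_keys(tr)
    hits[keys %in% rep_keys] <- hits[keys %in% rep_keys] + 1L
  }
  support <- hits / B
  attach_supports(point, support, redrawn)
}

# Deterministic per-(replicate, genome) resampling with replacement.
resample_proteomes <- function(proteomes, seed, b, attempt = 0L) {
  out <- proteomes
  for (g in seq_along(proteomes)) {
    sub_seed <- (seed + 1000003 * (b + 7919 * attempt) + 7919 * g) %% .Machine$integer.max
    set.seed(as.integer(sub_seed))
    p <- proteomes[[g]]
    idx <- sample.int(length(p$proteins), length(p$proteins), replace = TRUE)
    out[[g]] <- proteome(p$genome_id, p$proteins[idx], source = p$source)
  }
  out
}

# Write supports onto node labels of the point tree; the root and any node
# whose edge is trivial get an empty label.
attach_supports <- function(tree, support, redrawn) {
  N <- length(tree$tip.label)
  labs <- tree$tip.label
  ref <- sort(labs)[1L]
  clades <- node_clades(tree)  # internal nodes N+2 .. N+Nnode (root dropped)
  node.label <- rep("", tree$Nnode)
  supp_num <- rep(NA_real_, tree$Nnode)
  for (i in seq_along(clades)) {
    side <- labs[clades[[i]]]
    if (ref %in% side) side <- setdiff(labs, side)
    key <- paste(sort(side), collapse = ",")
    if (key %in% names(support)) {
      node.label[i + 1L] <- sprintf("%.3f", support[[key]])
      supp_num[i + 1L] <- support[[key]]
    }
  }
  tree$node.label <- node.label
  attr(tree, "support") <- supp_num
  attr(tree, "redrawn") <- redrawn
  tree
}
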