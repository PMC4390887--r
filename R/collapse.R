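#' Collapse a tree to a taxonomic rank
#'
#' Replaces every maximal branch whose classified leaves all belong to one
#' taxon at the given rank by a single labelled leaf.  Labels follow the
#' field's display conventions:
#' \describe{
#'   \item{`<R>Name{m}`}{m genomes with complete lineage, branch holds the
#'     whole taxon.}
#'   \item{`<R>Name{m+n}`}{additionally n genomes with an Unclassified rank
#'     somewhere in their lineage were absorbed into the branch.}
#'   \item{`<R>Name{k/m}`}{the taxon's m classified genomes are split over
#'     several branches; this branch holds k of them, so the taxon is not
#'     monophyletic in this tree.}
#' }
#' Only genomes with complete lineages (see [lineage_is_complete()]) count
#' towards m and define taxon membership; incomplete genomes never break a
#' branch but surface in the `+n` part.  A maximal branch containing only
#' incomplete genomes is labelled `{0+n}` at the deepest rank for which all
#' its members share a classified name (falling back to `Unclassified` at
#' the requested rank).
#'
#' @param tree An [ape::phylo] tree whose leaves are genome ids.
#' @param lineages A `"lineage_table"` covering every leaf.
#' @param rank Rank code to collapse to, one of D, P, C, O, F, G, S.
#' @return Object of class `"collapsed_tree"`: list with `tree` (a `phylo`
#'   over the collapsed leaves, or `NULL` when fewer than 2 remain), `leaves`
#'   (data frame with columns `label`, `rank`, `taxon`, `m`, `n`, `k`,
#'   `tips`) and `rank`.  The accounting identity
#'   `sum(k or m) + sum(n) == number of original leaves` always holds.
#' @export
collapse_tree <- function(tree, lineages, rank) {
  stopifnot(inherits(tree, "phylo"))
  if (!inherits(lineages, "lineage_table"))
    stop_usage("lineages must be a lineage_table")
  if (!rank %in% LINEAGE_RANKS)
    stop_usage("rank must be one of ", paste(LINEAGE_RANKS, collapse = ", "))
  labs <- tree$tip.label
  N <- length(labs)
  row <- match(labs, lineages$genome_id)
  if (anyNA(row))
    stop_input("leaf without lineage entry: ",
               paste(labs[is.na(row)], collapse = ", "))
  complete <- lineages$complete[row]
  taxon <- lineages[[rank]][row]
  # taxon name used for grouping; NA for incomplete genomes
  gtax <- ifelse(complete, taxon, NA_character_)

  branches <- maximal_uniform_branches(tree, gtax)

  # label each branch
  lin_mat <- as.matrix(lineages[row, LINEAGE_RANKS, drop = FALSE])
  info <- lapply(branches, function(tips) {
    cl <- tips[!is.na(gtax[tips])]
    un <- tips[is.na(gtax[tips])]
    if (length(cl)) {
      list(rank = rank, taxon = gtax[cl[1L]], m = length(cl), n = length(un),
           tips = tips)
    } else {
      # all-incomplete branch: deepest rank shared by every member
      shared_rank <- NA_character_
      shared_name <- UNCLASSIFIED
      for (r in LINEAGE_RANKS[seq_len(match(rank, LINEAGE_RANKS))]) {
        vals <- unique(lin_mat[tips, r])
        if (length(vals) == 1L && vals != UNCLASSIFIED) {
          shared_rank <- r
          shared_name <- vals
        }
      }
      list(rank = if (is.na(shared_rank)) rank else shared_rank,
           taxon = shared_name, m = 0L, n = length(un), tips = tips)
    }
  })

  df <- data.frame(rank = vapply(info, `[[`, "", "rank"),
                   taxon = vapply(info, `[[`, "", "taxon"),
                   m = vapply(info, function(x) as.integer(x$m), 0L),
                   n = vapply(info, function(x) as.integer(x$n), 0L),
                   k = NA_integer_,
                   stringsAsFactors = FALSE)
  df$tips <- lapply(info, `[[`, "tips")

  # taxa split over several branches get {k/m} labels with m the total count
  key <- paste(df$rank, df$taxon, sep = "\r")
  split_taxa <- names(which(table(key[df$m > 0L]) > 1L))
  for (s in split_taxa) {
    rows <- which(key == s & df$m > 0L)
    total <- sum(df$m[rows])
    df$k[rows] <- df$m[rows]
    df$m[rows] <- total
  }
  df$label <- render_collapsed_label(df$rank, df$taxon, df$m, df$n, df$k)
  if (anyDuplicated(df$label))
    df$label <- make.unique(df$label, sep = "#")
  df <- df[c("label", "rank", "taxon", "m", "n", "k", "tips")]

  # shrink the tree: keep one representative tip per branch, then relabel
  out_tree <- NULL
  if (nrow(df) >= 2L) {
    reps <- vapply(df$tips, function(t) labs[t[1L]], "")
    out_tree <- ape::keep.tip(tree, reps)
    out_tree$tip.label <- df$label[match(out_tree$tip.label, reps)]
  }
  structure(list(tree = out_tree, leaves = df, rank = rank,
                 n_original = N),
            class = "collapsed_tree")
}

# Maximal branches (as tip-index vectors) such that all classified leaves in
# a branch share one taxon name; leaves with NA taxon (incomplete lineage)
# never block merging.  Works on the tree's stored rooting: a preorder walk
# that stops descending at the first node whose classified leaves are
# uniform.
maximal_uniform_branches <- function(tree, taxon_by_tip) {
  N <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntax <- vector("list", N + tree$Nnode)   # distinct classified taxa below
  tips <- vector("list", N + tree$Nnode)   # tip indices below
  for (i in seq_len(N)) {
    ntax[[i]] <- if (is.na(taxon_by_tip[i])) character(0) else taxon_by_tip[i]
    tips[[i]] <- i
  }
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
    ntax[[p]] <- unique(c(ntax[[p]], ntax[[c]]))
    tips[[p]] <- c(tips[[p]], tips[[c]])
  }
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  root <- N + 1L
  out <- list()
  walk <- function(node) {
    if (length(ntax[[node]]) <= 1L) {
      out[[length(out) + 1L]] <<- sort(tips[[node]])
    } else {
      for (ch in children[[as.character(node)]]) walk(ch)
    }
  }
  walk(root)
  out
}

# Render "<R>Name{m}", "<R>Name{m+n}" or "<R>Name{k/m}" labels (vectorised).
render_collapsed_label <- function(rank, taxon, m, n, k = NA_integer_) {
  ifelse(!is.na(k), sprintf("<%s>%s{%d/%d}", rank, taxon, k, m),
         ifelse(n > 0L, sprintf("<%s>%s{%d+%d}", rank, taxon, m, n),
                sprintf("<%s>%s{%d}", rank, taxon, m)))
}

#' @export
print.collapsed_tree <- function(x, ...) {
  cat(sprintf("Tree collapsed to rank <%s>: %d leaves from %d genomes\n",
              x$rank, nrow(x$leaves), x$n_original))
  for (lab in x$leaves$label) cat("  ", lab, "\n", sep = "")
  invisible(x)
}
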