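#' Build a composition-vector tree from proteomes
#'
#' The core pipeline in memory: composition vectors at peptide length K for
#' every genome, the pairwise cosine dissimilarity matrix, and the
#' neighbor-joining tree.  Deterministic: the result is a function of the
#' proteomes, K and the storage flag alone.
#'
#' @param proteomes Named list of [proteome()] objects (>= 3).
#' @param K Peptide length (>= 3; 5 and 6 give the most taxonomically
#'   consistent trees, 6 is the default).
#' @param extended Extended composition-vector storage (see
#'   [composition_vector()]).
#' @return Object of class `"cvtree"`: list with `K`, `dist` (labelled
#'   symmetric matrix), `tree` ([ape::phylo]), `n_genomes`, `n_components`
#'   (stored components per genome).
#' @export
#' @examples
#' sim <- simulate_proteomes(random_tree(5, seed = 7),
#'                           sim_params(n_proteins = 20, seed = 7))
#' fit <- cvtree(sim$proteomes, K = 4)
#' fit
cvtree <- function(proteomes, K = 6, extended = FALSE) {
  if (is.null(names(proteomes)) || any(!nzchar(names(proteomes))))
    stop_usage("proteomes must be a named list")
  if (length(proteomes) < 3L) stop_usage("need at least 3 proteomes")
  cvs <- lapply(seq_along(proteomes), function(i) {
    tryCatch(cv_from_proteome(proteomes[[i]], K = K, extended = extended),
             cvtreer_degenerate_error = function(e)
               stop_degenerate("genome '", names(proteomes)[i], "': ",
                               conditionMessage(e)))
  })
  D <- distance_matrix(cvs, labels = names(proteomes))
  tree <- neighbor_joining(D)
  structure(list(K = K, dist = D, tree = tree,
                 n_genomes = length(proteomes),
                 n_components = vapply(cvs, function(v)
                   length(v$components), 0L)),
            class = "cvtree")
}

#' @export
print.cvtree <- function(x, ...) {
  cat(sprintf("Composition-vector tree: %d genomes, K=%d\n",
              x$n_genomes, x$K))
  cat(sprintf("  mean stored components per genome: %.0f\n",
              mean(x$n_components)))
  cat(sprintf("  dissimilarity range: [%.4f, %.4f]\n",
              min(x$dist[upper.tri(x$dist)]), max(x$dist[upper.tri(x$dist)])))
  cat("  tree:", ape::Ntip(x$tree), "leaves,", x$tree$Nnode,
      "internal nodes\n")
  invisible(x)
}

#' @method summary cvtree
#' @export
summary.cvtree <- function(object, ...) {
  ut <- object$dist[upper.tri(object$dist)]
  structure(list(K = object$K, n_genomes = object$n_genomes,
                 dist_summary = summary(ut),
                 clamped = attr(object$tree, "clamped"),
                 tree = object$tree),
            class = "summary.cvtree")
}

#' @export
print.summary.cvtree <- function(x, ...) {
  cat(sprintf("Composition-vector tree (K=%d, %d genomes)\n",
              x$K, x$n_genomes))
  cat("Pairwise dissimilarities:\n")
  print(x$dist_summary)
  if (!is.null(x$clamped) && x$clamped > 0)
    cat(sprintf("Negative branch lengths clamped (total %.3g)\n", x$clamped))
  invisible(x)
}

#' @method plot cvtree
#' @export
plot.cvtree <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
  invisible(x)
}

#' Pipeline run configuration
#'
#' Collects and validates everything a file-based run depends on; the
#' artifacts are a function of these values only (no hidden parameters).
#'
#' @param manifest Path to a `genome_id<TAB>fasta_path` manifest (see
#'   [read_manifest()]).
#' @param out_dir Output directory (created if missing).
#' @param K Integer vector of peptide lengths, all >= 3.
#' @param lineages Optional lineage TSV path; enables the taxonomy layer
#'   (collapsed trees and the convergence report).
#' @param bootstrap Number of bootstrap replicates (0 = none).
#' @param seed Integer seed for the bootstrap resampling.
#' @param outgroup Optional character vector of genome ids used to root the
#'   output trees.
#' @param extended Extended composition-vector storage.
#' @param ranks Ranks to collapse to when lineages are given.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(manifest, out_dir, K = c(5L, 6L), lineages = NULL,
                       bootstrap = 0L, seed = 1L, outgroup = NULL,
                       extended = FALSE, ranks = c("P", "C", "O", "F", "G")) {
  K <- as.integer(K)
  if (length(K) == 0L || anyNA(K) || any(K < 3L))
    stop_usage("K values must be integers >= 3")
  if (!file.exists(manifest)) stop_input("no such manifest: ", manifest)
  if (!is.null(lineages) && !file.exists(lineages))
    stop_input("no such lineage file: ", lineages)
  structure(list(manifest = manifest, out_dir = out_dir, K = sort(unique(K)),
                 lineages = lineages, bootstrap = as.integer(bootstrap),
                 seed = as.integer(seed), outgroup = outgroup,
                 extended = isTRUE(extended), ranks = ranks),
            class = "run_config")
}

#' Run the full pipeline and write every artifact
#'
#' For each configured K: the square PHYLIP distance matrix
#' (`dist_K<k>.phylip`), the neighbor-joining tree (`tree_K<k>.nwk`, with
#' bootstrap supports as internal labels when `bootstrap > 0`), and — when a
#' lineage table is given — one collapsed tree per configured rank
#' (`collapsed_K<k>_<rank>.nwk` plus a `.tsv` of leaf labels).  Across K, a
#' convergence-statistics report (`report.txt`, `report.tsv`).  A `run.log`
#' records the configuration and every decision taken (clamped branch
#' lengths, redrawn bootstrap replicates).  Re-running the same
#' configuration reproduces every artifact byte for byte.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a list with the per-K `"cvtree"` fits, the report (or
#'   NULL) and the artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  proteomes <- read_manifest(config$manifest)
  lineages <- if (!is.null(config$lineages)) read_lineages(config$lineages)
  log_lines <- c("# cvtreer run log",
                 paste0("package_version=", as.character(utils::packageVersion("cvtreer"))),
                 paste0("n_genomes=", length(proteomes)),
                 paste0("K=", paste(config$K, collapse = ",")),
                 paste0("bootstrap=", config$bootstrap),
                 paste0("seed=", config$seed),
                 paste0("extended=", config$extended))
  paths <- character(0)
  fits <- list()
  trees <- list()
  for (K in config$K) {
    fit <- if (config$bootstrap > 0L) {
      tr <- bootstrap_support(proteomes, K = K, B = config$bootstrap,
                              seed = config$seed, extended = config$extended)
      f <- cvtree(proteomes, K = K, extended = config$extended)
      f$tree <- tr
      log_lines <- c(log_lines,
                     sprintf("K%d_bootstrap_redrawn=%d", K,
                             attr(tr, "redrawn")))
      f
    } else {
      cvtree(proteomes, K = K, extended = config$extended)
    }
    if (!is.null(config$outgroup))
      fit$tree <- root_by_outgroup(fit$tree, config$outgroup)
    log_lines <- c(log_lines,
                   sprintf("K%d_clamped_branch_length=%.6g", K,
                           attr(fit$tree, "clamped") %||% 0))
    dp <- file.path(config$out_dir, sprintf("dist_K%d.phylip", K))
    tp <- file.path(config$out_dir, sprintf("tree_K%d.nwk", K))
    write_distmatrix(fit$dist, dp)
    write_newick(fit$tree, tp)
    paths <- c(paths, dp, tp)
    if (!is.null(lineages)) {
      for (r in config$ranks) {
        cl <- collapse_tree(fit$tree, lineages, r)
        cp <- file.path(config$out_dir,
                        sprintf("collapsed_K%d_%s.tsv", K, r))
        write.table(cl$leaves[c("label", "rank", "taxon", "m", "n", "k")],
                    cp, sep = "\t", quote = FALSE, row.names = FALSE)
        paths <- c(paths, cp)
        if (!is.null(cl$tree)) {
          cnp <- file.path(config$out_dir,
                           sprintf("collapsed_K%d_%s.nwk", K, r))
          write_newick(cl$tree, cnp)
          paths <- c(paths, cnp)
        }
      }
    }
    fits[[as.character(K)]] <- fit
    trees[[as.character(K)]] <- fit$tree
  }
  report <- NULL
  if (!is.null(lineages)) {
    report <- convergence_report(trees, lineages)
    rt <- file.path(config$out_dir, "report.txt")
    rv <- file.path(config$out_dir, "report.tsv")
    write_report(report, rt, "text")
    write_report(report, rv, "tsv")
    paths <- c(paths, rt, rv)
  }
  lp <- file.path(config$out_dir, "run.log")
  writeLines(log_lines, lp)
  paths <- c(paths, lp)
  invisible(list(fits = fits, report = report, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
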