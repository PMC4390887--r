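#' Cross-K monophyly ("convergence statistics") report
#'
#' For every taxon at ranks D..G (configurable), tests whether the taxon's
#' classified members form a monophyletic branch in the tree built at each K,
#' and reports one line per taxon.  Rendered lines follow the convention
#' `"<D>Archaea{165} - - K5 K6 K7"`: the count in braces, then one slot per
#' K in range — `K<k>` when monophyletic at that K, `-` when not.  Only
#' genomes with complete lineage information are counted and tested; a taxon
#' with a single member is trivially monophyletic everywhere.
#'
#' @param trees_by_K Named list of [ape::phylo] trees; names are the K
#'   values (e.g. `list("5" = t5, "6" = t6)`).  All trees must share one
#'   leaf set.
#' @param lineages A `"lineage_table"` covering every leaf.
#' @param ranks Rank codes to report, default D..G.
#' @return Object of class `"convergence_report"`: a data frame with columns
#'   `rank`, `taxon`, `size` and one logical column `K<k>` per tree.
#' @export
convergence_report <- function(trees_by_K, lineages,
                               ranks = c("D", "P", "C", "O", "F", "G")) {
  if (length(trees_by_K) == 0L) stop_usage("no trees given")
  Ks <- suppressWarnings(as.integer(names(trees_by_K)))
  if (anyNA(Ks)) stop_usage("trees_by_K must be named by integer K values")
  if (!inherits(lineages, "lineage_table"))
    stop_usage("lineages must be a lineage_table")
  if (any(!ranks %in% LINEAGE_RANKS)) stop_usage("bad rank code")
  leafsets <- lapply(trees_by_K, function(t) sort(t$tip.label))
  for (i in seq_along(leafsets)[-1L]) {
    if (!identical(leafsets[[i]], leafsets[[1L]]))
      stop_input("trees at different K have different leaf sets")
  }
  leaves <- leafsets[[1L]]
  miss <- setdiff(leaves, lineages$genome_id)
  if (length(miss))
    stop_input("leaf without lineage entry: ", paste(miss, collapse = ", "))
  lt <- lineages[match(leaves, lineages$genome_id), , drop = FALSE]
  lt <- lt[lt$complete, , drop = FALSE]

  rows <- list()
  for (r in ranks) {
    for (taxon in sort(unique(lt[[r]]))) {
      members <- lt$genome_id[lt[[r]] == taxon]
      flags <- vapply(trees_by_K, is_monophyletic, NA, leaves = members)
      rows[[length(rows) + 1L]] <-
        c(list(rank = r, taxon = taxon, size = length(members)),
          as.list(setNames(flags, paste0("K", Ks))))
    }
  }
  df <- do.call(rbind, lapply(rows, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  df <- df[c("rank", "taxon", "size", paste0("K", sort(Ks)))]
  attr(df, "K") <- sort(Ks)
  class(df) <- c("convergence_report", "data.frame")
  df
}

#' Render a convergence report as fixed-format text lines
#'
#' @param x A `"convergence_report"`.
#' @param ... Unused.
#' @return Character vector, one line per taxon, e.g.
#'   `"<D>Archaea{165} - - K5 K6 K7"`.
#' @method format convergence_report
#' @export
format.convergence_report <- function(x, ...) {
  Ks <- attr(x, "K")
  vapply(seq_len(nrow(x)), function(i) {
    slots <- vapply(Ks, function(k) {
      if (isTRUE(x[[paste0("K", k)]][i])) paste0("K", k) else "-"
    }, "")
    sprintf("<%s>%s{%d} %s", x$rank[i], x$taxon[i], x$size[i],
            paste(slots, collapse = " "))
  }, "")
}

#' @export
print.convergence_report <- function(x, ...) {
  writeLines(format(x))
  invisible(x)
}

#' Write a convergence report
#'
#' @param x A `"convergence_report"`.
#' @param path Output path.
#' @param format `"text"` (the fixed-format lines) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("text", "tsv")) {
  format <- match.arg(format)
  if (format == "text") {
    writeLines(format.convergence_report(x), path)
  } else {
    df <- as.data.frame(x)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
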