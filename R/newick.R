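#' Read a Newick tree file
#'
#' Thin wrapper over [ape::read.tree()] adding the validation this pipeline
#' relies on: the file must contain exactly one tree, parentheses must
#' balance, and leaf labels must be unique.
#'
#' @param path Newick file path.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  opens <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  closes <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (opens != closes)
    stop_parse("unbalanced parentheses in ", path,
               " (", opens, " '(' vs ", closes, "')')")
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop_parse("cannot parse Newick in ",
                                                path, ": ", conditionMessage(e)))
  if (is.null(tr)) stop_parse("cannot parse Newick in ", path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop_input(path, " contains more than one tree")
    tr <- tr[[1L]]
  }
  if (anyDuplicated(tr$tip.label))
    stop_parse("duplicate leaf label in ", path, ": ",
               tr$tip.label[duplicated(tr$tip.label)][1L])
  tr
}

#' Write a tree as Newick
#'
#' Branch lengths and internal-node labels (bootstrap supports) are kept;
#' child order is preserved, so writing then reading reproduces the tree.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}
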