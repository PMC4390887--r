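#' Create a lineage-modification rule
#'
#' A trial re-assignment written as "old_lineage new_lineage": genomes whose
#' lineage matches every rank named in the old fragment have exactly the
#' ranks named in the new fragment rewritten.  Fragments need not contain
#' all ranks, but must name the same rank set so that the rewrite is a
#' one-to-one replacement and the rule is invertible.
#'
#' @param old,new Lineage fragments such as
#'   `"<P>Thaumarchaeota<G>Caldiarchaeum"`, or a single string `old new`
#'   (whitespace-separated) in `old` with `new` omitted.
#' @return Object of class `"modification_rule"`.
#' @export
#' @examples
#' modification_rule("<P>Thaumarchaeota<G>Caldiarchaeum",
#'                   "<P>Aigarchaeota<G>Caldiarchaeum")
modification_rule <- function(old, new = NULL) {
  if (is.null(new)) {
    parts <- strsplit(trimws(old), "[[:space:]]+")[[1L]]
    if (length(parts) != 2L)
      stop_parse("rule must be two whitespace-separated lineage fragments")
    old <- parts[1L]
    new <- parts[2L]
  }
  old_f <- parse_lineage(old, fill = FALSE)
  new_f <- parse_lineage(new, fill = FALSE)
  if (length(old_f) == 0L || length(new_f) == 0L)
    stop_parse("empty lineage fragment in rule")
  if (!setequal(names(old_f), names(new_f)))
    stop_parse("old and new fragments must name the same ranks (got <",
               paste(names(old_f), collapse = "><"), "> vs <",
               paste(names(new_f), collapse = "><"), ">)")
  structure(list(old = old_f, new = new_f[names(old_f)]),
            class = "modification_rule")
}

#' @export
print.modification_rule <- function(x, ...) {
  cat("Lineage modification:", format_lineage(x$old), "->",
      format_lineage(x$new), "\n")
  invisible(x)
}

#' Apply a lineage-modification rule
#'
#' A genome matches when every (rank, name) pair of the rule's old fragment
#' equals its lineage at that rank; matching genomes have the ranks named in
#' the new fragment rewritten.  Because matching requires equality at every
#' named rank, all matched genomes share identical values there — the
#' written fragment is "uniquely recognizable" — and a rule matching nothing
#' is an error.
#'
#' @param lineages A `"lineage_table"`.
#' @param rule A [modification_rule()] (or a string parseable as one).
#' @return List with `lineages` (modified copy), `n_changed` and `genomes`
#'   (ids of the rewritten genomes).
#' @export
apply_modification <- function(lineages, rule) {
  if (!inherits(lineages, "lineage_table"))
    stop_usage("lineages must be a lineage_table")
  if (is.character(rule)) rule <- modification_rule(rule)
  stopifnot(inherits(rule, "modification_rule"))
  hit <- rep(TRUE, nrow(lineages))
  for (r in names(rule$old)) hit <- hit & lineages[[r]] == rule$old[[r]]
  if (!any(hit))
    stop_input("fragment not recognizable: no genome matches ",
               format_lineage(rule$old))
  out <- lineages
  for (r in names(rule$new)) out[[r]][hit] <- rule$new[[r]]
  mat <- as.matrix(out[, LINEAGE_RANKS, drop = FALSE])
  out$complete <- apply(mat, 1L, function(v) all(v != UNCLASSIFIED))
  list(lineages = out, n_changed = sum(hit),
       genomes = lineages$genome_id[hit])
}
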