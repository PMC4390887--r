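#' Parse one rank-labelled lineage string
#'
#' Lineages are written as a run of `<R>Name` tokens where `R` is one of the
#' rank codes D, P, C, O, F, G, S (domain, phylum, class, order, family,
#' genus, species) plus T (strain) for leaf display.  Ranks must appear in
#' that order, each at most once; ranks that are omitted (trailing or
#' interior) are filled with `"Unclassified"`, the marker for a missing rank
#' assignment.
#'
#' @param text A lineage string such as
#'   `"<D>Archaea<P>Euryarchaeota<C>Thermococci"`.
#' @param fill Logical; fill missing D..S ranks with `"Unclassified"`
#'   (default).  With `fill = FALSE` only the ranks actually written are
#'   returned (used for lineage-modification fragments).
#' @return Named character vector of taxon names, names being rank codes.
#' @seealso [parse_lineage_line()], [lineage_is_complete()]
#' @export
parse_lineage <- function(text, fill = TRUE) {
  text <- trimws(text)
  if (!nzchar(text)) stop_parse("empty lineage string")
  if (!grepl("^(<[^>]*>[^<>]*)+$", text))
    stop_parse("malformed lineage string: '", text, "'")
  m <- gregexpr("<([^>]*)>([^<>]*)", text, perl = TRUE)[[1L]]
  tokens <- regmatches(text, list(m))[[1L]]
  codes <- sub("^<([^>]*)>.*$", "\\1", tokens)
  names_ <- trimws(sub("^<[^>]*>", "", tokens))
  unknown <- setdiff(codes, RANK_CODES)
  if (length(unknown))
    stop_parse("unknown rank code <", unknown[1L], "> in '", text, "'")
  if (anyDuplicated(codes))
    stop_parse("duplicate rank code <", codes[duplicated(codes)][1L],
               "> in '", text, "'")
  ord <- match(codes, RANK_CODES)
  if (is.unsorted(ord, strictly = TRUE))
    stop_parse("ranks out of order in '", text, "'")
  if (any(!nzchar(names_)))
    stop_parse("empty taxon name at rank <",
               codes[!nzchar(names_)][1L], "> in '", text, "'")
  lin <- setNames(names_, codes)
  if (!fill) return(lin)
  full <- setNames(rep(UNCLASSIFIED, length(LINEAGE_RANKS)), LINEAGE_RANKS)
  full[intersect(names(lin), LINEAGE_RANKS)] <-
    lin[intersect(names(lin), LINEAGE_RANKS)]
  if ("T" %in% names(lin)) full <- c(full, lin["T"])
  full
}

#' Parse one line of a lineage table
#'
#' A lineage table line is `genome_id<TAB>lineage-string`; see
#' [parse_lineage()] for the lineage grammar.
#'
#' @param text One table line.
#' @return A list with `genome_id` and `lineage` (named character vector over
#'   ranks D..S, possibly with T).
#' @export
#' @examples
#' parse_lineage_line("g1\t<D>Archaea<P>Euryarchaeota<C>Thermococci")
parse_lineage_line <- function(text) {
  parts <- strsplit(text, "\t", fixed = TRUE)[[1L]]
  if (length(parts) != 2L)
    stop_parse("lineage line is not 'genome_id<TAB>lineage': '", text, "'")
  id <- trimws(parts[1L])
  if (!nzchar(id)) stop_parse("empty genome_id in lineage line: '", text, "'")
  list(genome_id = id, lineage = parse_lineage(parts[2L]))
}

#' Is a lineage complete?
#'
#' A lineage is complete when none of the ranks D..S is `"Unclassified"`.
#' Only genomes with complete lineages are counted as classified members of a
#' taxon; incomplete ones are tracked via the `+n` part of collapsed-leaf
#' labels.
#'
#' @param lineage Named character vector as returned by [parse_lineage()].
#' @return Logical scalar.
#' @export
lineage_is_complete <- function(lineage) {
  all(lineage[LINEAGE_RANKS] != UNCLASSIFIED) &&
    !anyNA(lineage[LINEAGE_RANKS])
}

#' Read a lineage table
#'
#' Tab-separated file with one `genome_id<TAB>lineage-string` per line;
#' blank lines and `#` comments are ignored.
#'
#' @param path File path.
#' @return A `data.frame` of class `"lineage_table"` with columns
#'   `genome_id`, `D`, `P`, `C`, `O`, `F`, `G`, `S` and logical `complete`.
#' @export
read_lineages <- function(path) {
  if (!file.exists(path)) stop_input("no such lineage file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  if (length(lines) == 0L) stop_input("lineage file has no entries: ", path)
  parsed <- lapply(seq_along(lines), function(i) {
    tryCatch(parse_lineage_line(lines[i]),
             cvtreer_parse_error = function(e)
               stop_parse("line ", which(keep)[i], " of ", path, ": ",
                          conditionMessage(e)))
  })
  ids <- vapply(parsed, `[[`, "", "genome_id")
  if (anyDuplicated(ids))
    stop_input("duplicate genome_id in ", path, ": ", ids[duplicated(ids)][1L])
  lineage_table(ids, t(vapply(parsed, function(p) p$lineage[LINEAGE_RANKS],
                              character(length(LINEAGE_RANKS)))))
}

lineage_table <- function(ids, mat) {
  colnames(mat) <- LINEAGE_RANKS
  df <- data.frame(genome_id = ids, mat, stringsAsFactors = FALSE,
                   row.names = NULL, check.names = FALSE)
  df$complete <- apply(mat, 1L, function(r) all(r != UNCLASSIFIED))
  class(df) <- c("lineage_table", "data.frame")
  df
}

#' Build a lineage table from named lineage vectors
#'
#' @param lineages Named list of lineage vectors (names = genome ids), each
#'   as returned by [parse_lineage()].
#' @return A `"lineage_table"` data frame; see [read_lineages()].
#' @export
as_lineage_table <- function(lineages) {
  if (is.null(names(lineages)) || any(!nzchar(names(lineages))))
    stop_usage("lineages must be a named list keyed by genome_id")
  lineage_table(names(lineages),
                t(vapply(lineages, function(l) {
                  full <- setNames(rep(UNCLASSIFIED, 7L), LINEAGE_RANKS)
                  full[intersect(names(l), LINEAGE_RANKS)] <-
                    l[intersect(names(l), LINEAGE_RANKS)]
                  full
                }, character(7L))))
}

#' Format a lineage as a rank-labelled string
#'
#' @param lineage Named character vector over ranks.
#' @return String such as `"<D>Archaea<P>Euryarchaeota..."`; all D..S ranks
#'   are written explicitly (including `Unclassified`) so tables round-trip.
#' @export
format_lineage <- function(lineage) {
  ranks <- intersect(RANK_CODES, names(lineage))
  paste0("<", ranks, ">", lineage[ranks], collapse = "")
}

#' Write a lineage table
#'
#' @param lineages A `"lineage_table"` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lineages <- function(lineages, path) {
  stopifnot(inherits(lineages, "lineage_table"))
  lines <- vapply(seq_len(nrow(lineages)), function(i) {
    paste0(lineages$genome_id[i], "\t",
           format_lineage(unlist(lineages[i, LINEAGE_RANKS])))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# genome_id -> taxon name at `rank`, NA for genomes absent from the table.
lineage_name_at <- function(lineages, rank, ids) {
  stopifnot(rank %in% LINEAGE_RANKS)
  lineages[[rank]][match(ids, lineages$genome_id)]
}
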