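#' Construct a proteome object
#'
#' A proteome is the complete set of protein products encoded by one genome:
#' an ordered list of uppercase amino-acid sequences under a single genome
#' identifier.  This is the unit of input for composition-vector phylogeny;
#' the identifier, not the per-protein FASTA headers, names the genome
#' throughout the pipeline.
#'
#' @param genome_id Non-empty string identifying the genome.
#' @param proteins Character vector of amino-acid sequences (uppercased and
#'   stripped of `*` and whitespace on construction).
#' @param source Provenance string, a file path or `"synthetic"`.
#' @return An object of class `"proteome"`: a list with elements `genome_id`,
#'   `proteins` and `source`.
#' @seealso [read_proteome()], [write_proteome()]
#' @export
#' @examples
#' p <- proteome("g1", c("MKVLT", "MAVR"))
#' p
proteome <- function(genome_id, proteins, source = "synthetic") {
  if (!is.character(genome_id) || length(genome_id) != 1L || !nzchar(genome_id))
    stop_usage("genome_id must be a single non-empty string")
  if (!is.character(proteins) || length(proteins) == 0L)
    stop_input("proteome '", genome_id, "' has no protein sequences")
  proteins <- toupper(gsub("[*[:space:]]", "", proteins))
  if (any(!nzchar(proteins)))
    stop_input("proteome '", genome_id, "' contains empty sequences after sanitization")
  bad <- grepl("[^A-Z]", proteins)
  if (any(bad))
    stop_input("proteome '", genome_id, "' has non-letter residues in sequence ",
               which(bad)[1L])
  structure(list(genome_id = genome_id, proteins = unname(proteins),
                 source = source),
            class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("Proteome '%s': %d proteins, %d residues (source: %s)\n",
              x$genome_id, length(x$proteins), sum(nchar(x$proteins)), x$source))
  invisible(x)
}

#' Read a proteome from a multi-record amino-acid FASTA file
#'
#' One file per genome, one record per protein product, in file order.
#' Sequences are uppercased; `*` (stop) characters and whitespace are stripped
#' wherever they occur, since exported protein sets vary in whether they keep
#' terminal stops.
#'
#' @param path Path to a FASTA file with at least one record.
#' @param genome_id Genome identifier; defaults to the file stem.  Never taken
#'   from FASTA headers, which name proteins rather than genomes.
#' @return A [proteome()] object.
#' @export
read_proteome <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  if (is.null(genome_id))
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- readLines(path, warn = FALSE)
  body <- raw[nzchar(trimws(raw))]
  if (length(body) == 0L)
    stop_input("empty FASTA file (zero records): ", path)
  if (!startsWith(trimws(body[1L]), ">")) {
    line_no <- which(nzchar(trimws(raw)))[1L]
    stop_parse("not FASTA: line ", line_no, " of ", path,
               " does not start a record")
  }
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L)
    stop_input("empty FASTA file (zero records): ", path)
  proteome(genome_id, as.character(seqs), source = path)
}

#' Write a proteome to FASTA
#'
#' Records are written in order with headers `p1`, `p2`, ... ; headers carry
#' no information in this pipeline.  `read_proteome(write_proteome(p))`
#' reproduces the sequences exactly.
#'
#' @param p A [proteome()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(p, path) {
  stopifnot(inherits(p, "proteome"))
  x <- Biostrings::BStringSet(p$proteins)
  names(x) <- paste0("p", seq_along(p$proteins))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a manifest of proteome FASTA files
#'
#' A manifest is a two-column TSV `genome_id<TAB>fasta_path` (relative paths
#' resolved against the manifest's directory, `#` comments allowed).  All
#' files are read with [read_proteome()].
#'
#' @param path Manifest TSV path.
#' @return Named list of [proteome()] objects, in manifest order.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_input("no such manifest: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop_input("empty manifest: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop_parse("manifest line ", which(lengths(parts) != 2L)[1L],
               " is not 'genome_id<TAB>path'")
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop_input("duplicate genome_id in manifest: ", ids[duplicated(ids)][1L])
  paths <- vapply(parts, `[[`, "", 2L)
  rel <- !grepl("^(/|[A-Za-z]:)", paths)
  paths[rel] <- file.path(dirname(path), paths[rel])
  missing <- !file.exists(paths)
  if (any(missing))
    stop_input("manifest references missing file(s): ",
               paste(paths[missing], collapse = ", "))
  setNames(Map(read_proteome, paths, ids), ids)
}
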