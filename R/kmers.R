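#' Count K-peptides in a proteome
#'
#' Every length-K window of consecutive residues is counted, within each
#' protein independently (windows never span protein boundaries).  Windows
#' containing any character outside the 20 standard amino acids are discarded
#' and do not contribute to the window total, so frequencies remain proper
#' frequencies over the counted windows.  Proteins shorter than K contribute
#' nothing.
#'
#' @param p A [proteome()] object.
#' @param K Window length, an integer >= 1.
#' @return An object of class `"kmer_table"`: list with `K`, `counts` (named
#'   integer vector, lexicographically sorted keys) and `total` (number of
#'   counted windows, `== sum(counts)`).
#' @export
#' @examples
#' count_kmers(proteome("g", "MKVMKV"), 2)$counts
count_kmers <- function(p, K) {
  stopifnot(inherits(p, "proteome"))
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop_usage("K must be an integer >= 1")
  w <- proteome_windows(p$proteins, K)
  if (length(w) == 0L)
    stop_degenerate("proteome '", p$genome_id,
                    "' has no valid length-", K, " window")
  r <- rle(sort(w, method = "radix"))
  structure(list(K = K,
                 counts = setNames(as.integer(r$lengths), r$values),
                 total = length(w)),
            class = "kmer_table")
}

# All valid K-windows of a character vector of sequences, file order.
proteome_windows <- function(seqs, K) {
  L <- nchar(seqs)
  seqs <- seqs[L >= K]
  L <- L[L >= K]
  if (length(seqs) == 0L) return(character(0))
  w <- unlist(lapply(seq_along(seqs), function(i) {
    substring(seqs[i], 1L:(L[i] - K + 1L), K:L[i])
  }), use.names = FALSE)
  w[!grepl(NON_AA_PATTERN, w)]
}

NON_AA_PATTERN <- "[^ACDEFGHIKLMNPQRSTVWY]"

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("K-mer table: K=%d, %d distinct peptides, %d windows\n",
              x$K, length(x$counts), x$total))
  invisible(x)
}
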