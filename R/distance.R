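#' Cosine correlation between two composition vectors
#'
#' \eqn{C(A,B) = \sum_s a_A(s) a_B(s) / (\|a_A\| \|a_B\|)}.  The dot product
#' runs over the intersection of the stored peptide sets — exact, because a
#' peptide absent from a vector's storage has component 0 there — while each
#' norm is taken over that vector's full stored set.
#'
#' @param a,b `"composition_vector"` objects with the same K.
#' @return Correlation in `[-1, 1]`.
#' @export
cv_correlation <- function(a, b) {
  stopifnot(inherits(a, "composition_vector"), inherits(b, "composition_vector"))
  if (a$K != b$K)
    stop_usage("composition vectors have different K (", a$K, " vs ", b$K, ")")
  if (a$norm <= 0 || b$norm <= 0)
    stop_degenerate("zero-norm composition vector")
  i <- match(names(b$components), names(a$components))
  keep <- !is.na(i)
  dot <- sum(a$components[i[keep]] * b$components[keep])
  max(-1, min(1, dot / (a$norm * b$norm)))
}

#' Cosine dissimilarity between two composition vectors
#'
#' \eqn{D(A,B) = (1 - C(A,B)) / 2}, mapping correlation 1 (identical
#' direction) to 0, orthogonality to 0.5 and opposition to 1.
#'
#' @inheritParams cv_correlation
#' @return Dissimilarity in `[0, 1]`.
#' @export
cv_dissimilarity <- function(a, b) {
  (1 - cv_correlation(a, b)) / 2
}

#' Pairwise dissimilarity matrix for a set of composition vectors
#'
#' @param cvs List of `"composition_vector"` objects, all with the same K.
#' @param labels Genome labels, unique, same length as `cvs`; defaults to
#'   `names(cvs)`.
#' @return Symmetric numeric matrix with zero diagonal, `dimnames` set to
#'   `labels`, entries in `[0, 1]`, label order preserved from the input.
#' @export
distance_matrix <- function(cvs, labels = names(cvs)) {
  n <- length(cvs)
  if (n < 3L) stop_usage("need at least 3 composition vectors")
  if (is.null(labels) || length(labels) != n || any(!nzchar(labels)))
    stop_usage("labels must be non-empty and match the number of vectors")
  if (anyDuplicated(labels))
    stop_usage("duplicate genome label: ", labels[duplicated(labels)][1L])
  Ks <- vapply(cvs, `[[`, 0L, "K")
  if (length(unique(Ks)) != 1L)
    stop_usage("composition vectors have mixed K values")
  bad <- vapply(cvs, function(v) v$norm <= 0, NA)
  if (any(bad))
    stop_degenerate("zero-norm composition vector for genome '",
                    labels[bad][1L], "'")
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- cv_dissimilarity(cvs[[i]], cvs[[j]])
    }
  }
  D
}

#' Write a distance matrix in square PHYLIP format
#'
#' First line is the taxon count; each following line is a taxon name and its
#' full row of distances, written with 10 significant digits so that
#' [read_distmatrix()] inverts the file to that precision.  Whitespace in
#' names is replaced by `_`.
#'
#' @param D Symmetric numeric matrix with `dimnames`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distmatrix <- function(D, path) {
  if (!is.matrix(D) || nrow(D) != ncol(D) || is.null(rownames(D)))
    stop_usage("D must be a square matrix with row names")
  labels <- gsub("[[:space:]]+", "_", rownames(D))
  if (anyDuplicated(labels))
    stop_input("taxon names collide after whitespace sanitization: ",
               labels[duplicated(labels)][1L])
  lines <- c(sprintf("%5d", nrow(D)),
             vapply(seq_len(nrow(D)), function(i) {
               paste(labels[i],
                     paste(sprintf("%.10g", D[i, ]), collapse = "  "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' @param path File written by [write_distmatrix()] or any square-format
#'   PHYLIP distance file.
#' @return Symmetric numeric matrix with `dimnames`.
#' @export
read_distmatrix <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop_parse("not a PHYLIP distance file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    stop_parse("bad taxon count on line 1 of ", path)
  if (length(lines) != n + 1L)
    stop_parse("expected ", n, " rows in ", path, ", found ", length(lines) - 1L)
  labels <- character(n)
  D <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(lines[i + 1L]), "[[:space:]]+")[[1L]]
    if (length(fields) != n + 1L)
      stop_parse("row ", i, " of ", path, " has ", length(fields) - 1L,
                 " values, expected ", n)
    labels[i] <- fields[1L]
    D[i, ] <- as.numeric(fields[-1L])
  }
  if (anyNA(D)) stop_parse("non-numeric distance in ", path)
  dimnames(D) <- list(labels, labels)
  D
}
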