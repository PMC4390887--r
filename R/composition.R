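#' Background-subtracted composition vector
#'
#' Converts raw K-peptide frequencies into selection-highlighting deviations
#' from a Markov background.  For a K-peptide \eqn{s = \alpha_1\ldots\alpha_K}
#' with observed frequency \eqn{f_K(s) = n(s)/T_K}, the (K-2)-th order Markov
#' prediction from the (K-1)- and (K-2)-peptide frequencies is
#' \deqn{f^0(s) = \frac{f_{K-1}(\alpha_1..\alpha_{K-1})\,
#'   f_{K-1}(\alpha_2..\alpha_K)}{f_{K-2}(\alpha_2..\alpha_{K-1})}}
#' and the stored component is the relative deviation
#' \eqn{a(s) = (f_K(s) - f^0(s))/f^0(s)} (0 when \eqn{f^0(s) = 0}).  This
#' subtraction removes the part of the K-peptide composition explained by
#' shorter-range correlations — the background of neutral mutation — leaving
#' the signature shaped by selection.
#'
#' By default only observed peptides (\eqn{n(s) > 0}) are stored; for an
#' observed peptide \eqn{f^0(s) > 0} always holds, because its prefix, suffix
#' and core were necessarily observed too.  With `extended = TRUE`,
#' unobserved peptides whose background prediction is positive are stored as
#' well; these have \eqn{a(s) = -1} exactly.  Components are bounded below by
#' -1, with equality only for such unobserved peptides.
#'
#' @param tK,tK1,tK2 [count_kmers()] tables of the same proteome at lengths
#'   K, K-1 and K-2 (K >= 3).
#' @param extended Also store unobserved-but-predicted peptides (a = -1)?
#' @return Object of class `"composition_vector"`: list with `K`,
#'   `components` (named numeric, lexicographically sorted) and `norm`
#'   (Euclidean norm of the stored components).
#' @export
composition_vector <- function(tK, tK1, tK2, extended = FALSE) {
  stopifnot(inherits(tK, "kmer_table"), inherits(tK1, "kmer_table"),
            inherits(tK2, "kmer_table"))
  K <- tK$K
  if (K < 3L) stop_usage("composition vectors need K >= 3")
  if (tK1$K != K - 1L || tK2$K != K - 2L)
    stop_usage("tables must have lengths K, K-1, K-2 (got ",
               tK$K, ", ", tK1$K, ", ", tK2$K, ")")
  if (tK$total == 0L || tK1$total == 0L || tK2$total == 0L)
    stop_degenerate("a k-mer table has zero counted windows")

  s <- names(tK$counts)
  fK <- tK$counts / tK$total
  f0 <- markov_background(s, K, tK1, tK2)
  if (any(f0 <= 0))
    stop_degenerate("observed peptide with zero background prediction; ",
                    "k-mer tables are not from the same proteome")
  a <- fK / f0 - 1

  if (extended) {
    pred <- predicted_kmers(K, tK1)
    extra <- setdiff(pred, s)
    if (length(extra)) {
      a <- c(a, setNames(rep(-1, length(extra)), extra))
      a <- a[order(names(a), method = "radix")]
    }
  }
  structure(list(K = K, components = a, norm = sqrt(sum(a * a))),
            class = "composition_vector")
}

# f0 for a vector of K-peptides from the K-1 / K-2 tables.
markov_background <- function(s, K, tK1, tK2) {
  pre <- substr(s, 1L, K - 1L)
  suf <- substr(s, 2L, K)
  mid <- substr(s, 2L, K - 1L)
  f1p <- unname(tK1$counts[pre]) / tK1$total
  f1s <- unname(tK1$counts[suf]) / tK1$total
  f2 <- unname(tK2$counts[mid]) / tK2$total
  f1p[is.na(f1p)] <- 0
  f1s[is.na(f1s)] <- 0
  out <- numeric(length(s))
  ok <- !is.na(f2) & f2 > 0
  out[ok] <- f1p[ok] * f1s[ok] / f2[ok]
  out
}

# All K-peptides with positive Markov prediction: prefix and suffix both
# observed as (K-1)-peptides, joined over their shared (K-2)-core.
predicted_kmers <- function(K, tK1) {
  km1 <- names(tK1$counts)
  starts <- split(substr(km1, 1L, 1L), substr(km1, 2L, K - 1L))
  ends <- split(substr(km1, K - 1L, K - 1L), substr(km1, 1L, K - 2L))
  mids <- intersect(names(starts), names(ends))
  unlist(lapply(mids, function(m) {
    as.vector(outer(starts[[m]], ends[[m]],
                    function(x, y) paste0(x, m, y)))
  }), use.names = FALSE)
}

#' Composition vector straight from a proteome
#'
#' Convenience wrapper: counts K-, (K-1)- and (K-2)-peptides and applies the
#' background subtraction of [composition_vector()].
#'
#' @inheritParams count_kmers
#' @inheritParams composition_vector
#' @return A `"composition_vector"` object.
#' @export
cv_from_proteome <- function(p, K = 6, extended = FALSE) {
  K <- as.integer(K)
  if (is.na(K) || K < 3L) stop_usage("K must be an integer >= 3")
  composition_vector(count_kmers(p, K), count_kmers(p, K - 1L),
                     count_kmers(p, K - 2L), extended = extended)
}

#' @export
print.composition_vector <- function(x, ...) {
  cat(sprintf("Composition vector: K=%d, %d stored components, norm %.6g\n",
              x$K, length(x$components), x$norm))
  invisible(x)
}

#' Tabulate a composition vector for inspection
#'
#' Recomputes every quantity entering the subtraction and returns them in one
#' table, lexicographically sorted: peptide, raw count, frequency f, Markov
#' background f0 and component a.  Intended for debugging and spot checks;
#' written as TSV when `path` is given.
#'
#' @inheritParams cv_from_proteome
#' @param path Optional TSV output path.
#' @return Invisibly (if `path` given) or visibly, a `data.frame` with
#'   columns `peptide`, `count`, `f`, `f0`, `a`.
#' @export
cv_tabulate <- function(p, K = 6, extended = FALSE, path = NULL) {
  K <- as.integer(K)
  tK <- count_kmers(p, K)
  tK1 <- count_kmers(p, K - 1L)
  tK2 <- count_kmers(p, K - 2L)
  cv <- composition_vector(tK, tK1, tK2, extended = extended)
  pep <- names(cv$components)
  cnt <- tK$counts[pep]
  cnt[is.na(cnt)] <- 0L
  df <- data.frame(peptide = pep,
                   count = as.integer(cnt),
                   f = as.integer(cnt) / tK$total,
                   f0 = markov_background(pep, K, tK1, tK2),
                   a = unname(cv$components),
                   stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
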