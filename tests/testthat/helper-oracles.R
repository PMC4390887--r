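# Shared fixtures and independent oracles.  Oracles deliberately use the
# most naive data structures (per-window loops, dense named vectors) so they
# share no code path with the package implementation.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_protein <- function(len, alphabet = AA) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

rand_proteome <- function(id = "g", n_prot = 3, len_min = 40, len_max = 120,
                          alphabet = AA) {
  proteome(id, vapply(seq_len(n_prot), function(i)
    rand_protein(sample(len_min:len_max, 1), alphabet), ""))
}

# Naive substring-enumeration K-mer counter: walks every window one by one.
naive_kmer_count <- function(proteins, K) {
  env <- new.env(parent = emptyenv())
  total <- 0L
  for (s in proteins) {
    ch <- strsplit(s, "")[[1]]
    L <- length(ch)
    if (L < K) next
    for (i in seq_len(L - K + 1L)) {
      w <- ch[i:(i + K - 1L)]
      if (all(w %in% AA)) {
        key <- paste(w, collapse = "")
        env[[key]] <- (if (is.null(env[[key]])) 0L else env[[key]]) + 1L
        total <- total + 1L
      }
    }
  }
  keys <- sort(ls(env))
  list(counts = setNames(vapply(keys, function(k) env[[k]], 0L), keys),
       total = total)
}

# Dense composition-vector oracle: direct dictionary arithmetic for f, f0, a
# over the observed K-peptides.
naive_cv <- function(proteins, K) {
  tK <- naive_kmer_count(proteins, K)
  tK1 <- naive_kmer_count(proteins, K - 1L)
  tK2 <- naive_kmer_count(proteins, K - 2L)
  a <- numeric(0)
  for (s in names(tK$counts)) {
    f <- tK$counts[[s]] / tK$total
    pre <- substr(s, 1, K - 1)
    suf <- substr(s, 2, K)
    mid <- substr(s, 2, K - 1)
    f1p <- if (pre %in% names(tK1$counts)) tK1$counts[[pre]] / tK1$total else 0
    f1s <- if (suf %in% names(tK1$counts)) tK1$counts[[suf]] / tK1$total else 0
    f2 <- if (mid %in% names(tK2$counts)) tK2$counts[[mid]] / tK2$total else 0
    f0 <- if (f2 > 0) f1p * f1s / f2 else 0
    a[[s]] <- if (f0 > 0) (f - f0) / f0 else 0
  }
  a
}

# Dense cosine over the union key set with absent entries as 0.
dense_cosine <- function(x, y) {
  keys <- union(names(x), names(y))
  xv <- setNames(numeric(length(keys)), keys)
  yv <- xv
  xv[names(x)] <- x
  yv[names(y)] <- y
  sum(xv * yv) / sqrt(sum(xv^2) * sum(yv^2))
}

# Independent bipartition oracle: cut each edge of the (unrooted) tree and
# flood-fill the remaining graph to find the two leaf sides.
edge_splits_bfs <- function(tree) {
  N <- length(tree$tip.label)
  M <- N + tree$Nnode
  adj <- vector("list", M)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(seq_len(nrow(tree$edge)), function(e) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    seen <- rep(FALSE, M)
    seen[b] <- TRUE
    queue <- b
    while (length(queue)) {
      nd <- queue[1L]; queue <- queue[-1L]
      for (nb in adj[[nd]]) {
        if (!seen[nb] && !(nd == b && nb == a)) {
          seen[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
    sort(tree$tip.label[which(seen[seq_len(N)])])
  })
}

# A small simulated dataset used by several files.
sim_fixture <- function(n_leaves = 8, seed = 11, n_proteins = 40) {
  tr <- random_tree(n_leaves, seed = seed)
  sim <- simulate_proteomes(tr, sim_params(n_proteins = n_proteins,
                                           seed = seed))
  sim$lineages <- sim_lineages(tr)
  sim
}
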