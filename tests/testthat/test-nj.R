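test_that("the textbook additive quartet is recovered with exact lengths", {
  # distances from the tree ((A:1,B:2):1,(C:3,D:4)) with internal edge 1
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = rep(list(c("A", "B", "C", "D")), 2))
  tr <- neighbor_joining(D)
  expect_identical(ape::Ntip(tr), 4L)
  expect_identical(tr$Nnode, 2L)
  # split AB|CD present, the two alternatives absent
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_false(is_monophyletic(tr, c("A", "D")))
  # additivity: path lengths reproduce D exactly
  expect_equal(as.matrix(stats::cophenetic(tr))[rownames(D), colnames(D)], D,
               tolerance = 1e-12)
  tip_len <- setNames(tr$edge.length[tr$edge[, 2] <= 4],
                      tr$tip.label[tr$edge[tr$edge[, 2] <= 4, 2]])
  expect_equal(tip_len[c("A", "B", "C", "D")],
               c(A = 1, B = 2, C = 3, D = 4), tolerance = 1e-12)
})

test_that("three taxa resolve to the closed-form star", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = rep(list(c("A", "B", "C")), 2))
  tr <- neighbor_joining(D)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[c("A", "B", "C")],
               c(A = (2 + 3 - 4) / 2, B = (2 + 4 - 3) / 2, C = (3 + 4 - 2) / 2),
               tolerance = 1e-12)
})

test_that("NJ is exactly consistent on random additive matrices", {
  set.seed(61)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    truth <- random_tree(n, seed = 6000 + i, len_min = 0.1, len_max = 1)
    D <- as.matrix(stats::cophenetic(truth))
    est <- neighbor_joining(D)
    expect_identical(rf_distance(est, truth), 0L)
    expect_equal(as.matrix(stats::cophenetic(est))[rownames(D), colnames(D)],
                 D, tolerance = 1e-9)
  }
})

test_that("NJ topology matches an independent implementation on noisy matrices", {
  set.seed(71)
  for (i in 1:10) {
    n <- sample(5:10, 1)
    truth <- random_tree(n, seed = 7000 + i, len_min = 0.1, len_max = 1)
    D <- as.matrix(stats::cophenetic(truth))
    noise <- matrix(runif(n * n, 0, 0.02), n, n)
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    Dn <- D + noise
    est <- neighbor_joining(Dn)
    ref <- ape::nj(Dn)
    expect_identical(rf_distance(est, ref), 0L)
  }
})

test_that("ties break by smallest index pair, deterministically", {
  # equidistant taxa: every Q entry ties, so the result is fixed by the rule
  D <- matrix(1, 5, 5, dimnames = rep(list(LETTERS[1:5]), 2))
  diag(D) <- 0
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  # first join must be (row 1, col 2) = A,B
  expect_true(is_monophyletic(t1, c("A", "B")))
})

test_that("negative branch estimates are clamped with the raw values retained", {
  D <- matrix(c(0, 0.1, 0.4, 0.5,
                0.1, 0, 0.45, 0.55,
                0.4, 0.45, 0, 0.05,
                0.5, 0.55, 0.05, 0), 4, 4,
              dimnames = rep(list(letters[1:4]), 2))
  # warp into a matrix violating additivity hard enough to go negative
  D["a", "b"] <- D["b", "a"] <- 0.9
  tr <- neighbor_joining(D)
  raw <- attr(tr, "raw.edge.length")
  expect_true(all(tr$edge.length >= 0))
  expect_equal(attr(tr, "clamped"), -sum(raw[raw < 0]), tolerance = 1e-12)
  expect_equal(pmax(raw, 0), tr$edge.length, tolerance = 0)
})

test_that("invalid matrices are usage errors", {
  D <- matrix(c(0, 1, 2, 1, 0, 1, 1.5, 1, 0), 3, 3,
              dimnames = rep(list(c("a", "b", "c")), 2))
  expect_error(neighbor_joining(D), class = "cvtreer_usage_error")
  D2 <- matrix(c(0, -1, 1, -1, 0, 1, 1, 1, 0), 3, 3,
               dimnames = rep(list(c("a", "b", "c")), 2))
  expect_error(neighbor_joining(D2), class = "cvtreer_usage_error")
  expect_error(neighbor_joining(matrix(0, 2, 2,
                                       dimnames = rep(list(c("a", "b")), 2))),
               class = "cvtreer_usage_error")
})

test_that("outgroup rooting requires a bipartition and preserves topology", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = rep(list(c("A", "B", "C", "D")), 2))
  tr <- neighbor_joining(D)
  rooted <- root_by_outgroup(tr, c("C", "D"))
  expect_true(ape::is.rooted(rooted))
  expect_identical(rf_distance(rooted, tr), 0L)
  expect_error(root_by_outgroup(tr, c("A", "C")),
               class = "cvtreer_input_error")
  expect_error(root_by_outgroup(tr, c("A", "Z")),
               class = "cvtreer_usage_error")
})
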