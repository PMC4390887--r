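fixture_trees <- function() {
  # 6 genomes, two classes X = {a,b,c}, Y = {d,e,f}
  good <- ape::read.tree(text = "(((a,b),c),((d,e),f));")
  bad <- ape::read.tree(text = "(((a,b),d),((c,e),f));")  # X,Y broken
  lin <- as_lineage_table(setNames(lapply(c("X", "X", "X", "Y", "Y", "Y"),
                                          function(cl) {
                                            l <- parse_lineage(sprintf(
                                              "<D>Dom<P>Phy<C>%s", cl))
                                            l[c("O", "F", "G", "S")] <-
                                              paste0(cl, c("o", "f", "g", "s"))
                                            l
                                          }),
                                   c("a", "b", "c", "d", "e", "f")))
  list(good = good, bad = bad, lineages = lin)
}

test_that("per-K flags equal direct monophyly calls", {
  fx <- fixture_trees()
  trees <- list("5" = fx$good, "6" = fx$bad)
  rep <- convergence_report(trees, fx$lineages, ranks = c("D", "P", "C"))
  for (i in seq_len(nrow(rep))) {
    members <- fx$lineages$genome_id[fx$lineages[[rep$rank[i]]] == rep$taxon[i]]
    expect_identical(rep$K5[i], is_monophyletic(fx$good, members))
    expect_identical(rep$K6[i], is_monophyletic(fx$bad, members))
  }
  x <- rep[rep$rank == "C" & rep$taxon == "X", ]
  expect_true(x$K5)
  expect_false(x$K6)
  expect_identical(x$size, 3L)
})

test_that("taxa monophyletic everywhere get every slot set; singletons always do", {
  fx <- fixture_trees()
  rep <- convergence_report(list("5" = fx$good, "6" = fx$good),
                            fx$lineages, ranks = c("C", "O"))
  expect_true(all(rep$K5 & rep$K6))
  orders <- rep[rep$rank == "O", ]
  expect_true(all(orders$size == 3L) || all(orders$K5))
})

test_that("rendered lines follow the <R>Name{N} K-slot convention", {
  fx <- fixture_trees()
  trees <- setNames(list(fx$good, fx$good, fx$bad, fx$good, fx$good),
                    as.character(3:7))
  rep <- convergence_report(trees, fx$lineages, ranks = c("D", "C"))
  lines <- format(rep)
  # the domain covers every leaf, so it is trivially monophyletic at all K
  expect_identical(lines[rep$rank == "D"], "<D>Dom{6} K3 K4 K5 K6 K7")
  xline <- lines[rep$rank == "C" & rep$taxon == "X"]
  expect_identical(xline, "<C>X{3} K3 K4 - K6 K7")
})

test_that("incomplete lineages are excluded from counts and membership", {
  fx <- fixture_trees()
  lin <- fx$lineages
  lin[lin$genome_id == "c", c("O", "F", "G", "S")] <- "Unclassified"
  lin$complete <- apply(as.matrix(lin[, c("D", "P", "C", "O", "F", "G", "S")]),
                        1, function(v) all(v != "Unclassified"))
  # with c incomplete, X has members {a,b}: monophyletic even in `bad`
  rep <- convergence_report(list("6" = fx$bad), lin, ranks = c("C"))
  x <- rep[rep$taxon == "X", ]
  expect_identical(x$size, 2L)
  expect_true(x$K6)
})

test_that("reports are invariant under leaf-order permutation of the trees", {
  fx <- fixture_trees()
  rot <- ape::rotateConstr(fx$good, rev(sort(fx$good$tip.label)))
  r1 <- convergence_report(list("5" = fx$good), fx$lineages)
  r2 <- convergence_report(list("5" = rot), fx$lineages)
  expect_identical(format(r1), format(r2))
})

test_that("trees over different leaf sets are rejected", {
  fx <- fixture_trees()
  pruned <- ape::drop.tip(fx$good, "a")
  expect_error(convergence_report(list("5" = fx$good, "6" = pruned),
                                  fx$lineages),
               class = "cvtreer_input_error")
})

test_that("reports write as text and TSV", {
  fx <- fixture_trees()
  rep <- convergence_report(list("5" = fx$good), fx$lineages)
  f1 <- withr::local_tempfile(fileext = ".txt")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep, f1, "text")
  write_report(rep, f2, "tsv")
  expect_identical(readLines(f1), format(rep))
  back <- read.delim(f2, stringsAsFactors = FALSE)
  expect_identical(nrow(back), nrow(rep))
})
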