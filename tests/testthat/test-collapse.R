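# helper: lineage table from a compact spec list
make_lineages <- function(...) {
  entries <- list(...)
  as_lineage_table(lapply(entries, function(e) parse_lineage(e)))
}

complete_lin <- function(class_name, tag) {
  sprintf("<D>Dom<P>Phy<C>%s<O>O%s<F>F%s<G>G%s<S>S%s",
          class_name, tag, tag, tag, tag)
}

test_that("monophyletic classes collapse to <C>Name{m} leaves", {
  tr <- ape::read.tree(text = "((x1,x2),(y1,y2));")
  lin <- make_lineages(x1 = complete_lin("X", "x1"),
                       x2 = complete_lin("X", "x2"),
                       y1 = complete_lin("Y", "y1"),
                       y2 = complete_lin("Y", "y2"))
  cl <- collapse_tree(tr, lin, "C")
  expect_setequal(cl$leaves$label, c("<C>X{2}", "<C>Y{2}"))
  expect_identical(sort(cl$tree$tip.label), sort(cl$leaves$label))
})

test_that("incomplete lineages are absorbed into the branch as +n", {
  tr <- ape::read.tree(text = "((x1,x2),(y1,y2));")
  lin <- make_lineages(x1 = complete_lin("X", "x1"),
                       x2 = "<D>Dom<P>Phy<C>Unclassified",
                       y1 = complete_lin("Y", "y1"),
                       y2 = complete_lin("Y", "y2"))
  cl <- collapse_tree(tr, lin, "C")
  expect_setequal(cl$leaves$label, c("<C>X{1+1}", "<C>Y{2}"))
})

test_that("paraphyletic taxa split into {k/m} leaves summing to m", {
  tr <- ape::read.tree(text = "((x1,y1),(x2,y2));")
  lin <- make_lineages(x1 = complete_lin("X", "x1"),
                       y1 = complete_lin("Y", "y1"),
                       x2 = complete_lin("X", "x2"),
                       y2 = complete_lin("Y", "y2"))
  cl <- collapse_tree(tr, lin, "C")
  expect_identical(sort(cl$leaves$label),
                   sort(c("<C>X{1/2}", "<C>X{1/2}#1",
                          "<C>Y{1/2}", "<C>Y{1/2}#1")))
  xs <- cl$leaves[cl$leaves$taxon == "X", ]
  expect_identical(sum(xs$k), unique(xs$m))
})

test_that("all-incomplete branches are labelled at the deepest shared rank", {
  tr <- ape::read.tree(text = "((u1,u2),((x1,x2),(y1,y2)));")
  lin <- make_lineages(u1 = "<D>Dom<P>Phy<C>Unclassified",
                       u2 = "<D>Dom<P>Phy<C>Unclassified",
                       x1 = complete_lin("X", "x1"),
                       x2 = complete_lin("X", "x2"),
                       y1 = complete_lin("Y", "y1"),
                       y2 = complete_lin("Y", "y2"))
  cl <- collapse_tree(tr, lin, "C")
  # u1,u2 share only the phylum, so their branch reads <P>Phy{0+2}
  expect_setequal(cl$leaves$label, c("<P>Phy{0+2}", "<C>X{2}", "<C>Y{2}"))
})

test_that("an unclassified cherry inside a taxon's branch is absorbed", {
  tr <- ape::read.tree(text = "(((u1,u2),x1),(y1,y2));")
  lin <- make_lineages(u1 = "<D>Dom<P>Phy<C>Unclassified",
                       u2 = "<D>Dom<P>Phy<C>Unclassified",
                       x1 = complete_lin("X", "x1"),
                       y1 = complete_lin("Y", "y1"),
                       y2 = complete_lin("Y", "y2"))
  cl <- collapse_tree(tr, lin, "C")
  expect_setequal(cl$leaves$label, c("<C>X{1+2}", "<C>Y{2}"))
})

test_that("collapse conserves leaf accounting on random fixtures", {
  set.seed(103)
  for (i in 1:6) {
    n <- sample(6:14, 1)
    tr <- random_tree(n, seed = 1030 + i)
    lin <- sim_lineages(tr)
    if (i %% 2 == 0) lin <- inject_unclassified(lin, 0.4, seed = i)
    for (rank in c("P", "C", "F")) {
      cl <- collapse_tree(tr, lin, rank)
      parts <- ifelse(!is.na(cl$leaves$k), cl$leaves$k, cl$leaves$m)
      expect_identical(sum(parts) + sum(cl$leaves$n), n)
      # collapsing only relabels; the backbone keeps leaves together
      expect_identical(sum(lengths(cl$leaves$tips)), n)
    }
  }
})

test_that("a leaf without lineage information is an input error", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  lin <- make_lineages(a = complete_lin("X", "a"),
                       b = complete_lin("X", "b"),
                       c = complete_lin("Y", "c"))
  expect_error(collapse_tree(tr, lin, "C"), class = "cvtreer_input_error")
})
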