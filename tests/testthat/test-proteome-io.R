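test_that("FASTA proteomes parse in file order with sanitization", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p1", "MKV", ">p2", "mav*"), f)
  p <- read_proteome(f, "g1")
  expect_s3_class(p, "proteome")
  expect_identical(p$proteins, c("MKV", "MAV"))
  expect_identical(p$genome_id, "g1")

  # genome id defaults to the file stem, never to headers
  p2 <- read_proteome(f)
  expect_identical(p2$genome_id, sub("\\.faa$", "", basename(f)))
})

test_that("empty and non-FASTA files are rejected with located errors", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(character(0), f)
  expect_error(read_proteome(f, "g"), class = "cvtreer_input_error")

  writeLines(c("", "MKVLLT"), f)
  err <- expect_error(read_proteome(f, "g"), class = "cvtreer_parse_error")
  expect_match(conditionMessage(err), "line 2")
})

test_that("FASTA round-trip reproduces random proteomes exactly", {
  set.seed(42)
  for (i in 1:10) {
    p <- rand_proteome(sprintf("g%d", i), n_prot = sample(1:8, 1))
    f <- withr::local_tempfile(fileext = ".faa")
    write_proteome(p, f)
    expect_identical(read_proteome(f, p$genome_id)$proteins, p$proteins)
  }
})

test_that("lineage lines parse, fill Unclassified, and reject bad grammar", {
  r <- parse_lineage_line("g1\t<D>Archaea<P>Euryarchaeota<C>Thermococci")
  expect_identical(r$genome_id, "g1")
  expect_identical(unname(r$lineage[c("D", "P", "C")]),
                   c("Archaea", "Euryarchaeota", "Thermococci"))
  expect_true(all(r$lineage[c("O", "F", "G", "S")] == "Unclassified"))
  expect_false(lineage_is_complete(r$lineage))

  full <- parse_lineage(paste0("<D>a<P>b<C>c<O>d<F>e<G>f<S>g"))
  expect_true(lineage_is_complete(full))

  expect_error(parse_lineage_line("g2\t<D>Archaea<C>Halobacteria<P>Eury"),
               class = "cvtreer_parse_error")
  expect_error(parse_lineage("<D>A<D>B"), class = "cvtreer_parse_error")
  expect_error(parse_lineage("<Q>A"), class = "cvtreer_parse_error")
  expect_error(parse_lineage("plain text"), class = "cvtreer_parse_error")

  r3 <- parse_lineage_line("g3\t<D>Archaea<P>Unclassified<C>Unclassified")
  expect_false(lineage_is_complete(r3$lineage))
})

test_that("lineage tables round-trip through TSV with comments ignored", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# a comment", "g1\t<D>Archaea<P>Euryarchaeota",
               "", "g2\t<D>Archaea<P>Crenarchaeota<C>Thermoprotei"), f)
  lt <- read_lineages(f)
  expect_s3_class(lt, "lineage_table")
  expect_identical(lt$genome_id, c("g1", "g2"))
  expect_identical(lt$C, c("Unclassified", "Thermoprotei"))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_lineages(lt, f2)
  lt2 <- read_lineages(f2)
  expect_identical(as.data.frame(lt), as.data.frame(lt2))
})

test_that("PHYLIP square matrices round-trip to 10 significant digits", {
  m <- matrix(c(0, 0.25, 0.25, 0), 2, 2,
              dimnames = rep(list(c("A", "B")), 2))
  f <- withr::local_tempfile(fileext = ".phylip")
  write_distmatrix(m, f)
  back <- read_distmatrix(f)
  expect_identical(back["A", "B"], 0.25)

  # 1x1 is a valid file
  m1 <- matrix(0, 1, 1, dimnames = list("solo", "solo"))
  write_distmatrix(m1, f)
  expect_identical(dim(read_distmatrix(f)), c(1L, 1L))

  set.seed(9)
  for (i in 1:5) {
    n <- sample(3:10, 1)
    x <- matrix(runif(n * n), n, n)
    x <- (x + t(x)) / 2
    diag(x) <- 0
    dimnames(x) <- rep(list(sprintf("t%02d", 1:n)), 2)
    write_distmatrix(x, f)
    expect_equal(read_distmatrix(f), x, tolerance = 1e-9)
  }

  bad <- matrix(0, 2, 2, dimnames = rep(list(c("a b", "a_b")), 2))
  expect_error(write_distmatrix(bad, f), class = "cvtreer_input_error")
})

test_that("Newick round-trips preserve topology, labels and lengths", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:2):0.5,C:3);", f)
  tr <- read_newick(f)
  expect_identical(sort(tr$tip.label), c("A", "B", "C"))
  f2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f2)
  expect_identical(readLines(f2), "((A:1,B:2):0.5,C:3);")

  writeLines("((A:1,A:2):0.5,C:3);", f)
  expect_error(read_newick(f), class = "cvtreer_parse_error")
  writeLines("((A:1,B:2:0.5,C:3);", f)
  expect_error(read_newick(f), class = "cvtreer_parse_error")

  set.seed(5)
  for (i in 1:5) {
    tr <- random_tree(sample(4:12, 1), seed = i)
    write_newick(tr, f)
    back <- read_newick(f)
    expect_identical(rf_distance(tr, back), 0L)
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-8)
  }
})
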