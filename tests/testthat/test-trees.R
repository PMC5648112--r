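test_that("newick parsing handles the basic grammar cases", {
  tr <- read_phylo(text = "((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 3)
  expect_length(tr$edge.length, 4)

  nolen <- read_phylo(text = "(A,B);")
  expect_null(nolen$edge.length)
  expect_error(cophenetic_dist(nolen), "branch length")

  expect_error(read_phylo(text = "((A:1,B:1:1,C;"), "parse")
  expect_error(read_phylo(text = "((A:1,A:2):1,B:1);"), "duplicate")
})

test_that("tip labels with spaces are sanitised with a recoverable map", {
  tr <- read_phylo(text = "(('Shorea parvifolia':1,'Shorea sp':1):1,Dipterocarpus:2);")
  expect_true(all(!grepl(" ", tr$tip.label)))
  m <- label_map(tr)
  expect_setequal(m$original[m$original != m$sanitized], c("Shorea parvifolia", "Shorea sp"))
  tf <- tempfile(fileext = ".tsv")
  side <- tempfile(fileext = ".tsv")
  write_phylo(tr, tf, label_map_file = side)
  expect_true(file.exists(side))
  expect_equal(nrow(readr::read_tsv(side, show_col_types = FALSE)), 3)
})

test_that("parse/write round-trip preserves topology and lengths", {
  set.seed(42)
  for (n in c(4, 9, 23, 50)) {
    tr <- ape::rtree(n)
    txt <- write_phylo(tr)
    back <- read_phylo(text = txt)
    expect_identical(tip_splits(back), tip_splits(tr))
    d1 <- cophenetic_dist(tr)
    d2 <- cophenetic_dist(back)
    expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-5)
  }
})

test_that("NEXUS trees blocks are read", {
  nex <- paste(
    "#NEXUS", "BEGIN TREES;",
    "TREE one = ((A:1,B:1):1,C:2);",
    "TREE two = ((A:2,C:2):1,B:3);",
    "END;",
    sep = "\n"
  )
  tf <- tempfile(fileext = ".nex")
  writeLines(nex, tf)
  trees <- read_phylo(tf)
  expect_s3_class(trees, "multiPhylo")
  expect_length(trees, 2)
  expect_equal(ape::Ntip(trees[[1]]), 3)
})

test_that("cophenetic distances equal hand sums and the path oracle", {
  tr <- read_phylo(text = "((A:5,B:5):5,C:10);")
  d <- cophenetic_dist(tr)
  expect_equal(d["A", "B"], 10)
  expect_equal(d["A", "C"], 20)
  expect_equal(d["B", "C"], 20)

  star <- read_phylo(text = "(A:3,B:3,C:3,D:3);")
  ds <- cophenetic_dist(star)
  expect_true(all(ds[upper.tri(ds)] == 6))

  set.seed(7)
  for (n in c(4, 7, 12)) {
    tr <- ape::rtree(n)
    d <- cophenetic_dist(tr)
    o <- oracle_cophenetic(tr)
    expect_equal(d[rownames(o), colnames(o)], o, tolerance = 1e-12)
    expect_true(isSymmetric(d))
    expect_true(all(diag(d) == 0))
  }
})

test_that("pruning preserves patristic distances among kept tips", {
  tr <- read_phylo(text = "((A:1,B:1):1,C:2);")
  pr <- prune_to_taxa(tr, c("A", "C"))
  expect_equal(ape::Ntip(pr), 2)
  expect_equal(cophenetic_dist(pr)["A", "C"], 4)

  expect_identical(prune_to_taxa(tr, c("A", "B", "C")), tr)
  expect_error(prune_to_taxa(tr, character(0)), "at least one")
  expect_error(prune_to_taxa(tr, c("A", "Z")), "Z")

  set.seed(11)
  for (rep in 1:5) {
    tr <- ape::rtree(20)
    keep <- sample(tr$tip.label, 8)
    d_full <- cophenetic_dist(tr)[keep, keep]
    d_sub <- cophenetic_dist(prune_to_taxa(tr, keep))[keep, keep]
    expect_equal(d_sub, d_full, tolerance = 1e-12)
  }
})

test_that("ultrametricity check reports deviation", {
  ok <- check_ultrametric(read_phylo(text = "((A:5,B:5):5,C:10);"))
  expect_true(ok$ultrametric)
  expect_equal(ok$max_deviation, 0)
  bad <- check_ultrametric(read_phylo(text = "((A:5,B:4):5,C:10);"), rel_tol = 1e-6)
  expect_false(bad$ultrametric)
  expect_gt(bad$max_deviation, 0.01)
})

test_that("constraint trees hang species as ordinal polytomies", {
  tax <- data.frame(
    taxon = c("sp1", "sp2", "sp3"),
    order = c("O1", "O1", "O2")
  )
  ct <- build_constraint_tree(tax, "(O1,O2);")
  expect_setequal(ct$tip.label, c("sp1", "sp2", "sp3"))
  expect_null(ct$edge.length)
  expect_identical(tip_splits(ct), tip_splits(read_phylo(text = "((sp1,sp2),sp3);")))

  # 25 orders, 3 species each: every order forms one polytomy
  orders <- sprintf("Ord%02d", 1:25)
  tax25 <- data.frame(
    taxon = sprintf("s%03d", 1:75),
    order = rep(orders, each = 3)
  )
  backbone <- paste0("(", paste(orders, collapse = ","), ");")
  ct25 <- build_constraint_tree(tax25, backbone)
  expect_equal(ape::Ntip(ct25), 75)
  # each order contributes exactly one internal node carrying its 3 species
  splits <- tip_splits(ct25)
  per_order <- vapply(orders, function(o) {
    paste(sort(tax25$taxon[tax25$order == o]), collapse = "|")
  }, "")
  expect_true(all(per_order %in% splits))

  # degenerate backbone: one order -> single polytomy
  ct1 <- build_constraint_tree(
    data.frame(taxon = c("a", "b", "c"), order = "O1"), "(O1,O2);"
  )
  expect_equal(ct1$Nnode, 1)

  expect_error(
    build_constraint_tree(
      data.frame(taxon = "x", order = "Nope"), "(O1,O2);"
    ),
    "x"
  )
})
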