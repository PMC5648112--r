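chronogram_fixture <- function(n = 15, seed = 3) {
  set.seed(seed)
  random_chronogram(n)
}

test_that("Faith's PD covers the spanning-subtree definition", {
  tr <- read_phylo(text = "((A:5,B:5):5,C:10);")
  # all taxa: the whole tree
  expect_equal(faith_pd(tr, c("A", "B", "C")), 25)
  # single taxon with root path: its depth
  expect_equal(faith_pd(tr, "A", include_root = TRUE), 10)
  expect_equal(faith_pd(tr, "A", include_root = FALSE), 0)
  # named abundances select presence: B drops out, leaving the A/C subtree
  expect_equal(faith_pd(tr, c(A = 2, B = 0, C = 1)), 20)
  expect_equal(faith_pd(tr, c("A", "C")), 20)
  expect_error(faith_pd(tr, "Z"), "Z")
  expect_error(faith_pd(tr, character(0)), "at least one")
})

test_that("PD equals the edge-set union oracle on random subsets", {
  tr <- chronogram_fixture(15)
  set.seed(5)
  for (rep in 1:20) {
    taxa <- sample(tr$tip.label, sample(1:15, 1))
    for (root in c(TRUE, FALSE)) {
      expect_equal(
        faith_pd(tr, taxa, include_root = root),
        oracle_pd(tr, taxa, include_root = root),
        tolerance = 1e-12
      )
    }
  }
})

test_that("PD is monotone under adding taxa", {
  tr <- chronogram_fixture(12, seed = 9)
  set.seed(10)
  for (rep in 1:10) {
    taxa <- sample(tr$tip.label, sample(1:11, 1))
    extra <- sample(setdiff(tr$tip.label, taxa), 1)
    expect_gte(faith_pd(tr, c(taxa, extra)), faith_pd(tr, taxa))
  }
})

test_that("MPD and MNTD match hand cases and picante on unweighted data", {
  skip_if_not_installed("picante")
  tr <- chronogram_fixture(10, seed = 2)
  d <- cophenetic_dist(tr)

  # two taxa: both metrics equal their distance, any abundances
  two <- setNames(c(3, 1), rownames(d)[1:2])
  expect_equal(mpd(d, two, weighted = TRUE), d[1, 2])
  expect_equal(mntd(d, two, weighted = TRUE), d[1, 2])

  # equal abundances: weighted equals unweighted for MPD
  eq <- setNames(rep(2, 4), rownames(d)[1:4])
  expect_equal(mpd(d, eq, weighted = TRUE), mpd(d, eq, weighted = FALSE))

  # picante cross-check (unweighted, and weighted MNTD which shares the
  # per-individual definition)
  samp <- matrix(0, 1, 10, dimnames = list("p1", rownames(d)))
  samp[1, 1:6] <- c(1, 2, 1, 5, 1, 3)
  ab <- setNames(samp[1, 1:6], colnames(samp)[1:6])
  expect_equal(mpd(d, ab, weighted = FALSE), picante::mpd(samp, d)[1])
  expect_equal(mntd(d, ab, weighted = FALSE), picante::mntd(samp, d)[1])
  expect_equal(
    mntd(d, ab, weighted = TRUE),
    picante::mntd(samp, d, abundance.weighted = TRUE)[1]
  )
})

test_that("weighted metrics equal the exhaustive pair-loop oracle", {
  tr <- chronogram_fixture(9, seed = 4)
  d <- cophenetic_dist(tr)
  set.seed(6)
  for (rep in 1:15) {
    s <- sample(2:6, 1)
    taxa <- sample(rownames(d), s)
    ab <- setNames(sample(1:5, s, replace = TRUE), taxa)
    ds <- d[taxa, taxa]
    for (w in c(TRUE, FALSE)) {
      expect_equal(mpd(d, ab, weighted = w), oracle_mpd(ds, ab, w), tolerance = 1e-12)
      expect_equal(mntd(d, ab, weighted = w), oracle_mntd(ds, ab, w), tolerance = 1e-12)
    }
  }
})

test_that("metrics are undefined below two taxa and ignore zero abundances", {
  tr <- chronogram_fixture(8, seed = 12)
  d <- cophenetic_dist(tr)
  one <- setNames(4, rownames(d)[1])
  expect_true(is.na(mpd(d, one)))
  expect_true(is.na(mntd(d, one)))
  ab <- setNames(c(2, 3, 0), rownames(d)[1:3])
  expect_equal(mpd(d, ab, weighted = TRUE), d[1, 2])
  # adding a zero-abundance taxon changes nothing
  ab4 <- setNames(c(2, 3, 0, 0), rownames(d)[1:4])
  expect_equal(mntd(d, ab4, weighted = TRUE), mntd(d, ab[1:2], weighted = TRUE))
})

test_that("tip-shuffle null preserves richness/abundances and is seeded", {
  tr <- chronogram_fixture(12, seed = 8)
  d <- cophenetic_dist(tr)
  ab <- setNames(c(1, 2, 4), rownames(d)[1:3])
  n1 <- tip_shuffle_null(d, ab, "mpd", weighted = TRUE, n_rand = 50, seed = 99)
  n2 <- tip_shuffle_null(d, ab, "mpd", weighted = TRUE, n_rand = 50, seed = 99)
  expect_identical(n1$values, n2$values)
  expect_length(n1$values, 50)
  expect_gte(n1$rank, 1)
  expect_lte(n1$rank, 51)
})

test_that("shuffling a community equal to the whole pool is degenerate", {
  tr <- chronogram_fixture(7, seed = 15)
  d <- cophenetic_dist(tr)
  ab <- setNames(rep(1, 7), rownames(d))
  nl <- tip_shuffle_null(d, ab, "mpd", n_rand = 25, seed = 1)
  expect_true(all(nl$values == nl$obs))
  s <- ses(nl)
  expect_true(s$degenerate)
  expect_true(is.na(s$ses))
  expect_equal(s$q, 1)

  # star tree: all distances equal, null spread zero
  star <- read_phylo(text = "(A:1,B:1,C:1,D:1,E:1);")
  dstar <- cophenetic_dist(star)
  ab3 <- setNames(c(1, 1, 1), c("A", "B", "C"))
  expect_true(ses(tip_shuffle_null(dstar, ab3, "mpd", n_rand = 20, seed = 2))$degenerate)
})

test_that("SES and rank quantiles behave at the extremes", {
  fake <- structure(
    list(
      metric = "mpd", weighted = FALSE, obs = 5, values = rep(c(4, 6), 50),
      mean = 5, sd = sd(rep(c(4, 6), 50)), rank = 50.5, n_rand = 100
    ),
    class = "null_ensemble"
  )
  expect_equal(ses(fake)$ses, 0)

  tr <- chronogram_fixture(10, seed = 30)
  d <- cophenetic_dist(tr)
  # force an observation below every null value by shrinking obs taxa dists
  ab <- setNames(c(1, 1), rownames(d)[1:2])
  nl <- tip_shuffle_null(d, ab, "mpd", n_rand = 100, seed = 3)
  nl$obs <- min(nl$values) - 1
  nl$rank <- 1
  s <- ses(nl)
  expect_equal(s$q, 1 / 101)
  expect_equal(classify_significance(s$q, alpha = 0.05), "clustered")
})

test_that("significance classification follows the configured tails", {
  expect_equal(classify_significance(0.01, 0.05, "two"), "clustered")
  expect_equal(classify_significance(0.5, 0.05, "two"), "random")
  expect_equal(classify_significance(0.97, 0.05, "one"), "overdispersed")
  expect_equal(classify_significance(0.97, 0.05, "two"), "random")
  expect_equal(classify_significance(NA_real_, 0.05, "two"), "random")
})

test_that("per-subplot structure table carries the index identities", {
  tr <- chronogram_fixture(20, seed = 40)
  set.seed(41)
  comm <- simulate_communities(simulate_traits(tr, 1), 6, c(3, 8), model = "neutral")
  ps <- phylo_structure(comm, tr, n_rand = 99, seed = 5)
  tb <- tidy(ps)
  expect_equal(nrow(tb), 6)
  expect_identical(tb$nri, -tb$ses_mpd)
  expect_identical(tb$nti, -tb$ses_mntd)
  g <- glance(ps)
  expect_equal(g$n_used, sum(tb$richness >= 2))
  # determinism across runs with the same seed
  tb2 <- tidy(phylo_structure(comm, tr, n_rand = 99, seed = 5))
  expect_equal(tb2, tb)
  # and independence of subplot order
  perm <- comm[c(3, 1, 2, 6, 5, 4), ]
  tb3 <- tidy(phylo_structure(perm, tr, n_rand = 99, seed = 5))
  expect_equal(dplyr::arrange(tb3, subplot), dplyr::arrange(tb, subplot))
  expect_error(phylo_structure(comm, tr, n_rand = 0), "n_rand")
})

test_that("subplots with fewer than two taxa are flagged, not crashed", {
  tr <- chronogram_fixture(10, seed = 50)
  m <- matrix(c(3L, 1L, 2L, 0L), nrow = 2,
    dimnames = list(c("a", "b"), tr$tip.label[1:2])
  )
  comm <- as_community(m)
  ps <- phylo_structure(comm, tr, n_rand = 49, seed = 1)
  tb <- tidy(ps)
  expect_true(is.na(tb$mpd[tb$subplot == "b"]))
  expect_false(is.na(tb$pd[tb$subplot == "b"]))
  expect_equal(glance(ps)$n_used, 1)
})
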