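test_that("haplotype collapsing groups identical sequences", {
  aln <- c(s1 = "ACGT", s2 = "ACGT", s3 = "ACGT", s4 = "ACGA")
  h <- collapse_haplotypes(aln)
  expect_equal(nrow(h), 2)
  expect_setequal(h$n_members, c(3, 1))
  expect_setequal(unlist(h$members), names(aln))

  # all distinct
  aln2 <- c(a = "AAAA", b = "AAAT", c = "AATT")
  expect_equal(nrow(collapse_haplotypes(aln2)), 3)

  expect_error(collapse_haplotypes(character(0)), "empty")
  expect_error(collapse_haplotypes(c(x = "AC", y = "ACG")), "length")
})

test_that("a morphotaxon split across haplotypes keeps both representatives", {
  aln <- c(s1 = "ACGT", s2 = "ACGA", s3 = "ACGT")
  morpho <- c(s1 = "Shorea_sp1", s2 = "Shorea_sp1", s3 = "Shorea_sp2")
  h <- collapse_haplotypes(aln, morphotaxa = morpho)
  expect_equal(nrow(h), 2)
  expect_true("Shorea_sp1" %in% unlist(h$morphotaxa[h$sequence == "ACGT"]))
  expect_true("Shorea_sp1" %in% unlist(h$morphotaxa[h$sequence == "ACGA"]))
})

test_that("wildcard mode lets missing data match while strict does not", {
  aln <- c(s1 = "ACGT", s2 = "AC-T", s3 = "ACGT")
  expect_equal(nrow(collapse_haplotypes(aln, mode = "strict")), 2)
  expect_equal(nrow(collapse_haplotypes(aln, mode = "wildcard")), 1)
})

test_that("alignment statistics count variable sites and missing cells", {
  aln <- c(a = "ACG", b = "ACG")
  st <- alignment_stats(aln)
  expect_equal(st$variable_sites, 0)
  expect_equal(st$missing_pct, 0)

  # one gap in three columns of two rows: 1/6 missing; the gapped column
  # has a single non-missing state so it is not variable
  st2 <- alignment_stats(c(a = "AC-", b = "ACG"))
  expect_equal(st2$length, 3)
  expect_equal(st2$variable_sites, 0)
  expect_equal(st2$missing_pct, 100 / 6, tolerance = 1e-9)

  st3 <- alignment_stats(c(a = "ACT", b = "ACG"))
  expect_equal(st3$variable_sites, 1)
})

test_that("planted variable columns are recovered from a synthetic alignment", {
  set.seed(31)
  n_col <- 200
  n_var <- 20
  base <- sample(c("A", "C", "G", "T"), n_col, replace = TRUE)
  rows <- lapply(1:8, function(i) base)
  var_cols <- sample(n_col, n_var)
  for (j in var_cols) {
    flip <- sample(2:8, 3)
    for (i in flip) rows[[i]][j] <- setdiff(c("A", "C", "G", "T"), base[j])[1]
  }
  aln <- vapply(rows, paste, "", collapse = "")
  names(aln) <- paste0("r", 1:8)
  expect_equal(alignment_stats(aln)$variable_sites, n_var)
})

test_that("per-locus statistics add over a concatenation of disjoint loci", {
  locus1 <- c(a = "ACGT", b = "ACGA") # 1 variable site
  locus2 <- c(a = "TT--", b = "TTGG") # gappy tail
  combined <- c(a = "ACGTTT--", b = "ACGATTGG")
  s1 <- alignment_stats(locus1)
  s2 <- alignment_stats(locus2)
  sc <- alignment_stats(combined)
  expect_equal(sc$variable_sites, s1$variable_sites + s2$variable_sites)
  expect_equal(
    sc$missing_pct * sc$length,
    s1$missing_pct * s1$length + s2$missing_pct * s2$length
  )
})

test_that("stop-codon screening is frame sensitive", {
  r <- stop_codon_screen("ATGTAAATG", frame = 0)
  expect_true(r$pseudogene)
  expect_equal(r$stop_codons, 2)
  expect_false(stop_codon_screen("ATGGCCGCA", frame = 0)$pseudogene)
  # shifting the frame dissolves the stop
  expect_false(stop_codon_screen("ATGTAAATG", frame = 1)$pseudogene)
  # a terminal stop is not a pseudogene signal
  expect_false(stop_codon_screen("ATGGCCTAA", frame = 0)$pseudogene)
  expect_error(stop_codon_screen("AT", frame = 0), "codon")
  expect_error(stop_codon_screen("ATGTAA", frame = 3), "frame")
})

test_that("FASTA round-trip preserves an aligned matrix", {
  aln <- c(tag1 = "ACGT-N?A", tag2 = "ACGTTNAA")
  tf <- tempfile(fileext = ".fasta")
  write_alignment(aln, tf)
  back <- read_alignment(tf)
  expect_equal(unname(back), unname(aln))
  expect_setequal(names(back), names(aln))
})

stem_fixture <- function() {
  tibble::tibble(
    tag = paste0("T", 1:10),
    subplot = rep(c("q1", "q2"), each = 5),
    morphotaxon = c("m1", "m1", "m2", "m2", NA, "m1", "m2", "m3", NA, "m9"),
    haplotype = c("H1", "H1", "H2", NA, "H3", NA, "H2", NA, NA, NA)
  )
}

test_that("community assembly assigns, excludes and conserves stems", {
  res <- build_community_matrix(stem_fixture())
  comm <- res$community
  m <- as.matrix(comm[, -1])
  rownames(m) <- comm$subplot
  # sequenced stems keep their haplotype; unsequenced m1/m2 stems inherit
  # the conspecific haplotype
  expect_equal(m["q1", "H1"], 2)
  expect_equal(m["q1", "H2"], 2) # T3 sequenced + T4 assigned
  expect_equal(m["q2", "H1"], 1) # T6 assigned via m1
  # exclusions: T8 (morphotaxon never sequenced), T9 (nothing), T10 (m9
  # never sequenced)
  expect_equal(nrow(res$exclusions), 3)
  expect_equal(res$excluded_fraction, 0.3)
  n_assigned <- sum(m)
  expect_equal(n_assigned + nrow(res$exclusions), nrow(stem_fixture()))
})

test_that("ambiguous morphotaxa follow the configured policy", {
  stems <- tibble::tibble(
    tag = paste0("T", 1:6),
    subplot = "q1",
    morphotaxon = c("m1", "m1", "m1", "m1", "m1", "m1"),
    haplotype = c("H1", "H1", "H2", NA, NA, NA)
  )
  res <- build_community_matrix(stems, ambiguous = "most_frequent")
  m <- as.matrix(res$community[, -1])
  expect_equal(unname(m[1, "H1"]), 5) # 2 sequenced + 3 assigned to majority
  expect_equal(nrow(res$ambiguity_log), 1)
  expect_equal(res$ambiguity_log$chosen_haplotype, "H1")

  res2 <- build_community_matrix(stems, ambiguous = "exclude")
  m2 <- as.matrix(res2$community[, -1])
  expect_equal(unname(m2[1, "H1"]), 2)
  expect_equal(nrow(res2$exclusions), 3)
})
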