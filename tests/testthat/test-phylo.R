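test_that("distance_matrix validates shape, labels, symmetry and sign", {
  d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_identical(distance_matrix(d), d)
  expect_error(distance_matrix(matrix(0, 2, 3)), "square")
  expect_error(distance_matrix(matrix(0, 2, 2)), "labels")
  bad <- d; bad[1, 2] <- 2
  expect_error(distance_matrix(bad), "not symmetric")
  bad2 <- d; bad2[1, 1] <- 0.1
  expect_error(distance_matrix(bad2), "diagonal")
  bad3 <- d; bad3[1, 2] <- bad3[2, 1] <- -1
  expect_error(distance_matrix(bad3), "negative")
})

test_that("nj solves the three-taxon linear system exactly", {
  d <- matrix(c(0, 2, 4,
                2, 0, 4,
                4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                      tr$edge[, 2L])], tr$tip.label)
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 3)
})

test_that("nj recovers additive 4-6 taxon trees exactly, matching the exhaustive LS oracle", {
  for (n in 4:6) {
    fix <- random_additive_matrix(n, seed = 100 + n)
    tr <- nj_tree(fix$d)
    # branch lengths: path distances reproduce the matrix exactly
    coph <- ape::cophenetic.phylo(tr)[rownames(fix$d), colnames(fix$d)]
    expect_equal(coph, fix$d, tolerance = 1e-8)
    expect_identical(attr(tr, "clamped"), 0L)
    # topology: identical to the exhaustive-topology least-squares optimum
    oracle <- oracle_best_tree(fix$d)
    expect_lt(oracle$rss, 1e-12)
    expect_identical(as.integer(phangorn::RF.dist(tr, oracle$tree)), 0L)
  }
})

test_that("nj is invariant to taxon input order", {
  fix <- random_additive_matrix(5, seed = 42)
  tr1 <- nj_tree(fix$d)
  perm <- c(3, 1, 5, 2, 4)
  tr2 <- nj_tree(fix$d[perm, perm])
  expect_identical(as.integer(phangorn::RF.dist(tr1, tr2)), 0L)
  expect_equal(sort(tr1$edge.length), sort(tr2$edge.length), tolerance = 1e-10)
})

test_that("negative NJ branch estimates are clamped and flagged", {
  # a strongly non-additive matrix known to produce a negative NJ branch
  d <- matrix(c(0, 1, 5, 5,
                1, 0, 1, 5,
                5, 1, 0, 1,
                5, 5, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
  expect_gte(attr(tr, "clamped"), 1L)
})

test_that("bootstrap support is deterministic, order-invariant and bounded", {
  aln <- four_taxon_alignment()
  tr1 <- bootstrap_support(aln, n_reps = 50, seed = 7)
  tr2 <- bootstrap_support(aln, n_reps = 50, seed = 7)
  expect_identical(tr1$node.label, tr2$node.label)
  expect_identical(attr(tr1, "support"), attr(tr2, "support"))
  # shuffled member order, same seed -> same supports
  shuffled <- codon_alignment(aln$members[c(3, 1, 4, 2)])
  tr3 <- bootstrap_support(shuffled, n_reps = 50, seed = 7)
  expect_identical(sort(attr(tr1, "support")), sort(attr(tr3, "support")))
  sup <- attr(tr1, "support")
  expect_true(all(sup >= 0 & sup <= 100))
})

test_that("a strongly divergent two-clade fixture gets full support", {
  aln <- four_taxon_alignment()
  tr <- bootstrap_support(aln, n_reps = 100, seed = 1)
  sup <- attr(tr, "support")
  expect_identical(unname(sup[["C|D"]]), 100)
  expect_identical(attr(tr, "skipped"), 0L)
})

test_that("a single bootstrap replicate gives support 0 or 100", {
  aln <- four_taxon_alignment(seed = 8)
  tr <- bootstrap_support(aln, n_reps = 1, seed = 3)
  sup <- attr(tr, "support")
  expect_true(all(sup %in% c(0, 100)))
})

test_that("saturated bootstrap replicates are skipped, counted and warned", {
  # TCT vs AGC columns contribute Sd = 1 on S = 2/3 per column; three such
  # columns against three identical GGG columns give full-data ps = 3/5 < 3/4,
  # but any resample drawing >= 4 saturating columns pushes ps over 3/4 (a
  # ~34% event per replicate), so some of 60 replicates must be skipped
  aln <- codon_alignment(c(A = "TCTTCTTCTGGGGGGGGG",
                           B = "AGCAGCAGCGGGGGGGGG",
                           C = "TCTTCTTCTGGGGGGGGG"))
  expect_length(ng86(aln, c("A", "B"))$undefined, 0L)
  expect_warning(
    tr <- bootstrap_support(aln, n_reps = 60, seed = 2),
    "skipped due to saturation")
  expect_gt(attr(tr, "skipped"), 0L)
  expect_lt(attr(tr, "skipped"), 60L)
})

test_that("monophyly is judged on the tree rooted at the outgroup", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(clade_monophyletic(tr, c("A", "B"), outgroup = "D"))
  expect_false(clade_monophyletic(tr, c("A", "C"), outgroup = "D"))
  expect_error(clade_monophyletic(tr, c("A", "Z"), outgroup = "D"),
               "unknown label")
  expect_error(clade_monophyletic(tr, c("A", "D"), outgroup = "D"),
               "outgroup cannot be in labels")
})

test_that("the Bayes-factor rule uses a strict 2*diff > 10 threshold", {
  dec <- bayes_factor_decision(0, -4.85)
  expect_equal(dec$diff, 4.85)
  expect_equal(dec$twice_diff, 9.7)
  expect_false(dec$significantly_worse)
  expect_false(bayes_factor_decision(0, -5)$significantly_worse)   # boundary
  expect_true(bayes_factor_decision(0, -5.001)$significantly_worse)
  # antisymmetry of the roles
  a <- bayes_factor_decision(-100.2, -105.4)
  b <- bayes_factor_decision(-105.4, -100.2)
  expect_equal(a$diff, -b$diff)
  expect_error(bayes_factor_decision(NaN, 0), "finite")
  expect_error(bayes_factor_decision(0, Inf), "finite")
})

test_that("Newick and distance-matrix TSV round-trip", {
  fix <- random_additive_matrix(5, seed = 77)
  tr <- nj_tree(fix$d)
  f <- tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_identical(sort(back$tip.label), sort(tr$tip.label))
  expect_identical(as.integer(phangorn::RF.dist(tr, back)), 0L)

  f2 <- tempfile(fileext = ".tsv")
  write_distance_tsv(fix$d, f2)
  d2 <- read_distance_tsv(f2)
  expect_equal(d2, fix$d, tolerance = 1e-12)
})
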