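test_that("codon-pair simulation is fully determined by the seed", {
  s1 <- simulate_codon_pair(100, 0.2, 0.05, seed = 17)
  s2 <- simulate_codon_pair(100, 0.2, 0.05, seed = 17)
  expect_identical(s1$alignment$members, s2$alignment$members)
  expect_identical(s1$events, s2$events)
  s3 <- simulate_codon_pair(100, 0.2, 0.05, seed = 18)
  expect_false(identical(s1$alignment$members, s3$alignment$members))
})

test_that("zero targets give identical sequences and an empty log", {
  s <- simulate_codon_pair(50, 0, 0, seed = 1)
  expect_identical(s$alignment$members[[1L]], s$alignment$members[[2L]])
  expect_identical(nrow(s$events), 0L)
  expect_equal(s$realized$ks, 0)
  expect_equal(s$realized$ka, 0)
})

test_that("the event log is consistent with the final sequences", {
  s <- simulate_codon_pair(80, 0.3, 0.08, seed = 23)
  # replaying the log from the ancestor reproduces each lineage
  for (lineage in 1:2) {
    cur <- divclock:::split_codons(s$ancestor)
    ev <- s$events[s$events$lineage == lineage, , drop = FALSE]
    for (r in seq_len(nrow(ev))) {
      expect_identical(cur[ev$codon[r]], ev$from[r])
      cur[ev$codon[r]] <- ev$to[r]
    }
    expect_identical(paste(cur, collapse = ""),
                     unname(s$alignment$members[[lineage]]))
  }
  # every logged event's syn flag matches the genetic code
  gc <- Biostrings::GENETIC_CODE
  expect_identical(s$events$syn,
                   unname(gc[s$events$from] == gc[s$events$to]))
})

test_that("realized divergence counts position-wise differences from the log", {
  s <- simulate_codon_pair(60, 0.25, 0.06, seed = 29)
  nd <- sum(strsplit(s$alignment$members[[1L]], "")[[1L]] !=
            strsplit(s$alignment$members[[2L]], "")[[1L]])
  # realized Sd + Nd cannot exceed the raw mismatch count
  expect_lte(s$realized$Sd + s$realized$Nd, nd)
  expect_equal(s$realized$ks, jc_correction(s$realized$Sd / s$S_anc))
})

test_that("an explicit ancestor chains simulations along a tree", {
  root <- simulate_codon_pair(40, 0.3, 0.05, seed = 3, ids = c("P", "Q"))
  child <- simulate_codon_pair(40, 0.05, 0.01, seed = 4, ids = c("A", "B"),
                               ancestor = root$alignment$members[["P"]])
  expect_identical(unname(child$ancestor),
                   unname(root$alignment$members[["P"]]))
  expect_error(simulate_codon_pair(39, 0.05, 0.01, seed = 4,
                                   ancestor = root$alignment$members[["P"]]),
               "sense codons")
})

test_that("invalid divergence targets are reported", {
  expect_error(simulate_codon_pair(10, -0.1, 0, seed = 1), ">= 0")
  expect_error(simulate_codon_pair(10, 0.1, Inf, seed = 1), "finite")
  # a poly-ATG ancestor has zero synonymous sites, so a synonymous target
  # yields no events rather than divergence
  s <- simulate_codon_pair(5, 3, 0, seed = 6, ancestor = strrep("ATG", 5))
  expect_equal(s$S_anc, 0)
  expect_identical(s$alignment$members[[1L]], s$alignment$members[[2L]])
})

test_that("JC pair simulation hits its expected mismatch probability", {
  s0 <- simulate_jc_pair(100, 0, seed = 5)
  expect_identical(s0$a, s0$b)
  s <- simulate_jc_pair(100000, 0.2646, seed = 5)
  expect_equal(s$p_expected, 0.75 * (1 - exp(-4 * 0.2646 / 3)))
  phat <- s$n_mismatches / 100000
  se <- sqrt(s$p_expected * (1 - s$p_expected) / 100000)
  expect_lt(abs(phat - s$p_expected), 3 * se)
  # the estimator recovers the generating distance within 3 SE (delta method)
  est <- jc_nucleotide_distance(s$a, s$b)
  se_d <- se / (1 - 4 * phat / 3)
  expect_lt(abs(est$d - 0.2646), 3 * se_d)
  # determinism
  expect_identical(simulate_jc_pair(500, 0.1, seed = 9),
                   simulate_jc_pair(500, 0.1, seed = 9))
})

test_that("noise-free clock datasets are recovered exactly by the clock", {
  ages <- c(near = 5, mid = 10, far = 20)
  rates <- c(locus1 = 0.01, locus2 = 0.02)
  ds <- simulate_clock_dataset(ages, rates, noise = FALSE, seed = 1)
  expect_identical(ds$anchor_taxon, "far")
  tab <- ds$table
  expect_equal(tab$ks, tab$true_ks)
  for (locus in names(rates)) {
    sub <- tab[tab$locus == locus, ]
    anc_ks <- sub$ks[sub$taxon == ds$anchor_taxon]
    anc <- calibration_anchor(paste0("focal-", ds$anchor_taxon), locus,
                              anc_ks, ages[[ds$anchor_taxon]])
    for (i in seq_len(nrow(sub))) {
      est <- estimate_age(sub$ks[i], anc)
      expect_equal(est$age_my, ages[[sub$taxon[i]]], tolerance = 1e-9)
    }
  }
})

test_that("clock dataset validation rejects bad designs", {
  expect_error(simulate_clock_dataset(c(5, 10), c(l = 0.01)), "named")
  expect_error(simulate_clock_dataset(c(a = -5, b = 10), c(l = 0.01)),
               "invalid timetree")
  expect_error(simulate_clock_dataset(c(a = 5), c(l = 0)), "rates")
})

test_that("simulated loci satisfy the published gene architecture", {
  fix <- simulate_locus(seed = 11)
  for (m in fix$models) {
    expect_identical(nrow(m$exons), 14L)
    expect_identical(nrow(introns(m)), 13L)
    # start codon in exon 2: the first exon is entirely 5' UTR
    ex1_len <- m$exons[1L, "end"] - m$exons[1L, "start"]
    expect_gt(m$cds_start, ex1_len)
    ex2_end <- ex1_len + (m$exons[2L, "end"] - m$exons[2L, "start"])
    expect_lt(m$cds_start, ex2_end)
    # the spliced CDS is a clean ORF
    v <- splice(m, fix$genome)
    cds <- substr(v$sequence, v$cds_start + 1L, v$cds_end)
    expect_identical(substr(cds, 1L, 3L), "ATG")
    p <- translate_cds(cds)
    expect_identical(substr(p, nchar(p), nchar(p)), "*")
  }
  # alpha - beta length difference is intron 1
  expect_identical(nchar(fix$variants$alpha$sequence) -
                     nchar(fix$variants$beta$sequence),
                   fix$intron_len[1L])
  expect_identical(fix$variants$alpha$cds_status, "CDS unchanged")
  # the probe window is 5' of the CDS of gene 1
  expect_identical(fix$probe[2L] - fix$probe[1L], 260L)
  # every shipped enzyme yields >= 2 probe-hybridizing fragments and the
  # digest conserves length
  for (e in fix$enzymes) {
    d <- digest(fix$genome, e)
    expect_equal(sum(d$fragments$length), nchar(fix$genome))
    expect_gte(nrow(probe_fragments(d, fix$probe)), 2L)
  }
  # determinism
  fix2 <- simulate_locus(seed = 11)
  expect_identical(fix$genome, fix2$genome)
  expect_error(simulate_locus(seed = 1, n_exons = 2L), "infeasible")
  expect_error(simulate_locus(seed = 1, exon_len_range = c(40L, 20L)),
               "infeasible")
})

test_that("seeded simulators restore the caller's RNG state", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_codon_pair(20, 0.1, 0.02, seed = 1))
  invisible(simulate_jc_pair(20, 0.1, seed = 1))
  invisible(simulate_locus(seed = 2))
  expect_identical(.Random.seed, before)
})
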