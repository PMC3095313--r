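test_that("gene_model validates exon and CDS geometry", {
  ex <- rbind(c(0L, 30L), c(50L, 80L))
  m <- gene_model("chr", "+", ex, 6, 36, name = "g")
  expect_s3_class(m, "gene_model")
  expect_error(gene_model("chr", "+", rbind(c(0, 30, 1)), 0, 3),
               "two columns")
  expect_error(gene_model("chr", "+", rbind(c(10L, 10L)), 0, 3),
               "empty or inverted")
  expect_error(gene_model("chr", "+", rbind(c(0L, 30L), c(20L, 50L)), 0, 3),
               "overlapping")
  expect_error(gene_model("chr", "+", rbind(c(50L, 80L), c(0L, 30L)), 0, 3),
               "not sorted")
  expect_error(gene_model("chr", "+", ex, 6, 100), "outside transcript")
  expect_error(gene_model("chr", "+", ex, 6, 37), "multiple of 3")
  # minus strand lists exons 5'->3' = descending genomic start
  m2 <- gene_model("chr", "-", rbind(c(50L, 80L), c(0L, 30L)), 6, 36)
  expect_s3_class(m2, "gene_model")
})

test_that("introns are the gaps between consecutive exons", {
  m <- gene_model("chr", "+", rbind(c(0L, 10L), c(25L, 40L), c(60L, 72L)),
                  0, 30)
  intr <- introns(m)
  expect_equal(unname(intr), rbind(c(10L, 25L), c(40L, 60L)))
  m2 <- gene_model("chr", "-", rbind(c(60L, 72L), c(25L, 40L), c(0L, 10L)),
                   0, 30)
  intr2 <- introns(m2)
  expect_equal(unname(intr2), rbind(c(40L, 60L), c(10L, 25L)))
})

test_that("splice concatenates exons and excises introns", {
  genome <- "AAAGGGTTT"
  m1 <- gene_model("s", "+", rbind(c(0L, 9L)), 0, 9, name = "whole")
  expect_identical(splice(m1, genome)$sequence, genome)
  m2 <- gene_model("s", "+", rbind(c(0L, 3L), c(6L, 9L)), 0, 6, name = "two")
  expect_identical(splice(m2, genome)$sequence, "AAATTT")
  # minus strand: reverse-complement at splice time
  m3 <- gene_model("s", "-", rbind(c(6L, 9L), c(0L, 3L)), 0, 6, name = "neg")
  expect_identical(splice(m3, genome)$sequence, "AAATTT")
  # out-of-bounds exon errors
  m4 <- gene_model("s", "+", rbind(c(0L, 12L)), 0, 12)
  expect_error(splice(m4, genome), "out of reference bounds")
})

test_that("UTR lengths derive from the CDS offsets", {
  genome <- paste(rep("ACGT", 30), collapse = "")
  m <- gene_model("s", "+", rbind(c(0L, 60L)), 12, 42, name = "g")
  v <- splice(m, genome)
  expect_identical(v$utr5_len, 12L)
  expect_identical(v$utr3_len, 18L)
  expect_identical(v$utr5_len + (v$cds_end - v$cds_start) + v$utr3_len,
                   nchar(v$sequence))
})

test_that("retaining an intron 5' of the start grows the UTR, not the CDS", {
  fix <- beta_like_locus()
  beta <- splice(fix$model, fix$genome)
  expect_identical(nchar(beta$sequence), 1624L)
  expect_identical(beta$utr5_len, 95L)
  expect_identical(beta$utr3_len, 242L)
  alpha <- retain_intron(fix$model, fix$genome, 1L)
  expect_identical(nchar(alpha$sequence), 1774L)
  expect_identical(nchar(alpha$sequence) - nchar(beta$sequence), fix$intron1)
  expect_identical(alpha$utr5_len, 245L)
  expect_identical(alpha$cds_status, "CDS unchanged")
  # identical protein from both variants
  pb <- translate_cds(substr(beta$sequence, beta$cds_start + 1L, beta$cds_end))
  pa <- translate_cds(substr(alpha$sequence, alpha$cds_start + 1L,
                             alpha$cds_end))
  expect_identical(pa, pb)
})

test_that("an intron inside the CDS is classified CDS changed", {
  fix <- beta_like_locus()
  v <- retain_intron(fix$model, fix$genome, 2L)  # intron 2 interrupts the CDS
  expect_identical(v$cds_status, "CDS changed")
  expect_identical(nchar(v$sequence), 1624L + 120L)
  expect_error(retain_intron(fix$model, fix$genome, 3L), "out of range")
  expect_error(retain_intron(fix$model, fix$genome, 0L), "out of range")
})

test_that("removing the retained intron reproduces the spliced transcript", {
  fix <- beta_like_locus()
  beta <- splice(fix$model, fix$genome)
  alpha <- retain_intron(fix$model, fix$genome, 1L)
  intr <- introns(fix$model)
  ex1_len <- fix$model$exons[1L, "end"] - fix$model$exons[1L, "start"]
  ilen <- intr[1L, "end"] - intr[1L, "start"]
  stitched <- paste0(substr(alpha$sequence, 1L, ex1_len),
                     substr(alpha$sequence, ex1_len + ilen + 1L,
                            nchar(alpha$sequence)))
  expect_identical(stitched, beta$sequence)
})

test_that("digest cuts at site_start + cut_offset and conserves length", {
  d <- digest("AAGATATCAA", shipped_enzymes()$EcoRV)
  expect_equal(d$fragments$length, c(5L, 5L))
  expect_equal(d$fragments$start, c(0L, 5L))
  # no sites: one full-length fragment
  d2 <- digest("AAAAAAAA", shipped_enzymes()$EcoRV)
  expect_equal(nrow(d2$fragments), 1L)
  expect_equal(d2$fragments$length, 8L)
  # gapped molecules rejected
  expect_error(digest("AC-GT", shipped_enzymes()$EcoRV), "ungapped")
})

test_that("circular digests wrap: fragments = cuts, lengths conserve", {
  mol <- paste0("GATATC", strrep("A", 20), "GATATC", strrep("C", 10))
  dl <- digest(mol, shipped_enzymes()$EcoRV, topology = "linear")
  expect_equal(sum(dl$fragments$length), nchar(mol))
  dc <- digest(mol, shipped_enzymes()$EcoRV, topology = "circular")
  expect_equal(nrow(dc$fragments), length(dc$cuts))
  expect_equal(sum(dc$fragments$length), nchar(mol))
  # uncut circle is one full-length fragment
  d0 <- digest("AAAACCCC", shipped_enzymes()$EcoRV, topology = "circular")
  expect_equal(nrow(d0$fragments), 1L)
  # a site spanning the origin is found on the circle but not the line
  mol2 <- paste0("ATCAAAAAAAAAGAT")  # GATATC wraps the origin
  expect_equal(nrow(digest(mol2, shipped_enzymes()$EcoRV)$fragments), 1L)
  expect_equal(length(digest(mol2, shipped_enzymes()$EcoRV,
                             topology = "circular")$cuts), 1L)
})

test_that("multi-enzyme digests merge all cut positions", {
  mol <- paste0(strrep("T", 10), "GATATC", strrep("T", 10), "AGATCT",
                strrep("T", 10))
  d <- digest(mol, shipped_enzymes()[c("EcoRV", "BglII")])
  expect_equal(length(d$cuts), 2L)
  expect_equal(sum(d$fragments$length), nchar(mol))
  expect_equal(nrow(d$fragments), 3L)
})

test_that("partial digest adds single-cut-skipped fragments", {
  mol <- paste0(strrep("T", 10), "GATATC", strrep("T", 10), "GATATC",
                strrep("T", 10))
  d <- digest(mol, shipped_enzymes()$EcoRV, partial = TRUE)
  full <- d$fragments
  pf <- d$partial_fragments
  expect_equal(nrow(pf), nrow(full) - 1L)
  expect_equal(pf$length, full$length[-nrow(full)] + full$length[-1L])
})

test_that("probe_fragments returns exactly the overlapping fragments", {
  mol <- paste0(strrep("T", 10), "GATATC", strrep("T", 20))
  d <- digest(mol, shipped_enzymes()$EcoRV)  # cut at 13
  expect_equal(d$cuts, 13L)
  # probe inside the first fragment
  expect_equal(nrow(probe_fragments(d, c(2L, 8L))), 1L)
  expect_equal(probe_fragments(d, c(2L, 8L))$start, 0L)
  # probe spanning the cut hits both fragments
  expect_equal(nrow(probe_fragments(d, c(10L, 16L))), 2L)
  # min_overlap filters marginal overlaps
  expect_equal(nrow(probe_fragments(d, c(12L, 16L), min_overlap = 2L)), 1L)
  expect_error(probe_fragments(d, c(5L, 5L)), "empty")
  expect_error(probe_fragments(d, c(-1L, 5L)), "outside molecule")
  expect_error(probe_fragments(d, c(0L, 100L)), "outside molecule")
})

test_that("digest report flags hybridizing fragments", {
  mol <- paste0(strrep("T", 10), "GATATC", strrep("T", 20))
  d <- digest(mol, shipped_enzymes()$EcoRV)
  f <- tempfile(fileext = ".tsv")
  rep <- write_digest_report(d, f, probe = c(2L, 8L))
  expect_identical(rep$hybridizing, c(TRUE, FALSE))
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_identical(names(back), c("start", "end", "length", "hybridizing"))
})

test_that("gene models round-trip through GFF3", {
  fix <- beta_like_locus()
  f <- tempfile(fileext = ".gff3")
  write_gene_models_gff3(list(fix$model), f)
  back <- read_gene_models_gff3(f)
  m <- back[["beta_like"]]
  expect_equal(unname(m$exons), unname(fix$model$exons))
  expect_identical(m$cds_start, fix$model$cds_start)
  expect_identical(m$cds_end, fix$model$cds_end)
  expect_identical(m$strand, "+")
  # spliced products are identical
  expect_identical(splice(m, fix$genome)$sequence,
                   splice(fix$model, fix$genome)$sequence)
})

test_that("minus-strand gene models round-trip through GFF3", {
  # place a small 2-exon gene on the minus strand of a random reference
  set.seed(5)
  genome <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  m <- gene_model("ref", "-", rbind(c(200L, 260L), c(100L, 160L)),
                  10, 100, name = "minus_gene")
  f <- tempfile(fileext = ".gff3")
  write_gene_models_gff3(list(m), f)
  back <- read_gene_models_gff3(f)[["minus_gene"]]
  expect_equal(unname(back$exons), unname(m$exons))
  expect_identical(back$cds_start, m$cds_start)
  expect_identical(back$cds_end, m$cds_end)
  expect_identical(splice(back, genome)$sequence, splice(m, genome)$sequence)
})

test_that("BED12 gene models are read with blocks as exons and thick as CDS", {
  # one gene: chrom start 100, two blocks of 60 and 90, CDS from 130 to 250
  # thick [130, 280): 30 CDS bases in block 1 + 30 in block 2
  bed <- paste(c("ref", 100, 340, "bed_gene", 0, "+", 130, 280, "0",
                 2, "60,90,", "0,150,"), collapse = "\t")
  f <- tempfile(fileext = ".bed")
  writeLines(bed, f)
  models <- read_gene_models_bed12(f)
  m <- models[["bed_gene"]]
  expect_equal(unname(m$exons), rbind(c(100L, 160L), c(250L, 340L)))
  expect_identical(m$cds_start, 30L)
  expect_identical(m$cds_end, 90L)
})
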