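#!/usr/bin/env Rscript
# Stage 5: accession-dependent checks (requires user-downloaded sequences).
#
# The remaining published values are tied to database records that this
# repository does not download: the paralog CDS pair (coding Ks 0.1541 /
# Ka 0.0274; protein MW 47212 Da, pI 6.68; 94% identity with 26 substitutions
# over 428 residues), the aligned first introns (JC distance 0.2646), and the
# annotated BAC for the EcoRV Southern prediction (hybridizing fragments of
# 6227 and 8906 bp with a 260 bp probe at the 5' end of the first paralog).
#
# Provide the inputs yourself and run:
#   Rscript analysis/05_accession_checks.R \
#       --cds paralog_cds.fa        # two in-frame paralog CDS records
#       [--introns introns.fa]      # two pre-aligned first-intron records
#       [--genome bac.fa --gff models.gff3 --probe-start N --probe-end N]
#
# Everything below is plain local-file analysis; no network access.

suppressPackageStartupMessages({
  library(optparse)
  library(divclock)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--cds", type = "character", default = NULL),
  make_option("--introns", type = "character", default = NULL),
  make_option("--genome", type = "character", default = NULL),
  make_option("--gff", type = "character", default = NULL),
  make_option("--probe-start", type = "integer", default = NULL,
              dest = "probe_start"),
  make_option("--probe-end", type = "integer", default = NULL,
              dest = "probe_end"),
  make_option("--out", type = "character", default = "results/05_accessions")
)))

if (is.null(opts$cds)) {
  stop("--cds <FASTA with the two paralog CDS> is required; ",
       "download the accessions and extract the CDS first", call. = FALSE)
}
dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)

seqs <- read_fasta(opts$cds)
if (length(seqs) < 2L) stop("need two CDS records", call. = FALSE)
aln <- align_codons(seqs[1L], seqs[2L], ids = names(seqs)[1:2])
est <- ng86(aln)
cat("Coding divergence:\n")
print(est)
write_divergence_report(list(est), file.path(opts$out, "coding_divergence.tsv"))

anchor <- calibration_anchor("Medicago-Pisum", "GS2", 0.2475, 14.9)
dup <- date_duplication(aln, anchor, digits = 0)
cat(sprintf("Duplication age: %s My (ks %.4f against anchor %.4f / %.1f My)\n",
            format(dup$age_rounded), dup$ks, anchor$ks, anchor$age_my))

prots <- lapply(seq_len(2L), function(i) {
  sub("\\*$", "", translate_cds(divclock::degap(aln$members[[i]])))
})
paln <- nw_align(prots[[1L]], prots[[2L]])
ident <- identity_stats(paln$a_aln, paln$b_aln)
cat(sprintf("Protein identity: %.2f%% (%d substitutions over %d residues)\n",
            ident$identity_pct, ident$n_substitutions, ident$positions))
for (i in 1:2) {
  cat(sprintf("%s: %d aa, MW %.0f Da, pI %.2f\n", names(seqs)[i],
              nchar(prots[[i]]), protein_mw(prots[[i]]),
              protein_pi(prots[[i]])))
}

if (!is.null(opts$introns)) {
  intr <- read_fasta(opts$introns)
  jc <- jc_nucleotide_distance(intr[[1L]], intr[[2L]])
  cat(sprintf("Intron JC distance: %.4f (p = %.4f over %d sites)\n",
              jc$d, jc$p, jc$sites_used))
}

if (!is.null(opts$genome) && !is.null(opts$probe_start) &&
    !is.null(opts$probe_end)) {
  probe <- c(opts$probe_start, opts$probe_end)
  if (!is.null(opts$gff)) {
    res <- run_locus(list(outdir = opts$out, seed = 0,
                          genome = opts$genome, models = opts$gff,
                          enzymes = c("EcoRV", "NcoI", "BglII"),
                          probe = probe))
    cat("Hybridizing fragments:\n")
    print(res$digests[res$digests$hybridizing, ])
  } else {
    genome <- read_fasta(opts$genome)[[1L]]
    for (nm in c("EcoRV", "NcoI", "BglII")) {
      d <- digest(genome, shipped_enzymes()[[nm]])
      cat(nm, "hybridizing fragments:\n")
      print(probe_fragments(d, probe))
    }
  }
}
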