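# Independent oracles the tests check the implementation against.
# These deliberately reimplement the quantities from first principles
# (enumeration, least squares, grid search) and never call the code paths
# they are used to verify.

GC_TABLE <- Biostrings::GENETIC_CODE

# --- brute-force pathway enumeration for codon differences ----------------

# all permutations of a vector, iteratively (Heap-like insertion scheme)
all_perms <- function(v) {
  out <- list(v[1L])
  for (k in seq_along(v)[-1L]) {
    nxt <- list()
    for (p in out) {
      for (at in 0:length(p)) {
        nxt[[length(nxt) + 1L]] <- append(p, v[k], after = at)
      }
    }
    out <- nxt
  }
  out
}

# pathway-averaged (sd, nd) between two sense codons by explicit enumeration
oracle_codon_differences <- function(a, b) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  pos <- which(av != bv)
  if (length(pos) == 0L) return(c(sd = 0, nd = 0))
  sd_sum <- 0; nd_sum <- 0; n_valid <- 0L
  for (ord in all_perms(pos)) {
    cur <- av
    sd <- 0L; nd <- 0L; valid <- TRUE
    for (p in ord) {
      aa_before <- GC_TABLE[[paste(cur, collapse = "")]]
      cur[p] <- bv[p]
      aa_after <- GC_TABLE[[paste(cur, collapse = "")]]
      if (aa_after == "*") { valid <- FALSE; break }
      if (aa_after == aa_before) sd <- sd + 1L else nd <- nd + 1L
    }
    if (valid) {
      n_valid <- n_valid + 1L
      sd_sum <- sd_sum + sd
      nd_sum <- nd_sum + nd
    }
  }
  if (n_valid == 0L) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = sd_sum / n_valid, nd = nd_sum / n_valid)
}

# --- exhaustive-topology least-squares tree oracle ------------------------

# best unrooted topology for a distance matrix by enumerating all topologies
# and least-squares fitting branch lengths; returns the tree and its RSS
oracle_best_tree <- function(d) {
  labs <- rownames(d)
  trees <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  best <- NULL
  best_rss <- Inf
  # index via [[ so the multiPhylo's shared tip labels are restored per tree
  for (i in seq_along(trees)) {
    fit <- phangorn::nnls.tree(d, trees[[i]], method = "unrooted", trace = 0)
    coph <- ape::cophenetic.phylo(fit)[labs, labs]
    rss <- sum((coph - d)^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- fit
    }
  }
  list(tree = best, rss = best_rss)
}

# additive distance matrix from a random tree with known branch lengths
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE,
                   br = function(k) runif(k, 0.1, 1))
  d <- ape::cophenetic.phylo(tr)
  labs <- sort(rownames(d))
  list(tree = tr, d = d[labs, labs])
}

# --- fine grid scan for the isoelectric point -----------------------------

oracle_pi_grid <- function(p, step = 1e-4) {
  ph <- seq(0, 14, by = step)
  ch <- vapply(ph, function(x) divclock::protein_charge(p, x), 0)
  ph[which.min(abs(ch))]
}

# --- small fixture builders -----------------------------------------------

# an alignment of four taxa in two clades, all from one ancestor
four_taxon_alignment <- function(n_codons = 200L, deep = 0.5, shallow = 0.05,
                                 seed = 4L) {
  anc <- simulate_codon_pair(n_codons, deep, deep / 5, seed = seed,
                             ids = c("P", "Q"))
  ab <- simulate_codon_pair(n_codons, shallow, shallow / 5, seed = seed + 1L,
                            ids = c("A", "B"),
                            ancestor = anc$alignment$members[["P"]])
  cd <- simulate_codon_pair(n_codons, shallow, shallow / 5, seed = seed + 2L,
                            ids = c("C", "D"),
                            ancestor = anc$alignment$members[["Q"]])
  codon_alignment(c(ab$alignment$members, cd$alignment$members))
}

# gene model with the beta-transcript arithmetic of the studied locus:
# 5' UTR 95 nt, first intron 150 nt, CDS 1287 nt (428 aa + stop),
# 3' UTR 242 nt => spliced transcript 1624 nt, intron-1-retained 1774 nt
beta_like_locus <- function(seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  n_aa <- 428L
  cds_len <- 3L * (n_aa + 1L)  # 1287
  mid <- sample(setdiff(divclock:::sense_codons(), "ATG"), n_aa - 1L,
                replace = TRUE)
  cds <- paste0("ATG", paste(mid, collapse = ""), "TAA")
  exon1 <- 60L; intron1 <- 150L; u2 <- 35L  # 5' UTR = 60 + 35 = 95
  utr3 <- 242L
  exon2 <- u2 + 500L
  intron2 <- 120L
  exon3 <- cds_len - 500L + utr3
  seqs <- c(paste(sample(bases, exon1, TRUE), collapse = ""),
            paste(sample(bases, intron1, TRUE), collapse = ""),
            paste(sample(bases, u2, TRUE), collapse = ""),
            substr(cds, 1L, 500L),
            paste(sample(bases, intron2, TRUE), collapse = ""),
            substr(cds, 501L, cds_len),
            paste(sample(bases, utr3, TRUE), collapse = ""))
  genome <- paste(seqs, collapse = "")
  starts <- cumsum(c(0L, nchar(seqs)))
  exons <- rbind(c(starts[1L], starts[2L]),          # exon 1 (UTR)
                 c(starts[3L], starts[5L]),          # exon 2 (u2 + CDS part)
                 c(starts[6L], starts[8L]))          # exon 3 (CDS rest + UTR)
  model <- gene_model("toy", "+", exons, cds_start = exon1 + u2,
                      cds_end = exon1 + u2 + cds_len, name = "beta_like")
  list(genome = genome, model = model, intron1 = intron1,
       utr5_beta = exon1 + u2, cds_len = cds_len, utr3 = utr3)
}
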