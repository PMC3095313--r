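# Seeded simulators emulating every statistical structure the analyses
# assume: codon pairs evolved to target synonymous/nonsynonymous divergence
# with a full event log, non-coding pairs at a target JC distance, multi-locus
# clock datasets with known ages, and two-paralog loci with a 14-exon gene
# architecture.
#
# Every simulator takes an integer seed that fully determines its output and
# restores the caller's RNG state on exit.

#' Evaluate an expression under a fixed seed, restoring the RNG state
#' @noRd
with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

#' Per-codon single-base change tables (syn and nonsyn non-stop changes)
#' @noRd
codon_change_tables <- function() {
  if (is.null(.ng_cache$changes)) {
    gc <- genetic_code()
    cods <- sense_codons()
    syn <- list()
    nonsyn <- list()
    for (cd in cods) {
      ch <- seq_chars(cd)
      s <- list(); n <- list()
      for (pos in 1:3) {
        for (b in BASES[BASES != ch[pos]]) {
          mut <- ch; mut[pos] <- b
          mcd <- paste(mut, collapse = "")
          if (gc[[mcd]] == "*") next
          rec <- list(pos = pos, to = b, codon = mcd)
          if (gc[[mcd]] == gc[[cd]]) s[[length(s) + 1L]] <- rec
          else n[[length(n) + 1L]] <- rec
        }
      }
      syn[[cd]] <- s
      nonsyn[[cd]] <- n
    }
    .ng_cache$changes <- list(syn = syn, nonsyn = nonsyn)
  }
  .ng_cache$changes
}

#' Simulate a codon-aligned sequence pair with an event log
#'
#' An ancestral CDS of `n_codons` uniform sense codons receives, on each of
#' two lineages, a Poisson number of substitution events: the expected total
#' count of synonymous events across both lineages is `ks_target * S` (S =
#' ancestral synonymous sites) and of nonsynonymous events `ka_target * N`.
#' Each event picks uniformly among the currently available single-base
#' changes of its class that do not create a stop codon. Every event is
#' logged, and realized divergences are classified from the log, giving a
#' generator-side truth against which estimators can be scored.
#'
#' @param n_codons Number of codons.
#' @param ks_target Target synonymous divergence per synonymous site
#'   (substitutions; the pair's total, not per lineage).
#' @param ka_target Target nonsynonymous divergence per nonsynonymous site.
#' @param seed Integer seed.
#' @param ids Member ids of the returned alignment.
#' @param ancestor Optional ancestral CDS (string of `3 * n_codons` sense
#'   codons) to evolve from instead of drawing one; lets callers chain
#'   simulations along a tree.
#' @return List with `alignment` (a [codon_alignment()]), `ancestor`,
#'   `events` (data frame: lineage, codon, pos, from, to, syn), `S_anc`,
#'   `N_anc`, and `realized` (list Sd, Nd, ps, pn, ks, ka classified from the
#'   event log).
#' @export
simulate_codon_pair <- function(n_codons, ks_target, ka_target, seed,
                                ids = c("lineage_1", "lineage_2"),
                                ancestor = NULL) {
  if (!is.finite(ks_target) || ks_target < 0 ||
      !is.finite(ka_target) || ka_target < 0) {
    stop("divergence targets must be finite and >= 0", call. = FALSE)
  }
  tabs <- ng86_tables()
  chg <- codon_change_tables()
  with_seed(seed, {
    anc <- if (is.null(ancestor)) {
      sample(sense_codons(), n_codons, replace = TRUE)
    } else {
      cods <- split_codons(toupper(ancestor))
      if (length(cods) != n_codons || !all(cods %in% sense_codons())) {
        stop("ancestor must be ", n_codons, " sense codons", call. = FALSE)
      }
      cods
    }
    S <- sum(tabs$sites[anc, "s"])
    N <- sum(tabs$sites[anc, "n"])
    n_syn <- rpois(1L, ks_target * S)
    n_non <- rpois(1L, ka_target * N)
    if (n_syn > 0 && all(vapply(chg$syn[anc], length, 0L) == 0L)) {
      stop("unreachable synonymous target: no synonymous changes available",
           call. = FALSE)
    }
    syn_l1 <- rbinom(1L, n_syn, 0.5)
    non_l1 <- rbinom(1L, n_non, 0.5)
    seqs <- list(anc, anc)
    ev <- list()
    apply_events <- function(lineage, class_name, count) {
      cur <- seqs[[lineage]]
      pool <- chg[[class_name]]
      for (e in seq_len(count)) {
        counts <- vapply(pool[cur], length, 0L)
        tot <- sum(counts)
        if (tot == 0L) {
          stop("unreachable target: no ", class_name,
               " changes available in current sequence", call. = FALSE)
        }
        pick <- sample.int(tot, 1L)
        ci <- findInterval(pick - 0.5, cumsum(counts)) + 1L
        within <- pick - if (ci > 1L) cumsum(counts)[ci - 1L] else 0L
        rec <- pool[[cur[ci]]][[within]]
        ev[[length(ev) + 1L]] <<- data.frame(
          lineage = lineage, codon = ci, pos = rec$pos,
          from = cur[ci], to = rec$codon, syn = (class_name == "syn"))
        cur[ci] <- rec$codon
      }
      seqs[[lineage]] <<- cur
    }
    apply_events(1L, "syn", syn_l1)
    apply_events(1L, "nonsyn", non_l1)
    apply_events(2L, "syn", n_syn - syn_l1)
    apply_events(2L, "nonsyn", n_non - non_l1)
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(lineage = integer(0), codon = integer(0), pos = integer(0),
                 from = character(0), to = character(0), syn = logical(0))
    aln <- codon_alignment(setNames(
      c(paste(seqs[[1L]], collapse = ""), paste(seqs[[2L]], collapse = "")),
      ids))
    realized <- realized_divergence(seqs[[1L]], seqs[[2L]], events, S, N)
    list(alignment = aln, ancestor = paste(anc, collapse = ""),
         events = events, S_anc = S, N_anc = N, realized = realized)
  })
}

#' Classify the realized divergence of a simulated pair from its event log
#'
#' For every nucleotide position at which the two final sequences differ, the
#' difference is classified synonymous/nonsynonymous from the classes of the
#' logged events at that position (split half/half in the rare mixed case).
#' Positions whose events reverted are not counted, so this is the realized
#' difference, not the nominal target.
#' @noRd
realized_divergence <- function(seq1, seq2, events, S, N) {
  Sd <- 0; Nd <- 0
  c1 <- vapply(seq1, seq_chars, character(3L))
  c2 <- vapply(seq2, seq_chars, character(3L))
  diffs <- which(c1 != c2, arr.ind = TRUE)  # rows: (pos-in-codon, codon)
  if (nrow(diffs) > 0L) {
    for (r in seq_len(nrow(diffs))) {
      pos <- diffs[r, 1L]; ci <- diffs[r, 2L]
      cls <- events$syn[events$codon == ci & events$pos == pos]
      if (length(cls) == 0L) next
      if (all(cls)) Sd <- Sd + 1
      else if (all(!cls)) Nd <- Nd + 1
      else { Sd <- Sd + 0.5; Nd <- Nd + 0.5 }
    }
  }
  ps <- if (S > 0) Sd / S else 0  # a zero-site class realizes no divergence
  pn <- if (N > 0) Nd / N else 0
  list(Sd = Sd, Nd = Nd, ps = ps, pn = pn,
       ks = if (ps < 0.75) jc_correction(ps) else NA_real_,
       ka = if (pn < 0.75) jc_correction(pn) else NA_real_)
}

#' Simulate an aligned nucleotide pair at a target JC distance
#'
#' Each site of the second sequence is independently substituted to a
#' uniformly chosen different base with probability
#' `p = (3/4) * (1 - exp(-4 d / 3))`.
#'
#' @param n_sites Number of sites.
#' @param d Target JC distance (>= 0).
#' @param seed Integer seed.
#' @param ids Names of the two sequences.
#' @return List with `a`, `b` (aligned strings), `p_expected` and
#'   `n_mismatches`.
#' @export
simulate_jc_pair <- function(n_sites, d, seed, ids = c("a", "b")) {
  if (!is.finite(d) || d < 0) stop("d must be >= 0", call. = FALSE)
  p <- 0.75 * (1 - exp(-4 * d / 3))
  with_seed(seed, {
    a <- sample(BASES, n_sites, replace = TRUE)
    b <- a
    hit <- runif(n_sites) < p
    if (any(hit)) {
      b[hit] <- vapply(a[hit], function(x) sample(BASES[BASES != x], 1L), "")
    }
    out <- setNames(c(paste(a, collapse = ""), paste(b, collapse = "")), ids)
    list(a = out[[1L]], b = out[[2L]], p_expected = p,
         n_mismatches = sum(hit), ids = ids)
  })
}

#' Simulate a multi-locus molecular-clock dataset with known ages
#'
#' For a focal taxon and a set of split ages (My), each locus has a
#' per-lineage rate (ks per My per lineage). True divergence of each
#' focal-vs-taxon pair at each locus is `2 * rate * age` (both lineages
#' accumulate substitutions since the split); in `noise = TRUE` mode a codon
#' pair is
#' simulated at that target with [simulate_codon_pair()] and its NG86 `ks`
#' estimate enters the table, otherwise the exact value does.
#'
#' @param ages Named numeric vector of split ages (My) of each taxon from the
#'   focal taxon; all > 0 (the star design is trivially ultrametric).
#' @param rates Named numeric vector of per-locus per-lineage rates
#'   (ks/My/lineage).
#' @param n_codons Codons per locus alignment.
#' @param seed Integer seed.
#' @param noise Simulate sequences (TRUE) or emit exact divergences (FALSE).
#' @param focal Focal taxon name.
#' @param ka_fraction Nonsynonymous target as a fraction of the synonymous
#'   target (default 0.2).
#' @return List with `table` (data frame pair, locus, ks), `true_ages`,
#'   `rates`, `anchor_taxon` (the oldest split, the designated calibration
#'   pair).
#' @export
simulate_clock_dataset <- function(ages, rates, n_codons = 1000L, seed = 1L,
                                   noise = TRUE, focal = "focal",
                                   ka_fraction = 0.2) {
  if (is.null(names(ages)) || is.null(names(rates))) {
    stop("ages and rates must be named", call. = FALSE)
  }
  if (any(!is.finite(ages)) || any(ages <= 0)) {
    stop("invalid timetree: all split ages must be > 0", call. = FALSE)
  }
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("all locus rates must be > 0", call. = FALSE)
  }
  rows <- list()
  k <- 0L
  for (locus in names(rates)) {
    for (taxon in names(ages)) {
      k <- k + 1L
      true_ks <- 2 * rates[[locus]] * ages[[taxon]]
      ks <- if (noise) {
        sim <- simulate_codon_pair(n_codons, true_ks,
                                   ka_fraction * true_ks,
                                   seed = as.integer(seed) + k,
                                   ids = c(focal, taxon))
        ng86(sim$alignment)$ks
      } else true_ks
      rows[[k]] <- data.frame(pair = paste(focal, taxon, sep = "-"),
                              taxon = taxon, locus = locus, ks = ks,
                              true_ks = true_ks)
    }
  }
  list(table = do.call(rbind, rows), true_ages = ages, rates = rates,
       focal = focal, anchor_taxon = names(ages)[which.max(ages)])
}

#' Simulate a two-paralog locus with a 14-exon gene architecture
#'
#' Builds a reference sequence carrying two paralogous genes a configurable
#' distance apart (default ~8 kb), each with `n_exons` exons (start codon in
#' exon 2, stop codon in the last exon). Recognition sites of every shipped
#' enzyme are planted inside the probe interval at the 5' end of the first
#' gene so that each enzyme's digest yields at least two probe-hybridizing
#' fragments. The second gene's alpha (intron-1 retained) and beta (fully
#' spliced) transcript variants are emitted.
#'
#' @param seed Integer seed.
#' @param n_exons Exons per gene (default 14; introns = n_exons - 1).
#' @param exon_len_range,intron_len_range Length ranges (bp).
#' @param spacer Distance between the genes (bp).
#' @param ks_target,ka_target Divergence targets between the paralog CDSs.
#' @param intron_jc Target JC distance between paralog non-coding regions.
#' @return List with `genome`, `models` (list of two [gene_model()]),
#'   `probe` (c(start, end)), `variants` (list alpha, beta of gene 2),
#'   `enzymes`.
#' @export
simulate_locus <- function(seed, n_exons = 14L,
                           exon_len_range = c(40L, 382L),
                           intron_len_range = c(81L, 1201L),
                           spacer = 8000L,
                           ks_target = 0.15, ka_target = 0.03,
                           intron_jc = 0.26) {
  if (n_exons < 3L) stop("infeasible locus spec: need >= 3 exons", call. = FALSE)
  if (exon_len_range[2L] < exon_len_range[1L] || exon_len_range[1L] < 10L ||
      intron_len_range[2L] < intron_len_range[1L] || intron_len_range[1L] < 4L) {
    stop("infeasible length constraints", call. = FALSE)
  }
  enzymes <- shipped_enzymes()
  with_seed(seed, {
    rint <- function(lo, hi) sample(seq.int(lo, hi), 1L)
    n_introns <- n_exons - 1L
    exon_len <- vapply(seq_len(n_exons), function(i)
      rint(exon_len_range[1L], exon_len_range[2L]), 0L)
    intron_len <- vapply(seq_len(n_introns), function(i)
      rint(intron_len_range[1L], intron_len_range[2L]), 0L)
    # keep the planted probe/sites 5' of the CDS: widen exon 1 + intron 1
    exon_len[1L] <- max(exon_len[1L], min(100L, exon_len_range[2L]))
    intron_len[1L] <- max(intron_len[1L], min(200L, intron_len_range[2L]))
    u2 <- min(35L, exon_len[2L] - 10L)            # UTR bases in exon 2
    u_last <- min(40L, exon_len[n_exons] - 10L)   # 3' UTR bases in last exon
    cds_len <- sum(exon_len[-1L]) - u2 - u_last
    u_last <- u_last + cds_len %% 3L              # fix frame
    cds_len <- cds_len - cds_len %% 3L
    if (cds_len < 9L) stop("infeasible length constraints: CDS too short",
                           call. = FALSE)
    n_mid <- cds_len / 3L - 2L
    mid <- sample(setdiff(sense_codons(), "ATG"), n_mid, replace = TRUE)
    cds <- paste0("ATG", paste(mid, collapse = ""), "TAA")
    utr5 <- paste(sample(BASES, exon_len[1L] + u2, replace = TRUE),
                  collapse = "")
    utr3 <- paste(sample(BASES, u_last, replace = TRUE), collapse = "")
    transcript <- paste0(utr5, cds, utr3)
    intron_seq <- vapply(intron_len, function(L)
      paste(sample(BASES, L, replace = TRUE), collapse = ""), "")
    # assemble gene 1 and its exon coordinates
    assemble <- function(transcript, intron_seq, offset) {
      pos <- offset
      t_off <- 0L
      exons <- matrix(0L, n_exons, 2L,
                      dimnames = list(NULL, c("start", "end")))
      pieces <- character(0)
      for (i in seq_len(n_exons)) {
        exons[i, ] <- c(pos, pos + exon_len[i])
        pieces <- c(pieces, substr(transcript, t_off + 1L,
                                   t_off + exon_len[i]))
        t_off <- t_off + exon_len[i]
        pos <- pos + exon_len[i]
        if (i <= n_introns) {
          pieces <- c(pieces, intron_seq[i])
          pos <- pos + intron_len[i]
        }
      }
      list(seq = paste(pieces, collapse = ""), exons = exons)
    }
    prefix_len <- 500L
    g1 <- assemble(transcript, intron_seq, prefix_len)
    gene_span <- nchar(g1$seq)
    # paralog: diverge the CDS via logged events, the non-coding via JC
    pair <- simulate_codon_pair(cds_len / 3L, ks_target, ka_target,
                                seed = as.integer(seed) + 101L)
    # rebuild paralog CDS from ancestor-free pair: take lineage 2 relative
    # to lineage 1 replaced into gene 1's CDS? keep gene 1 as drawn and
    # derive paralog CDS by mutating gene 1's CDS like lineage 2 vs 1.
    mutate_jc <- function(x, d) {
      p <- 0.75 * (1 - exp(-4 * d / 3))
      ch <- seq_chars(x)
      hit <- runif(length(ch)) < p
      ch[hit] <- vapply(ch[hit], function(b) sample(BASES[BASES != b], 1L), "")
      paste(ch, collapse = "")
    }
    cds2_codons <- split_codons(cds)
    ev <- pair$events
    for (r in seq_len(nrow(ev))) {
      if (ev$lineage[r] != 2L) next
      ci <- ev$codon[r]
      cur <- seq_chars(cds2_codons[ci])
      to <- seq_chars(ev$to[r])
      cur[ev$pos[r]] <- to[ev$pos[r]]
      cand <- paste(cur, collapse = "")
      # skip an event that would create a stop in this background
      if (genetic_code()[[cand]] == "*") next
      cds2_codons[ci] <- cand
    }
    cds2 <- paste(cds2_codons, collapse = "")
    substr(cds2, 1L, 3L) <- "ATG"
    substr(cds2, cds_len - 2L, cds_len) <- "TAA"
    transcript2 <- paste0(mutate_jc(utr5, intron_jc), cds2,
                          mutate_jc(utr3, intron_jc))
    intron_seq2 <- vapply(intron_seq, mutate_jc, "", d = intron_jc)
    g2_offset <- prefix_len + gene_span + spacer
    g2 <- assemble(transcript2, intron_seq2, g2_offset)
    suffix <- paste(sample(BASES, 500L, replace = TRUE), collapse = "")
    genome <- paste0(paste(sample(BASES, prefix_len, replace = TRUE),
                           collapse = ""),
                     g1$seq,
                     paste(sample(BASES, spacer, replace = TRUE),
                           collapse = ""),
                     g2$seq, suffix)
    # plant one site of each enzyme inside the probe window (5' of the CDS)
    probe <- c(prefix_len, prefix_len + 260L)
    at <- prefix_len + c(20L, 70L, 120L, 170L, 220L)
    for (i in seq_along(enzymes)) {
      site <- enzymes[[i]]$site
      substr(genome, at[i] + 1L, at[i] + nchar(site)) <- site
    }
    utr5_len <- exon_len[1L] + u2
    model1 <- gene_model("synthetic_locus", "+", g1$exons,
                         utr5_len, utr5_len + cds_len, name = "geneA")
    model2 <- gene_model("synthetic_locus", "+", g2$exons,
                         utr5_len, utr5_len + cds_len, name = "geneB")
    beta <- splice(model2, genome)
    alpha <- retain_intron(model2, genome, 1L)
    list(genome = genome, models = list(geneA = model1, geneB = model2),
         probe = probe, variants = list(alpha = alpha, beta = beta),
         enzymes = enzymes,
         exon_len = exon_len, intron_len = intron_len)
  })
}
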