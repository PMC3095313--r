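# End-to-end report drivers: divergence -> clock -> tree (run_dating) and
# locus characterization (run_locus). These are the programmatic entry points
# the analysis scripts call; both write TSV reports whose first line records
# the seed, and both return a `status` field (0 ok, 2 validation error
# raised, 3 partial result, e.g. saturation or a locus without an anchor).

#' Write a data frame as TSV with a seed-stamped header comment
#' @noRd
write_report_tsv <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# divclock report; seed=%s", as.character(seed)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV report written by the pipeline (skips '#' header lines)
#' @param path TSV path.
#' @return Data frame.
#' @export
read_report_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Run the divergence -> clock -> tree dating pipeline
#'
#' Inputs may be printed divergences (a table of pair/locus/ks) or coding
#' FASTA files from which pairwise Ks is computed; ages are obtained by
#' rescaling each pair's Ks against the anchor of its locus, averaged across
#' loci per pair, and an optional paralog pair is dated as a duplication.
#'
#' @param cfg A list with elements:
#'   \describe{
#'     \item{outdir}{Output directory (created if needed).}
#'     \item{seed}{Integer seed, stamped into report headers.}
#'     \item{divergence_table}{Data frame (or TSV path) with columns `pair`,
#'       `locus`, `ks` — e.g. published Ks values used as inputs.}
#'     \item{loci}{Alternative to `divergence_table`: named list
#'       `locus = list(path = <FASTA of aligned or unaligned CDS>,
#'       focal = <id>, type = "coding"|"noncoding")`; pairwise divergence of
#'       the focal member against every other member is computed (NG86 Ks
#'       after protein-guided codon alignment for coding input, JC distance
#'       for pre-aligned non-coding input).}
#'     \item{anchors}{List of [calibration_anchor()] (or anchor TSV path);
#'       matched to divergence rows by locus.}
#'     \item{duplication}{Optional: `list(ks =, locus =, pair_label =,
#'       digits = 0)` or `list(path = <FASTA with two paralog CDS>, locus =,
#'       digits = 0)`.}
#'     \item{tree}{Optional: `list(path = <FASTA of >= 3 aligned CDS>,
#'       bootstrap = <n>, distance = "ks")` for an NJ tree with support.}
#'   }
#' @return List with `status`, `divergence`, `ages`, `averages`,
#'   `duplication`, `tree`, `paths`.
#' @export
run_dating <- function(cfg) {
  if (is.null(cfg$outdir)) stop("cfg$outdir required", call. = FALSE)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(cfg$seed)) 0L else as.integer(cfg$seed)
  status <- 0L
  paths <- list()

  # --- divergence table ---
  div <- NULL
  if (!is.null(cfg$divergence_table)) {
    div <- cfg$divergence_table
    if (is.character(div)) div <- read_report_tsv(div)
    need <- c("pair", "locus", "ks")
    if (!all(need %in% names(div))) {
      stop("divergence_table needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
  } else if (!is.null(cfg$loci)) {
    rows <- list()
    for (locus in names(cfg$loci)) {
      spec <- cfg$loci[[locus]]
      seqs <- read_fasta(spec$path)
      focal <- spec$focal
      if (!focal %in% names(seqs)) {
        stop("focal id '", focal, "' absent from ", spec$path, call. = FALSE)
      }
      for (other in setdiff(names(seqs), focal)) {
        ks <- if (identical(spec$type, "noncoding")) {
          jc_nucleotide_distance(seqs[[focal]], seqs[[other]])$d
        } else {
          aln <- align_codons(seqs[focal], seqs[other],
                              ids = c(focal, other))
          est <- ng86(aln)
          if (is.na(est$ks)) { status <- 3L; NA_real_ } else est$ks
        }
        rows[[length(rows) + 1L]] <- data.frame(
          pair = paste(focal, other, sep = "-"), locus = locus, ks = ks)
      }
    }
    div <- do.call(rbind, rows)
  } else {
    stop("cfg needs divergence_table or loci", call. = FALSE)
  }
  paths$divergence <- file.path(cfg$outdir, "divergence.tsv")
  write_report_tsv(transform(div, ks = round(ks, 4)), paths$divergence, seed)

  # --- anchors & ages ---
  anchors <- cfg$anchors
  if (is.character(anchors)) anchors <- read_anchor_table(anchors)
  if (is.null(anchors)) stop("cfg$anchors required", call. = FALSE)
  ages <- div
  ages$anchor_ks <- NA_real_
  ages$anchor_age_my <- NA_real_
  ages$age_my <- NA_real_
  est_list <- list()
  for (i in seq_len(nrow(ages))) {
    anc <- anchors[[ages$locus[i]]]
    if (is.null(anc) || is.na(ages$ks[i])) {
      status <- 3L
      next
    }
    est <- estimate_age(ages$ks[i], anc, pair_label = ages$pair[i],
                        locus = ages$locus[i])
    est_list[[length(est_list) + 1L]] <- est
    ages$anchor_ks[i] <- anc$ks
    ages$anchor_age_my[i] <- anc$age_my
    ages$age_my[i] <- est$age_rounded
  }
  paths$ages <- file.path(cfg$outdir, "ages.tsv")
  write_report_tsv(ages, paths$ages, seed)

  by_pair <- split(est_list,
                   vapply(est_list, function(e) e$pair_label, ""))
  averages <- do.call(rbind, lapply(by_pair, function(es) {
    av <- average_ages(es)
    data.frame(pair = av$pair_label, n_loci = length(av$per_locus),
               mean_age_my = av$mean_my)
  }))
  paths$averages <- file.path(cfg$outdir, "average_ages.tsv")
  write_report_tsv(averages, paths$averages, seed)

  # --- duplication dating ---
  dup <- NULL
  if (!is.null(cfg$duplication)) {
    dspec <- cfg$duplication
    digits <- if (is.null(dspec$digits)) 1 else dspec$digits
    anc <- anchors[[dspec$locus]]
    if (is.null(anc)) stop("no anchor for duplication locus '", dspec$locus,
                           "'", call. = FALSE)
    est <- if (!is.null(dspec$path)) {
      seqs <- read_fasta(dspec$path)
      aln <- align_codons(seqs[1L], seqs[2L], ids = names(seqs)[1:2])
      date_duplication(aln, anc, digits = digits)
    } else {
      estimate_age(dspec$ks, anc,
                   pair_label = if (is.null(dspec$pair_label)) "paralogs"
                                else dspec$pair_label,
                   digits = digits)
    }
    dup <- data.frame(pair = est$pair_label, locus = est$locus,
                      ks = round(est$ks, 4), anchor_ks = anc$ks,
                      anchor_age_my = anc$age_my,
                      age_my = est$age_rounded)
    paths$duplication <- file.path(cfg$outdir, "duplication.tsv")
    write_report_tsv(dup, paths$duplication, seed)
  }

  # --- tree ---
  tree <- NULL
  if (!is.null(cfg$tree)) {
    seqs <- read_fasta(cfg$tree$path)
    members <- codon_alignment(seqs)
    if (is.null(cfg$tree$bootstrap)) {
      labs <- names(seqs)
      m <- length(labs)
      d <- matrix(0, m, m, dimnames = list(labs, labs))
      for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
        est <- ng86(members, pair = labs[c(i, j)])
        if (is.na(est$ks)) status <- 3L
        d[i, j] <- d[j, i] <- est$ks
      }
      tree <- nj_tree(d)
    } else {
      tree <- bootstrap_support(members, n_reps = cfg$tree$bootstrap,
                                seed = seed,
                                distance = if (is.null(cfg$tree$distance))
                                  "ks" else cfg$tree$distance)
    }
    paths$tree <- file.path(cfg$outdir, "tree.nwk")
    write_newick(tree, paths$tree)
  }

  list(status = status, divergence = div, ages = ages, averages = averages,
       duplication = dup, tree = tree, paths = paths)
}

#' Run the locus characterization pipeline
#'
#' Restriction digest with probe-hybridization flags, transcript/variant
#' table and protein statistics for a genome plus gene models.
#'
#' @param cfg A list with elements:
#'   \describe{
#'     \item{outdir}{Output directory.}
#'     \item{seed}{Integer seed for report headers.}
#'     \item{genome}{Reference sequence string, or FASTA path (first record).}
#'     \item{models}{List of [gene_model()] or a GFF3 path.}
#'     \item{enzymes}{Character names into [shipped_enzymes()] or a list of
#'       [restriction_enzyme()]; empty/NULL skips the digest section.}
#'     \item{probe}{Optional probe interval `c(start, end)`.}
#'     \item{retain}{Optional named list `gene_name = intron index` of
#'       intron-retention variants to emit.}
#'   }
#' @return List with `status`, `digests`, `transcripts`, `proteins`, `paths`.
#' @export
run_locus <- function(cfg) {
  if (is.null(cfg$outdir)) stop("cfg$outdir required", call. = FALSE)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(cfg$seed)) 0L else as.integer(cfg$seed)
  paths <- list()
  genome <- cfg$genome
  if (is.character(genome) && nchar(genome) < 1000L && file.exists(genome)) {
    genome <- read_fasta(genome)[[1L]]
  }
  models <- cfg$models
  if (is.character(models)) models <- read_gene_models_gff3(models)

  # --- digest section ---
  digests <- NULL
  enz <- cfg$enzymes
  if (!is.null(enz) && length(enz) > 0L) {
    if (is.character(enz)) enz <- shipped_enzymes()[enz]
    rows <- list()
    for (e in enz) {
      d <- digest(genome, e, topology = "linear")
      fr <- d$fragments
      fr$enzyme <- e$name
      fr$hybridizing <- FALSE
      if (!is.null(cfg$probe)) {
        hy <- probe_fragments(d, cfg$probe)
        fr$hybridizing <- rownames(fr) %in% rownames(hy)
      }
      rows[[length(rows) + 1L]] <- fr
    }
    digests <- do.call(rbind, rows)
    digests <- digests[, c("enzyme", "start", "end", "length", "hybridizing")]
    paths$digest <- file.path(cfg$outdir, "digest.tsv")
    write_report_tsv(digests, paths$digest, seed)
  }

  # --- transcripts ---
  variants <- list()
  for (nm in names(models)) {
    variants[[length(variants) + 1L]] <- splice(models[[nm]], genome)
    if (!is.null(cfg$retain) && nm %in% names(cfg$retain)) {
      variants[[length(variants) + 1L]] <-
        retain_intron(models[[nm]], genome, cfg$retain[[nm]])
    }
  }
  transcripts <- do.call(rbind, lapply(variants, function(v) {
    data.frame(name = v$name, length = nchar(v$sequence),
               utr5_len = v$utr5_len,
               cds_len = v$cds_end - v$cds_start, utr3_len = v$utr3_len,
               retained_introns = paste(v$retained_introns, collapse = ","),
               cds_status = v$cds_status)
  }))
  paths$transcripts <- file.path(cfg$outdir, "transcripts.tsv")
  write_report_tsv(transcripts, paths$transcripts, seed)

  # --- proteins ---
  prots <- lapply(variants, function(v) {
    cds <- substr(v$sequence, v$cds_start + 1L, v$cds_end)
    sub("\\*$", "", translate_cds(cds))
  })
  names(prots) <- vapply(variants, function(v) v$name, "")
  proteins <- do.call(rbind, lapply(names(prots), function(nm) {
    p <- prots[[nm]]
    data.frame(name = nm, length = nchar(p),
               mw_da = round(protein_mw(p), 0), pi = protein_pi(p))
  }))
  # identity between the first two distinct gene products, if present
  identity <- NULL
  distinct <- prots[!duplicated(unname(unlist(prots)))]
  if (length(distinct) >= 2L) {
    aln <- nw_align(distinct[[1L]], distinct[[2L]])
    identity <- identity_stats(aln$a_aln, aln$b_aln)
  }
  paths$proteins <- file.path(cfg$outdir, "proteins.tsv")
  write_report_tsv(proteins, paths$proteins, seed)

  list(status = 0L, digests = digests, transcripts = transcripts,
       proteins = proteins, identity = identity, paths = paths)
}
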