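# In-silico locus characterization: gene models, splicing and
# intron-retention transcript variants, restriction digests and Southern
# probe fragment prediction.
#
# All reference coordinates are 0-based, half-open. Minus-strand genes store
# exons in transcript (5'->3') orientation and are reverse-complemented at
# splice time; stored coordinates are never flipped.

#' Construct and validate a gene model
#'
#' @param seq_id Reference sequence label.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data frame of 0-based half-open exon
#'   intervals on the reference, ordered 5'->3' in transcript orientation
#'   (ascending genomic start for `+`, descending for `-`).
#' @param cds_start,cds_end Transcript-relative, 0-based half-open CDS span:
#'   `cds_start` is the offset of the start codon's first base, `cds_end` the
#'   offset just past the stop codon's last base. CDS length must be a
#'   multiple of 3.
#' @param name Gene/transcript name.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(seq_id, strand, exons, cds_start, cds_end,
                       name = "gene") {
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L) stop("exons must have two columns", call. = FALSE)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  if (any(exons[, "end"] <= exons[, "start"])) {
    stop("empty or inverted exon interval", call. = FALSE)
  }
  g <- exons[order(exons[, "start"]), , drop = FALSE]
  if (any(g[-1L, "start"] < g[-nrow(g), "end"])) {
    stop("overlapping exons", call. = FALSE)
  }
  expect_order <- if (strand == "+") order(exons[, "start"]) else
    order(-exons[, "start"])
  if (!identical(expect_order, seq_len(nrow(exons)))) {
    stop("exons not sorted 5'->3' in transcript orientation", call. = FALSE)
  }
  tlen <- sum(exons[, "end"] - exons[, "start"])
  if (cds_start < 0 || cds_end > tlen || cds_end <= cds_start) {
    stop("CDS outside transcript bounds", call. = FALSE)
  }
  if ((cds_end - cds_start) %% 3L != 0L) {
    stop("CDS length not a multiple of 3", call. = FALSE)
  }
  structure(list(seq_id = seq_id, strand = strand, exons = exons,
                 cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end), name = name),
            class = "gene_model")
}

#' Intron intervals of a gene model
#'
#' Gaps between consecutive exons, in transcript orientation. For a minus
#' strand gene the reference interval is still reported as
#' (start, end) with start < end.
#'
#' @param model A [gene_model()].
#' @return Integer matrix with columns start, end (0-based half-open); one
#'   row per intron, ordered 5'->3'.
#' @export
introns <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  if (n < 2L) {
    return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("start", "end"))))
  }
  out <- matrix(0L, n - 1L, 2L, dimnames = list(NULL, c("start", "end")))
  for (i in seq_len(n - 1L)) {
    if (model$strand == "+") {
      out[i, ] <- c(ex[i, "end"], ex[i + 1L, "start"])
    } else {
      out[i, ] <- c(ex[i + 1L, "end"], ex[i, "start"])
    }
  }
  out
}

#' Extract a 0-based half-open interval from a sequence string
#' @noRd
subseq0 <- function(genome, start, end) {
  if (start < 0 || end > nchar(genome)) {
    stop("interval [", start, ",", end, ") out of reference bounds",
         call. = FALSE)
  }
  substr(genome, start + 1L, end)
}

#' Build a transcript variant from blocks
#' @noRd
new_variant <- function(name, blocks, genome, strand, cds_start, cds_end,
                        retained = integer(0), cds_status = "CDS unchanged") {
  pieces <- vapply(seq_len(nrow(blocks)), function(i) {
    s <- subseq0(genome, blocks[i, "start"], blocks[i, "end"])
    if (strand == "-") revcomp(s) else s
  }, "")
  sequence <- paste(pieces, collapse = "")
  structure(list(name = name, blocks = blocks, sequence = sequence,
                 utr5_len = as.integer(cds_start),
                 utr3_len = nchar(sequence) - as.integer(cds_end),
                 cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end),
                 retained_introns = retained, cds_status = cds_status),
            class = "transcript_variant")
}

#' @export
print.transcript_variant <- function(x, ...) {
  cat(sprintf("transcript_variant '%s': %d nt (5'UTR %d, CDS %d, 3'UTR %d)%s\n",
              x$name, nchar(x$sequence), x$utr5_len, x$cds_end - x$cds_start,
              x$utr3_len,
              if (length(x$retained_introns))
                paste0(", retained intron(s) ",
                       paste(x$retained_introns, collapse = ","),
                       " [", x$cds_status, "]") else ""))
  invisible(x)
}

#' Splice a gene model into its mature transcript
#'
#' Concatenates the exon sequences in transcript orientation
#' (reverse-complementing for minus-strand genes). UTR lengths derive from
#' the model's CDS offsets.
#'
#' @param model A [gene_model()].
#' @param genome Reference sequence (character string).
#' @return A `transcript_variant`.
#' @export
splice <- function(model, genome) {
  genome <- toupper(as.character(genome)[1L])
  new_variant(model$name, model$exons, genome, model$strand,
              model$cds_start, model$cds_end)
}

#' Transcript variant retaining one intron
#'
#' Includes intron `k` (1-based, 5'->3') in the mature transcript. If the
#' intron lies entirely 5' of the start codon the 5' UTR grows by the intron
#' length and the encoded protein is unchanged (`cds_status = "CDS
#' unchanged"`); an intron inserted at or past `cds_end` likewise leaves the
#' CDS intact; anything else is classified `"CDS changed"`.
#'
#' @param model A [gene_model()].
#' @param genome Reference sequence.
#' @param k Intron index, `1 <= k <=` number of introns.
#' @return A `transcript_variant` with `retained_introns = k`.
#' @export
retain_intron <- function(model, genome, k) {
  genome <- toupper(as.character(genome)[1L])
  intr <- introns(model)
  if (k < 1L || k > nrow(intr)) {
    stop("intron index ", k, " out of range (gene has ", nrow(intr),
         " introns)", call. = FALSE)
  }
  ex <- model$exons
  ilen <- intr[k, "end"] - intr[k, "start"]
  # merge exon k, intron k, exon k+1 into one block (reference-contiguous)
  if (model$strand == "+") {
    merged <- c(ex[k, "start"], ex[k + 1L, "end"])
  } else {
    merged <- c(ex[k + 1L, "start"], ex[k, "end"])
  }
  keep_before <- if (k > 1L) ex[seq_len(k - 1L), , drop = FALSE] else NULL
  keep_after <- if (k + 1L < nrow(ex)) {
    ex[(k + 2L):nrow(ex), , drop = FALSE]
  } else NULL
  blocks <- rbind(keep_before, matrix(merged, 1L,
                                      dimnames = list(NULL, c("start", "end"))),
                  keep_after)
  insertion <- sum(ex[seq_len(k), "end"] - ex[seq_len(k), "start"])
  if (insertion <= model$cds_start) {
    cds_start <- model$cds_start + ilen
    cds_end <- model$cds_end + ilen
    status <- "CDS unchanged"
  } else if (insertion >= model$cds_end) {
    cds_start <- model$cds_start
    cds_end <- model$cds_end
    status <- "CDS unchanged"
  } else {
    cds_start <- model$cds_start
    cds_end <- model$cds_end + ilen
    status <- "CDS changed"
  }
  new_variant(paste0(model$name, ".retained_intron", k), blocks, genome,
              model$strand, cds_start, cds_end, retained = k,
              cds_status = status)
}

#' Define a restriction enzyme
#'
#' @param name Enzyme name.
#' @param site Unambiguous recognition sequence.
#' @param cut_offset Bases 5' of the cut within the site (top strand),
#'   `0 <= cut_offset <= nchar(site)`.
#' @return Object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, site, cut_offset) {
  site <- toupper(site)
  if (!grepl("^[ACGT]+$", site)) {
    stop("recognition site must be unambiguous DNA", call. = FALSE)
  }
  if (cut_offset < 0 || cut_offset > nchar(site)) {
    stop("cut_offset outside site", call. = FALSE)
  }
  structure(list(name = name, site = site, cut_offset = as.integer(cut_offset)),
            class = "restriction_enzyme")
}

#' The enzymes shipped with the package
#'
#' EcoRV, BglII, NcoI, AluI and Sau3AI; others can be defined with
#' [restriction_enzyme()].
#'
#' @return Named list of [restriction_enzyme()] objects.
#' @export
shipped_enzymes <- function() {
  list(
    EcoRV  = restriction_enzyme("EcoRV",  "GATATC", 3L),
    BglII  = restriction_enzyme("BglII",  "AGATCT", 1L),
    NcoI   = restriction_enzyme("NcoI",   "CCATGG", 1L),
    AluI   = restriction_enzyme("AluI",   "AGCT",   2L),
    Sau3AI = restriction_enzyme("Sau3AI", "GATC",   0L)
  )
}

#' Restriction digest of a molecule
#'
#' All top-strand occurrences of each recognition site are located
#' (palindromic sites once) and the molecule is cut at
#' `site_start + cut_offset`. Fragments partition the molecule; for a linear
#' molecule their lengths sum to the molecule length, for a circular one the
#' number of fragments equals the number of cuts (an uncut circle is one
#' full-length fragment).
#'
#' @param molecule Ungapped DNA string.
#' @param enzymes A [restriction_enzyme()] or list of them.
#' @param topology `"linear"` or `"circular"`.
#' @param partial Also return single-cut-skipped fragments (partial-digest
#'   bands) in `$partial_fragments`.
#' @return Object of class `digest_result`: list with `fragments` (data frame
#'   start, end, length; 0-based half-open, `end` may exceed the molecule
#'   length for the circular wrap fragment), `cuts`, `topology`, `length`,
#'   and optionally `partial_fragments`.
#' @export
digest <- function(molecule, enzymes, topology = c("linear", "circular"),
                   partial = FALSE) {
  topology <- match.arg(topology)
  molecule <- toupper(as.character(molecule)[1L])
  if (grepl("-", molecule, fixed = TRUE)) {
    stop("molecule must be ungapped", call. = FALSE)
  }
  if (inherits(enzymes, "restriction_enzyme")) enzymes <- list(enzymes)
  len <- nchar(molecule)
  cuts <- integer(0)
  search_space <- if (topology == "circular") {
    # allow sites spanning the origin
    paste0(molecule, substr(molecule, 1L,
                            max(vapply(enzymes, function(e) nchar(e$site), 0L)) - 1L))
  } else molecule
  for (e in enzymes) {
    hits <- gregexpr(e$site, search_space, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) next
    starts <- as.integer(hits) - 1L          # 0-based site starts
    starts <- starts[starts < len]           # wrap copies start the same sites
    pos <- starts + e$cut_offset
    if (topology == "circular") pos <- pos %% len
    cuts <- c(cuts, pos)
  }
  cuts <- sort(unique(cuts[cuts >= 0L & cuts <= len]))
  if (topology == "linear") {
    bounds <- unique(c(0L, cuts[cuts > 0L & cuts < len], len))
    frags <- data.frame(start = head(bounds, -1L), end = tail(bounds, -1L))
  } else {
    cuts <- cuts[cuts < len]
    if (length(cuts) == 0L) {
      frags <- data.frame(start = 0L, end = len)
    } else {
      starts <- cuts
      ends <- c(cuts[-1L], cuts[1L] + len)
      frags <- data.frame(start = starts, end = ends)
    }
  }
  frags$length <- frags$end - frags$start
  res <- structure(list(fragments = frags, cuts = cuts, topology = topology,
                        length = len), class = "digest_result")
  if (partial && nrow(frags) > 1L) {
    pf <- data.frame(start = head(frags$start, -1L), end = tail(frags$end, -1L))
    pf$length <- pf$end - pf$start
    res$partial_fragments <- pf
  }
  res
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("digest_result: %d fragment(s) of a %s molecule of %d bp\n",
              nrow(x$fragments), x$topology, x$length))
  print(x$fragments)
  invisible(x)
}

#' Fragments hybridizing to a probe interval
#'
#' Probe hybridization is modeled as interval overlap on the reference: the
#' fragments overlapping the probe by at least `min_overlap` bases are the
#' predicted Southern bands.
#'
#' @param d A [digest()] result.
#' @param probe Integer vector `c(start, end)`, 0-based half-open, non-empty,
#'   within the molecule.
#' @param min_overlap Minimum overlap in bases (default 1).
#' @return The hybridizing subset of `d$fragments`.
#' @export
probe_fragments <- function(d, probe, min_overlap = 1L) {
  stopifnot(inherits(d, "digest_result"))
  if (length(probe) != 2L || probe[2L] <= probe[1L]) {
    stop("probe interval is empty", call. = FALSE)
  }
  if (probe[1L] < 0L || probe[2L] > d$length) {
    stop("probe outside molecule", call. = FALSE)
  }
  fr <- d$fragments
  ov <- pmin(fr$end, probe[2L]) - pmax(fr$start, probe[1L])
  if (d$topology == "circular") {
    # wrap fragment also covers [0, end - length)
    wrap <- fr$end > d$length
    ov2 <- pmin(fr$end - d$length, probe[2L]) - pmax(0L, probe[1L])
    ov[wrap] <- pmax(ov[wrap], ov2[wrap])
  }
  fr[ov >= min_overlap, , drop = FALSE]
}

#' Write a digest report as TSV
#'
#' Columns: fragment start, end, length, hybridizing flag.
#'
#' @param d A [digest()] result.
#' @param path Output path.
#' @param probe Optional probe interval for the hybridizing flag.
#' @param min_overlap Passed to [probe_fragments()].
#' @return The report data frame, invisibly.
#' @export
write_digest_report <- function(d, path, probe = NULL, min_overlap = 1L) {
  fr <- d$fragments
  fr$hybridizing <- FALSE
  if (!is.null(probe)) {
    hy <- probe_fragments(d, probe, min_overlap)
    fr$hybridizing <- rownames(fr) %in% rownames(hy)
  }
  write.table(fr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fr)
}
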