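# Gene-model interchange: GFF3 (gene/mRNA/exon/CDS features) and BED12.
# rtracklayer does the parsing/formatting; this file converts between its
# GRanges representation (1-based closed) and the package's 0-based half-open
# gene_model.

#' Map a transcript-relative position to its genomic coordinate
#' @noRd
transcript_to_genome <- function(model, tpos) {
  ex <- model$exons
  lens <- ex[, "end"] - ex[, "start"]
  cum <- cumsum(lens)
  i <- which(tpos < cum)[1L]
  if (is.na(i)) stop("transcript position out of range", call. = FALSE)
  off <- tpos - if (i > 1L) cum[i - 1L] else 0L
  if (model$strand == "+") ex[i, "start"] + off else ex[i, "end"] - 1L - off
}

#' Genomic CDS intervals of a gene model (0-based half-open)
#' @noRd
cds_genomic_blocks <- function(model) {
  ex <- model$exons
  lens <- ex[, "end"] - ex[, "start"]
  cum <- cumsum(lens)
  prev <- c(0L, head(cum, -1L))
  out <- NULL
  for (i in seq_len(nrow(ex))) {
    lo <- max(model$cds_start, prev[i])
    hi <- min(model$cds_end, cum[i])
    if (hi <= lo) next
    if (model$strand == "+") {
      out <- rbind(out, c(ex[i, "start"] + (lo - prev[i]),
                          ex[i, "start"] + (hi - prev[i])))
    } else {
      out <- rbind(out, c(ex[i, "end"] - (hi - prev[i]),
                          ex[i, "end"] - (lo - prev[i])))
    }
  }
  colnames(out) <- c("start", "end")
  out
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA, exon and CDS features with ID/Parent links.
#'
#' @param models List of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(models, path) {
  rows <- list()
  for (m in models) {
    g <- m$exons[order(m$exons[, "start"]), , drop = FALSE]
    gid <- m$name
    mid <- paste0(gid, ".1")
    add <- function(type, start, end, id = NA, parent = NA, phase = NA) {
      data.frame(seqid = m$seq_id, start = start + 1L, end = end,
                 strand = m$strand, type = type, ID = id, Parent = parent,
                 phase = phase, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- add("gene", g[1L, "start"],
                                     g[nrow(g), "end"], id = gid)
    rows[[length(rows) + 1L]] <- add("mRNA", g[1L, "start"],
                                     g[nrow(g), "end"], id = mid, parent = gid)
    for (i in seq_len(nrow(g))) {
      rows[[length(rows) + 1L]] <- add("exon", g[i, "start"], g[i, "end"],
                                       parent = mid)
    }
    cb <- cds_genomic_blocks(m)
    cb <- cb[order(cb[, "start"]), , drop = FALSE]
    # GFF3 phase: bases to skip at a block's 5' end to reach a codon start
    tr_order <- if (m$strand == "-") rev(seq_len(nrow(cb))) else
      seq_len(nrow(cb))
    phase <- integer(nrow(cb))
    cum <- 0L
    for (i in tr_order) {
      phase[i] <- (3L - cum %% 3L) %% 3L
      cum <- cum + (cb[i, "end"] - cb[i, "start"])
    }
    for (i in seq_len(nrow(cb))) {
      rows[[length(rows) + 1L]] <- add("CDS", cb[i, "start"], cb[i, "end"],
                                       parent = mid, phase = phase[i])
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  gr$type <- df$type
  gr$ID <- df$ID
  gr$Parent <- ifelse(is.na(df$Parent), NA_character_, df$Parent)
  gr$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects gene/mRNA/exon/CDS features linked by ID/Parent; one mRNA per
#' gene. CDS offsets are recomputed transcript-relative.
#'
#' @param path GFF3 path.
#' @return Named list of [gene_model()] objects (names = gene IDs).
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  first_chr <- function(x) {
    if (is.list(x) || methods::is(x, "List")) {
      vapply(x, function(e) if (length(e)) as.character(e[[1L]]) else
        NA_character_, "")
    } else as.character(x)
  }
  type <- as.character(gr$type)
  parent <- first_chr(gr$Parent)
  mrnas <- which(type == "mRNA")
  out <- list()
  for (mi in mrnas) {
    mid <- as.character(gr$ID[mi])
    gid <- parent[mi]
    strand <- as.character(BiocGenerics::strand(gr[mi]))
    seq_id <- as.character(GenomeInfoDb::seqnames(gr[mi]))
    ex_idx <- which(type == "exon" & parent == mid)
    cds_idx <- which(type == "CDS" & parent == mid)
    if (length(ex_idx) == 0L || length(cds_idx) == 0L) {
      stop("mRNA '", mid, "' lacks exon or CDS features", call. = FALSE)
    }
    ex <- cbind(start = BiocGenerics::start(gr[ex_idx]) - 1L,
                end = BiocGenerics::end(gr[ex_idx]))
    ex <- ex[order(ex[, "start"] * ifelse(strand == "+", 1L, -1L)), ,
             drop = FALSE]
    cds <- cbind(start = BiocGenerics::start(gr[cds_idx]) - 1L,
                 end = BiocGenerics::end(gr[cds_idx]))
    cds_len <- sum(cds[, "end"] - cds[, "start"])
    # transcript offset of the CDS 5' end
    g5 <- if (strand == "+") min(cds[, "start"]) else max(cds[, "end"]) - 1L
    lens <- ex[, "end"] - ex[, "start"]
    prev <- c(0L, head(cumsum(lens), -1L))
    cds_start <- NA_integer_
    for (i in seq_len(nrow(ex))) {
      if (g5 >= ex[i, "start"] && g5 < ex[i, "end"]) {
        cds_start <- prev[i] + if (strand == "+") g5 - ex[i, "start"] else
          ex[i, "end"] - 1L - g5
        break
      }
    }
    if (is.na(cds_start)) stop("CDS start not inside any exon of '", mid, "'",
                               call. = FALSE)
    out[[gid]] <- gene_model(seq_id, strand, ex, cds_start,
                             cds_start + cds_len, name = gid)
  }
  out
}

#' Read gene models from BED12
#'
#' Blocks become exons; thickStart/thickEnd become the CDS span.
#'
#' @param path BED12 path.
#' @return Named list of [gene_model()] objects.
#' @export
read_gene_models_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- list()
  for (i in seq_along(gr)) {
    g <- gr[i]
    strand <- as.character(BiocGenerics::strand(g))
    if (!strand %in% c("+", "-")) strand <- "+"
    blocks <- rtracklayer::blocks(g)[[1L]]
    ex <- cbind(start = BiocGenerics::start(blocks) - 1L,
                end = BiocGenerics::end(blocks))
    ex <- ex[order(ex[, "start"] * ifelse(strand == "+", 1L, -1L)), ,
             drop = FALSE]
    thick <- g$thick
    t0 <- BiocGenerics::start(thick) - 1L
    t1 <- BiocGenerics::end(thick)
    lens <- ex[, "end"] - ex[, "start"]
    prev <- c(0L, head(cumsum(lens), -1L))
    to_t <- function(gpos_first) {  # genomic base (0-based) -> transcript offset
      for (j in seq_len(nrow(ex))) {
        if (gpos_first >= ex[j, "start"] && gpos_first < ex[j, "end"]) {
          return(prev[j] + if (strand == "+") gpos_first - ex[j, "start"] else
            ex[j, "end"] - 1L - gpos_first)
        }
      }
      stop("thick boundary not inside any block", call. = FALSE)
    }
    cds_start <- if (strand == "+") to_t(t0) else to_t(t1 - 1L)
    cds_len <- 0L
    for (j in seq_len(nrow(ex))) {
      cds_len <- cds_len + max(0L, min(t1, ex[j, "end"]) -
                                 max(t0, ex[j, "start"]))
    }
    nm <- as.character(g$name)
    out[[nm]] <- gene_model(as.character(GenomeInfoDb::seqnames(g)), strand,
                            ex, cds_start, cds_start + cds_len, name = nm)
  }
  out
}
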