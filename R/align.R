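# Protein-guided pairwise codon alignment.
#
# Coding sequences are aligned at the protein level by global
# Needleman-Wunsch with affine gaps (Gotoh), then each aligned amino-acid
# column is expanded back to its source codon (or '---'). Pairwise global
# alignment replaces a multiple aligner because every downstream divergence
# computation is pairwise; the traceback tie-break (diagonal over up over
# left) makes alignments bit-stable.

#' Global protein alignment with affine gaps
#'
#' Needleman–Wunsch/Gotoh. A gap of length L scores
#' `gap_open + (L - 1) * gap_extend` (the opening penalty covers the first
#' gapped column). Traceback ties are broken diagonal > up > left.
#'
#' @param a,b Amino-acid strings (no gaps).
#' @param sub_matrix Square scoring matrix with residue dimnames; default
#'   BLOSUM62.
#' @param gap_open,gap_extend Gap scores (negative).
#' @return List with `a_aln`, `b_aln` (gapped strings) and `score`.
#' @export
nw_align <- function(a, b, sub_matrix = NULL, gap_open = -10, gap_extend = -1) {
  if (is.null(sub_matrix)) sub_matrix <- blosum62()
  av <- seq_chars(a)
  bv <- seq_chars(b)
  n <- length(av)
  m <- length(bv)
  if (n == 0L || m == 0L) stop("cannot align empty sequence", call. = FALSE)
  if (!all(av %in% rownames(sub_matrix)) || !all(bv %in% rownames(sub_matrix))) {
    stop("residue absent from scoring matrix", call. = FALSE)
  }
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)  # (i,j) aligned
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in b (consumes a, "up")
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in a (consumes b, "left")
  M[1L, 1L] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- gap_open + (i - 1L) * gap_extend
  for (j in seq_len(m)) Y[1L, j + 1L] <- gap_open + (j - 1L) * gap_extend
  S <- sub_matrix[av, bv, drop = FALSE]
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + S[i, j]
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] + gap_open,
                               X[i, j + 1L] + gap_extend)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] + gap_open,
                               Y[i + 1L, j] + gap_extend)
    }
  }
  score <- max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  near <- function(x, y) abs(x - y) < 1e-9
  # traceback; state preference M (diag) > X (up) > Y (left)
  state <- if (near(M[n + 1L, m + 1L], score)) "M"
           else if (near(X[n + 1L, m + 1L], score)) "X" else "Y"
  i <- n; j <- m
  ares <- character(0); bres <- character(0)
  while (i > 0L || j > 0L) {
    if (state == "M") {
      ares <- c(av[i], ares); bres <- c(bv[j], bres)
      prev <- M[i + 1L, j + 1L] - S[i, j]
      state <- if (i > 1L || j > 1L) {
        if (near(M[i, j], prev)) "M" else if (near(X[i, j], prev)) "X" else "Y"
      } else "M"
      i <- i - 1L; j <- j - 1L
    } else if (state == "X") {
      ares <- c(av[i], ares); bres <- c("-", bres)
      state <- if (near(M[i, j + 1L] + gap_open, X[i + 1L, j + 1L])) "M" else "X"
      i <- i - 1L
    } else {
      ares <- c("-", ares); bres <- c(bv[j], bres)
      state <- if (near(M[i + 1L, j] + gap_open, Y[i + 1L, j + 1L])) "M" else "Y"
      j <- j - 1L
    }
  }
  list(a_aln = paste(ares, collapse = ""),
       b_aln = paste(bres, collapse = ""),
       score = score)
}

#' BLOSUM62 scoring matrix
#' @noRd
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Construct and validate a codon alignment
#'
#' @param members Named character vector (>= 2) of equal-length aligned
#'   coding sequences; gaps in runs whose length is a multiple of 3.
#' @return Object of class `codon_alignment` with elements `members` and
#'   `length` (columns).
#' @export
codon_alignment <- function(members) {
  if (length(members) < 2L) stop("need >= 2 members", call. = FALSE)
  if (is.null(names(members)) || anyDuplicated(names(members)) ||
      any(names(members) == "")) {
    stop("members must have unique non-empty names", call. = FALSE)
  }
  len <- unique(nchar(members))
  if (length(len) != 1L) stop("members differ in aligned length", call. = FALSE)
  if (len %% 3L != 0L) stop("aligned length not a multiple of 3", call. = FALSE)
  gc <- genetic_code()
  for (id in names(members)) {
    runs <- regmatches(members[[id]], gregexpr("-+", members[[id]]))[[1L]]
    if (any(nchar(runs) %% 3L != 0L)) {
      stop("member '", id, "' has a gap run whose length is not a multiple of 3",
           call. = FALSE)
    }
    codons <- split_codons(degap(members[[id]]))
    stops <- which(codons %in% names(gc)[gc == "*"])
    if (any(stops < length(codons))) {
      stop("member '", id, "' has an internal stop codon", call. = FALSE)
    }
  }
  structure(list(members = members, length = len), class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$members), "members,",
      x$length, "columns (", x$length / 3L, "codons )\n")
  invisible(x)
}

#' Trim a terminal stop codon from a CDS, if present
#' @noRd
trim_stop <- function(seq) {
  codons <- split_codons(toupper(seq))
  gc <- genetic_code()
  if (gc[[codons[length(codons)]]] == "*") {
    seq <- substr(seq, 1L, nchar(seq) - 3L)
  }
  seq
}

#' Protein-guided codon alignment of two coding sequences
#'
#' Both inputs must be in-frame CDS (terminal stop codons are trimmed before
#' alignment). The translated proteins are globally aligned with
#' [nw_align()], and each aligned amino-acid column is expanded to its source
#' codon or `'---'`.
#'
#' @param a,b Coding sequences (character) or length-1 named vectors.
#' @param ids Character vector of two member ids; defaults to names of `a`
#'   and `b`, else `"a"`/`"b"`.
#' @param sub_matrix,gap_open,gap_extend Passed to [nw_align()].
#' @return A [codon_alignment()] with attribute `protein_score`.
#' @examples
#' aln <- align_codons(c(x = "ATGAAA"), c(y = "ATGGGGAAA"))
#' aln$members
#' @export
align_codons <- function(a, b, ids = NULL, sub_matrix = NULL,
                         gap_open = -10, gap_extend = -1) {
  if (is.null(ids)) {
    ids <- c(if (!is.null(names(a))) names(a)[1L] else "a",
             if (!is.null(names(b))) names(b)[1L] else "b")
  }
  a <- trim_stop(as.character(a)[1L])
  b <- trim_stop(as.character(b)[1L])
  pa <- translate_cds(a)
  pb <- translate_cds(b)
  aln <- nw_align(pa, pb, sub_matrix = sub_matrix,
                  gap_open = gap_open, gap_extend = gap_extend)
  thread <- function(prot_aln, cds) {
    codons <- split_codons(cds)
    out <- character(nchar(prot_aln))
    k <- 0L
    cols <- seq_chars(prot_aln)
    for (i in seq_along(cols)) {
      if (cols[i] == "-") {
        out[i] <- "---"
      } else {
        k <- k + 1L
        out[i] <- codons[k]
      }
    }
    paste(out, collapse = "")
  }
  members <- setNames(c(thread(aln$a_aln, a), thread(aln$b_aln, b)), ids)
  res <- codon_alignment(members)
  attr(res, "protein_score") <- aln$score
  res
}
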