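# Sequence I/O and validation.
#
# Sequences are plain upper-case character strings; a collection is a named
# character vector (names = record ids) carrying a "descriptions" attribute.
# Alphabet: IUPAC nucleotide codes plus the gap character '-'.

NUC_ALPHABET <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N", "-")
PROT_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                   "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*", "-")

#' Split a sequence string into single characters
#' @noRd
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' Validate residues of one record against an alphabet
#' @noRd
check_alphabet <- function(id, residues, alphabet, what = "nucleotide") {
  ch <- seq_chars(residues)
  bad <- which(!(ch %in% alphabet))
  if (length(bad) > 0L) {
    stop(sprintf("record '%s': illegal %s residue '%s' at position %d",
                 id, what, ch[bad[1L]], bad[1L]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read nucleotide sequences from a FASTA file
#'
#' Records are returned in file order with residues upper-cased. Ids are the
#' first whitespace-delimited token of each header; the remainder of the
#' header is kept in the `descriptions` attribute.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names = ids), with a
#'   `descriptions` character-vector attribute of equal length.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a first", "ACGT"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA record with empty id in ", path, call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id '", dup[1L], "' in ", path, call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  for (i in seq_along(seqs)) check_alphabet(ids[i], seqs[i], NUC_ALPHABET)
  attr(seqs, "descriptions") <- desc
  seqs
}

#' Write nucleotide sequences to a FASTA file
#'
#' Lines are wrapped at 60 columns. Round-trips with [read_fasta()] on id and
#' residues exactly.
#'
#' @param seqs Named character vector of sequences; an optional
#'   `descriptions` attribute is appended to headers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named", call. = FALSE)
  }
  desc <- attr(seqs, "descriptions")
  set <- Biostrings::BStringSet(unname(as.character(seqs)))
  hdr <- names(seqs)
  if (!is.null(desc)) {
    hdr <- ifelse(desc == "", hdr, paste(hdr, desc))
  }
  names(set) <- hdr
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Reverse-complement a DNA string
#'
#' Handles IUPAC ambiguity codes and gaps.
#'
#' @param x DNA string.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B", N = "N", "-" = "-")
  ch <- rev(seq_chars(toupper(x)))
  out <- comp[ch]
  if (anyNA(out)) stop("cannot complement residue '", ch[which(is.na(out))[1L]],
                       "'", call. = FALSE)
  paste(out, collapse = "")
}

#' Remove gap characters from a sequence
#' @param x Sequence string.
#' @return String without '-' characters.
#' @export
degap <- function(x) gsub("-", "", x, fixed = TRUE)
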