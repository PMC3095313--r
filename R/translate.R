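# Translation under the NCBI standard genetic code (table 1).

#' The standard genetic code as a named vector (codon -> amino acid)
#' @noRd
genetic_code <- function() Biostrings::GENETIC_CODE

#' All 61 sense (non-stop) codons
#' @noRd
sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

#' Split an ungapped CDS into codons
#' @noRd
split_codons <- function(x) {
  n <- nchar(x)
  if (n %% 3L != 0L) {
    stop("frame error: sequence length ", n, " is not a multiple of 3",
         call. = FALSE)
  }
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a coding sequence
#'
#' Gaps are removed before translation; the remaining length must be a
#' multiple of 3. Codons containing ambiguity codes translate to `'X'` with a
#' warning. A terminal stop renders `'*'`. An internal stop is an error
#' unless `permissive = TRUE`, in which case it renders `'X'` with a warning.
#'
#' @param seq Nucleotide string (may contain gaps).
#' @param permissive Tolerate internal stop codons as `'X'`.
#' @return Amino-acid string.
#' @examples
#' translate_cds("ATGTTTTAA")  # "MF*"
#' @export
translate_cds <- function(seq, permissive = FALSE) {
  gc <- genetic_code()
  codons <- split_codons(degap(toupper(seq)))
  n <- length(codons)
  aa <- character(n)
  ambiguous <- FALSE
  for (i in seq_len(n)) {
    cd <- codons[i]
    if (!grepl("^[ACGT]{3}$", cd)) {
      aa[i] <- "X"
      ambiguous <- TRUE
      next
    }
    r <- gc[[cd]]
    if (r == "*" && i < n) {
      if (!permissive) {
        stop("internal stop codon '", cd, "' at codon ", i, call. = FALSE)
      }
      warning("internal stop codon at codon ", i, " rendered as 'X'",
              call. = FALSE)
      r <- "X"
    }
    aa[i] <- r
  }
  if (ambiguous) {
    warning("ambiguous codon(s) translated as 'X'", call. = FALSE)
  }
  paste(aa, collapse = "")
}
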