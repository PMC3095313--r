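# Nei-Gojobori (1986) synonymous/nonsynonymous divergence with Jukes-Cantor
# correction, plus plain JC distance for non-coding sequence.
#
# Conventions (DnaSP-compatible): single-base changes that create a stop
# codon are excluded from the site denominators, and mutational pathways
# passing through a stop codon are excluded from pathway averaging; gapped,
# ambiguous or stop-containing codon columns are removed pairwise.

.ng_cache <- new.env(parent = emptyenv())

BASES <- c("A", "C", "G", "T")

#' Synonymous/nonsynonymous site fractions of one codon
#'
#' For each of the three positions, the synonymous contribution is the number
#' of synonymous single-base changes divided by the number of single-base
#' changes that do not create a stop codon; the nonsynonymous contribution is
#' its complement. The two contributions therefore sum to 1 at every position
#' that has at least one non-stop neighbor, so `s + n = 3` under the standard
#' code.
#'
#' @param codon In-frame triplet, no gaps/ambiguity, not a stop codon.
#' @return Named numeric vector `c(s = ..., n = ...)`.
#' @examples
#' codon_sites("TTT")  # s = 1/3
#' codon_sites("ATG")  # s = 0
#' @export
codon_sites <- function(codon) {
  codon <- toupper(codon)
  gc <- genetic_code()
  if (!grepl("^[ACGT]{3}$", codon)) {
    stop("codon '", codon, "' contains gap or ambiguity", call. = FALSE)
  }
  if (gc[[codon]] == "*") stop("stop codon '", codon, "'", call. = FALSE)
  aa <- gc[[codon]]
  s <- 0
  n <- 0
  ch <- seq_chars(codon)
  for (pos in 1:3) {
    syn <- 0L
    valid <- 0L
    for (b in BASES[BASES != ch[pos]]) {
      mut <- ch
      mut[pos] <- b
      maa <- gc[[paste(mut, collapse = "")]]
      if (maa == "*") next
      valid <- valid + 1L
      if (maa == aa) syn <- syn + 1L
    }
    if (valid > 0L) {
      s <- s + syn / valid
      n <- n + 1 - syn / valid
    }
  }
  c(s = s, n = n)
}

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' All minimal mutational pathways between the codons (permutations of the
#' differing positions) are enumerated, pathways passing through a stop codon
#' are discarded, and the synonymous/nonsynonymous step counts are averaged
#' over the remaining pathways with equal weight.
#'
#' @param a,b Non-stop, unambiguous codons.
#' @return Named numeric vector `c(sd = ..., nd = ...)`; `sd + nd` equals the
#'   Hamming distance of the pair.
#' @examples
#' codon_differences("TTT", "TTA")  # c(sd = 0, nd = 1)
#' codon_differences("TTG", "CTA") # c(sd = 2, nd = 0)
#' @export
codon_differences <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  gc <- genetic_code()
  for (cd in c(a, b)) {
    if (!grepl("^[ACGT]{3}$", cd)) {
      stop("codon '", cd, "' contains gap or ambiguity", call. = FALSE)
    }
    if (gc[[cd]] == "*") stop("stop codon '", cd, "'", call. = FALSE)
  }
  av <- seq_chars(a); bv <- seq_chars(b)
  diffpos <- which(av != bv)
  k <- length(diffpos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  orders <- perms(diffpos)
  sd_tot <- 0
  nd_tot <- 0
  valid <- 0L
  for (r in seq_len(nrow(orders))) {
    cur <- av
    sd <- 0L; nd <- 0L
    ok <- TRUE
    for (pos in orders[r, ]) {
      from_aa <- gc[[paste(cur, collapse = "")]]
      cur[pos] <- bv[pos]
      to_cd <- paste(cur, collapse = "")
      to_aa <- gc[[to_cd]]
      if (to_aa == "*") { ok <- FALSE; break }
      if (to_aa == from_aa) sd <- sd + 1L else nd <- nd + 1L
    }
    if (ok) {
      valid <- valid + 1L
      sd_tot <- sd_tot + sd
      nd_tot <- nd_tot + nd
    }
  }
  if (valid == 0L) {
    stop("no stop-free mutational pathway between '", a, "' and '", b, "'",
         call. = FALSE)
  }
  c(sd = sd_tot / valid, nd = nd_tot / valid)
}

#' All permutations of a vector (k <= 3 in practice)
#' @noRd
perms <- function(v) {
  k <- length(v)
  if (k == 1L) return(matrix(v, 1L))
  out <- NULL
  for (i in seq_len(k)) {
    sub <- perms(v[-i])
    out <- rbind(out, cbind(v[i], sub))
  }
  out
}

#' Lookup tables for sites and pairwise differences over the 61 sense codons
#' @noRd
ng86_tables <- function() {
  if (is.null(.ng_cache$sites)) {
    cods <- sense_codons()
    sites <- t(vapply(cods, codon_sites, c(s = 0, n = 0)))
    nc <- length(cods)
    sd <- matrix(0, nc, nc, dimnames = list(cods, cods))
    nd <- sd
    for (i in seq_len(nc)) {
      for (j in seq_len(nc)) {
        if (i < j) {
          d <- codon_differences(cods[i], cods[j])
          sd[i, j] <- sd[j, i] <- d[["sd"]]
          nd[i, j] <- nd[j, i] <- d[["nd"]]
        }
      }
    }
    .ng_cache$sites <- sites
    .ng_cache$sd <- sd
    .ng_cache$nd <- nd
  }
  list(sites = .ng_cache$sites, sd = .ng_cache$sd, nd = .ng_cache$nd)
}

#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) * log(1 - 4p/3)`, converting an observed difference proportion
#' into substitutions per site under equal-rate substitution.
#'
#' @param p Observed proportion of differing sites, `0 <= p < 3/4`.
#' @return Corrected distance `d >= p`.
#' @examples
#' jc_correction(0.1)  # 0.107326
#' @export
jc_correction <- function(p) {
  if (!is.finite(p) || p < 0) stop("p must be in [0, 3/4): got ", p, call. = FALSE)
  if (p >= 0.75) {
    stop("saturation: p = ", p, " >= 3/4, Jukes-Cantor distance undefined",
         call. = FALSE)
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori divergence between two members of a codon alignment
#'
#' Codon columns containing a gap, ambiguity code or stop codon in either
#' member are removed (pairwise deletion). Site counts `S`, `N` are the
#' averages of the two members' [codon_sites()] sums; difference counts `Sd`,
#' `Nd` are the sums of [codon_differences()] over retained columns. `ks` and
#' `ka` are the Jukes-Cantor corrections of `ps = Sd/S` and `pn = Nd/N`. A
#' saturated proportion (>= 3/4) yields `NA` in the corresponding `ks`/`ka`
#' with the component recorded in `undefined`.
#'
#' @param aln A [codon_alignment()].
#' @param pair Character vector of two member ids (defaults to the first two
#'   members).
#' @return Object of class `divergence_estimate`: list with `ids`,
#'   `codons_used`, `S`, `N`, `Sd`, `Nd`, `ps`, `pn`, `ks`, `ka`,
#'   `undefined` (character vector, possibly empty).
#' @export
ng86 <- function(aln, pair = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (is.null(pair)) pair <- names(aln$members)[1:2]
  if (!all(pair %in% names(aln$members))) {
    stop("pair ids not found in alignment", call. = FALSE)
  }
  gc <- genetic_code()
  tabs <- ng86_tables()
  ca <- split_codons(aln$members[[pair[1L]]])
  cb <- split_codons(aln$members[[pair[2L]]])
  usable <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  usable <- usable & ca %in% rownames(tabs$sites) & cb %in% rownames(tabs$sites)
  ca <- ca[usable]; cb <- cb[usable]
  codons_used <- length(ca)
  if (codons_used == 0L) stop("no usable codon columns after pairwise deletion",
                              call. = FALSE)
  Sa <- sum(tabs$sites[ca, "s"]); Na <- sum(tabs$sites[ca, "n"])
  Sb <- sum(tabs$sites[cb, "s"]); Nb <- sum(tabs$sites[cb, "n"])
  S <- (Sa + Sb) / 2
  N <- (Na + Nb) / 2
  idx <- cbind(match(ca, rownames(tabs$sd)), match(cb, colnames(tabs$sd)))
  Sd <- sum(tabs$sd[idx])
  Nd <- sum(tabs$nd[idx])
  ps <- Sd / S
  pn <- Nd / N
  undefined <- character(0)
  ks <- if (ps >= 0.75) { undefined <- c(undefined, "ks"); NA_real_ }
        else jc_correction(ps)
  ka <- if (pn >= 0.75) { undefined <- c(undefined, "ka"); NA_real_ }
        else jc_correction(pn)
  structure(list(ids = pair, codons_used = codons_used,
                 S = S, N = N, Sd = Sd, Nd = Nd,
                 ps = ps, pn = pn, ks = ks, ka = ka,
                 undefined = undefined),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("ng86 %s vs %s: %d codons, S=%.2f N=%.2f Sd=%.2f Nd=%.2f\n",
              x$ids[1L], x$ids[2L], x$codons_used, x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  ps=%.4f pn=%.4f Ks=%s Ka=%s%s\n", x$ps, x$pn,
              format(round(x$ks, 4)), format(round(x$ka, 4)),
              if (length(x$undefined)) paste0("  [undefined: ",
                paste(x$undefined, collapse = ","), "]") else ""))
  invisible(x)
}

#' Jukes-Cantor nucleotide distance between two aligned sequences
#'
#' Columns with a gap or ambiguity code in either member are removed
#' (pairwise deletion). Intended for non-coding regions such as introns,
#' where synonymy is undefined.
#'
#' @param a,b Aligned sequences of equal length.
#' @return List with `p` (observed proportion), `d` (JC-corrected distance)
#'   and `sites_used`.
#' @export
jc_nucleotide_distance <- function(a, b) {
  a <- toupper(as.character(a)[1L]); b <- toupper(as.character(b)[1L])
  if (nchar(a) != nchar(b)) stop("aligned lengths differ", call. = FALSE)
  av <- seq_chars(a); bv <- seq_chars(b)
  ok <- av %in% BASES & bv %in% BASES
  sites <- sum(ok)
  if (sites == 0L) stop("zero usable sites after pairwise deletion", call. = FALSE)
  p <- sum(av[ok] != bv[ok]) / sites
  list(p = p, d = jc_correction(p), sites_used = sites)
}

#' Write a TSV divergence report
#'
#' One row per estimate with columns id_a, id_b, codons_used, S, N, Sd, Nd,
#' ps, pn, ks, ka. Divergences are reported to 4 decimals.
#'
#' @param estimates List of `divergence_estimate` objects.
#' @param path Output path.
#' @return The report data frame, invisibly.
#' @export
write_divergence_report <- function(estimates, path) {
  rows <- lapply(estimates, function(e) {
    data.frame(id_a = e$ids[1L], id_b = e$ids[2L], codons_used = e$codons_used,
               S = round(e$S, 4), N = round(e$N, 4),
               Sd = round(e$Sd, 4), Nd = round(e$Nd, 4),
               ps = round(e$ps, 4), pn = round(e$pn, 4),
               ks = round(e$ks, 4), ka = round(e$ka, 4))
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
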