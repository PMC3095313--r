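# Protein statistics: average-isotopic molecular weight, theoretical
# isoelectric point (Bjellqvist pKa set, bisection on the
# Henderson-Hasselbalch net-charge curve) and alignment identity.

# Average residue masses (Da), ProtParam-compatible; one water (18.01524 Da)
# is added per chain.
RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

# Bjellqvist pKa values as used for theoretical pI computation. Side chains
# and termini; N-terminal pKa depends on the first residue.
PKA_SIDE_POS <- c(K = 10.0, R = 12.0, H = 5.98)
PKA_SIDE_NEG <- c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
PKA_CTERM <- 3.55
PKA_NTERM_DEFAULT <- 7.5
PKA_NTERM <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
               E = 7.7, G = 7.5)

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water (18.01524 Da).
#'
#' @param p Amino-acid string of standard residues (a single terminal `'*'`
#'   is tolerated and ignored).
#' @return Molecular weight in daltons.
#' @examples
#' protein_mw("G")  # 75.07
#' @export
protein_mw <- function(p) {
  p <- sub("\\*$", "", toupper(as.character(p)[1L]))
  if (nchar(p) == 0L) stop("empty protein sequence", call. = FALSE)
  ch <- seq_chars(p)
  bad <- setdiff(ch, names(RESIDUE_MASS))
  if (length(bad) > 0L) {
    stop("non-standard residue '", bad[1L], "' in protein", call. = FALSE)
  }
  sum(RESIDUE_MASS[ch]) + WATER_MASS
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum: positive terms from the N-terminus, K, R and H;
#' negative terms from the C-terminus, D, E, C and Y.
#'
#' @param p Amino-acid string (standard residues).
#' @param pH pH value.
#' @return Net charge (elementary charges).
#' @export
protein_charge <- function(p, pH) {
  p <- sub("\\*$", "", toupper(as.character(p)[1L]))
  ch <- seq_chars(p)
  bad <- setdiff(ch, names(RESIDUE_MASS))
  if (length(bad) > 0L) {
    stop("non-standard residue '", bad[1L], "' in protein", call. = FALSE)
  }
  nterm_pka <- if (ch[1L] %in% names(PKA_NTERM)) PKA_NTERM[[ch[1L]]] else
    PKA_NTERM_DEFAULT
  pos <- 1 / (1 + 10^(pH - nterm_pka))
  for (res in names(PKA_SIDE_POS)) {
    n <- sum(ch == res)
    if (n > 0L) pos <- pos + n / (1 + 10^(pH - PKA_SIDE_POS[[res]]))
  }
  neg <- 1 / (1 + 10^(PKA_CTERM - pH))
  for (res in names(PKA_SIDE_NEG)) {
    n <- sum(ch == res)
    if (n > 0L) neg <- neg + n / (1 + 10^(PKA_SIDE_NEG[[res]] - pH))
  }
  pos - neg
}

#' Theoretical isoelectric point
#'
#' Bisection root of the net-charge curve on (0, 14) to a tolerance of 0.001
#' pH units; reported to 2 decimals.
#'
#' @param p Amino-acid string (standard residues).
#' @param tol Bisection tolerance in pH units.
#' @return pI (pH units, rounded to 2 decimals).
#' @export
protein_pi <- function(p, tol = 0.001) {
  lo <- 0
  hi <- 14
  clo <- protein_charge(p, lo)
  chi <- protein_charge(p, hi)
  if (clo <= 0 || chi >= 0) {
    stop("net charge does not cross zero in (0, 14)", call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_charge(p, mid) > 0) lo <- mid else hi <- mid
  }
  round((lo + hi) / 2, 2)
}

#' Identity statistics between two aligned proteins
#'
#' Matches and substitutions are counted over aligned positions where neither
#' member has a gap; identity is reported both exactly and rounded to the
#' integer percentage.
#'
#' @param a,b Aligned amino-acid strings of equal length (may contain gaps).
#' @return List with `positions` (non-gap aligned positions), `matches`,
#'   `n_substitutions`, `identity_pct` (exact) and `identity_pct_rounded`.
#' @export
identity_stats <- function(a, b) {
  a <- toupper(as.character(a)[1L]); b <- toupper(as.character(b)[1L])
  if (nchar(a) != nchar(b)) stop("aligned lengths differ", call. = FALSE)
  av <- seq_chars(a); bv <- seq_chars(b)
  ok <- av != "-" & bv != "-"
  positions <- sum(ok)
  if (positions == 0L) stop("zero aligned non-gap positions", call. = FALSE)
  matches <- sum(av[ok] == bv[ok])
  pct <- 100 * matches / positions
  list(positions = positions, matches = matches,
       n_substitutions = positions - matches,
       identity_pct = pct, identity_pct_rounded = round_half_up(pct, 0))
}
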