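# Molecular-clock rescaling of synonymous divergence into ages.
#
# Under a clock, pairwise Ks is proportional to the age of the split
# (Ks = 2 * rate * time; the factor 2 cancels in the ratio, so anchors store
# pairwise ks-per-age, never per-lineage rates). Reported ages round
# half-away-from-zero to 0.1 My, and multi-locus averages are means of the
# rounded per-locus ages, matching the convention of published age tables.

#' Round half away from zero
#'
#' `round()` in R rounds half to even; published age tables round half away
#' from zero, so dating reports use this instead.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Construct a calibration anchor
#'
#' @param pair_label Label of the calibrated taxon pair.
#' @param locus Region name.
#' @param ks Divergence of that pair at that locus (> 0).
#' @param age_my Known age of the split in My (> 0).
#' @return Object of class `calibration_anchor`.
#' @examples
#' calibration_anchor("Medicago-Pisum", "GS2", 0.2475, 14.9)
#' @export
calibration_anchor <- function(pair_label, locus, ks, age_my) {
  if (!is.finite(ks) || ks <= 0) stop("anchor ks must be > 0", call. = FALSE)
  if (!is.finite(age_my) || age_my <= 0) stop("anchor age must be > 0", call. = FALSE)
  structure(list(pair_label = pair_label, locus = locus,
                 ks = ks, age_my = age_my),
            class = "calibration_anchor")
}

#' Estimate the age of a split from its divergence and a calibration anchor
#'
#' `age = ks / anchor$ks * anchor$age_my`. `age_my` is exact;
#' `age_rounded` is rounded half-away-from-zero to `digits` decimals.
#'
#' @param ks Observed divergence (>= 0).
#' @param anchor A [calibration_anchor()].
#' @param pair_label,locus Optional labels for the dated pair.
#' @param digits Reporting precision (decimal places of My); default 1.
#' @return Object of class `age_estimate`: list with `pair_label`, `locus`,
#'   `ks`, `age_my`, `age_rounded`, `anchor`.
#' @examples
#' a <- calibration_anchor("Medicago-Pisum", "GS2", 0.2475, 14.9)
#' estimate_age(0.1668, a, digits = 0)$age_rounded  # 10
#' @export
estimate_age <- function(ks, anchor, pair_label = NA_character_,
                         locus = anchor$locus, digits = 1) {
  stopifnot(inherits(anchor, "calibration_anchor"))
  if (!is.finite(ks) || ks < 0) stop("ks must be >= 0", call. = FALSE)
  age <- ks / anchor$ks * anchor$age_my
  structure(list(pair_label = pair_label, locus = locus, ks = ks,
                 age_my = age, age_rounded = round_half_up(age, digits),
                 anchor = anchor),
            class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf("%s (%s): Ks=%s -> %s My (rounded %s)\n  anchor %s: Ks=%s at %s My\n",
              x$pair_label, x$locus, format(round(x$ks, 4)),
              format(round(x$age_my, 4)), format(x$age_rounded),
              x$anchor$pair_label, format(x$anchor$ks),
              format(x$anchor$age_my)))
  invisible(x)
}

#' Derive a secondary anchor for a pair observed at the same locus
#'
#' Rescales the primary anchor to a new pair whose divergence at the primary
#' anchor's locus is known, enabling chained dating when the primary pair is
#' not available at another locus. Dating via the secondary anchor equals
#' dating directly with the primary anchor (exactly, before rounding).
#'
#' @param primary A [calibration_anchor()].
#' @param observed_ks Divergence of the new pair at the primary locus.
#' @param new_pair_label Label of the new pair.
#' @param rounded Use the rounded age for the secondary anchor (published
#'   tables do); default FALSE keeps chaining exact.
#' @return A [calibration_anchor()] for the new pair.
#' @export
rescale_anchor <- function(primary, observed_ks, new_pair_label,
                           rounded = FALSE) {
  est <- estimate_age(observed_ks, primary, pair_label = new_pair_label)
  calibration_anchor(new_pair_label, primary$locus, observed_ks,
                     if (rounded) est$age_rounded else est$age_my)
}

#' Average per-locus age estimates for one taxon pair
#'
#' The arithmetic mean of the per-locus *rounded* ages, itself rounded to 0.1
#' My — the convention under which published multi-locus age tables
#' reproduce.
#'
#' @param estimates List of `age_estimate` objects for the same pair.
#' @return List with `pair_label`, `per_locus` (named rounded ages) and
#'   `mean_my`.
#' @export
average_ages <- function(estimates) {
  if (length(estimates) == 0L) stop("no estimates to average", call. = FALSE)
  labs <- unique(vapply(estimates, function(e) e$pair_label, ""))
  if (length(labs) != 1L) {
    stop("estimates mix pair labels: ", paste(labs, collapse = ", "),
         call. = FALSE)
  }
  per <- vapply(estimates, function(e) e$age_rounded, 0)
  names(per) <- vapply(estimates, function(e) as.character(e$locus), "")
  list(pair_label = labs, per_locus = per,
       mean_my = round_half_up(mean(per), 1))
}

#' Date a gene duplication from a paralog codon alignment
#'
#' Composes [ng86()] (paralog Ks) with [estimate_age()] against an anchor of
#' the same locus class (coding Ks against coding Ks).
#'
#' @param paralog_aln A [codon_alignment()] of the two paralogs.
#' @param anchor A [calibration_anchor()].
#' @param digits Reporting precision; default 1.
#' @return An `age_estimate`; the `ks` field records the paralog Ks used.
#' @export
date_duplication <- function(paralog_aln, anchor, digits = 1) {
  est <- ng86(paralog_aln)
  if (is.na(est$ks)) {
    stop("paralog Ks saturated; duplication age undefined", call. = FALSE)
  }
  estimate_age(est$ks, anchor,
               pair_label = paste(est$ids, collapse = "-"),
               digits = digits)
}

#' Read a calibration-anchor table
#'
#' TSV with columns `pair`, `locus`, `ks`, `age_my`.
#'
#' @param path TSV path.
#' @return List of [calibration_anchor()] objects named by locus.
#' @export
read_anchor_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("pair", "locus", "ks", "age_my")
  if (!all(need %in% names(df))) {
    stop("anchor table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  anchors <- lapply(seq_len(nrow(df)), function(i) {
    calibration_anchor(df$pair[i], df$locus[i], df$ks[i], df$age_my[i])
  })
  names(anchors) <- df$locus
  anchors
}

#' Write a calibration-anchor table
#' @param anchors List of [calibration_anchor()] objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_anchor_table <- function(anchors, path) {
  df <- do.call(rbind, lapply(anchors, function(a) {
    data.frame(pair = a$pair_label, locus = a$locus, ks = a$ks,
               age_my = a$age_my)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
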