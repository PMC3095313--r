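# Distance-based phylogeny: neighbor-joining with codon-aware bootstrap,
# monophyly checks, and the Bayes-factor topology decision rule.
#
# Neighbor-joining stands in for MCMC tree inference as a deterministic
# surrogate; marginal likelihoods for the decision rule are user-supplied
# inputs.

#' Construct and validate a distance matrix
#'
#' @param values Square numeric matrix with dimnames (taxa).
#' @return The matrix, validated: symmetric within 1e-12, zero diagonal,
#'   non-negative, labelled.
#' @export
distance_matrix <- function(values) {
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  labs <- rownames(values)
  if (is.null(labs) || is.null(colnames(values)) ||
      !identical(labs, colnames(values)) || anyDuplicated(labs)) {
    stop("distance matrix needs matching unique row/column labels",
         call. = FALSE)
  }
  if (any(values < 0)) stop("negative distances", call. = FALSE)
  if (any(abs(diag(values)) > 1e-12)) stop("non-zero diagonal", call. = FALSE)
  if (any(abs(values - t(values)) > 1e-12)) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  values
}

#' Neighbor-joining tree
#'
#' Saitou–Nei neighbor-joining (via ape). Labels are sorted internally so the
#' result does not depend on input order; negative branch-length estimates
#' are clamped to zero with the count recorded in the `clamped` attribute.
#' Additive matrices are recovered exactly (topology and branch lengths).
#'
#' @param d A validated square distance matrix (see [distance_matrix()]).
#' @return An `ape::phylo` tree (unrooted) with attribute `clamped`.
#' @export
nj_tree <- function(d) {
  d <- distance_matrix(d)
  if (nrow(d) < 3L) stop("need >= 3 taxa", call. = FALSE)
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  tr <- ape::nj(stats::as.dist(d))
  neg <- tr$edge.length < 0
  tr$edge.length[neg] <- 0
  attr(tr, "clamped") <- sum(neg)
  tr
}

#' Canonical bipartition keys of a tree's internal edges
#'
#' Each non-trivial bipartition is keyed by the sorted label set of the side
#' not containing the alphabetically first leaf, pasted with '|'.
#' @noRd
bipartition_keys <- function(tree) {
  labs <- tree$tip.label
  anchor <- sort(labs)[1L]
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    side <- labs[p]
    if (length(side) <= 1L || length(side) >= length(labs) - 1L) next
    if (anchor %in% side) side <- setdiff(labs, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Columns are resampled with replacement (codon columns for a
#' [codon_alignment()], nucleotide columns otherwise), the chosen pairwise
#' distance is recomputed, and a replicate NJ tree is built. Support on each
#' internal edge of the full-data tree is the percentage of valid replicate
#' trees containing the same bipartition, stored in `$node.label` (empty for
#' the arbitrary root node). Replicates on which any pairwise distance
#' saturates are skipped, counted in the `skipped` attribute, and reported
#' with a warning.
#'
#' @param aln A [codon_alignment()] (>= 3 members) or a named character
#'   vector of equal-length aligned nucleotide sequences.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; fully determines the resampling.
#' @param distance `"ks"` or `"ka"` (NG86 on codon input) or `"jc"`
#'   (Jukes-Cantor nucleotide distance).
#' @return The full-data NJ tree with `$node.label` supports and attributes
#'   `n_reps`, `skipped`.
#' @export
bootstrap_support <- function(aln, n_reps, seed,
                              distance = c("ks", "jc", "ka")) {
  distance <- match.arg(distance)
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  coding <- inherits(aln, "codon_alignment")
  members <- if (coding) aln$members else aln
  if (length(members) < 3L) stop("need >= 3 members", call. = FALSE)
  members <- members[order(names(members))]  # order-invariance
  if (distance %in% c("ks", "ka") && !coding) {
    stop("distance '", distance, "' needs a codon alignment", call. = FALSE)
  }
  cols <- lapply(members, function(s) {
    if (coding) split_codons(s) else seq_chars(s)
  })
  ncol_ <- length(cols[[1L]])
  labs <- names(members)
  pair_dist <- function(colsets) {
    m <- length(labs)
    d <- matrix(0, m, m, dimnames = list(labs, labs))
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        val <- if (distance == "jc") {
          jc_nucleotide_distance(paste(colsets[[i]], collapse = ""),
                                 paste(colsets[[j]], collapse = ""))$d
        } else {
          pairaln <- codon_alignment(setNames(
            c(paste(colsets[[i]], collapse = ""),
              paste(colsets[[j]], collapse = "")), labs[c(i, j)]))
          est <- ng86(pairaln)
          if (distance == "ks") est$ks else est$ka
        }
        if (is.na(val)) stop("saturated", call. = FALSE)
        d[i, j] <- d[j, i] <- val
      }
    }
    d
  }
  ref_tree <- nj_tree(pair_dist(cols))
  ref_keys <- bipartition_keys(ref_tree)
  counts <- setNames(numeric(length(ref_keys)), ref_keys)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  skipped <- 0L
  valid <- 0L
  for (r in seq_len(n_reps)) {
    idx <- sample.int(ncol_, ncol_, replace = TRUE)
    res <- tryCatch({
      rcols <- lapply(cols, function(cc) cc[idx])
      nj_tree(pair_dist(rcols))
    }, error = function(e) {
      if (grepl("saturat", conditionMessage(e))) NULL else stop(e)
    })
    if (is.null(res)) {
      skipped <- skipped + 1L
      next
    }
    valid <- valid + 1L
    hit <- intersect(bipartition_keys(res), ref_keys)
    counts[hit] <- counts[hit] + 1
  }
  if (skipped > 0L) {
    warning(skipped, " bootstrap replicate(s) skipped due to saturation",
            call. = FALSE)
  }
  support <- if (valid > 0L) 100 * counts / valid else counts * NA
  # map supports onto internal nodes of the reference tree
  labs_ref <- ref_tree$tip.label
  anchor <- sort(labs_ref)[1L]
  parts <- ape::prop.part(ref_tree)
  node_lab <- character(ref_tree$Nnode)
  for (k in seq_along(parts)) {
    side <- labs_ref[parts[[k]]]
    if (length(side) <= 1L || length(side) >= length(labs_ref) - 1L) {
      node_lab[k] <- ""
      next
    }
    if (anchor %in% side) side <- setdiff(labs_ref, side)
    key <- paste(sort(side), collapse = "|")
    node_lab[k] <- if (key %in% names(support)) {
      as.character(round(support[[key]]))
    } else ""
  }
  ref_tree$node.label <- node_lab
  attr(ref_tree, "n_reps") <- n_reps
  attr(ref_tree, "skipped") <- skipped
  attr(ref_tree, "support") <- support
  ref_tree
}

#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

#' @noRd
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Is a label set monophyletic when the tree is rooted at an outgroup?
#'
#' TRUE iff some edge of the tree rooted at `outgroup` separates exactly
#' `labels` from the remaining taxa.
#'
#' @param tree An `ape::phylo` tree.
#' @param labels Taxon subset (not containing the outgroup).
#' @param outgroup Single taxon used to root the tree.
#' @return Logical flag.
#' @export
clade_monophyletic <- function(tree, labels, outgroup) {
  tips <- tree$tip.label
  unknown <- setdiff(c(labels, outgroup), tips)
  if (length(unknown) > 0L) {
    stop("unknown label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (outgroup %in% labels) stop("outgroup cannot be in labels", call. = FALSE)
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ape::is.monophyletic(rooted, labels)
}

#' Bayes-factor topology decision rule
#'
#' A constrained topology is deemed significantly worse than the
#' unconstrained one only if twice the difference of (log) marginal
#' likelihoods exceeds 10 (strict inequality).
#'
#' @param lnL_unconstrained,lnL_constrained Log marginal likelihoods.
#' @return List with `diff`, `twice_diff`, `significantly_worse`.
#' @examples
#' bayes_factor_decision(0, -4.85)  # twice_diff 9.7, not significantly worse
#' @export
bayes_factor_decision <- function(lnL_unconstrained, lnL_constrained) {
  if (!is.finite(lnL_unconstrained) || !is.finite(lnL_constrained)) {
    stop("log marginal likelihoods must be finite", call. = FALSE)
  }
  diff <- lnL_unconstrained - lnL_constrained
  list(diff = diff, twice_diff = 2 * diff,
       significantly_worse = (2 * diff) > 10)
}

#' Write a tree in Newick format
#' @param tree An `ape::phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Newick file.
#' @return An `ape::phylo`.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write a distance matrix as square TSV with header row and column
#' @param d Square labelled matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(d, path) {
  df <- data.frame(taxon = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square TSV distance matrix written by [write_distance_tsv()]
#' @param path TSV path.
#' @return Labelled square matrix.
#' @export
read_distance_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1L]]
  distance_matrix(m)
}
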