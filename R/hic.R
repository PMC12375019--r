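#' Hi-C contact matrix
#'
#' Symmetric binned contact-count matrix with bin size, chromosome label
#' and a masked-bin set (masked bins are excluded from coverage totals and
#' downstream comparison).
#'
#' @param counts square numeric matrix of non-negative counts; must be
#'   symmetric.
#' @param bin_bp bin size in base pairs.
#' @param chrom chromosome label (default `"chr"`).
#' @param masked integer vector of masked bin indices.
#' @return Object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, bin_bp, chrom = "chr", masked = integer()) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("`counts` must be square")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!isSymmetric(unname(counts), tol = 1e-8))
    stop("`counts` must be symmetric")
  structure(list(counts = counts, bin_bp = bin_bp, chrom = chrom,
                 masked = sort(unique(as.integer(masked)))),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d bins of %s bp on %s; %d masked; total %.0f\n",
              nrow(x$counts), format(x$bin_bp, big.mark = ","), x$chrom,
              length(x$masked), hic_total(x)))
  invisible(x)
}

unmasked_bins <- function(m) setdiff(seq_len(nrow(m$counts)), m$masked)

hic_total <- function(m) {
  keep <- unmasked_bins(m)
  sum(m$counts[keep, keep])
}

#' Mask bins by coverage z-score
#'
#' Computes `log(1 + row sum)` coverage over currently unmasked bins,
#' z-scores it, and masks bins below `z_low` or above `z_high`. Z-scores
#' are computed once (single pass), so the operation is idempotent on its
#' own output convention.
#'
#' @param m a [contact_matrix()].
#' @param z_low,z_high z-score thresholds (defaults -1.5 and 5).
#' @return The matrix with an updated masked-bin set.
#' @export
mask_bins_by_coverage <- function(m, z_low = -1.5, z_high = 5) {
  keep <- unmasked_bins(m)
  if (length(keep) < 2) stop("need >= 2 unmasked bins")
  cov <- log1p(rowSums(m$counts[keep, keep, drop = FALSE]))
  sdv <- stats::sd(cov)
  z <- if (sdv == 0) rep(0, length(cov)) else (cov - mean(cov)) / sdv
  bad <- keep[z < z_low | z > z_high]
  m$masked <- sort(union(m$masked, bad))
  if (length(m$masked) >= nrow(m$counts)) stop("all bins masked")
  m
}

#' Iterative correction (ICE) balancing
#'
#' Iteratively divides rows and columns of the unmasked submatrix by their
#' marginal sums normalized to mean one, until the maximum relative
#' marginal deviation falls below `tol`. After convergence all unmasked
#' rows have equal visibility.
#'
#' @param m a [contact_matrix()]; mask zero-coverage bins first.
#' @param tol convergence tolerance on `max |marginal/mean - 1|`
#'   (default 1e-5).
#' @param max_iter iteration cap (default 200); non-convergence returns the
#'   partial result with a warning and `converged = FALSE` attribute.
#' @return The balanced matrix (attribute `converged`).
#' @export
ice_balance <- function(m, tol = 1e-5, max_iter = 200) {
  keep <- unmasked_bins(m)
  A <- m$counts[keep, keep, drop = FALSE]
  if (any(rowSums(A) == 0))
    stop("unmasked zero-coverage bin: run mask_bins_by_coverage() first")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- rowSums(A)
    b <- s / mean(s)
    A <- A / (b %o% b)
    if (max(abs(b - 1)) < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("ICE balancing did not converge; partial result")
  m$counts[keep, keep] <- A
  attr(m, "converged") <- converged
  m
}

#' Normalize two contact matrices to common coverage
#'
#' Scales the higher-coverage matrix by the ratio of unmasked totals so
#' both matrices carry the same total signal.
#'
#' @param a,b [contact_matrix()] objects on the same bin grid.
#' @return List with elements `a` and `b`.
#' @export
normalize_to_common_coverage <- function(a, b) {
  check_same_grid(a, b)
  ta <- hic_total(a); tb <- hic_total(b)
  if (ta == 0 || tb == 0) stop("zero total coverage")
  if (ta > tb) a$counts <- a$counts * (tb / ta)
  else if (tb > ta) b$counts <- b$counts * (ta / tb)
  list(a = a, b = b)
}

check_same_grid <- function(a, b) {
  if (nrow(a$counts) != nrow(b$counts) || a$bin_bp != b$bin_bp)
    stop("contact matrices are on different bin grids")
  invisible(TRUE)
}

#' Merge contact-matrix bins
#'
#' Sums counts over `factor x factor` blocks (the trailing partial block is
#' kept) and multiplies the bin size accordingly. A merged bin is masked
#' only when all of its constituent bins were masked.
#'
#' @param m a [contact_matrix()].
#' @param factor number of bins merged into one (default 100, e.g. 10 kb
#'   to 1 Mb).
#' @return The merged [contact_matrix()].
#' @export
merge_bins <- function(m, factor = 100) {
  if (factor < 1) stop("`factor` must be >= 1")
  if (factor == 1) return(m)
  n <- nrow(m$counts)
  grp <- ((seq_len(n) - 1L) %/% factor) + 1L
  G <- rowsum(m$counts, grp)
  G <- t(rowsum(t(G), grp))
  masked_old <- seq_len(n) %in% m$masked
  grp_f <- factor(grp, levels = sort(unique(grp)))
  merged_masked <- which(as.logical(tapply(masked_old, grp_f, all)))
  contact_matrix(G, m$bin_bp * factor, m$chrom, merged_masked)
}

#' Entrywise log2 ratio of two contact matrices
#'
#' `log2((a + pseudocount) / (b + pseudocount))`; entries where either side
#' is zero (at pseudocount 0) or where either bin is masked are missing.
#'
#' @param a,b [contact_matrix()] objects processed identically upstream.
#' @param pseudocount added to both sides before the ratio (default 0).
#' @return Signed numeric matrix with NAs at undefined entries.
#' @export
log2_ratio <- function(a, b, pseudocount = 0) {
  check_same_grid(a, b)
  num <- a$counts + pseudocount
  den <- b$counts + pseudocount
  out <- log2(num / den)
  out[num == 0 | den == 0] <- NA_real_
  bad <- union(a$masked, b$masked)
  if (length(bad)) { out[bad, ] <- NA_real_; out[, bad] <- NA_real_ }
  out
}

#' Full Hi-C comparison pipeline
#'
#' Runs mask -> ICE balance -> common-coverage normalization -> bin merge
#' -> log2 ratio on a pair of contact matrices and reports outlier cells.
#'
#' @param a,b raw [contact_matrix()] objects on the same grid.
#' @param z_low,z_high coverage-mask thresholds (defaults -1.5, 5).
#' @param merge_factor bin-merge factor (default 100).
#' @param ratio_threshold absolute log2 ratio for the outlier-cell report
#'   (default 1).
#' @return List with `ratio` (merged log2-ratio matrix), `merged_bin_bp`,
#'   and `outliers` (data frame `bin_i`, `bin_j`, `log2_ratio` over the
#'   upper triangle with `|ratio| > ratio_threshold`).
#' @export
hic_compare_pipeline <- function(a, b, z_low = -1.5, z_high = 5,
                                 merge_factor = 100, ratio_threshold = 1) {
  a <- mask_bins_by_coverage(a, z_low, z_high)
  b <- mask_bins_by_coverage(b, z_low, z_high)
  a <- ice_balance(a)
  b <- ice_balance(b)
  nn <- normalize_to_common_coverage(a, b)
  am <- merge_bins(nn$a, merge_factor)
  bm <- merge_bins(nn$b, merge_factor)
  ratio <- log2_ratio(am, bm)
  ut <- which(upper.tri(ratio, diag = TRUE), arr.ind = TRUE)
  vals <- ratio[ut]
  sel <- !is.na(vals) & abs(vals) > ratio_threshold
  list(ratio = ratio, merged_bin_bp = am$bin_bp,
       outliers = data.frame(bin_i = ut[sel, 1], bin_j = ut[sel, 2],
                             log2_ratio = vals[sel]))
}
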