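#' Ancestry-informative-marker genotype matrix
#'
#' Container for ancestry states of admixed individuals at ancestry
#' informative markers (AIMs). States follow the polarity convention
#' 0 = homozygous coastal ancestry, 1 = interspecific heterozygote,
#' 2 = homozygous inland ancestry; missing calls are `NA`. Loci are kept
#' sorted by (chromosome, position).
#'
#' @param states integer matrix, individuals in rows and loci in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param loci data frame with columns `chrom` (character) and `pos`
#'   (1-based integer position); one row per column of `states`.
#' @param individual_ids character vector of unique individual identifiers,
#'   one per row of `states`. Defaults to rownames or `ind<k>`.
#' @param z_chrom chromosome label treated as the Z (sex) chromosome.
#'
#' @return An object of class `aim_matrix`: a list with elements `states`
#'   (matrix with dimnames), `loci` (data frame with `chrom`, `pos`, `is_z`)
#'   and `individual_ids`.
#' @export
aim_matrix <- function(states, loci, individual_ids = NULL, z_chrom = "chrZ") {
  states <- as.matrix(states)
  if (!is.numeric(states)) stop("`states` must be a numeric matrix")
  bad <- !is.na(states) & !(states %in% c(0, 1, 2))
  if (any(bad)) stop("`states` entries must be 0, 1, 2 or NA")
  if (!is.data.frame(loci) || !all(c("chrom", "pos") %in% names(loci)))
    stop("`loci` must be a data frame with columns `chrom` and `pos`")
  if (nrow(loci) != ncol(states))
    stop("nrow(loci) must equal ncol(states)")
  if (any(loci$pos < 1)) stop("locus positions must be >= 1")
  if (is.null(individual_ids)) {
    individual_ids <- rownames(states)
    if (is.null(individual_ids))
      individual_ids <- paste0("ind", seq_len(nrow(states)))
  }
  if (anyDuplicated(individual_ids))
    stop("`individual_ids` must be unique")
  loci <- data.frame(chrom = as.character(loci$chrom),
                     pos = as.integer(loci$pos),
                     stringsAsFactors = FALSE)
  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  states <- states[, ord, drop = FALSE]
  if (anyDuplicated(loci[, c("chrom", "pos")]))
    stop("positions must be unique within a chromosome")
  loci$is_z <- loci$chrom == z_chrom
  rownames(loci) <- NULL
  dimnames(states) <- list(individual_ids,
                           paste0(loci$chrom, ":", loci$pos))
  structure(list(states = states, loci = loci,
                 individual_ids = individual_ids, z_chrom = z_chrom),
            class = "aim_matrix")
}

#' @export
print.aim_matrix <- function(x, ...) {
  cat(sprintf("aim_matrix: %d individuals x %d loci on %d chromosome(s)\n",
              nrow(x$states), ncol(x$states), length(unique(x$loci$chrom))))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * mean(is.na(x$states))))
  invisible(x)
}

#' @export
dim.aim_matrix <- function(x) dim(x$states)

#' Hard-call ancestry states from posterior probabilities
#'
#' Converts per-locus, per-individual ancestry posteriors (p0, p1, p2) to
#' hard genotype states. A state is called when its posterior strictly
#' exceeds `threshold`; otherwise the call is set to missing.
#'
#' @param posteriors numeric array of dimension `n_loci x n_individuals x 3`
#'   giving posterior probabilities of states 0, 1, 2.
#' @param loci data frame of locus metadata (see [aim_matrix()]).
#' @param individual_ids character vector of individual identifiers.
#' @param threshold posterior probability a state must strictly exceed to be
#'   hard-called (default 0.9).
#' @param z_chrom Z chromosome label.
#' @return An [aim_matrix()].
#' @export
harden_posteriors <- function(posteriors, loci, individual_ids,
                              threshold = 0.9, z_chrom = "chrZ") {
  d <- dim(posteriors)
  if (length(d) != 3L || d[3] != 3L)
    stop("`posteriors` must be an n_loci x n_individuals x 3 array")
  if (any(posteriors < 0, na.rm = TRUE)) {
    idx <- which(apply(posteriors < 0, c(1, 2), any), arr.ind = TRUE)[1, ]
    stop(sprintf("negative posterior at locus %d, individual %s",
                 idx[1], individual_ids[idx[2]]))
  }
  sums <- posteriors[, , 1] + posteriors[, , 2] + posteriors[, , 3]
  off <- abs(sums - 1) > 1e-6
  if (any(off, na.rm = TRUE)) {
    idx <- which(off, arr.ind = TRUE)
    if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
    stop(sprintf("posterior triple does not sum to 1 at locus %d, individual %s",
                 idx[1, 1], individual_ids[idx[1, 2]]))
  }
  m <- cbind(as.vector(posteriors[, , 1]), as.vector(posteriors[, , 2]),
             as.vector(posteriors[, , 3]))
  arg <- max.col(m, ties.method = "first") - 1L
  pmax3 <- m[cbind(seq_len(nrow(m)), arg + 1L)]
  states <- ifelse(pmax3 > threshold, arg, NA_integer_)
  states <- t(matrix(states, nrow = d[1], ncol = d[2]))
  aim_matrix(states, loci, individual_ids, z_chrom = z_chrom)
}

#' Select ancestry informative markers from parental panel allele counts
#'
#' Retains candidate loci whose allele-frequency difference between the two
#' parental panels strictly exceeds `min_diff`.
#'
#' @param panel data frame with columns `chrom`, `pos`, `coastal_ref`,
#'   `coastal_alt`, `inland_ref`, `inland_alt` (non-negative allele counts).
#' @param min_diff minimum absolute allele-frequency difference (strict;
#'   default 0.5).
#' @return The panel data frame augmented with `freq_coastal`, `freq_inland`,
#'   `freq_diff` and a logical `retained` column. Loci with zero observed
#'   alleles in either panel are dropped from consideration with a warning
#'   (`retained = NA`).
#' @export
select_aims <- function(panel, min_diff = 0.5) {
  need <- c("chrom", "pos", "coastal_ref", "coastal_alt",
            "inland_ref", "inland_alt")
  if (!all(need %in% names(panel)))
    stop("`panel` must have columns ", paste(need, collapse = ", "))
  cnt <- as.matrix(panel[, need[-(1:2)]])
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("allele counts must be non-negative integers")
  tot_c <- panel$coastal_ref + panel$coastal_alt
  tot_i <- panel$inland_ref + panel$inland_alt
  panel$freq_coastal <- ifelse(tot_c > 0, panel$coastal_alt / tot_c, NA_real_)
  panel$freq_inland <- ifelse(tot_i > 0, panel$inland_alt / tot_i, NA_real_)
  panel$freq_diff <- abs(panel$freq_coastal - panel$freq_inland)
  panel$retained <- panel$freq_diff > min_diff
  zero <- tot_c == 0 | tot_i == 0
  if (any(zero)) {
    warning(sprintf("%d locus/loci dropped: zero observed alleles in a panel",
                    sum(zero)))
    panel$retained[zero] <- NA
  }
  panel
}
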