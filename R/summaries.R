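#' Genome-wide ancestry (hybrid index)
#'
#' Mean ancestry state across non-missing loci, divided by two so that a
#' parental coastal individual scores 0, an F1 hybrid 0.5 and a parental
#' inland individual 1.
#'
#' @param x an [aim_matrix()].
#' @param individuals individual ids or indices; default all.
#' @return Named numeric vector of ancestry fractions in `[0, 1]`; `NA`
#'   (with a warning) for individuals missing at every locus.
#' @export
genome_wide_ancestry <- function(x, individuals = NULL) {
  s <- subset_individuals(x, individuals)
  q <- rowMeans(s, na.rm = TRUE) / 2
  allmiss <- rowSums(!is.na(s)) == 0
  if (any(allmiss)) {
    warning(sprintf("%d individual(s) missing at all loci; ancestry set to NA",
                    sum(allmiss)))
    q[allmiss] <- NA_real_
  }
  q
}

#' Individual interspecific heterozygosity
#'
#' Proportion of non-missing loci at which the individual is heterozygous
#' for coastal and inland ancestry (state 1).
#'
#' @inheritParams genome_wide_ancestry
#' @return Named numeric vector in `[0, 1]`; `NA` for all-missing individuals.
#' @export
individual_heterozygosity <- function(x, individuals = NULL) {
  s <- subset_individuals(x, individuals)
  h <- rowMeans(s == 1, na.rm = TRUE)
  allmiss <- rowSums(!is.na(s)) == 0
  if (any(allmiss)) {
    warning(sprintf("%d individual(s) missing at all loci; heterozygosity set to NA",
                    sum(allmiss)))
    h[allmiss] <- NA_real_
  }
  h
}

subset_individuals <- function(x, individuals) {
  stopifnot(inherits(x, "aim_matrix"))
  if (is.null(individuals)) return(x$states)
  if (is.character(individuals)) {
    idx <- match(individuals, x$individual_ids)
    if (anyNA(idx)) stop("unknown individual id(s)")
    x$states[idx, , drop = FALSE]
  } else {
    x$states[individuals, , drop = FALSE]
  }
}

#' Interspecific heterozygosity indicator at one locus
#'
#' Collapses ancestry states at a locus into the binary response used by the
#' viability scan: 1 for heterozygotes, 0 for either homozygote, with
#' missingness propagated.
#'
#' @param x an [aim_matrix()].
#' @param locus locus column index or `"chrom:pos"` name.
#' @return Integer vector (one entry per individual) in `{0, 1, NA}`.
#' @export
interspecific_het_vector <- function(x, locus) {
  stopifnot(inherits(x, "aim_matrix"))
  if (is.character(locus)) {
    locus <- match(locus, colnames(x$states))
    if (is.na(locus)) stop("unknown locus")
  }
  if (locus < 1 || locus > ncol(x$states)) stop("locus index out of range")
  as.integer(x$states[, locus] == 1)
}

#' Squared genotype-dosage correlation between two loci
#'
#' r-squared of the 0/1/2 state vectors over pairwise-complete individuals
#' (the `vcftools --geno-r2` statistic on ancestry dosages).
#'
#' @param x an [aim_matrix()].
#' @param locus_a,locus_b locus indices or `"chrom:pos"` names.
#' @return r-squared in `[0, 1]`, or `NA` if fewer than two complete pairs or
#'   either locus is monomorphic in the complete subset.
#' @export
dosage_r2 <- function(x, locus_a, locus_b) {
  stopifnot(inherits(x, "aim_matrix"))
  resolve <- function(l) {
    if (is.character(l)) l <- match(l, colnames(x$states))
    if (is.na(l) || l < 1 || l > ncol(x$states)) stop("unknown locus")
    l
  }
  a <- x$states[, resolve(locus_a)]
  b <- x$states[, resolve(locus_b)]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

state_freq <- function(states) {
  # inland allele frequency per locus (columns)
  colMeans(states, na.rm = TRUE) / 2
}

#' Sliding-window LD pruning of AIMs
#'
#' Mirrors `plink --indep-pairwise <window> <step> <r2>` with a minor-state
#' frequency pre-filter. Within each window (of currently retained loci,
#' per chromosome), while any pair exceeds `r2_max` in dosage r-squared, the
#' member of the worst pair with the lower minor-state frequency is removed
#' (ties: the locus later in position).
#'
#' @param x an [aim_matrix()].
#' @param window_snps window size in SNPs (default 200).
#' @param step_snps step size in SNPs (default 20).
#' @param r2_max maximum tolerated pairwise r-squared (default 0.2).
#' @param maf_min minimum minor-state frequency; loci strictly below are
#'   removed before the pairwise step (default 0.05).
#' @return Integer vector of retained locus column indices (sorted).
#' @export
ld_prune <- function(x, window_snps = 200, step_snps = 20,
                     r2_max = 0.2, maf_min = 0.05) {
  stopifnot(inherits(x, "aim_matrix"))
  if (window_snps < 2) stop("`window_snps` must be >= 2")
  if (step_snps < 1) stop("`step_snps` must be >= 1")
  if (r2_max <= 0 || r2_max >= 1) stop("`r2_max` must be in (0, 1)")
  f <- state_freq(x$states)
  maf <- pmin(f, 1 - f)
  keep <- which(!is.na(maf) & maf >= maf_min)
  retained <- rep(TRUE, ncol(x$states))
  retained[setdiff(seq_len(ncol(x$states)), keep)] <- FALSE
  for (chr in unique(x$loci$chrom)) {
    idx <- which(x$loci$chrom == chr & retained)
    if (length(idx) < 2) next
    start <- 1L
    repeat {
      cur <- idx[retained[idx]]
      if (start > length(cur)) break
      win <- cur[seq(start, min(start + window_snps - 1L, length(cur)))]
      if (length(win) >= 2) {
        sub <- x$states[, win, drop = FALSE]
        r2 <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))^2
        diag(r2) <- 0
        r2[is.na(r2)] <- 0
        alive <- rep(TRUE, length(win))
        while (TRUE) {
          r2a <- r2[alive, alive, drop = FALSE]
          if (length(r2a) == 0 || max(r2a) <= r2_max) break
          w <- which(r2a == max(r2a), arr.ind = TRUE)[1, ]
          pair <- which(alive)[w]
          li <- win[pair[1]]; lj <- win[pair[2]]
          drop_local <- if (maf[li] < maf[lj]) pair[1]
          else if (maf[lj] < maf[li]) pair[2]
          else pair[which.max(c(x$loci$pos[li], x$loci$pos[lj]))]
          alive[drop_local] <- FALSE
        }
        retained[win[!alive]] <- FALSE
      }
      n_now <- sum(retained[idx])
      if (start + window_snps - 1L >= n_now) break
      start <- start + step_snps
    }
  }
  which(retained)
}
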