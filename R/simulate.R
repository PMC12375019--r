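default_chromosomes <- function() {
  data.frame(
    chrom = c("chr1", "chr2", "chr3", "chr5", "chr12", "chrZ"),
    length_bp = c(120e6, 100e6, 80e6, 60e6, 20e6, 70e6),
    n_loci = c(560L, 480L, 380L, 300L, 80L, 200L),
    is_z = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

#' Simulation configuration for a synthetic hybrid-zone cohort
#'
#' Defaults emulate the study conditions the scans assume: a cohort of 900
#' admixed individuals in three age classes, 2,000 AIMs with block-wise
#' ancestry linkage on six chromosomes (including a Z), mean inland
#' ancestry 0.77, locus- and pair-specific viability selection whose
#' strength can depend on genome-wide ancestry, and a planted
#' recombination-suppressed inversion on chr5.
#'
#' @param n_individuals cohort size (default 900).
#' @param chromosomes data frame `chrom`, `length_bp`, `n_loci`, `is_z`.
#' @param target_mean_ancestry population mean inland ancestry; the
#'   later-generation ancestry distribution is solved to hit it
#'   (default 0.77).
#' @param ancestry_mix named proportions over classes `coastal`, `inland`,
#'   `f1`, `bc_coastal`, `bc_inland`, `latergen` (must sum to 1).
#' @param tract_switch_rate ancestry-switch probability per Mb per mosaic
#'   haplotype (default 0.1; higher values shorten ancestry tracts).
#' @param ancestry_kappa Beta concentration of later-generation individual
#'   ancestry proportions (default 1.5, giving the broad ancestry spectrum
#'   of a deep hybrid zone).
#' @param selection_targets data frame `chrom`, `pos`, `beta_het`,
#'   `beta_int`: per-locus survival effects of heterozygosity and of
#'   heterozygosity-by-ancestry, on the logit scale. `NULL` for the default
#'   5 planted loci; `FALSE`-like empty frame for a null cohort.
#' @param mismatch_targets data frame `chrom_i`, `pos_i`, `chrom_j`,
#'   `pos_j`, `beta_d`, `beta_dq`: survival effects of the pair mismatch
#'   distance (`beta_d`, ancestry-independent) and of its interaction with
#'   centered genome-wide ancestry (`beta_dq`; see [simulate_cohort()]).
#'   `NULL` for the default 3 planted cross-chromosome pairs.
#' @param survival_base logit-scale intercepts for the HY-to-SY and
#'   SY-to-ASY transitions (default `c(0.5, 0.5)`, i.e. about 62% annual
#'   survival for an ancestry-matched average bird).
#' @param inversion `list(chrom, start, end)` or `NULL`; default chr5
#'   20-36 Mb.
#' @param ancestry_error per-haplotype probability of an ancestry-call flip
#'   at a locus (default 0; set small and positive to emulate call error /
#'   within-arrangement polymorphism).
#' @param seed integer root seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 900,
                       chromosomes = default_chromosomes(),
                       target_mean_ancestry = 0.77,
                       ancestry_mix = NULL,
                       tract_switch_rate = 0.1,
                       ancestry_kappa = 1.5,
                       selection_targets = NULL,
                       mismatch_targets = NULL,
                       survival_base = c(0.5, 0.5),
                       inversion = list(chrom = "chr5", start = 20e6, end = 36e6),
                       ancestry_error = 0,
                       seed = 1) {
  if (is.null(ancestry_mix))
    ancestry_mix <- c(coastal = 0.02, inland = 0.05, f1 = 0.01,
                      bc_coastal = 0.02, bc_inland = 0.05, latergen = 0.85)
  if (abs(sum(ancestry_mix) - 1) > 1e-8)
    stop("`ancestry_mix` proportions must sum to 1")
  if (tract_switch_rate < 0 || ancestry_error < 0 || ancestry_error > 1)
    stop("rates must be non-negative (error in [0,1])")
  class_means <- c(coastal = 0, inland = 1, f1 = 0.5,
                   bc_coastal = 0.25, bc_inland = 0.75)
  fixed <- sum(ancestry_mix[names(class_means)] * class_means)
  if (ancestry_mix[["latergen"]] > 0) {
    m_later <- (target_mean_ancestry - fixed) / ancestry_mix[["latergen"]]
    if (m_later <= 0 || m_later >= 1)
      stop("`target_mean_ancestry` infeasible under `ancestry_mix`")
  } else {
    m_later <- NA_real_
    if (abs(fixed - target_mean_ancestry) > 0.05)
      warning("ancestry_mix mean differs from target_mean_ancestry")
  }
  if (is.null(selection_targets))
    selection_targets <- data.frame(
      chrom = c("chr1", "chr2", "chr3", "chr12", "chrZ"),
      pos = c(50e6, 50e6, 40e6, 10e6, 35e6),
      beta_het = rep(-2, 5), beta_int = rep(0, 5),
      stringsAsFactors = FALSE)
  if (is.null(mismatch_targets))
    mismatch_targets <- data.frame(
      chrom_i = c("chr1", "chr5", "chr2"), pos_i = c(60e6, 30e6, 30e6),
      chrom_j = c("chrZ", "chrZ", "chr3"), pos_j = c(35e6, 20e6, 20e6),
      beta_d = rep(0, 3), beta_dq = rep(-6, 3),
      stringsAsFactors = FALSE)
  if (!is.null(inversion)) {
    ci <- match(inversion$chrom, chromosomes$chrom)
    if (is.na(ci) || inversion$start < 1 ||
        inversion$end > chromosomes$length_bp[ci] ||
        inversion$start >= inversion$end)
      stop("inversion interval must lie within its chromosome")
  }
  structure(list(n_individuals = n_individuals, chromosomes = chromosomes,
                 target_mean_ancestry = target_mean_ancestry,
                 ancestry_mix = ancestry_mix, m_later = m_later,
                 tract_switch_rate = tract_switch_rate,
                 ancestry_kappa = ancestry_kappa,
                 selection_targets = selection_targets,
                 mismatch_targets = mismatch_targets,
                 survival_base = survival_base, inversion = inversion,
                 ancestry_error = ancestry_error, seed = as.integer(seed)),
            class = "sim_config")
}

nearest_locus <- function(loci, chrom, pos) {
  sel <- which(loci$chrom == chrom)
  if (!length(sel)) stop("no loci on chromosome ", chrom)
  sel[which.min(abs(loci$pos[sel] - pos))]
}

# one mosaic haplotype along all chromosomes; theta = inland proportion
sim_haplotype <- function(loci, chrom_tab, theta, switch_rate, pure = FALSE) {
  if (pure) return(rep(as.integer(round(theta)), nrow(loci)))
  hap <- integer(nrow(loci))
  for (chr in chrom_tab$chrom) {
    sel <- which(loci$chrom == chr)
    pos <- loci$pos[sel]
    n <- length(sel)
    redraw <- if (n > 1) {
      gap_mb <- diff(pos) / 1e6
      stats::runif(n - 1) < pmin(1, switch_rate * gap_mb)
    } else logical()
    seg <- cumsum(c(TRUE, redraw))  # tract index; new draw per tract
    draws <- stats::rbinom(max(seg), 1, theta)
    hap[sel] <- draws[seg]
  }
  hap
}

#' Simulate a synthetic admixed cohort with ground truth
#'
#' Simulates, per individual, two haplotypes as Markov ancestry tracts
#' along each chromosome; locus states are haplotype sums (0/1/2). Within
#' the inversion interval each haplotype carries a single arrangement
#' ancestry (recombination suppression), so inversion heterokaryotypes are
#' heterozygous across the interval. Age classes arise from simulated
#' viability: survival of each annual transition has logit
#' `base + sum(beta_het het_l + beta_int het_l q)
#'  + sum((beta_d + beta_dq (q - q0)) d_pair)` with `q0` the target mean
#' ancestry, and the cohort is a cross-sectional sample of survivors
#' (HY = 0 transitions survived, SY = 1, ASY = 2). The planted effects are
#' orthogonalized to genome-wide ancestry before use (their q-conditional
#' mean, a cubic fit, is absorbed into the baseline), so selection is
#' locus- or pair-specific conditional on q and q itself confers no
#' survival differential. Sex is assigned 50/50 and has no simulated
#' effect.
#'
#' @param config a [sim_config()].
#' @return List with `aim` (an [aim_matrix()]), `meta` (data frame
#'   `individual_id`, `age`, `age_class`, `sex`, `ancestry_q`,
#'   `heterozygosity_h`, `class`), and `truth` (selected loci and
#'   coefficients, mismatch pairs, inversion coordinates and per-individual
#'   karyotypes, latent survival probabilities).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chrom_tab <- config$chromosomes
  loci <- do.call(rbind, lapply(seq_len(nrow(chrom_tab)), function(i) {
    data.frame(chrom = chrom_tab$chrom[i],
               pos = sort(sample.int(chrom_tab$length_bp[i],
                                     chrom_tab$n_loci[i])),
               stringsAsFactors = FALSE)
  }))
  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  n <- config$n_individuals
  classes <- sample(names(config$ancestry_mix), n, replace = TRUE,
                    prob = config$ancestry_mix)
  inv <- config$inversion
  inv_sel <- if (!is.null(inv))
    which(loci$chrom == inv$chrom & loci$pos >= inv$start &
            loci$pos <= inv$end) else integer()
  states <- matrix(0L, n, nrow(loci))
  inv_geno <- integer(n)
  kappa <- config$ancestry_kappa
  for (ind in seq_len(n)) {
    cls <- classes[ind]
    spec <- switch(cls,
      coastal    = list(theta = c(0, 0),     pure = c(TRUE, TRUE)),
      inland     = list(theta = c(1, 1),     pure = c(TRUE, TRUE)),
      f1         = list(theta = c(0, 1),     pure = c(TRUE, TRUE)),
      bc_coastal = list(theta = c(0, 0.5),   pure = c(TRUE, FALSE)),
      bc_inland  = list(theta = c(1, 0.5),   pure = c(TRUE, FALSE)),
      latergen   = {
        th <- stats::rbeta(1, kappa * config$m_later,
                           kappa * (1 - config$m_later))
        list(theta = c(th, th), pure = c(FALSE, FALSE))
      })
    geno <- integer(nrow(loci))
    arr_sum <- 0L
    for (h in 1:2) {
      hap <- sim_haplotype(loci, chrom_tab, spec$theta[h],
                           config$tract_switch_rate, spec$pure[h])
      if (length(inv_sel)) {
        arr <- if (spec$pure[h]) as.integer(round(spec$theta[h]))
               else stats::rbinom(1, 1, spec$theta[h])
        hap[inv_sel] <- arr
        arr_sum <- arr_sum + arr
      }
      if (config$ancestry_error > 0) {
        flip <- stats::runif(nrow(loci)) < config$ancestry_error
        hap[flip] <- 1L - hap[flip]
      }
      geno <- geno + hap
    }
    states[ind, ] <- geno
    inv_geno[ind] <- arr_sum
  }
  ids <- sprintf("ind%04d", seq_len(n))
  z_name <- chrom_tab$chrom[chrom_tab$is_z][1]
  if (is.na(z_name)) z_name <- "chrZ"
  aim <- aim_matrix(states, loci, ids, z_chrom = z_name)
  # target coordinates resolve to the nearest simulated locus
  st <- config$selection_targets
  sel_idx <- if (nrow(st)) mapply(nearest_locus, st$chrom, st$pos,
                                  MoreArgs = list(loci = aim$loci))
             else integer()
  mt <- config$mismatch_targets
  pair_idx <- if (nrow(mt))
    cbind(mapply(nearest_locus, mt$chrom_i, mt$pos_i,
                 MoreArgs = list(loci = aim$loci)),
          mapply(nearest_locus, mt$chrom_j, mt$pos_j,
                 MoreArgs = list(loci = aim$loci)))
  else matrix(integer(), ncol = 2)
  q <- rowMeans(aim$states) / 2
  eta <- rep(0, n)
  if (length(sel_idx)) for (k in seq_along(sel_idx)) {
    het <- as.numeric(aim$states[, sel_idx[k]] == 1)
    eta <- eta + st$beta_het[k] * het + st$beta_int[k] * het * q
  }
  # beta_dq is the slope of the pair effect in q, centered on the target
  # mean: birds more inland than average experience beta_dq-signed selection
  # on the pair mismatch, birds more coastal the opposite sign.
  q0 <- config$target_mean_ancestry
  if (nrow(mt)) for (k in seq_len(nrow(mt))) {
    d <- abs(aim$states[, pair_idx[k, 1]] - aim$states[, pair_idx[k, 2]]) / sqrt(2)
    eta <- eta + (mt$beta_d[k] + mt$beta_dq[k] * (q - q0)) * d
  }
  # Orthogonalize the planted effects to genome-wide ancestry: selection is
  # locus-specific conditional on q; q itself confers no survival
  # differential (its q-conditional mean is absorbed into the baseline).
  if (any(eta != 0) && length(unique(q)) > 4) {
    eta <- eta - stats::fitted(stats::lm(eta ~ stats::poly(q, 3)))
  } else if (any(eta != 0)) {
    eta <- eta - mean(eta)
  }
  p1 <- stats::plogis(config$survival_base[1] + eta)
  p2 <- stats::plogis(config$survival_base[2] + eta)
  if (max(p1) == 0) stop("infeasible config: no survival possible")
  s1 <- stats::rbinom(n, 1, p1)
  s2 <- stats::rbinom(n, 1, p2)
  age <- ifelse(s1 == 0, 0L, ifelse(s2 == 0, 1L, 2L))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  meta <- data.frame(
    individual_id = ids, age = age,
    age_class = c("HY", "SY", "ASY")[age + 1L],
    sex = sex,
    ancestry_q = suppressWarnings(genome_wide_ancestry(aim)),
    heterozygosity_h = suppressWarnings(individual_heterozygosity(aim)),
    class = classes, row.names = NULL, stringsAsFactors = FALSE)
  truth <- list(
    selection = cbind(st, locus = sel_idx),
    mismatch = if (nrow(mt)) cbind(mt, locus_i = pair_idx[, 1],
                                   locus_j = pair_idx[, 2]) else mt,
    inversion = inv,
    inversion_genotype = if (length(inv_sel)) inv_geno else NULL,
    survival_p1 = p1, survival_p2 = p2, classes = classes,
    seed = config$seed)
  list(aim = aim, meta = meta, truth = truth)
}

#' Simulate a windowed recombination-rate map
#'
#' Constant-rate 100 kb windows with multiplicative log-normal noise;
#' windows whose midpoint falls inside the configured inversion get the
#' low rate (recombination suppression), all others the high rate.
#'
#' @param config a [sim_config()].
#' @param window_bp window size (default 100000).
#' @param low_rate,high_rate rates inside/outside the inversion (defaults
#'   0.5 and 5, arbitrary population-scaled units).
#' @param noise_sd standard deviation of the log-normal noise (default
#'   0.2; 0 gives an exact two-valued map).
#' @param seed RNG seed (default `config$seed + 1`).
#' @return Data frame `chrom`, `start`, `end`, `rate`, `in_inversion`.
#' @export
simulate_recomb_map <- function(config, window_bp = 100000, low_rate = 0.5,
                                high_rate = 5, noise_sd = 0.2,
                                seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (window_bp <= 0) stop("`window_bp` must be positive")
  if (low_rate < 0 || high_rate < 0 || low_rate >= high_rate)
    stop("need 0 <= low_rate < high_rate")
  set.seed(seed)
  out <- NULL
  inv <- config$inversion
  for (i in seq_len(nrow(config$chromosomes))) {
    chr <- config$chromosomes$chrom[i]
    n_win <- ceiling(config$chromosomes$length_bp[i] / window_bp)
    start <- (seq_len(n_win) - 1) * window_bp + 1
    end <- pmin(seq_len(n_win) * window_bp, config$chromosomes$length_bp[i])
    mid <- (start + end) / 2
    inside <- if (!is.null(inv) && chr == inv$chrom)
      mid >= inv$start & mid <= inv$end else rep(FALSE, n_win)
    base <- ifelse(inside, low_rate, high_rate)
    noise <- if (noise_sd > 0) exp(stats::rnorm(n_win, 0, noise_sd)) else 1
    out <- rbind(out, data.frame(chrom = chr, start = start, end = end,
                                 rate = base * noise, in_inversion = inside,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Simulate a pair of Hi-C contact matrices with one planted interaction
#'
#' Both matrices share a distance-decay Poisson expectation
#' `depth / (1 + |i - j|)`; matrix A additionally multiplies the mean in a
#' small neighborhood of the planted cell by `fold`, emulating a
#' long-range contact present in only one parental genome.
#'
#' @param n_bins number of bins (default 300).
#' @param bin_bp bin size (default 10000).
#' @param planted `list(bin_i, bin_j, fold)` with `1 <= bin_i < bin_j <=
#'   n_bins` and `fold >= 1`, or `NULL` for an exchangeable null pair.
#' @param depth decay amplitude (expected diagonal count; default 500).
#' @param radius half-width of the boosted neighborhood in bins (default 4,
#'   i.e. a 9 x 9 bin contact blob).
#' @param seed RNG seed.
#' @param chrom chromosome label.
#' @return List with contact matrices `a` (carrying the planted
#'   interaction) and `b`.
#' @export
simulate_hic_pair <- function(n_bins = 300, bin_bp = 10000, planted = NULL,
                              depth = 500, radius = 4, seed = 1,
                              chrom = "chr5") {
  set.seed(seed)
  if (!is.null(planted)) {
    if (planted$bin_i < 1 || planted$bin_j <= planted$bin_i ||
        planted$bin_j > n_bins)
      stop("need 1 <= bin_i < bin_j <= n_bins")
    if (planted$fold < 1) stop("`fold` must be >= 1")
  }
  dist <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
  mu <- depth / (1 + dist)
  mu_a <- mu
  if (!is.null(planted) && planted$fold > 1) {
    ii <- pmax(1, planted$bin_i - radius):pmin(n_bins, planted$bin_i + radius)
    jj <- pmax(1, planted$bin_j - radius):pmin(n_bins, planted$bin_j + radius)
    mu_a[ii, jj] <- mu_a[ii, jj] * planted$fold
    mu_a[jj, ii] <- t(mu_a[ii, jj])
  }
  draw <- function(m) {
    upper <- which(upper.tri(m, diag = TRUE))
    cnt <- matrix(0, n_bins, n_bins)
    cnt[upper] <- stats::rpois(length(upper), m[upper])
    cnt[lower.tri(cnt)] <- t(cnt)[lower.tri(cnt)]
    cnt
  }
  list(a = contact_matrix(draw(mu_a), bin_bp, chrom),
       b = contact_matrix(draw(mu), bin_bp, chrom))
}
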