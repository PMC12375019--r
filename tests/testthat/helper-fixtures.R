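# Small builders and independent oracles shared across test files.

toy_aim <- function(states, chrom = NULL, pos = NULL, z_chrom = "chrZ") {
  states <- as.matrix(states)
  n_loci <- ncol(states)
  if (is.null(chrom)) chrom <- rep("chr1", n_loci)
  if (is.null(pos)) pos <- seq_len(n_loci) * 1000
  aim_matrix(states, data.frame(chrom = chrom, pos = pos), z_chrom = z_chrom)
}

# Independent Newton-Raphson GLM oracle (binomial-logit / poisson-log),
# written directly from the score and Fisher information.
nr_glm_oracle <- function(y, X, family, tol = 1e-12, max_iter = 200) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    if (family == "binomial") {
      mu <- 1 / (1 + exp(-eta))
      w <- mu * (1 - mu)
    } else {
      mu <- exp(eta)
      w <- mu
    }
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X * w, X)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(info)))
  list(coefficients = beta, se = se)
}

# Exact rank-sum oracle: enumerate every assignment of the pooled values.
rank_sum_oracle <- function(g1, g2) {
  n1 <- length(g1)
  vals <- c(g1, g2)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subsets <- utils::combn(length(vals), n1)
  u_all <- apply(subsets, 2, function(s) sum(r[s]) - n1 * (n1 + 1) / 2)
  eps <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
}

# Cohort simulated at reduced genome scale for scan tests.
small_genome <- function(n_loci_per_chrom = 40) {
  data.frame(chrom = c("chr1", "chr2", "chr3", "chr5", "chrZ"),
             length_bp = rep(40e6, 5),
             n_loci = rep(n_loci_per_chrom, 5),
             is_z = c(FALSE, FALSE, FALSE, FALSE, TRUE),
             stringsAsFactors = FALSE)
}

null_targets <- function() {
  list(
    selection = data.frame(chrom = character(), pos = numeric(),
                           beta_het = numeric(), beta_int = numeric()),
    mismatch = data.frame(chrom_i = character(), pos_i = numeric(),
                          chrom_j = character(), pos_j = numeric(),
                          beta_d = numeric(), beta_dq = numeric()))
}

true_anchor_means <- function(x) {
  data.frame(chrom = x$loci$chrom, pos = x$loci$pos,
             coastal_mean = 0, inland_mean = 2)
}
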