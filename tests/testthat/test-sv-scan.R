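test_that("window summaries match a dense eigendecomposition oracle", {
  set.seed(25)
  states <- matrix(sample(0:2, 20 * 12, TRUE), 20, 12)
  x <- toy_aim(states, pos = c(1:6 * 1e4, 1e5 + 1:6 * 1e4))
  ws <- window_summaries(x, window_bp = 1e5, min_loci = 5)
  expect_equal(nrow(ws$windows), 2)
  for (s in ws$summaries) {
    sel <- which(x$loci$pos >= s$start & x$loci$pos <= s$end)
    X <- x$states[, sel]
    X[is.na(X)] <- 0
    X <- sweep(X, 2, colMeans(X))
    C <- X %*% t(X) / ncol(X)
    ei <- eigen(C, symmetric = TRUE)
    expect_equal(s$lambda, ei$values[1:2], tolerance = 1e-8)
    # eigenvectors up to sign
    for (k in 1:2)
      expect_equal(abs(sum(s$vectors[, k] * ei$vectors[, k])), 1,
                   tolerance = 1e-8)
  }
})

test_that("degenerate windows are skipped with flags", {
  states <- cbind(matrix(1, 10, 5),                       # invariant window
                  matrix(sample(0:2, 10 * 5, TRUE), 10, 5))
  x <- toy_aim(states, pos = c(1:5 * 1e4, 1e5 + 1:5 * 1e4))
  ws <- window_summaries(x, window_bp = 1e5)
  expect_equal(ws$windows$flag[1], "zero_variance")
  expect_false(ws$windows$used[1])
  # identical submatrices give identical summaries
  s2 <- cbind(states[, 6:10], states[, 6:10])
  x2 <- toy_aim(s2, pos = c(1:5 * 1e4, 1e5 + 1:5 * 1e4))
  ws2 <- window_summaries(x2, window_bp = 1e5)
  expect_equal(ws2$summaries[[1]]$lambda, ws2$summaries[[2]]$lambda)
  expect_equal(window_distance(ws2$summaries[[1]], ws2$summaries[[2]]), 0,
               tolerance = 1e-10)
})

test_that("window distance identity equals the explicit Frobenius oracle", {
  set.seed(26)
  rand_summary <- function(n) {
    Q <- qr.Q(qr(matrix(rnorm(n * 2), n, 2)))
    list(lambda = sort(abs(rnorm(2, 2)), decreasing = TRUE), vectors = Q)
  }
  for (rep in 1:100) {
    a <- rand_summary(12)
    b <- rand_summary(12)
    Pa <- a$vectors %*% diag(a$lambda) %*% t(a$vectors)
    Pb <- b$vectors %*% diag(b$lambda) %*% t(b$vectors)
    expect_equal(window_distance(a, b), norm(Pa - Pb, "F"),
                 tolerance = 1e-10)
    expect_equal(window_distance(a, b), window_distance(b, a))
    expect_equal(window_distance(a, a), 0, tolerance = 1e-10)
  }
  # orthogonal rank-1 summaries with unit eigenvalues: distance sqrt(2)
  e1 <- list(lambda = c(1, 0), vectors = cbind(c(1, 0, 0), c(0, 1, 0)))
  e2 <- list(lambda = c(1, 0), vectors = cbind(c(0, 0, 1), c(0, 1, 0)))
  expect_equal(window_distance(e1, e2), sqrt(2), tolerance = 1e-12)
  expect_error(window_distance(e1, list(lambda = c(1, 0),
                                        vectors = matrix(0, 5, 2))),
               "mismatched")
})

test_that("classical MDS embeds Euclidean configurations exactly", {
  set.seed(27)
  # collinear points with spacings 1 and 2
  D <- as.matrix(dist(c(0, 1, 3)))
  Y <- classical_mds(D, 2)
  expect_equal(as.matrix(dist(Y[, 1])), D, tolerance = 1e-8,
               ignore_attr = TRUE)
  # 2-D random configurations: pairwise distances reproduced
  for (rep in 1:10) {
    P <- matrix(rnorm(16), 8, 2)
    D <- as.matrix(dist(P))
    Y <- classical_mds(D, 2)
    expect_equal(as.matrix(dist(Y)), D, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # degenerate all-zero distances
  expect_equal(classical_mds(matrix(0, 4, 4), 2), matrix(0, 4, 2))
  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("silhouette-based k selection recovers planted cluster counts", {
  set.seed(28)
  make_clouds <- function(k) {
    centers <- cbind(cos(2 * pi * 1:k / k), sin(2 * pi * 1:k / k)) * 20
    do.call(rbind, lapply(seq_len(k), function(i)
      sweep(matrix(rnorm(30, sd = 0.5), 15, 2), 2, centers[i, ], "+")))
  }
  r2 <- choose_k_silhouette(make_clouds(2), k_range = 2:6, seed = 1)
  expect_equal(r2$best_k, 2)
  r4 <- choose_k_silhouette(make_clouds(4), k_range = 2:6, seed = 1)
  expect_equal(r4$best_k, 4)
  expect_error(choose_k_silhouette(matrix(1, 10, 2), k_range = 2:4),
               "degenerate")
  expect_error(choose_k_silhouette(make_clouds(2)[1:4, ], k_range = 2:8),
               "k_range")
})

test_that("outlier region calling respects threshold, run length and gaps", {
  n <- 60
  win <- data.frame(chrom = "chr1", start = (0:(n - 1)) * 1e5 + 1,
                    end = (1:n) * 1e5)
  base <- rnorm(n, 0, 0.05)
  # 12 consecutive strong outliers
  sc <- base; sc[21:32] <- 3
  reg <- outlier_regions(win, sc, z_threshold = 1, min_run = 10)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$n_windows, 12)
  expect_equal(c(reg$start, reg$end), c(win$start[21], win$end[32]))
  # 9 consecutive: below the minimum run
  sc9 <- base; sc9[21:29] <- 3
  expect_equal(nrow(outlier_regions(win, sc9, min_run = 10)), 0)
  # alternating outliers never form a run
  alt <- base; alt[seq(2, n, 2)] <- 3
  expect_equal(nrow(outlier_regions(win, alt, min_run = 10)), 0)
  # a genomic gap breaks a run even when scores qualify
  win_gap <- win; win_gap$start[27] <- win_gap$start[27] + 5e5
  win_gap$end[27] <- win_gap$end[27] + 5e5
  reg_gap <- outlier_regions(win_gap[-(28:n), ], sc[-(28:n)], min_run = 10)
  expect_equal(nrow(reg_gap), 0)
  # zero-variance scores: no regions, flagged
  flat <- outlier_regions(win, rep(1, n), min_run = 10)
  expect_equal(nrow(flat), 0)
  expect_equal(attr(flat, "flag"), "zero_score_variance")
})

test_that("region PCA genotyping flags a parental-only (two-cluster) cohort", {
  set.seed(29)
  # only homokaryotypes: states 0 or 2 across the region, two PCA clusters
  karyo <- sample(c(0, 2), 40, replace = TRUE)
  karyo[1:2] <- c(0, 2)
  states <- matrix(rep(karyo, 10), 40, 10)
  x <- toy_aim(states, pos = 1:10 * 1e4)
  res <- region_pca_genotype(x, "chr1", 1, 1e5)
  expect_true(res$flag %in% c("empty_cluster", "kmeans_collapse"))
})

test_that("region PCA cluster labels are invariant to individual order", {
  set.seed(30)
  karyo <- sample(0:2, 60, replace = TRUE)
  states <- matrix(rep(karyo, 12), 60, 12)
  flip <- matrix(runif(720) < 0.03, 60, 12)
  states[flip] <- (states[flip] + 1) %% 3
  x <- toy_aim(states, pos = 1:12 * 1e4)
  r1 <- region_pca_genotype(x, "chr1", 1, 2e5, seed = 5)
  perm <- sample(60)
  x2 <- aim_matrix(states[perm, ], x$loci[, c("chrom", "pos")],
                   x$individual_ids[perm])
  r2 <- region_pca_genotype(x2, "chr1", 1, 2e5, seed = 5)
  expect_equal(r2$cluster[match(x$individual_ids, x2$individual_ids)],
               r1$cluster)
})

test_that("ld_heatmap filters by MAF (inclusive), missingness and thinning", {
  set.seed(31)
  n <- 40
  # locus 2 has minor-state frequency exactly 0.05: retained
  s1 <- sample(0:2, n, replace = TRUE)
  s2 <- c(rep(1, 4), rep(0, n - 4))   # freq = 4/80 = 0.05
  s3 <- sample(0:2, n, replace = TRUE)
  s3[1:10] <- NA                       # 25% missing: dropped at 0.1
  s4 <- sample(0:2, n, replace = TRUE)
  x <- toy_aim(cbind(s1, s2, s3, s4), pos = c(1e4, 2e4, 3e4, 9e5))
  tab <- ld_heatmap(x, "chr1", "all", maf_min = 0.05, max_missing = 0.1)
  expect_true(2e4 %in% c(tab$pos_i, tab$pos_j))
  expect_false(3e4 %in% c(tab$pos_i, tab$pos_j))
  # thinning to one locus per Mb leaves a single pairable locus at most
  tab2 <- ld_heatmap(x, "chr1", "all", thin_bp = 1e6)
  expect_lte(nrow(tab2), 1)
  expect_error(ld_heatmap(x, "chr1", "homozygote-major"), "cluster_labels")
})
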