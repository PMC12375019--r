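#' Local-PCA window summaries
#'
#' Splits each chromosome into non-overlapping windows and computes, per
#' window, the top-2 eigenpairs of the individuals-by-individuals sample
#' covariance of mean-imputed, per-locus-centered genotypes
#' (`C = X X' / L_w`). This is the windowed local-PCA step used to detect
#' regions of discordant population structure.
#'
#' @param x an [aim_matrix()] (or any individuals-by-loci state matrix
#'   wrapped as one).
#' @param window_bp window size in base pairs (default 100000).
#' @param min_loci minimum loci per window; windows below are skipped with
#'   a flag (default 5).
#' @return List with `windows` (data frame: `chrom`, `start`, `end`,
#'   `n_loci`, `used`, `flag`) and `summaries` (per used window: list with
#'   `lambda` length-2 and `vectors` n-by-2, plus window coordinates).
#' @export
window_summaries <- function(x, window_bp = 100000, min_loci = 5) {
  stopifnot(inherits(x, "aim_matrix"))
  if (nrow(x$states) < 2) stop("need at least 2 individuals")
  win_df <- NULL
  summaries <- list()
  for (chr in unique(x$loci$chrom)) {
    sel <- which(x$loci$chrom == chr)
    pos <- x$loci$pos[sel]
    wid <- (pos - 1L) %/% window_bp
    for (w in sort(unique(wid))) {
      loci_w <- sel[wid == w]
      start <- w * window_bp + 1
      end <- (w + 1) * window_bp
      flag <- ""
      used <- FALSE
      if (length(loci_w) < min_loci) {
        flag <- "too_few_loci"
      } else {
        X <- impute_center(x$states[, loci_w, drop = FALSE])
        if (all(abs(X) < 1e-12)) {
          flag <- "zero_variance"
        } else {
          C <- tcrossprod(X) / ncol(X)
          ei <- eigen(C, symmetric = TRUE)
          lam <- pmax(ei$values[1:2], 0)
          vec <- ei$vectors[, 1:2, drop = FALSE]
          summaries[[length(summaries) + 1L]] <-
            list(chrom = chr, start = start, end = end,
                 lambda = lam, vectors = vec, n_loci = length(loci_w))
          used <- TRUE
        }
      }
      win_df <- rbind(win_df, data.frame(
        chrom = chr, start = start, end = end,
        n_loci = length(loci_w), used = used, flag = flag,
        stringsAsFactors = FALSE))
    }
  }
  list(windows = win_df, summaries = summaries)
}

impute_center <- function(X) {
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mu[j]
  }
  sweep(X, 2, colMeans(X))
}

#' Distance between two local-PCA window summaries
#'
#' Frobenius distance between the rank-2 covariance reconstructions of two
#' windows, `d = ||P_A - P_B||_F` with
#' `P_w = lambda1 v1 v1' + lambda2 v2 v2'`, evaluated through the identity
#' `d^2 = sum(lambda_A^2) + sum(lambda_B^2)
#'        - 2 sum_kl lambda_Ak lambda_Bl (v_Ak . v_Bl)^2`.
#'
#' @param a,b window summaries from [window_summaries()].
#' @return Non-negative distance.
#' @export
window_distance <- function(a, b) {
  if (nrow(a$vectors) != nrow(b$vectors))
    stop("window summaries have mismatched individual sets")
  if (identical(a$lambda, b$lambda) && identical(a$vectors, b$vectors))
    return(0)
  cross <- crossprod(a$vectors, b$vectors)  # 2x2 of v_Ak . v_Bl
  d2 <- sum(a$lambda^2) + sum(b$lambda^2) -
    2 * sum((a$lambda %o% b$lambda) * cross^2)
  sqrt(max(d2, 0))
}

#' All pairwise window distances
#'
#' @param summaries the `summaries` element of [window_summaries()].
#' @return Symmetric distance matrix with zero diagonal.
#' @export
window_dist_matrix <- function(summaries) {
  n <- length(summaries)
  D <- matrix(0, n, n)
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- window_distance(summaries[[i]], summaries[[j]])
  }
  D
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a symmetric distance matrix into `n_axes` coordinates by double
#' centering and eigendecomposition (via `stats::cmdscale`). Axes with
#' non-positive eigenvalues are set to zero; each axis is sign-fixed so its
#' first nonzero loading is positive.
#'
#' @param distances symmetric matrix with zero diagonal.
#' @param n_axes number of output axes (default 2).
#' @return Matrix (`n x n_axes`) of coordinates.
#' @export
classical_mds <- function(distances, n_axes = 2) {
  distances <- as.matrix(distances)
  if (!isSymmetric(unname(distances), tol = 1e-8))
    stop("`distances` must be symmetric")
  if (any(abs(diag(distances)) > 1e-12))
    stop("`distances` must have a zero diagonal")
  n <- nrow(distances)
  # degenerate inputs (all-zero distances) legitimately yield no positive
  # eigenvalues; the coordinates are then all zero
  pts <- suppressWarnings(stats::cmdscale(distances, k = min(n_axes, n - 1)))
  out <- matrix(0, n, n_axes)
  if (length(pts) && ncol(pts) > 0)
    out[, seq_len(ncol(pts))] <- pts
  for (a in seq_len(n_axes)) {
    nz <- which(abs(out[, a]) > 1e-12)
    if (length(nz) && out[nz[1], a] < 0) out[, a] <- -out[, a]
  }
  out
}

#' Choose k for k-means by maximum mean silhouette
#'
#' Runs k-means (25 restarts, fixed seed) on MDS coordinates for each
#' candidate k and returns the k with the highest mean silhouette width;
#' ties go to the smaller k.
#'
#' @param coords matrix of coordinates (windows in rows).
#' @param k_range candidate cluster counts (default `2:8`).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart k-means restarts (default 25).
#' @return List with `best_k`, `labels`, and `silhouette` (mean width per k).
#' @export
choose_k_silhouette <- function(coords, k_range = 2:8, seed = 1, nstart = 25) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (max(k_range) >= n)
    stop("`k_range` exceeds the number of points minus 1")
  if (nrow(unique(coords)) < 2)
    stop("degenerate input: all points identical, silhouette undefined")
  d <- stats::dist(coords)
  sil <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  labels <- vector("list", length(k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    if (nrow(unique(coords)) < k) next
    set.seed(seed)
    km <- stats::kmeans(coords, centers = k, nstart = nstart)
    sw <- cluster::silhouette(km$cluster, d)
    sil[ki] <- mean(sw[, "sil_width"])
    labels[[ki]] <- km$cluster
  }
  if (all(is.na(sil))) stop("no feasible k in `k_range`")
  best <- which.max(sil)  # first max -> smaller k on ties
  list(best_k = k_range[best], labels = labels[[best]], silhouette = sil)
}

#' Call outlier regions from MDS1 scores
#'
#' z-scores each window's MDS1 value against the mean and standard
#' deviation of all windows; outlier windows exceed the threshold in
#' absolute value (MDS axis orientation is arbitrary) or, with
#' `signed = TRUE`, in the positive direction only. Maximal runs of at
#' least `min_run` consecutive genomic windows (same chromosome, adjacent
#' window grid; gaps break runs) become regions.
#'
#' @param windows data frame with `chrom`, `start`, `end` and the score
#'   column, ordered by genome position.
#' @param mds1 per-window MDS1 scores (default: `windows$mds1`).
#' @param z_threshold z-score threshold (default 1).
#' @param min_run minimum run length in windows (default 10).
#' @param window_bp window size used to define adjacency (default inferred
#'   from `end - start + 1` of the first window).
#' @param signed threshold `z` instead of `|z|`.
#' @return Data frame of regions: `chrom`, `start`, `end`, `n_windows`,
#'   `mean_z`, plus a `windows` list column of member row indices. Empty
#'   (with a flag attribute) when scores have zero variance.
#' @export
outlier_regions <- function(windows, mds1 = windows$mds1, z_threshold = 1,
                            min_run = 10, window_bp = NULL, signed = FALSE) {
  if (length(mds1) != nrow(windows)) stop("score length mismatch")
  if (sum(is.finite(mds1)) < 2) stop("need >= 2 finite scores")
  if (is.null(window_bp)) window_bp <- windows$end[1] - windows$start[1] + 1
  mu <- mean(mds1, na.rm = TRUE)
  sdv <- stats::sd(mds1, na.rm = TRUE)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      mean_z = numeric())
  if (is.na(sdv) || sdv == 0) {
    attr(empty, "flag") <- "zero_score_variance"
    return(empty)
  }
  z <- (mds1 - mu) / sdv
  out <- if (signed) z > z_threshold else abs(z) > z_threshold
  out[is.na(out)] <- FALSE
  regions <- NULL
  run <- integer()
  flush <- function(regions, run) {
    if (length(run) >= min_run) {
      reg <- data.frame(chrom = windows$chrom[run[1]],
                        start = windows$start[run[1]],
                        end = windows$end[run[length(run)]],
                        n_windows = length(run),
                        mean_z = mean(z[run]),
                        stringsAsFactors = FALSE)
      reg$windows <- list(run)
      regions <- rbind(regions, reg)
    }
    regions
  }
  for (i in seq_len(nrow(windows))) {
    contiguous <- length(run) > 0 &&
      windows$chrom[i] == windows$chrom[run[length(run)]] &&
      windows$start[i] == windows$end[run[length(run)]] + 1
    if (out[i] && (length(run) == 0 || contiguous)) {
      run <- c(run, i)
    } else {
      regions <- flush(regions, run)
      run <- if (out[i]) i else integer()
    }
  }
  regions <- flush(regions, run)
  if (is.null(regions)) empty else regions
}

#' Genotype a putative structural-variant region by PCA clustering
#'
#' PCA on mean-imputed, centered genotypes restricted to the region, then
#' k-means with k = 3 on PC1. Clusters are relabelled in increasing order
#' of mean PC1, so clusters 1 and 3 are the putative homokaryotypes and
#' cluster 2 the putative heterokaryotypes. Reports per-cluster mean
#' genome-wide heterozygosity and region-restricted heterozygosity; an
#' inversion is supported when the central cluster shows the highest
#' region heterozygosity.
#'
#' @param x an [aim_matrix()].
#' @param chrom,start,end region coordinates (1-based, closed).
#' @param seed RNG seed for the k-means restarts.
#' @return List with `scores` (PC1/PC2 per individual), `cluster`
#'   (1/2/3 ordered by PC1), `summary` (per-cluster n, mean PC1, mean
#'   genome-wide and region heterozygosity) and `flag` (non-empty when the
#'   three clusters are not all occupied or k-means collapsed).
#' @export
region_pca_genotype <- function(x, chrom, start, end, seed = 1) {
  stopifnot(inherits(x, "aim_matrix"))
  sel <- which(x$loci$chrom == chrom & x$loci$pos >= start &
                 x$loci$pos <= end)
  if (nrow(x$states) < 6) stop("need >= 6 individuals")
  sub <- x$states[, sel, drop = FALSE]
  poly <- apply(sub, 2, function(v) stats::sd(v, na.rm = TRUE) > 0)
  poly[is.na(poly)] <- FALSE
  if (sum(poly) < 2) stop("region must contain >= 2 polymorphic loci")
  X <- impute_center(sub[, poly, drop = FALSE])
  pc <- stats::prcomp(X, center = FALSE)
  scores <- pc$x[, 1:2, drop = FALSE]
  colnames(scores) <- c("PC1", "PC2")
  flag <- ""
  if (length(unique(round(scores[, 1], 10))) < 3) {
    flag <- "kmeans_collapse"
    cl <- rep(1L, nrow(scores))
  } else {
    set.seed(seed)
    km <- stats::kmeans(scores[, 1], centers = 3, nstart = 25)
    ord <- order(km$centers)
    cl <- match(km$cluster, ord)
    if (min(table(factor(cl, levels = 1:3))) == 0)
      flag <- "empty_cluster"
  }
  h_gw <- suppressWarnings(individual_heterozygosity(x))
  h_region <- rowMeans(sub == 1, na.rm = TRUE)
  summary <- data.frame(
    cluster = 1:3,
    n = as.integer(table(factor(cl, levels = 1:3))),
    mean_pc1 = tapply(scores[, 1], factor(cl, levels = 1:3), mean),
    het_genomewide = tapply(h_gw, factor(cl, levels = 1:3), mean, na.rm = TRUE),
    het_region = tapply(h_region, factor(cl, levels = 1:3), mean, na.rm = TRUE),
    row.names = NULL)
  list(scores = scores, cluster = cl, summary = summary, flag = flag)
}

#' Pairwise LD table for a chromosome, by sample subset
#'
#' Filters loci by minor-state frequency and missingness, optionally thins
#' to one locus per `thin_bp`, and returns dosage r-squared for all
#' retained pairs. The `"homozygote-major"` subset restricts to individuals
#' in the larger of the two homokaryotype clusters from
#' [region_pca_genotype()], the standard contrast for inversion detection
#' (LD elevated in all samples but not within a karyotype).
#'
#' @param x an [aim_matrix()].
#' @param chrom chromosome to analyse.
#' @param subset `"all"` or `"homozygote-major"`.
#' @param cluster_labels per-individual 1/2/3 labels (required for the
#'   homozygote subset).
#' @param maf_min minimum minor-state frequency, inclusive (default 0.05).
#' @param thin_bp keep one locus per `thin_bp`; 0 disables thinning.
#' @param max_missing maximum fraction of missing calls per locus
#'   (default 0.1).
#' @return Long data frame: `pos_i`, `pos_j`, `r2` (NA for monomorphic
#'   pairs after subsetting).
#' @export
ld_heatmap <- function(x, chrom, subset = c("all", "homozygote-major"),
                       cluster_labels = NULL, maf_min = 0.05, thin_bp = 0,
                       max_missing = 0.1) {
  stopifnot(inherits(x, "aim_matrix"))
  subset <- match.arg(subset)
  rows <- seq_len(nrow(x$states))
  if (subset == "homozygote-major") {
    if (is.null(cluster_labels))
      stop("`cluster_labels` required for the homozygote-major subset")
    n1 <- sum(cluster_labels == 1); n3 <- sum(cluster_labels == 3)
    major <- if (n3 >= n1) 3L else 1L
    rows <- which(cluster_labels == major)
    if (!length(rows)) stop("empty homozygote-major subset")
  }
  sel <- which(x$loci$chrom == chrom)
  S <- x$states[rows, sel, drop = FALSE]
  missfrac <- colMeans(is.na(S))
  f <- colMeans(S, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  keep <- !is.na(maf) & maf >= maf_min & missfrac <= max_missing
  sel <- sel[keep]
  if (thin_bp > 0 && length(sel)) {
    bins <- (x$loci$pos[sel] - 1L) %/% thin_bp
    sel <- sel[!duplicated(bins)]
  }
  if (length(sel) < 2)
    return(data.frame(pos_i = integer(), pos_j = integer(), r2 = numeric()))
  S <- x$states[rows, sel, drop = FALSE]
  r2 <- suppressWarnings(stats::cor(S, use = "pairwise.complete.obs"))^2
  ut <- which(upper.tri(r2), arr.ind = TRUE)
  data.frame(pos_i = x$loci$pos[sel][ut[, 1]],
             pos_j = x$loci$pos[sel][ut[, 2]],
             r2 = r2[ut])
}
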