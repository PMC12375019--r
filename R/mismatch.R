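#' Pairwise ancestry-mismatch distance
#'
#' For a pair of loci, the mismatch of an individual is the perpendicular
#' Euclidean distance of its two-locus genotype point from the line joining
#' the parental mean-ancestry anchor points (coastal mean and inland mean at
#' the two loci). Individuals whose genotype lies on the parental line
#' (e.g. concordant ancestry at both loci) score 0; discordant-ancestry
#' genotypes score high.
#'
#' @param g genotype point `c(state_i, state_j)`, or a 2-column matrix of
#'   points (one row per individual; NA rows give NA distances).
#' @param c_anchor coastal anchor `c(c_i, c_j)` (panel mean states).
#' @param u_anchor inland anchor `c(u_i, u_j)`.
#' @return Non-negative distance(s); errors if the anchors coincide.
#' @export
mismatch_distance <- function(g, c_anchor, u_anchor) {
  v <- u_anchor - c_anchor
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("degenerate anchors: coastal and inland means coincide")
  g <- if (is.matrix(g)) g else matrix(g, ncol = 2)
  abs((g[, 1] - c_anchor[1]) * v[2] - (g[, 2] - c_anchor[2]) * v[1]) / nv
}

#' Parental anchor means per locus
#'
#' Mean ancestry state of designated parental panels at every locus. If
#' explicit panel individuals are not supplied, individuals with genome-wide
#' ancestry below `q_low` (coastal proxies) and above `q_high` (inland
#' proxies) are used.
#'
#' @param x an [aim_matrix()].
#' @param coastal_ids,inland_ids optional individual ids forming the panels.
#' @param q_low,q_high ancestry thresholds for proxy panels (defaults 0.05
#'   and 0.95).
#' @return Data frame with `chrom`, `pos`, `coastal_mean`, `inland_mean`.
#' @export
panel_anchor_means <- function(x, coastal_ids = NULL, inland_ids = NULL,
                               q_low = 0.05, q_high = 0.95) {
  stopifnot(inherits(x, "aim_matrix"))
  if (is.null(coastal_ids) || is.null(inland_ids)) {
    q <- suppressWarnings(genome_wide_ancestry(x))
    if (is.null(coastal_ids)) coastal_ids <- x$individual_ids[!is.na(q) & q < q_low]
    if (is.null(inland_ids)) inland_ids <- x$individual_ids[!is.na(q) & q > q_high]
  }
  if (!length(coastal_ids) || !length(inland_ids))
    stop("no parental panel individuals available for anchor means")
  cm <- colMeans(subset_individuals(x, coastal_ids), na.rm = TRUE)
  um <- colMeans(subset_individuals(x, inland_ids), na.rm = TRUE)
  data.frame(chrom = x$loci$chrom, pos = x$loci$pos,
             coastal_mean = cm, inland_mean = um, row.names = NULL)
}

#' Per-pair ancestry-mismatch viability scan
#'
#' For each locus pair, the per-individual mismatch distance is the response
#' of a Poisson log-link GLM with the same design as [het_scan()]
#' (ancestry, age, sex, ancestry-by-age). The Poisson family is applied to
#' the continuous non-negative distance as quasi-likelihood estimating
#' equations with dispersion fixed at 1. BH q-values are computed per term
#' in the same autosome/Z strata (a pair is assigned to the Z stratum when
#' either locus is on the Z).
#'
#' @param x an [aim_matrix()].
#' @param meta sample metadata as in [het_scan()].
#' @param pairs 2-column matrix/data frame of locus column indices, or
#'   `"all"` for every pair (requires `allow_all = TRUE`; the full pair
#'   universe is quadratic in loci).
#' @param panel_means anchor table from [panel_anchor_means()]; computed
#'   from proxy panels when `NULL`.
#' @param allow_all gate for `pairs = "all"`.
#' @param min_cases minimum complete cases per pair (default 20).
#' @param alpha FDR threshold for the outlier flags (default 0.05).
#' @return A `scan_result` data frame, one row per pair, with locus-pair
#'   coordinates, anchor coordinates, per-term `beta_`/`p_`/`q_`/`sig_`
#'   columns and skip flags (`degenerate_anchors`, `constant_response`, ...).
#' @export
pair_scan <- function(x, meta, pairs, panel_means = NULL,
                      allow_all = FALSE, min_cases = 20, alpha = 0.05) {
  stopifnot(inherits(x, "aim_matrix"))
  n_loci <- ncol(x$states)
  if (identical(pairs, "all")) {
    if (!allow_all)
      stop(sprintf(paste0("pairs = \"all\" would scan %d pairs; set ",
                          "allow_all = TRUE or supply a pair list"),
                   choose(n_loci, 2)))
    pairs <- t(utils::combn(n_loci, 2))
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2 || nrow(pairs) == 0) stop("empty or malformed pair list")
  if (any(pairs < 1 | pairs > n_loci)) stop("pair indices out of range")
  if (is.null(panel_means)) panel_means <- panel_anchor_means(x)
  idx <- match(x$individual_ids, meta$individual_id)
  if (anyNA(idx)) stop("`meta` must cover every individual in the matrix")
  meta <- meta[idx, , drop = FALSE]
  X_all <- scan_design(meta)
  terms <- c("ancestry", "age", "sex", "ancestry_age")
  res <- data.frame(
    locus_i = pairs[, 1], locus_j = pairs[, 2],
    chrom_i = x$loci$chrom[pairs[, 1]], pos_i = x$loci$pos[pairs[, 1]],
    chrom_j = x$loci$chrom[pairs[, 2]], pos_j = x$loci$pos[pairs[, 2]],
    is_z = x$loci$is_z[pairs[, 1]] | x$loci$is_z[pairs[, 2]],
    stringsAsFactors = FALSE)
  for (t in terms) {
    res[[paste0("beta_", t)]] <- NA_real_
    res[[paste0("p_", t)]] <- NA_real_
  }
  res$n_used <- NA_integer_
  res$converged <- NA
  res$flag <- ""
  n_skipped <- 0L
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    ca <- c(panel_means$coastal_mean[i], panel_means$coastal_mean[j])
    ua <- c(panel_means$inland_mean[i], panel_means$inland_mean[j])
    if (anyNA(c(ca, ua)) || sum((ua - ca)^2) == 0) {
      res$flag[k] <- "degenerate_anchors"; n_skipped <- n_skipped + 1L; next
    }
    d <- mismatch_distance(cbind(x$states[, i], x$states[, j]), ca, ua)
    ok <- !is.na(d) & stats::complete.cases(X_all)
    if (sum(ok) < min_cases) {
      res$flag[k] <- "too_few_cases"; n_skipped <- n_skipped + 1L; next
    }
    if (stats::sd(d[ok]) == 0) {
      res$flag[k] <- "constant_response"; n_skipped <- n_skipped + 1L; next
    }
    fit <- fit_glm_irls(d[ok], X_all[ok, , drop = FALSE], "poisson")
    res <- fill_scan_row(res, k, fit, terms)
  }
  if (n_skipped) message(sprintf("pair_scan: %d pair(s) skipped", n_skipped))
  finalize_scan(res, terms, alpha)
}

#' Cross-chromosome mismatch pairs below a raw-p threshold
#'
#' The paper-style report of between-chromosome locus pairs whose unadjusted
#' p-value for a chosen term falls below `alpha_raw`.
#'
#' @param scan a `scan_result` from [pair_scan()].
#' @param term model term whose raw p-value is thresholded (default
#'   `"ancestry_age"`).
#' @param alpha_raw raw p-value threshold (strict `<`; default 0.05).
#' @return List with `pairs` (the qualifying cross-chromosome rows) and
#'   `counts` (a data frame of counts per chromosome pair).
#' @export
interchrom_report <- function(scan, term = "ancestry_age", alpha_raw = 0.05) {
  terms <- attr(scan, "terms")
  if (!term %in% terms)
    stop("unknown term; available: ", paste(terms, collapse = ", "))
  p <- scan[[paste0("p_", term)]]
  sel <- scan$chrom_i != scan$chrom_j & !is.na(p) & p < alpha_raw
  hits <- scan[sel, , drop = FALSE]
  if (nrow(hits)) {
    key <- paste(pmin(hits$chrom_i, hits$chrom_j),
                 pmax(hits$chrom_i, hits$chrom_j), sep = "|")
    tab <- table(key)
    counts <- data.frame(
      chrom_a = sub("\\|.*", "", names(tab)),
      chrom_b = sub(".*\\|", "", names(tab)),
      n_pairs = as.integer(tab), row.names = NULL)
  } else {
    counts <- data.frame(chrom_a = character(), chrom_b = character(),
                         n_pairs = integer())
  }
  list(pairs = hits, counts = counts)
}
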