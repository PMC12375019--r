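#' Linkage blocks around focal loci
#'
#' For each focal locus, the block interval spans from the minimum to the
#' maximum position of same-chromosome loci whose dosage r-squared with the
#' focal locus strictly exceeds `r2_threshold` (the focal locus included).
#' A monomorphic focal locus yields a zero-width block with a flag.
#'
#' @param x an [aim_matrix()].
#' @param focal focal locus column indices.
#' @param r2_threshold r-squared threshold (strict `>`; default 0.5).
#' @return Data frame with `focal`, `chrom`, `focal_pos`, `start`, `end`,
#'   `n_members` and `flag`; `members` (locus indices) is attached as a
#'   list column.
#' @export
ld_blocks <- function(x, focal, r2_threshold = 0.5) {
  stopifnot(inherits(x, "aim_matrix"))
  if (any(focal < 1 | focal > ncol(x$states))) stop("focal index out of range")
  out <- data.frame(focal = focal,
                    chrom = x$loci$chrom[focal],
                    focal_pos = x$loci$pos[focal],
                    start = NA_integer_, end = NA_integer_,
                    n_members = NA_integer_, flag = "",
                    stringsAsFactors = FALSE)
  members <- vector("list", length(focal))
  for (k in seq_along(focal)) {
    f <- focal[k]
    same <- which(x$loci$chrom == x$loci$chrom[f])
    y <- x$states[, f]
    if (stats::sd(y, na.rm = TRUE) %in% c(0, NA)) {
      out$start[k] <- out$end[k] <- x$loci$pos[f]
      out$n_members[k] <- 1L
      out$flag[k] <- "monomorphic_focal"
      members[[k]] <- f
      next
    }
    r2 <- suppressWarnings(
      stats::cor(y, x$states[, same, drop = FALSE],
                 use = "pairwise.complete.obs"))^2
    linked <- same[!is.na(r2) & r2 > r2_threshold]
    linked <- union(linked, f)
    out$start[k] <- min(x$loci$pos[linked])
    out$end[k] <- max(x$loci$pos[linked])
    out$n_members[k] <- length(linked)
    members[[k]] <- sort(linked)
  }
  out$members <- members
  out
}

#' Genes overlapping linkage blocks
#'
#' Assigns a gene to a block when their intervals (1-based, closed) overlap
#' by at least one base pair on the same chromosome. The union counts each
#' gene once.
#'
#' @param blocks block table from [ld_blocks()].
#' @param annotation data frame with `gene`, `chrom`, `start`, `end`
#'   (1-based closed; see [read_gene_annotation()] for BED/GFF3 input).
#' @return List with `per_block` (character vector of gene ids per block)
#'   and `union` (unique gene ids across blocks).
#' @export
genes_in_blocks <- function(blocks, annotation) {
  need <- c("gene", "chrom", "start", "end")
  if (!all(need %in% names(annotation)))
    stop("`annotation` must have columns ", paste(need, collapse = ", "))
  if (any(annotation$start > annotation$end))
    stop("annotation intervals must have start <= end")
  unmatched <- setdiff(unique(blocks$chrom), unique(annotation$chrom))
  if (length(unmatched))
    warning(sprintf("%d block chromosome(s) absent from annotation: %s",
                    length(unmatched), paste(unmatched, collapse = ", ")))
  gr_genes <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start, annotation$end))
  gr_blocks <- GenomicRanges::GRanges(
    blocks$chrom, IRanges::IRanges(blocks$start, blocks$end))
  # seqlevel-mismatch chatter is handled by the explicit warning above
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_blocks, gr_genes))
  per_block <- vector("list", nrow(blocks))
  for (k in seq_len(nrow(blocks))) per_block[[k]] <- character()
  sp <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  for (qs in names(sp))
    per_block[[as.integer(qs)]] <- unique(annotation$gene[sp[[qs]]])
  list(per_block = per_block,
       union = unique(unlist(per_block, use.names = FALSE)))
}

#' Expected candidate-gene overlap under random draws
#'
#' With `a` of `b` linkage-block genes associated with viability and `c`
#' candidate genes drawn from the block-gene universe, the expected overlap
#' is `(a/b) * c`.
#'
#' @param a number of viability-associated block genes.
#' @param b total number of block genes (`> 0`).
#' @param c_candidates number of candidate genes.
#' @return List with `expected` (real) and `expected_rounded`.
#' @export
overlap_expectation <- function(a, b, c_candidates) {
  if (b <= 0) stop("`b` must be positive")
  if (a < 0 || a > b) stop("need 0 <= a <= b")
  if (c_candidates < 0) stop("`c_candidates` must be non-negative")
  e <- (a / b) * c_candidates
  list(expected = e, expected_rounded = round(e))
}

#' Chi-square test of candidate-gene overlap
#'
#' One-degree-of-freedom goodness-of-fit over the `c` candidates split into
#' overlapping / non-overlapping categories with expected proportions
#' `a/b` and `1 - a/b`. An exact binomial tail is reported as a cross-check.
#'
#' @param observed observed overlap count (`0 <= observed <= c_candidates`).
#' @inheritParams overlap_expectation
#' @return List with `statistic`, `df`, `p_value`, `expected`, and
#'   `p_binomial` (two-sided exact binomial cross-check).
#' @export
overlap_chisq <- function(observed, a, b, c_candidates) {
  e <- overlap_expectation(a, b, c_candidates)$expected
  if (observed < 0 || observed > c_candidates)
    stop("need 0 <= observed <= c_candidates")
  if (e == 0 || c_candidates - e == 0)
    stop("degenerate expectation (0 or c)")
  stat <- (observed - e)^2 / e +
    ((c_candidates - observed) - (c_candidates - e))^2 / (c_candidates - e)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  pb <- stats::binom.test(observed, c_candidates, p = a / b)$p.value
  list(statistic = stat, df = 1L, p_value = p, expected = e, p_binomial = pb)
}

#' Wilcoxon rank-sum contrast of recombination rates
#'
#' Two-sided unpaired rank-sum test comparing window recombination rates in
#' outlier versus non-outlier windows. Uses exact enumeration over all
#' group assignments (with midrank ties) when both groups have at most
#' `exact_max` observations, and a tie-corrected normal approximation
#' otherwise. The reported `W` is the Mann-Whitney statistic for the
#' outlier group, as in `wilcox.test`.
#'
#' @param rates numeric vector of per-window rates.
#' @param outlier logical vector flagging outlier windows.
#' @param exact_max largest per-group size for exact enumeration (default 10).
#' @return List with `W`, `p_value` and `method`.
#' @export
recomb_contrast <- function(rates, outlier, exact_max = 10) {
  if (length(rates) != length(outlier)) stop("length mismatch")
  ok <- !is.na(rates) & !is.na(outlier)
  g1 <- rates[ok & outlier]
  g2 <- rates[ok & !outlier]
  if (!length(g1) || !length(g2)) stop("both groups must be non-empty")
  rank_sum_test(g1, g2, exact_max)
}

rank_sum_test <- function(g1, g2, exact_max = 10) {
  n1 <- length(g1); n2 <- length(g2); n <- n1 + n2
  r <- rank(c(g1, g2))  # midranks
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    subsets <- utils::combn(n, n1)
    u_all <- colSums(matrix(r[subsets], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_all <= u_obs + eps),
                        mean(u_all >= u_obs - eps)))
    return(list(W = u_obs, p_value = p, method = "exact enumeration"))
  }
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (u_obs - n1 * n2 / 2) / sqrt(sigma2)
  list(W = u_obs, p_value = 2 * stats::pnorm(-abs(z)),
       method = "normal approximation with tie correction")
}
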