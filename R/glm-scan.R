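#' Fit a GLM by iteratively reweighted least squares
#'
#' Maximum-likelihood GLM fit with dispersion fixed at 1, for the two
#' families the viability scans use: binomial with logit link and Poisson
#' with log link. The Poisson path accepts non-integer non-negative
#' responses (quasi-likelihood estimating equations; coefficients and Wald
#' tests are unchanged). Wald two-sided p-values use the standard normal.
#'
#' Apparent complete separation in the binomial family (any coefficient
#' beyond 30 on the logit scale) is flagged: the fit is marked
#' non-converged and its p-values are set to missing.
#'
#' @param y response vector (binary for binomial; non-negative for Poisson).
#' @param X design matrix including the intercept column; rows with missing
#'   values must be dropped beforehand.
#' @param family `"binomial"` (logit link) or `"poisson"` (log link).
#' @param epsilon convergence tolerance on the maximum absolute coefficient
#'   change (default 1e-8).
#' @param max_iter maximum IRLS iterations (default 100).
#' @return A list of class `glm_fit` with `coefficients`, `se`, `z`, `p`
#'   (per design column; `NA` for aliased columns), `loglik`, `converged`,
#'   `separation`, `aliased` and `n_used`.
#' @export
fit_glm_irls <- function(y, X, family = c("binomial", "poisson"),
                         epsilon = 1e-8, max_iter = 100) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (length(y) == 0) stop("empty response")
  if (nrow(X) != length(y)) stop("rows(X) must equal length(y)")
  if (anyNA(y) || anyNA(X)) stop("drop incomplete rows before fitting")
  fam <- if (family == "binomial") stats::binomial("logit")
         else stats::poisson("log")
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = fam,
    control = stats::glm.control(epsilon = min(epsilon, 1e-12),
                                 maxit = max_iter)))
  beta <- fit$coefficients
  aliased <- is.na(beta)
  p_cols <- ncol(X)
  # covariance from the final weighted least-squares problem, dispersion 1
  se <- rep(NA_real_, p_cols)
  if (fit$rank > 0) {
    Rmat <- fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
    Rmat[lower.tri(Rmat)] <- 0
    cov_est <- chol2inv(Rmat)
    est_cols <- fit$qr$pivot[seq_len(fit$rank)]
    se[est_cols] <- sqrt(diag(cov_est))
  }
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  mu <- fit$fitted.values
  loglik <- if (family == "binomial") {
    sum(y * log(mu) + (1 - y) * log1p(-mu))
  } else {
    # quasi log-likelihood kernel; equals the Poisson log-likelihood up to
    # the lgamma(y+1) term, which we include when y is integral
    ll <- sum(y * log(pmax(mu, .Machine$double.xmin)) - mu)
    if (all(y == round(y))) ll - sum(lgamma(y + 1)) else ll
  }
  separation <- family == "binomial" && any(abs(beta) > 30, na.rm = TRUE)
  converged <- fit$converged && !separation
  if (separation) p[] <- NA_real_
  names(beta) <- names(se) <- names(z) <- names(p) <- colnames(X)
  structure(list(coefficients = beta, se = se, z = z, p = p,
                 loglik = loglik, converged = converged,
                 separation = separation, aliased = aliased,
                 n_used = length(y)),
            class = "glm_fit")
}

#' Stratified Benjamini-Hochberg FDR adjustment
#'
#' BH step-up q-values computed independently within each stratum (the scan
#' uses two strata: pooled autosomes, and the Z chromosome alone). Missing
#' p-values are ignored and returned as missing.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (NA allowed).
#' @param strata stratum labels, one per p-value; `NULL` for a single stratum.
#' @return q-values in the original order.
#' @export
fdr_adjust <- function(pvals, strata = NULL) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (is.null(strata)) strata <- rep(1L, length(pvals))
  if (length(strata) != length(pvals))
    stop("`strata` must match `pvals` in length")
  q <- rep(NA_real_, length(pvals))
  for (s in unique(strata)) {
    sel <- which(strata == s & !is.na(pvals))
    if (length(sel)) q[sel] <- stats::p.adjust(pvals[sel], method = "BH")
  }
  q
}

scan_design <- function(meta, age_coding = "numeric") {
  need <- c("individual_id", "age", "sex", "ancestry_q")
  if (!all(need %in% names(meta)))
    stop("`meta` must have columns ", paste(need, collapse = ", "))
  sex <- ifelse(meta$sex == "M", 1, ifelse(meta$sex == "F", 0, NA))
  age <- as.numeric(meta$age)
  if (age_coding == "numeric") {
    X <- cbind(intercept = 1, ancestry = meta$ancestry_q, age = age,
               sex = sex, ancestry_age = meta$ancestry_q * age)
  } else {
    af <- stats::poly(age, degree = min(2, length(unique(age[!is.na(age)])) - 1))
    X <- cbind(intercept = 1, ancestry = meta$ancestry_q, age = af[, 1],
               age_quad = if (ncol(af) > 1) af[, 2] else NULL, sex = sex,
               ancestry_age = meta$ancestry_q * af[, 1])
  }
  X
}

#' Per-locus viability-selection scan on interspecific heterozygosity
#'
#' Fits, for every locus, a binomial-logit GLM of the locus heterozygosity
#' indicator on genome-wide ancestry, age class (numeric 0/1/2 by default),
#' sex, and the ancestry-by-age interaction; then computes BH q-values per
#' model term in two strata (autosomes pooled; Z chromosome alone).
#'
#' @param x an [aim_matrix()].
#' @param meta data frame with columns `individual_id`, `age` (0 = HY,
#'   1 = SY, 2 = ASY), `sex` (`"F"`/`"M"`/`"U"`), `ancestry_q`. Unknown-sex
#'   individuals are dropped.
#' @param age_coding `"numeric"` (single linear age coefficient, the
#'   default) or `"factor"` (orthogonal-polynomial contrasts; the reported
#'   age term is the linear contrast).
#' @param min_cases minimum complete cases per locus (default 20); loci
#'   below this, or with a monomorphic response, are skipped with a flag.
#' @param alpha FDR threshold recorded in the outlier flags (default 0.05).
#' @return A data frame of class `scan_result`: one row per locus with
#'   chromosome, position, `is_z`, per-term coefficients (`beta_*`), raw
#'   p-values (`p_*`), stratified q-values (`q_*`), outlier flags
#'   (`sig_*`, strict `q < alpha`), `n_used`, `converged` and `flag`.
#' @export
het_scan <- function(x, meta, age_coding = c("numeric", "factor"),
                     min_cases = 20, alpha = 0.05) {
  stopifnot(inherits(x, "aim_matrix"))
  age_coding <- match.arg(age_coding)
  idx <- match(x$individual_ids, meta$individual_id)
  if (anyNA(idx)) stop("`meta` must cover every individual in the matrix")
  meta <- meta[idx, , drop = FALSE]
  X_all <- scan_design(meta, age_coding)
  terms <- c("ancestry", "age", "sex", "ancestry_age")
  n_loci <- ncol(x$states)
  res <- make_scan_frame(x$loci, terms, n_loci)
  any_fit <- FALSE
  for (l in seq_len(n_loci)) {
    yv <- interspecific_het_vector(x, l)
    ok <- !is.na(yv) & stats::complete.cases(X_all)
    if (sum(ok) < min_cases) { res$flag[l] <- "too_few_cases"; next }
    if (length(unique(yv[ok])) < 2) { res$flag[l] <- "monomorphic"; next }
    fit <- fit_glm_irls(yv[ok], X_all[ok, , drop = FALSE], "binomial")
    res <- fill_scan_row(res, l, fit, terms)
    any_fit <- TRUE
  }
  if (!any_fit) stop("no valid loci to scan")
  finalize_scan(res, terms, alpha)
}

make_scan_frame <- function(loci, terms, n) {
  res <- data.frame(chrom = loci$chrom, pos = loci$pos, is_z = loci$is_z,
                    stringsAsFactors = FALSE)
  for (t in terms) {
    res[[paste0("beta_", t)]] <- NA_real_
    res[[paste0("p_", t)]] <- NA_real_
  }
  res$n_used <- NA_integer_
  res$converged <- NA
  res$flag <- ""
  res
}

fill_scan_row <- function(res, l, fit, terms) {
  for (t in terms) {
    res[[paste0("beta_", t)]][l] <- fit$coefficients[[t]]
    res[[paste0("p_", t)]][l] <- fit$p[[t]]
  }
  res$n_used[l] <- fit$n_used
  res$converged[l] <- fit$converged
  if (fit$separation) res$flag[l] <- "separation"
  res
}

finalize_scan <- function(res, terms, alpha) {
  strata <- ifelse(res$is_z, "Z", "autosome")
  for (t in terms) {
    res[[paste0("q_", t)]] <- fdr_adjust(res[[paste0("p_", t)]], strata)
    res[[paste0("sig_", t)]] <- !is.na(res[[paste0("q_", t)]]) &
      res[[paste0("q_", t)]] < alpha
  }
  attr(res, "terms") <- terms
  attr(res, "alpha") <- alpha
  class(res) <- c("scan_result", class(res))
  res
}

#' Extract outlier loci from a scan
#'
#' Loci with FDR-adjusted q strictly below `alpha` for the given model term,
#' sorted by q.
#'
#' @param scan a `scan_result` from [het_scan()].
#' @param term one of the fitted terms (e.g. `"age"`, `"ancestry_age"`).
#' @param alpha significance threshold (strict `<`; default 0.05).
#' @return The outlier rows of `scan`, ordered by increasing q.
#' @export
outlier_loci <- function(scan, term, alpha = 0.05) {
  terms <- attr(scan, "terms")
  if (!term %in% terms)
    stop("unknown term; available: ", paste(terms, collapse = ", "))
  q <- scan[[paste0("q_", term)]]
  out <- scan[!is.na(q) & q < alpha, , drop = FALSE]
  out[order(out[[paste0("q_", term)]]), , drop = FALSE]
}
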