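test_that("aim_matrix validates states and sorts loci", {
  x <- aim_matrix(matrix(c(0, 1, 2, NA), 2, 2),
                  data.frame(chrom = c("chr2", "chr1"), pos = c(10, 5)))
  expect_equal(x$loci$chrom, c("chr1", "chr2"))
  expect_equal(x$loci$pos, c(5L, 10L))
  expect_error(aim_matrix(matrix(3, 1, 1), data.frame(chrom = "c", pos = 1)),
               "0, 1, 2 or NA")
  expect_error(aim_matrix(matrix(0, 1, 2),
                          data.frame(chrom = c("c", "c"), pos = c(3, 3))),
               "unique")
})

test_that("posterior hard-calling uses a strict threshold", {
  post <- array(0, c(3, 1, 3))
  post[1, 1, ] <- c(0.02, 0.03, 0.95)   # clear call: state 2
  post[2, 1, ] <- c(0.3, 0.4, 0.3)      # ambiguous: missing
  post[3, 1, ] <- c(0.05, 0.90, 0.05)   # exactly 0.9 is not > 0.9
  x <- harden_posteriors(post, data.frame(chrom = "chr1", pos = 1:3), "i1")
  expect_equal(unname(x$states[1, ]), c(2L, NA, NA))
})

test_that("malformed posterior triples are rejected with coordinates", {
  post <- array(1 / 3, c(2, 2, 3))
  post[2, 1, ] <- c(0.5, 0.1, 0.1)
  expect_error(harden_posteriors(post, data.frame(chrom = "c", pos = 1:2),
                                 c("a", "b")),
               "locus 2, individual a")
  post[2, 1, ] <- c(-0.1, 0.6, 0.5)
  expect_error(harden_posteriors(post, data.frame(chrom = "c", pos = 1:2),
                                 c("a", "b")),
               "negative")
})

test_that("AIM selection retains loci strictly above the frequency difference", {
  panel <- data.frame(
    chrom = "chr1", pos = 1:3,
    coastal_ref = c(2, 5, 0), coastal_alt = c(18, 15, 20),
    inland_ref = c(14, 15, 20), inland_alt = c(6, 5, 0))
  res <- select_aims(panel)
  # diffs: 0.6 (kept), exactly 0.5 (dropped, strict), 1.0 (kept)
  expect_equal(res$retained, c(TRUE, FALSE, TRUE))
  empty <- data.frame(chrom = "chr1", pos = 9, coastal_ref = 0,
                      coastal_alt = 0, inland_ref = 10, inland_alt = 10)
  expect_warning(res2 <- select_aims(empty), "zero observed")
  expect_true(is.na(res2$retained))
})

test_that("ancestry and heterozygosity reproduce the canonical examples", {
  x <- toy_aim(rbind(rep(0, 4), rep(1, 4), rep(2, 4), c(0, 1, 2, 2)))
  q <- genome_wide_ancestry(x)
  expect_equal(unname(q), c(0, 0.5, 1, 0.625))
  h <- individual_heterozygosity(x)
  expect_equal(unname(h), c(0, 1, 0, 0.25))
  expect_equal(unname(individual_heterozygosity(toy_aim(rbind(c(0, 1, 2, 1))))),
               0.5)
  expect_equal(unname(individual_heterozygosity(toy_aim(rbind(c(0, 2, 0, 2))))),
               0)
})

test_that("summaries ignore missing loci and are locus-order invariant", {
  s <- rbind(c(0, NA, 2, 1), c(NA, NA, NA, NA))
  x <- toy_aim(s)
  expect_warning(q <- genome_wide_ancestry(x), "missing at all loci")
  expect_equal(unname(q[1]), mean(c(0, 2, 1)) / 2)
  expect_true(is.na(q[2]))
  # permuting loci changes nothing (construction re-sorts by position)
  perm <- c(3, 1, 4, 2)
  x2 <- toy_aim(s[, perm], pos = (1:4 * 1000)[perm])
  expect_equal(suppressWarnings(genome_wide_ancestry(x2)),
               suppressWarnings(genome_wide_ancestry(x)))
})

test_that("interspecific het vector collapses states and propagates missing", {
  x <- toy_aim(rbind(c(0, 1), c(1, 2), c(2, NA)))
  expect_equal(interspecific_het_vector(x, 1), c(0L, 1L, 0L))
  expect_equal(interspecific_het_vector(x, 2), c(1L, 0L, NA))
})

test_that("dosage r2 handles correlation sign, symmetry and degeneracy", {
  x <- toy_aim(cbind(c(0, 1, 2, 0), c(2, 1, 0, 2), c(0, 0, 2, 2),
                     c(0, 2, 0, 2), c(1, 1, 1, 1)))
  expect_equal(dosage_r2(x, 1, 1), 1)
  expect_equal(dosage_r2(x, 1, 2), 1)              # perfect negative corr
  expect_equal(dosage_r2(x, 3, 4), 0)              # orthogonal
  expect_equal(dosage_r2(x, 1, 3), dosage_r2(x, 3, 1))
  expect_true(is.na(dosage_r2(x, 1, 5)))           # monomorphic
})

test_that("dosage r2 is invariant to polarity swap at either locus", {
  set.seed(42)
  for (rep in 1:20) {
    a <- sample(0:2, 15, replace = TRUE)
    b <- sample(0:2, 15, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    x1 <- toy_aim(cbind(a, b))
    x2 <- toy_aim(cbind(2 - a, b))
    x3 <- toy_aim(cbind(a, 2 - b))
    expect_equal(dosage_r2(x2, 1, 2), dosage_r2(x1, 1, 2), tolerance = 1e-12)
    expect_equal(dosage_r2(x3, 1, 2), dosage_r2(x1, 1, 2), tolerance = 1e-12)
  }
})

test_that("LD pruning removes duplicates, rare loci, and is a fixed point", {
  set.seed(7)
  base <- matrix(sample(0:2, 30 * 8, replace = TRUE, prob = c(.3, .4, .3)),
                 30, 8)
  base[, 2] <- base[, 1]                     # duplicate pair
  rare <- c(rep(0, 29), 1)                   # minor-state freq 1/60 < 0.05
  states <- cbind(base, rare)
  x <- toy_aim(states, pos = 1:9 * 1000)
  kept <- ld_prune(x, window_snps = 9, step_snps = 2, r2_max = 0.2)
  expect_false(9 %in% kept)                  # rare locus gone
  expect_false(all(c(1, 2) %in% kept))       # one duplicate gone
  expect_true(xor(1 %in% kept, 2 %in% kept))
  # re-pruning the pruned set changes nothing
  x2 <- toy_aim(states[, kept, drop = FALSE], pos = (1:9 * 1000)[kept])
  kept2 <- ld_prune(x2, window_snps = 9, step_snps = 2, r2_max = 0.2)
  expect_equal(kept2, seq_along(kept))
  expect_error(ld_prune(x, window_snps = 1), "window_snps")
})

test_that("LD pruning is a no-op when all pairwise r2 is below threshold", {
  set.seed(101)
  repeat {  # draw until the triple is genuinely weakly correlated
    states <- matrix(sample(0:2, 30, replace = TRUE), 10, 3)
    x <- toy_aim(states)
    r2s <- c(dosage_r2(x, 1, 2), dosage_r2(x, 1, 3), dosage_r2(x, 2, 3))
    f <- colMeans(states) / 2
    if (!anyNA(r2s) && all(r2s <= 0.2) && all(pmin(f, 1 - f) >= 0.05)) break
  }
  expect_equal(ld_prune(x, window_snps = 3, step_snps = 1, r2_max = 0.2,
                        maf_min = 0.05), 1:3)
})
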