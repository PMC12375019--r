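test_that("LD blocks span linked loci with a strict r2 threshold", {
  set.seed(17)
  a <- sample(0:2, 40, replace = TRUE)
  noise <- sample(0:2, 40, replace = TRUE)
  # three duplicated (r2 = 1) loci; an unlinked neighbor
  x <- toy_aim(cbind(a, a, a, noise), pos = c(1e4, 2e4, 3e4, 4e4))
  b <- ld_blocks(x, focal = 2)
  expect_equal(b$start, 1e4)
  expect_equal(b$end, 3e4)
  expect_equal(b$n_members, 3L)
  # no linked neighbors: zero-width block
  b2 <- ld_blocks(x, focal = 4)
  expect_equal(c(b2$start, b2$end), c(4e4, 4e4))
  # monomorphic focal flagged
  x3 <- toy_aim(cbind(rep(2, 40), a), pos = c(1e4, 2e4))
  b3 <- ld_blocks(x3, focal = 1)
  expect_equal(b3$flag, "monomorphic_focal")
  expect_equal(b3$n_members, 1L)
})

test_that("a neighbor at exactly the r2 threshold is excluded", {
  # duplicated loci have r2 exactly 1: a threshold of 1 must exclude them
  a <- c(0, 0, 1, 1, 2, 2, 0, 2)
  x <- toy_aim(cbind(a, a), pos = c(1e4, 2e4))
  blk <- ld_blocks(x, focal = 1, r2_threshold = 1)   # strict >
  expect_equal(blk$n_members, 1L)
  blk2 <- ld_blocks(x, focal = 1, r2_threshold = 0.999)
  expect_equal(blk2$n_members, 2L)
})

test_that("gene assignment uses 1-bp closed-interval overlap and set union", {
  blocks <- data.frame(chrom = c("chr1", "chr1"),
                       start = c(100, 400), end = c(300, 600))
  annotation <- data.frame(
    gene = c("inside", "abut", "spanning", "elsewhere"),
    chrom = c("chr1", "chr1", "chr1", "chr9"),
    start = c(150, 301, 250, 100), end = c(200, 350, 450, 200))
  res <- genes_in_blocks(blocks, annotation)
  expect_setequal(res$per_block[[1]], c("inside", "spanning"))
  expect_setequal(res$per_block[[2]], "spanning")
  # "abut" starts 1 bp after block 1 ends: no overlap
  expect_false("abut" %in% unlist(res$per_block))
  # union counts the spanning gene once
  expect_setequal(res$union, c("inside", "spanning"))
  # block on a chromosome the annotation lacks triggers a named warning
  blocks2 <- rbind(blocks, data.frame(chrom = "chrUn", start = 1, end = 10))
  expect_warning(genes_in_blocks(blocks2, annotation), "chrUn")
})

test_that("overlap expectation reproduces the printed arithmetic", {
  e <- overlap_expectation(750, 1606, 358)
  expect_equal(e$expected_rounded, 167)
  expect_equal(e$expected, 750 / 1606 * 358, tolerance = 1e-12)
  expect_equal(overlap_expectation(0, 100, 50)$expected, 0)
  expect_equal(overlap_expectation(10, 100, 50)$expected, 5)
  expect_error(overlap_expectation(5, 0, 10), "positive")
  # linear in c and in a; invariant to common scaling of (a, b)
  expect_equal(overlap_expectation(10, 100, 100)$expected,
               2 * overlap_expectation(10, 100, 50)$expected)
  expect_equal(overlap_expectation(30, 300, 50)$expected,
               overlap_expectation(10, 100, 50)$expected)
})

test_that("overlap chi-square matches hand arithmetic and the z-statistic", {
  t0 <- overlap_chisq(observed = 10, a = 10, b = 100, c_candidates = 100)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  t1 <- overlap_chisq(observed = 30, a = 10, b = 100, c_candidates = 100)
  expect_equal(t1$statistic, 400 / 10 + 400 / 90, tolerance = 1e-12)
  # equals the squared one-sample proportion z-statistic
  p0 <- 0.1
  z <- (30 / 100 - p0) / sqrt(p0 * (1 - p0) / 100)
  expect_equal(t1$statistic, z^2, tolerance = 1e-12)
  # binomial cross-check is in rough agreement for strong signals
  expect_lt(t1$p_binomial, 1e-4)
  t2 <- overlap_chisq(observed = 232, a = 750, b = 1606, c_candidates = 358)
  expect_lt(t2$p_value, 1e-4)
  expect_error(overlap_chisq(5, 0, 100, 50), "degenerate")
})

test_that("rank-sum test reproduces exact enumeration results", {
  # the most extreme split of {1..6}: 2 of 20 orderings as or more extreme
  r <- recomb_contrast(c(1, 2, 3, 4, 5, 6),
                       c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact enumeration")
  # identical groups: all assignments equivalent
  r2 <- recomb_contrast(rep(5, 6), rep(c(TRUE, FALSE), each = 3))
  expect_equal(r2$p_value, 1)
})

test_that("rank-sum implementation matches the enumeration oracle up to n=8", {
  set.seed(18)
  for (n1 in c(2, 3, 5, 8)) for (n2 in c(2, 4, 8)) {
    for (rep in 1:3) {
      g1 <- sample(1:6, n1, replace = TRUE)   # ties guaranteed possible
      g2 <- sample(1:6, n2, replace = TRUE)
      got <- recomb_contrast(c(g1, g2),
                             c(rep(TRUE, n1), rep(FALSE, n2)))
      expect_equal(got$p_value, rank_sum_oracle(g1, g2), tolerance = 1e-12,
                   label = sprintf("n1=%d n2=%d rep=%d", n1, n2, rep))
    }
  }
})

test_that("large-sample path agrees with wilcox.test on tie-free data", {
  set.seed(19)
  g1 <- rnorm(30)
  g2 <- rnorm(40, 0.5)
  got <- recomb_contrast(c(g1, g2), c(rep(TRUE, 30), rep(FALSE, 40)))
  ref <- stats::wilcox.test(g1, g2, exact = FALSE, correct = FALSE)
  expect_equal(got$W, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_error(recomb_contrast(g1, rep(TRUE, 30)), "non-empty")
})

test_that("simulated recombination map separates inversion windows", {
  cfg <- sim_config(n_individuals = 10, seed = 23)
  map <- simulate_recomb_map(cfg, noise_sd = 0)
  inv <- map$in_inversion
  expect_true(all(map$rate[inv] == 0.5))
  expect_true(all(map$rate[!inv] == 5))
  expect_equal(sum(inv & map$chrom == "chr5"), sum(inv))
  expect_equal(sum(inv), 160)  # 16 Mb inversion / 100 kb windows
  r <- recomb_contrast(map$rate, inv)
  expect_lt(r$p_value, 1e-3)
  # no inversion: single-valued map
  cfg0 <- sim_config(n_individuals = 10, inversion = NULL, seed = 23)
  map0 <- simulate_recomb_map(cfg0, noise_sd = 0)
  expect_true(all(map0$rate == 5))
})
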