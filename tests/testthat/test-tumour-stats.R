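# Upper limit of normal, over-editing calls and prevalence, pileup editing
# levels, size factors, Fisher-z intervals and logistic detection models.

test_that("small reference groups pool into 'other'", {
  g <- c(rep("liver", 20), rep("pleura", 2), rep("eye", 3))
  pooled <- pool_small_groups(g)
  expect_equal(sum(pooled == "liver"), 20L)
  expect_equal(sum(pooled == "other"), 5L)
  expect_false(any(pooled %in% c("pleura", "eye")))
  big <- rep(c("a", "b"), c(10, 10))
  expect_equal(pool_small_groups(big), big)
  tiny <- rep(c("a", "b"), c(2, 3))
  expect_true(all(pool_small_groups(tiny) == "other"))
})

test_that("ULN is the maximum organ-level 95th percentile", {
  values <- c(1:20, seq(2, 20, by = 2))
  groups <- rep(c("A", "B"), c(20, 10))
  res <- compute_uln(values, groups)
  # hand-computed linear-interpolation percentiles:
  # A = 1..20 -> 1 + 0.95*19 = 19.05; B = 2,4,..,20 -> 18 + 0.55*2 = 19.1
  expect_equal(unname(res$per_group_p95["A"]), 19.05)
  expect_equal(unname(res$per_group_p95["B"]), 19.1)
  expect_equal(res$uln, 19.1)
  # single group: ULN is its own P95
  one <- compute_uln(1:20, rep("A", 20))
  expect_equal(one$uln, 19.05)
  # invariant to permutations within groups
  set.seed(1)
  perm <- sample(seq_along(values))
  expect_equal(compute_uln(values[perm], groups[perm])$uln, res$uln)
  # scale equivariance
  expect_equal(compute_uln(3 * values, groups)$uln, 3 * res$uln)
  expect_error(compute_uln(c(NA, NA), c("A", "A")), "no healthy")
})

test_that("over-editing uses strict fold > 1 and a display-only 1/32 floor", {
  calls <- over_editing_calls(c(25, 10, 9, NA, 0.1), uln = 10)
  expect_equal(calls$fold_change[1], 2.5)
  expect_true(calls$over_edited[1])
  expect_false(calls$over_edited[2]) # exactly ULN is not over-edited
  expect_false(calls$over_edited[3])
  expect_false(calls$over_edited[4]) # undetected
  expect_equal(calls$display_value[4], 1 / 32)
  expect_equal(calls$display_value[5], 1 / 32) # below the floor
  expect_equal(calls$fold_change[5], 0.01)     # raw fold kept for analysis
  expect_error(over_editing_calls(1, uln = 0), "positive")
  # calls match a brute-force comparison oracle, and survive rescaling
  set.seed(7)
  v <- stats::rlnorm(200, 5, 1)
  u <- stats::quantile(v, 0.9, names = FALSE)
  got <- over_editing_calls(v, u)
  expect_equal(got$over_edited, v > u)
  rescaled <- over_editing_calls(10 * v, 10 * u)
  expect_equal(rescaled$over_edited, got$over_edited)
  expect_equal(rescaled$fold_change, got$fold_change)
})

test_that("prevalence percentages reproduce worked examples and recompute", {
  over <- c(rep(TRUE, 9), rep(FALSE, 13))
  p <- prevalence_by_group(over, rep("ovarian", 22))
  expect_equal(p$percent[p$group == "ovarian"], 41)
  over2 <- c(rep(TRUE, 36), rep(FALSE, 468))
  p2 <- prevalence_by_group(over2, rep("all", 504))
  expect_equal(p2$percent[p2$group == "overall"], 7)
  p3 <- prevalence_by_group(c(rep(TRUE, 210), rep(FALSE, 5896)),
                            rep("tcga", 6106), digits = 1)
  expect_equal(p3$percent[p3$group == "overall"], 3.4)
  expect_equal(prevalence_by_group(rep(FALSE, 10), rep("g", 10))$percent,
               c(0, 0))
  # every percentage recomputes from its own (k, n)
  set.seed(2)
  calls <- stats::runif(300) < 0.2
  groups <- sample(letters[1:5], 300, replace = TRUE)
  tab <- prevalence_by_group(calls, groups, digits = 1)
  expect_equal(tab$percent, floor(100 * tab$k / tab$n * 10 + 0.5) / 10)
})

test_that("pileup filtering matches a per-read loop and respects strand", {
  reads <- data.frame(
    base = c(rep("G", 3), rep("A", 7), "G"),
    base_quality = c(rep(30, 10), 19),   # one edited read fails base quality
    mapping_quality = rep(40, 11))
  res <- pileup_editing_level(reads, strand = "+")
  expect_equal(res$edited_reads, 3L)
  expect_equal(res$total_reads, 10L)
  expect_equal(res$excluded_reads, 1L)
  expect_equal(res$editing_fraction, 0.3)
  # minus strand: genomic C counts as edited
  reads_minus <- data.frame(base = c("C", "T", "T"), base_quality = 30,
                            mapping_quality = 40)
  expect_equal(pileup_editing_level(reads_minus, "-")$editing_fraction, 1 / 3)
  # no read passes -> undefined fraction, flagged
  lowq <- data.frame(base = "G", base_quality = 5, mapping_quality = 40)
  out <- pileup_editing_level(lowq, "+")
  expect_true(out$undefined)
  expect_true(is.na(out$editing_fraction))
  # brute-force agreement and planted-fraction recovery on simulated pileups
  for (seed in c(1, 2)) {
    sim <- simulate_pileup(depth = 1000, editing_fraction = 0.3, seed = seed)
    got <- pileup_editing_level(sim$reads, sim$truth$strand)
    oracle <- oracle_pileup(sim$reads, sim$truth$strand)
    expect_equal(got$edited_reads, oracle$edited)
    expect_equal(got$total_reads, oracle$total)
    ci <- stats::binom.test(got$edited_reads, got$total_reads)$conf.int
    expect_true(ci[1] <= 0.3 && 0.3 <= ci[2])
  }
})

test_that("size factors are median-of-ratios to the geometric-mean reference", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(NULL, c("A", "B")))
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- cbind(A = c(10, 20, 30), B = c(20, 40, 60))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))
  # scaling one sample by c multiplies its factor by c
  m3 <- m2; m3[, "B"] <- m3[, "B"] * 5
  expect_equal(unname(size_factors(m3))[2], sqrt(2) * 5 / sqrt(5))
  # genes with zeros are excluded from the reference
  m4 <- rbind(m2, c(0, 100))
  expect_equal(size_factors(m4), size_factors(m2))
  expect_error(size_factors(rbind(c(0, 1), c(1, 0))), "non-zero")
})

test_that("size factors agree with the DESeq implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(4)
  counts <- matrix(stats::rnbinom(500, mu = 100, size = 5), ncol = 5)
  counts[counts == 0] <- 1
  ours <- unname(size_factors(counts))
  ref <- unname(DESeq2::estimateSizeFactorsForMatrix(counts))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("Fisher-z intervals reproduce printed bounds and attain coverage", {
  ci1 <- fisher_ci(0.67, 39)
  expect_equal(round(ci1$ci_low, 2), 0.45)
  expect_equal(round(ci1$ci_high, 2), 0.81)
  ci2 <- fisher_ci(0.28, 8241)
  expect_equal(round(ci2$ci_low, 2), 0.26)
  expect_equal(round(ci2$ci_high, 2), 0.30)
  ci0 <- fisher_ci(0, 1000)
  expect_equal(ci0$ci_low, -ci0$ci_high)
  expect_true(fisher_ci(1, 10)$degenerate)
  expect_error(fisher_ci(0.5, 3), "n >= 4")
  # empirical coverage ~95% over bivariate-normal simulations at n = 40
  set.seed(12)
  rho <- 0.5
  hits <- vapply(seq_len(1000), function(i) {
    x <- stats::rnorm(40)
    y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(40)
    ci <- pearson_with_ci(x, y)
    ci$ci_low <= rho && rho <= ci$ci_high
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.95), 0.02)
})

test_that("pearson_with_ci drops incomplete and non-positive pairs when logging", {
  set.seed(3)
  x <- stats::rlnorm(50); y <- x * stats::rlnorm(50, 0, 0.2)
  x[c(3, 7)] <- NA; y[11] <- 0
  res <- pearson_with_ci(x, y, log_transform = TRUE)
  expect_equal(res$n, 47L)
  keep <- !is.na(x) & !is.na(y) & x > 0 & y > 0
  expect_equal(res$r, stats::cor(log(x[keep]), log(y[keep])))
})

test_that("logistic detection model recovers planted odds ratios", {
  # coefficient ln(3): truth inside the Wald 95% CI in >= 90% of seeds
  hits <- vapply(seq_len(100), function(seed) {
    d <- simulate_detection_data(n = 2000, seed = seed)
    f <- logistic_detection_model(d$detected, d$expression)
    se <- summary(f$fit)$coefficients[2, 2]
    ci <- f$coefficients$coefficient + c(-1.96, 1.96) * se
    ci[1] <= log(3) && log(3) <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # null predictor: OR near 1
  set.seed(33)
  d0 <- simulate_detection_data(n = 4000, beta = 0, beta0 = 0, seed = 33)
  f0 <- logistic_detection_model(d0$detected, d0$expression)
  expect_lt(abs(f0$coefficients$odds_ratio - 1), 0.15)
  expect_gt(f0$coefficients$p_value, 0.001)
  # degenerate outcomes
  expect_error(logistic_detection_model(rep(TRUE, 50), stats::runif(50)),
               "both")
  # complete separation is flagged, not thrown
  xx <- c(stats::runif(25, 0, 1), stats::runif(25, 10, 11))
  yy <- rep(c(FALSE, TRUE), each = 25)
  fs <- logistic_detection_model(yy, xx)
  expect_true(fs$separation)
  expect_false(fs$converged)
})

test_that("fold differences report magnitude and direction", {
  fd <- fold_difference(2.93, 0.073)
  expect_equal(round(fd$fold), 40)
  expect_equal(fd$direction, "higher in first")
  expect_equal(fold_difference(5, 5)$fold, 1)
  lower <- fold_difference(1, 4)
  expect_equal(lower$fold, 4)
  expect_equal(lower$direction, "lower in first")
  expect_error(fold_difference(0, 1), "positive")
})
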