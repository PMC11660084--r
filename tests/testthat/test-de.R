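test_that("median-of-ratios size factors match hand-computed values", {
  m <- matrix(c(2, 4, 4, 8, 8, 16), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  # geometric means per gene: 2.828, 5.657, 11.314; every ratio in column 1 is
  # 1/sqrt(2) and in column 2 sqrt(2)
  s <- estimate_size_factors(m)
  expect_equal(unname(s), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # a gene with a zero count is excluded from the reference set
  m2 <- rbind(m, g4 = c(0, 5))
  expect_equal(estimate_size_factors(m2), s)

  # identical columns give unit size factors
  m3 <- matrix(c(3, 3, 7, 7), nrow = 2, byrow = TRUE)
  expect_equal(unname(estimate_size_factors(m3)), c(1, 1))

  # no all-positive gene is an explicit failure, not a silent pseudocount
  expect_error(estimate_size_factors(matrix(c(0, 1, 1, 0), 2)),
               "no reference gene")
})

test_that("size factors agree with DESeq2 on simulated counts", {
  skip_if_not_installed("DESeq2")
  b <- default_sim_bundle()
  dds <- suppressMessages(DESeq2::estimateSizeFactorsForMatrix(b$counts))
  expect_equal(unname(b$sf), unname(dds), tolerance = 1e-8)
})

test_that("normalization divides columns by size factors", {
  m <- matrix(c(2, 4, 4, 8, 8, 16), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  s <- estimate_size_factors(m)
  norm <- normalize_counts(m, s)
  # both columns collapse onto the geometric means
  expect_equal(unname(norm[, 1]), c(2 * sqrt(2), 4 * sqrt(2), 8 * sqrt(2)),
               tolerance = 1e-12)
  expect_equal(norm[, 1], norm[, 2])
  expect_equal(normalize_counts(m, c(1, 1)), m)
  # doubling a column and its size factor leaves the result unchanged
  m2 <- m; m2[, 2] <- m2[, 2] * 2
  expect_equal(normalize_counts(m2, s * c(1, 2)), norm)
  expect_error(normalize_counts(m, c(1, 0)), "positive")
  expect_error(normalize_counts(m, 1), "length")
})

test_that("Wald contrast reproduces the worked single-gene example", {
  m <- matrix(c(100, 110, 90, 10, 9, 11), nrow = 1,
              dimnames = list("g1", paste0("s", 1:6)))
  tb <- nb_wald_contrast(m, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(tb$log2fc, log2(100.5 / 10.5), tolerance = 1e-12)
  expect_lt(tb$p, 1e-6)
})

test_that("Wald contrast handles degenerate groups per contract", {
  # identical groups: zero fold change, p = 1
  m <- matrix(rep(c(5, 7, 6), 2), nrow = 1,
              dimnames = list("g", paste0("s", 1:6)))
  tb <- nb_wald_contrast(m, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(tb$log2fc, 0)
  expect_equal(tb$p, 1)

  # all-zero gene: log2fc 0, p 1
  m0 <- matrix(0, nrow = 2, ncol = 6,
               dimnames = list(c("a", "b"), paste0("s", 1:6)))
  m0["b", ] <- c(9, 10, 11, 10, 9, 11)
  tb0 <- nb_wald_contrast(m0, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(tb0$log2fc[tb0$gene == "a"], 0)
  expect_equal(tb0$p[tb0$gene == "a"], 1)

  expect_error(nb_wald_contrast(m0, paste0("s", 1:3), paste0("s", 4:6),
                                genes = "zzz"), "absent")
  expect_error(nb_wald_contrast(m0, "s1", paste0("s", 4:6)),
               "at least two samples")
})

test_that("consistency: large balanced groups with a true 2-fold change
           approach log2fc 1 with vanishing p", {
  set.seed(42)
  n <- 200
  m <- matrix(c(rpois(n, 400), rpois(n, 200)), nrow = 1,
              dimnames = list("g", paste0("s", 1:(2 * n))))
  tb <- nb_wald_contrast(m, paste0("s", 1:n), paste0("s", (n + 1):(2 * n)))
  expect_equal(tb$log2fc, 1, tolerance = 0.05)
  expect_lt(tb$p, 1e-10)
})

test_that("swapping groups negates log2fc and preserves p exactly", {
  b <- default_sim_bundle()
  md <- b$sim$metadata
  a <- md$sample[md$treatment == "CA" & md$timepoint == 5]
  c2 <- md$sample[md$treatment == "MCP" & md$timepoint == 5]
  t1 <- nb_wald_contrast(b$norm, a, c2)
  t2 <- nb_wald_contrast(b$norm, c2, a)
  expect_equal(t1$log2fc, -t2$log2fc)
  expect_equal(t1$p, t2$p)
  expect_equal(t1$se, t2$se)
})

test_that("contrast results are invariant to sample rescaling after
           re-normalization", {
  b <- default_sim_bundle()
  md <- b$sim$metadata
  a <- md$sample[md$treatment == "CA" & md$timepoint == 2]
  c2 <- md$sample[md$treatment == "MCP" & md$timepoint == 2]
  base <- nb_wald_contrast(b$norm, a, c2)

  scaled <- b$counts
  scaled[, a[1]] <- scaled[, a[1]] * 3
  renorm <- normalize_counts(scaled, estimate_size_factors(scaled))
  again <- nb_wald_contrast(renorm, a, c2)
  # rescaling one sample shifts the geometric-mean reference, so all size
  # factors (and the normalized matrix) pick up a common factor 3^(1/n);
  # only the pseudocount is sensitive to that global scale
  expect_equal(base$log2fc, again$log2fc, tolerance = 1e-3)
  expect_equal(base$p, again$p, tolerance = 1e-3)
})

test_that("Bonferroni adjustment multiplies by family size and caps at 1", {
  expect_equal(adjust_bonferroni(c(0.01, rep(0.5, 9)))[1], 0.1)
  expect_equal(adjust_bonferroni(c(0.2, rep(0.5, 9)))[1], 1)
  expect_equal(adjust_bonferroni(rep(0, 3)), rep(0, 3))
  expect_error(adjust_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(adjust_bonferroni(c(-0.1)), "\\[0, 1\\]")
})

test_that("up-regulation calls are strict on both thresholds", {
  tb <- fake_table(c("a", "b", "c", "d"),
                   log2fc = c(1.0, 2.0, 2.0, 1.5),
                   padj = c(0.01, 0.049, 0.05, 0.04))
  up <- call_upregulated(tb)
  expect_false("a" %in% up) # log2fc exactly 1 excluded
  expect_true("b" %in% up)
  expect_false("c" %in% up) # padj exactly 0.05 excluded
  expect_true("d" %in% up)
})

test_that("null-simulation type-I rate is near nominal and the joint call is
           essentially never made", {
  set.seed(1)
  n <- 2000
  mu <- exp(runif(n, log(100), log(2000)))
  m <- matrix(rnbinom(n * 6, mu = rep(mu, 6), size = 1 / 0.1), nrow = n,
              dimnames = list(sprintf("N%04d", 1:n), paste0("s", 1:6)))
  tb <- nb_wald_contrast(m, paste0("s", 1:3), paste0("s", 4:6))
  rate <- mean(tb$p < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.10)
  expect_length(call_upregulated(tb), 0)
})
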