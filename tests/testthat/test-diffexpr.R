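test_that("median-of-ratios size factors match their definition", {
  counts <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
                   dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  sf <- size_factors(counts)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # identical samples give unit factors
  eq <- cbind(s1 = c(5, 7, 9), s2 = c(5, 7, 9))
  rownames(eq) <- letters[1:3]
  expect_equal(unname(size_factors(eq)), c(1, 1))

  # permuting gene order changes nothing
  set.seed(1)
  m <- matrix(rpois(60, 40) + 1, 20, 3,
              dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:3)))
  expect_equal(unname(size_factors(m)),
               unname(size_factors(m[sample(20), ])))

  # scaling one sample by c: its factor scales by c up to the geometric-mean
  # renormalization (exactly c^(1 - 1/n)), and relative factors scale by c
  m2 <- m
  m2[, 2] <- m2[, 2] * 3
  sf0 <- size_factors(m)
  sf3 <- size_factors(m2)
  expect_equal(unname(sf3[2] / sf0[2]), 3^(1 - 1 / 3), tolerance = 1e-12)
  expect_equal(unname(sf3[2] / sf3[1]), unname(3 * sf0[2] / sf0[1]),
               tolerance = 1e-12)

  # no all-positive gene -> informative error
  sparse <- matrix(c(0, 5, 5, 0), 2, 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(size_factors(sparse), "pseudo_reference")
})

test_that("the low-count filter removes genes below 10 total reads", {
  counts <- matrix(c(4, 5,   # total 9: removed
                     5, 5,   # total 10: retained
                     0, 0),
                   ncol = 2, byrow = TRUE,
                   dimnames = list(c("below", "at", "zero"), NULL))
  cm <- make_cm(counts, timepoint_h = c(0, 1))
  out <- filter_low_counts(cm)
  expect_identical(rownames(out$counts), "at")
  expect_setequal(attr(out, "removed"), c("below", "zero"))
  # empty in, empty out
  empty <- make_cm(counts[0, , drop = FALSE], timepoint_h = c(0, 1))
  expect_equal(nrow(filter_low_counts(empty)$counts), 0)
})

test_that("dispersion estimation recovers simulated dispersions", {
  set.seed(5)
  # Poisson data: final dispersion collapses towards zero at mu >= 100
  mu <- runif(400, 100, 1000)
  pois <- matrix(rpois(400 * 6, rep(mu, 6)), 400, 6)
  phi <- estimate_dispersion(pois, rep(c("a", "b"), each = 3))
  expect_lt(median(phi), 0.01)

  # NB with phi = 0.1 at n = 50: median gene-wise estimate in [0.05, 0.2]
  nb <- matrix(rnbinom(200 * 50, mu = rep(runif(200, 100, 500), 50),
                       size = 10), 200, 50)
  phi2 <- estimate_dispersion(nb, rep("a", 50))
  expect_gt(median(phi2), 0.05)
  expect_lt(median(phi2), 0.2)

  # constant counts give a zero gene-wise estimate before shrinkage
  const <- matrix(50, 5, 4)
  phi3 <- estimate_dispersion(const, rep(c("a", "b"), each = 2))
  expect_true(all(attr(phi3, "genewise") == 0))
})

test_that("the NB Wald test follows its stated formulas", {
  # identical groups: log2fc 0 and p near 1
  counts <- matrix(rep(c(100, 200, 400), each = 6), nrow = 3, byrow = TRUE,
                   dimnames = list(c("a", "b", "c"), NULL))
  cm <- make_cm(counts, timepoint_h = rep(c(0, 2), each = 3))
  res <- nb_wald_test(cm, treat = sprintf("s%02d", 4:6),
                      ref = sprintf("s%02d", 1:3))
  expect_equal(res$log2fc, rep(0, 3))
  expect_true(all(res$p > 0.99))

  # group means 100 vs 800 at phi = 0.01, n = 3: direct evaluation of the
  # stated formulas gives log2fc ~ 2.994 and a vanishing p
  m0 <- 100; m1 <- 800; phi <- 0.01; n <- 3; eps <- 0.5
  lfc_expect <- log2((m1 + eps) / (m0 + eps))
  se_expect <- sqrt((m1 + phi * m1^2) / (n * (m1 + eps)^2) +
                    (m0 + phi * m0^2) / (n * (m0 + eps)^2)) / log(2)
  p_expect <- 2 * pnorm(-abs(lfc_expect / se_expect))
  counts2 <- matrix(c(rep(100, 3), rep(800, 3),
                      rep(300, 3), rep(300, 3)), nrow = 2, byrow = TRUE,
                    dimnames = list(c("de", "flat"), NULL))
  cm2 <- make_cm(counts2, timepoint_h = rep(c(0, 2), each = 3))
  sf1 <- setNames(rep(1, 6), sprintf("s%02d", 1:6))
  res2 <- nb_wald_test(cm2, treat = sprintf("s%02d", 4:6),
                       ref = sprintf("s%02d", 1:3),
                       phi = setNames(c(phi, phi), c("de", "flat")),
                       sf = sf1)
  expect_equal(res2$log2fc[1], lfc_expect, tolerance = 1e-12)
  expect_equal(res2$se[1], se_expect, tolerance = 1e-12)
  expect_equal(res2$p[1], p_expect, tolerance = 1e-12)
  expect_lt(res2$p[1], 1e-6)
  expect_gt(res2$log2fc[1], 2.9)

  # missing reference samples are a hard error
  expect_error(nb_wald_test(cm2, treat = "s04", ref = character(0)),
               "reference")
})

test_that("log2 fold changes are invariant to scaling one sample", {
  set.seed(2)
  counts <- nb_two_group(50, runif(50, 50, 500), runif(50, 50, 500),
                         0.05, 3)
  rownames(counts) <- sprintf("g%d", 1:50)
  cm <- make_cm(counts, timepoint_h = rep(c(0, 2), each = 3))
  res <- nb_wald_test(cm, sprintf("s%02d", 4:6), sprintf("s%02d", 1:3))
  scaled <- counts
  scaled[, 4] <- scaled[, 4] * 5
  cm2 <- make_cm(scaled, timepoint_h = rep(c(0, 2), each = 3))
  res2 <- nb_wald_test(cm2, sprintf("s%02d", 4:6), sprintf("s%02d", 1:3))
  expect_equal(res2$log2fc, res$log2fc, tolerance = 0.02)
})

test_that("power: 4-fold changes at base mean >= 200 are detected", {
  set.seed(3)
  n <- 200
  mu <- runif(n, 200, 1000)
  changed <- seq_len(n) %% 10 == 0   # 10% of genes up, as in a real MZT DE
  mu2 <- ifelse(changed, mu * 4, mu)
  counts <- nb_two_group(n, mu, mu2, 0.05, 2, seed = 3)
  rownames(counts) <- sprintf("g%d", 1:n)
  cm <- make_cm(counts, timepoint_h = rep(c(0, 2), each = 2))
  res <- nb_wald_test(cm, sprintf("s%02d", 3:4), sprintf("s%02d", 1:2))
  hit <- res$gene_id[res$padj < 0.05 & res$log2fc > 1]
  expect_gte(mean(sprintf("g%d", which(changed)) %in% hit), 0.9)
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.001, 0.5)), c(0.002, 0.5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_stepup_oracle(p), tolerance = 1e-12)
  }
  # padj is monotone in the rank of p and >= p
  p <- runif(100)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})
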