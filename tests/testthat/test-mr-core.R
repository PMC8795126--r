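test_that("Wald ratio arithmetic, null case and zero-exposure error", {
  h <- data.frame(variant_id = "rs1", b_X = 0.3, se_X = 0.05,
                  b_Y = 0.6, se_Y = 0.09)
  w <- waldRatio(h)
  expect_equal(w$beta, 2)
  expect_equal(w$se, 0.3)
  expect_equal(w$nsnp, 1L)

  h$b_Y <- 0
  w0 <- waldRatio(h)
  expect_equal(w0$beta, 0)
  expect_equal(w0$pvalue, 1)

  h$b_X <- 0
  expect_error(waldRatio(h), "zero")
})

test_that("IVW reproduces the closed-form two-instrument example", {
  h <- data.frame(variant_id = c("a", "b"), b_X = c(0.5, 0.25),
                  se_X = c(0.05, 0.05), b_Y = c(0.10, 0.05),
                  se_Y = c(0.10, 0.10))
  f <- mrIVW(h)
  expect_equal(f$beta, 0.2, tolerance = 1e-12)
  expect_equal(f$cochran_q, 0, tolerance = 1e-12)
  expect_equal(f$se, sqrt(1 / 31.25), tolerance = 1e-12)
  expect_equal(f$mean_f, 62.5, tolerance = 1e-12)
  expect_equal(f$q_df, 1L)
  expect_error(mrIVW(h[1, , drop = FALSE]), "at least 2")
})

test_that("collinear instruments give the common ratio with zero heterogeneity", {
  h <- data.frame(variant_id = sprintf("v%d", 1:4), b_X = c(0.2, 0.4, 0.6, 0.8),
                  se_X = 0.05, b_Y = c(0.2, 0.4, 0.6, 0.8) * 0.3, se_Y = 0.05)
  f <- mrIVW(h)
  expect_equal(f$beta, 0.3, tolerance = 1e-12)
  expect_equal(f$cochran_q, 0, tolerance = 1e-10)
  expect_equal(f$q_pvalue, 1)
})

test_that("IVW equals the weighted through-origin lm fit, and its dispersion floor works", {
  for (seed in 1:10) {
    h <- random_harmonized(J = 12, seed = seed, theta = 0.15, se_y = 0.08)
    f <- mrIVW(h)
    fit <- lm(b_Y ~ 0 + b_X, data = h, weights = 1 / h$se_Y^2)
    expect_equal(f$beta, unname(coef(fit)[1]), tolerance = 1e-10)
    # the constrained (zero-intercept) fit IS the IVW estimate
    s <- summary(fit)
    phi <- max(1, sqrt(f$cochran_q / f$q_df))
    # lm's residual scaling equals sqrt(Q/(J-1)); flooring explains any gap
    expect_equal(f$se, unname(s$coefficients[1, 2]) / s$sigma * phi,
                 tolerance = 1e-10)
    expect_gte(f$se, sqrt(1 / sum(h$b_X^2 / h$se_Y^2)) - 1e-14)
  }
})

test_that("Egger recovers an exact line and degenerates sensibly", {
  h <- data.frame(variant_id = c("a", "b", "c"), b_X = c(1, 2, 3),
                  se_X = 0.1, b_Y = c(0.5, 0.7, 0.9), se_Y = 0.1)
  e <- mrEgger(h)
  expect_equal(e$slope$beta, 0.2, tolerance = 1e-10)
  expect_equal(e$intercept$beta, 0.3, tolerance = 1e-10)
  expect_equal(e$rucker_q, 0, tolerance = 1e-10)
  expect_equal(e$qprime_df, 1L)

  # identical exposure statistics: no spread in b_X/se_X, so I2_GX = 0
  h2 <- data.frame(variant_id = c("a", "b", "c"), b_X = 0.4, se_X = 0.05,
                   b_Y = c(0.1, 0.12, 0.08), se_Y = 0.05)
  expect_error(mrEgger(h2), "singular")
  h3 <- h2; h3$b_X <- c(0.4, 0.4, 0.400001)
  expect_equal(mrEgger(h3)$i2_gx, 0, tolerance = 1e-6)

  expect_error(mrEgger(h[1:2, ]), "at least 3")
})

test_that("Egger matches weighted lm with intercept on random instances", {
  for (seed in 1:10) {
    h <- random_harmonized(J = 15, seed = 100 + seed)
    e <- mrEgger(h)
    or <- ifelse(h$b_X < 0, -1, 1)
    fit <- lm(I(h$b_Y * or) ~ I(h$b_X * or), weights = 1 / h$se_Y^2)
    expect_equal(e$intercept$beta, unname(coef(fit)[1]), tolerance = 1e-10)
    expect_equal(e$slope$beta, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(e$rucker_q, sum(residuals(fit)^2 / h$se_Y^2),
                 tolerance = 1e-10)
  }
})

test_that("heterogeneity statistics: manual arithmetic, Q' <= Q, chi-square tails", {
  h <- data.frame(variant_id = c("a", "b", "c"), b_X = c(0.3, 0.5, 0.4),
                  se_X = 0.06, b_Y = c(0.05, 0.02, 0.09), se_Y = c(0.05, 0.08, 0.06))
  f <- mrIVW(h)
  w <- 1 / h$se_Y^2
  theta <- sum(w * h$b_X * h$b_Y) / sum(w * h$b_X^2)
  q_manual <- sum(w * (h$b_Y - theta * h$b_X)^2)
  expect_equal(f$cochran_q, q_manual, tolerance = 1e-12)
  expect_equal(f$q_pvalue, pchisq(q_manual, 2, lower.tail = FALSE),
               tolerance = 1e-12)

  for (seed in 1:20) {
    h <- random_harmonized(J = sample(3:20, 1), seed = 200 + seed,
                           theta = runif(1, -0.3, 0.3))
    hs <- heterogeneityStats(h)
    expect_lte(hs$rucker_q, hs$cochran_q + 1e-10)
    expect_gte(hs$rucker_q, 0)
    expect_gte(hs$cochran_q, 0)
    expect_gte(hs$i2_gx, 0); expect_lte(hs$i2_gx, 1)
  }
})

test_that("estimates are invariant to simultaneous sign flips of instrument subsets", {
  for (seed in 1:8) {
    h <- random_harmonized(J = 10, seed = 300 + seed)
    f0 <- mrIVW(h)
    e0 <- mrEgger(h)
    set.seed(seed)
    flip <- sample(c(-1, 1), 10, replace = TRUE)
    hf <- h
    hf$b_X <- h$b_X * flip
    hf$b_Y <- h$b_Y * flip
    f1 <- mrIVW(hf)
    expect_equal(f1$beta, f0$beta, tolerance = 1e-12)
    expect_equal(f1$cochran_q, f0$cochran_q, tolerance = 1e-10)
    # Egger re-orients to b_X >= 0 internally, so flips cannot matter
    e1 <- mrEgger(hf)
    expect_equal(e1$slope$beta, e0$slope$beta, tolerance = 1e-12)
    expect_equal(e1$intercept$beta, e0$intercept$beta, tolerance = 1e-12)
  }
})

test_that("leave-one-out reduces to the expected special cases and localizes an outlier", {
  # equal ratios: every leave-one-out estimate equals the full estimate
  h <- data.frame(variant_id = c("a", "b", "c"), b_X = c(0.2, 0.4, 0.6),
                  se_X = 0.05, b_Y = c(0.2, 0.4, 0.6) * 0.25, se_Y = 0.05)
  lo <- leaveOneOut(h)
  expect_equal(lo$beta, rep(0.25, 3), tolerance = 1e-10)

  # J = 2: each row is the other instrument's Wald ratio
  h2 <- h[1:2, ]
  lo2 <- leaveOneOut(h2)
  expect_equal(lo2$method, c("wald", "wald"))
  expect_equal(lo2$beta[1], h2$b_Y[2] / h2$b_X[2])
  expect_equal(lo2$beta[2], h2$b_Y[1] / h2$b_X[1])

  # a gross outlier: only its own exclusion recovers the truth
  h3 <- random_harmonized(J = 10, seed = 77, theta = 0.1, se_y = 0.02)
  h3$b_Y[4] <- h3$b_Y[4] + 1
  lo3 <- leaveOneOut(h3)
  err <- abs(lo3$beta - 0.1)
  expect_equal(which.min(err), 4L)
  expect_lt(err[4], 0.05)
  expect_true(all(err[-4] > err[4]))
})

test_that("MR-PRESSO is seeded, flags a planted outlier, and validates its inputs", {
  h <- random_harmonized(J = 15, seed = 88, theta = 0.1, se_y = 0.03)
  p1 <- mrPresso(h, n_sim = 500, seed = 42)
  p2 <- mrPresso(h, n_sim = 500, seed = 42)
  expect_identical(p1$global_pvalue, p2$global_pvalue)
  expect_identical(p1$outliers$pvalue, p2$outliers$pvalue)
  expect_gt(p1$global_pvalue, 0.05)          # clean data: no global signal
  expect_false(any(p1$outliers$outlier))

  ho <- h
  ho$b_Y[7] <- ho$b_Y[7] + 12 * ho$se_Y[7]
  po <- mrPresso(ho, n_sim = 1000, seed = 42)
  expect_lt(po$global_pvalue, 0.05)
  expect_true(po$outliers$outlier[7])
  expect_equal(sum(po$outliers$outlier), 1)

  expect_error(mrPresso(h[1:3, ], n_sim = 500), "at least 4")
  expect_error(mrPresso(h, n_sim = 0), "n_sim")
})

test_that("grouped MR applies the single-vs-multiple instrument rule per group", {
  h <- random_harmonized(J = 5, seed = 99)
  h$gene_id <- c("G1", "G1", "G2", "G3", "G3")
  h$tissue <- c("T1", "T2", "T1", "T1", "T2")
  g <- groupedMr(h, by = "gene")
  expect_equal(g$method[g$group == "G2"], "wald")
  expect_equal(g$method[g$group == "G1"], "ivw")
  expect_equal(sort(unique(g$group)), c("G1", "G2", "G3"))
  expect_equal(g$nsnp, c(2L, 1L, 2L))

  t <- groupedMr(h, by = "tissue")
  expect_equal(t$nsnp[t$group == "T1"], 3L)
  # a group's IVW equals running mrIVW on that slice directly
  expect_equal(g$beta[g$group == "G1"],
               mrIVW(h[h$gene_id == "G1", ])$beta, tolerance = 1e-12)
})

test_that("the sensitivity battery lays out the full diagnostic block", {
  h <- random_harmonized(J = 12, seed = 111, theta = 0.05)
  b <- sensitivityBattery(h, outcome = "trait", exposure = "PW",
                          presso_nsim = 300, seed = 5)
  expect_setequal(b$method, c("ivw", "egger_intercept", "egger_slope", "presso"))
  ivw_row <- b[b$method == "ivw", ]
  expect_equal(ivw_row$beta, mrIVW(h)$beta, tolerance = 1e-12)
  expect_equal(ivw_row$het_stat, mrIVW(h)$cochran_q, tolerance = 1e-12)
  eg <- mrEgger(h)
  expect_equal(b$beta[b$method == "egger_slope"], eg$slope$beta, tolerance = 1e-12)
  expect_equal(b$het_stat[b$method == "egger_slope"], eg$rucker_q, tolerance = 1e-12)
  expect_true(all(b$i2_gx == eg$i2_gx))
  expect_true(all(b$mean_f == mrIVW(h)$mean_f))
})
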