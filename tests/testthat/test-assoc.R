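test_that("Fisher's exact test matches hypergeometric enumeration on toys", {
  # margins (2,2,2,2): table probabilities 1/6, 4/6, 1/6; the observed
  # diagonal table has p = 1/6, two-sided sum = 1/3
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
  # dark/light derived-allele counts: strongly significant
  expect_lt(fisher_exact_2x2(matrix(c(54, 14, 66, 2), 2, byrow = TRUE)),
            0.01)
})

test_that("trend test: degenerate, toy-exact and published tables", {
  # identical genotype distributions: statistic 0, p = 1
  same <- rbind(c(10, 20, 5), c(10, 20, 5))
  r <- ca_trend(same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  # tiny 2x3 table: exact p by complete enumeration of case-index
  # subsets (independent permutation oracle)
  tb <- rbind(c(2, 1, 0), c(0, 1, 2))
  doses <- rep(0:2, colSums(tb))
  R <- sum(tb[1, ])
  combos <- combn(length(doses), R)
  T_all <- apply(combos, 2, function(ix) sum(doses[ix]))
  T_obs <- sum(c(0, 1, 2) * tb[1, ])
  mu <- mean(T_all)
  p_oracle <- mean(abs(T_all - mu) >= abs(T_obs - mu) - 1e-9)
  expect_equal(ca_trend(tb, mode = "exact")$p, p_oracle, tolerance = 1e-10)

  # melanoma vs all controls: the exact p reproduces the published value
  mel <- rbind(c(107, 12, 0), c(659, 276, 35))
  ex <- ca_trend(mel, mode = "exact")
  expect_equal(ex$mode_used, "exact")
  expect_equal(ex$p, 1.42e-06, tolerance = 0.01)
  expect_lt(ca_trend(mel)$p, 1e-5)
})

test_that("asymptotic trend p approaches the exact p on large balanced tables", {
  tabs <- list(rbind(c(150, 80, 20), c(140, 90, 25)),
               rbind(c(160, 75, 15), c(130, 95, 30)),
               rbind(c(155, 85, 15), c(135, 85, 30)))
  for (tb in tabs) {
    pe <- ca_trend(tb, mode = "exact")$p
    pa <- ca_trend(tb)$p
    expect_lt(abs(pa - pe) / pe, 0.10)
  }
})

test_that("HWE exact test matches Levene enumeration and its conventions", {
  expect_equal(hwe_exact(c(12, 0, 0)), 1)          # monomorphic
  # published control counts under both conventions
  expect_equal(hwe_exact(c(659, 276, 35), "dost"), 0.412, tolerance = 0.01)
  expect_equal(hwe_exact(c(659, 276, 35)), 0.380, tolerance = 0.01)
  # all genotype configurations with n <= 10 against the Levene oracle
  for (n in 2:10) {
    for (nAA in 0:n) for (nAa in 0:(n - nAA)) {
      naa <- n - nAA - nAa
      nA <- 2 * nAA + nAa; na <- 2 * naa + nAa
      if (nA == 0 || na == 0) next
      rare <- min(nA, na)
      hets <- seq(rare %% 2, rare, by = 2)
      probs <- vapply(hets, levene_prob, numeric(1), nA = nA, na = na)
      p_obs <- probs[hets == nAa]
      oracle <- sum(probs[probs <= p_obs + 1e-12])
      expect_equal(hwe_exact(c(nAA, nAa, naa)), min(1, oracle),
                   tolerance = 1e-9)
    }
  }
})

test_that("allelic odds ratios and their CIs follow the log-Wald form", {
  r <- allelic_or(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r$or, 1)
  expect_true(r$ci_95[1] < 1 && r$ci_95[2] > 1)
  expect_equal(allelic_or(matrix(c(20, 10, 10, 20), 2, byrow = TRUE))$or, 4)
  rz <- allelic_or(matrix(c(5, 0, 3, 4), 2, byrow = TRUE))
  expect_true(rz$corrected)
  expect_true(is.finite(rz$or))
})

test_that("two-proportion Z test matches the pooled closed form", {
  expect_equal(two_proportion_z(0.4, 50, 0.4, 80)$p, 1)
  expect_equal(two_proportion_z(0.960, 68, 0.949, 760)$p, 0.69,
               tolerance = 0.01)
  # hand case (0.5, 100) vs (0.7, 100) by direct formula
  pool <- 0.6
  z_oracle <- (0.5 - 0.7) / sqrt(pool * 0.4 * (1 / 100 + 1 / 100))
  r <- two_proportion_z(0.5, 100, 0.7, 100)
  expect_equal(r$z, z_oracle, tolerance = 1e-12)
  expect_equal(r$p, 2 * pnorm(-abs(z_oracle)), tolerance = 1e-12)
  expect_equal(two_proportion_z(0, 10, 0, 10)$p, 1)  # degenerate pool
})

test_that("pairwise LD matches direct frequency arithmetic", {
  # identical columns: complete disequilibrium
  h1 <- toy_hap(c("11", "11", "00"))
  l1 <- ld_pair(h1, 1, 2)
  expect_equal(l1$D_prime, 1)
  expect_equal(l1$r2, 1)
  # all four gametes equally frequent: no disequilibrium
  h2 <- toy_hap(c("11", "10", "01", "00"))
  l2 <- ld_pair(h2, 1, 2)
  expect_equal(l2$D, 0)
  expect_equal(l2$r2, 0)
  # {AB x2, Ab, aB, ab}: D = 0.04, D' = 1/6, r2 = 1/36
  h3 <- toy_hap(c("11", "11", "10", "01", "00"))
  l3 <- ld_pair(h3, 1, 2)
  expect_equal(l3$D, 0.04, tolerance = 1e-12)
  expect_equal(l3$D_prime, 0.04 / 0.24, tolerance = 1e-12)
  expect_equal(l3$r2, 0.04^2 / (0.6 * 0.4 * 0.6 * 0.4), tolerance = 1e-12)
  expect_error(ld_pair(toy_hap(c("10", "10")), 1, 2), "polymorphic")
})

test_that("UV correlation matches the closed-form Pearson r", {
  lin <- data.frame(uv = c(1, 2, 3, 4), freq = c(0.9, 0.8, 0.7, 0.6))
  expect_equal(uv_correlation(lin)$r, -1, tolerance = 1e-12)
  # six hand points against cor() directly
  pts <- data.frame(uv = c(24500, 26500, 28500, 30500, 33000, 43400),
                    freq = c(0.93, 0.95, 0.89, 0.86, 0.84, 0.70))
  r <- uv_correlation(pts)
  expect_equal(r$r, cor(pts$uv, pts$freq), tolerance = 1e-12)
  expect_lt(r$p, 0.05)
  # excluding the outlier band changes the support, not the machinery
  r2 <- uv_correlation(pts, exclude = 6)
  expect_equal(r2$n, 5)
  expect_error(uv_correlation(pts[1:2, ]), "at least 3")
})
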