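test_that("the carrier consensus is the columnwise majority, ties derived", {
  expect_equal(consensus_ancestral_haplotype(toy_hap(c("110", "100", "110"))),
               c(1L, 1L, 0L))
  expect_equal(consensus_ancestral_haplotype(toy_hap(c("101", "101"))),
               c(1L, 0L, 1L))
  # tie column (2 vs 2) goes to the derived allele
  expect_equal(consensus_ancestral_haplotype(
    toy_hap(c("1", "1", "0", "0"))), 1L)
})

# independent oracle: explicit probability product over the m+1 switch
# hypotheses of the absorbing two-state chain
hmm_oracle <- function(match, bg, eps, p_sw) {
  m <- length(match)
  eA <- ifelse(match, 1 - eps, eps)
  eB <- ifelse(match, bg, 1 - bg)
  ll <- numeric(m + 1)
  for (k in 0:m) {
    v <- prod(1 - rep(p_sw, k)) * prod(eA[seq_len(k)])
    if (k < m) v <- v * p_sw * prod(eB[(k + 1):m])
    ll[k + 1] <- v
  }
  which.max(ll) - 1
}

test_that("HMM endpoints match exhaustive enumeration of switch points", {
  anc <- rep(1L, 11)
  pos <- c(0, (1:10) * 100)
  # matching at 1-6, mismatching at 7-10: switch lands between 6 and 7
  carrier <- c(1L, rep(1L, 6), rep(0L, 4))
  e <- hmm_segment_endpoints(carrier, anc, pos, 1, bg_freq = rep(0.5, 11),
                             switch_prob = 0.05, window = c(0, 1000))
  expect_false(e$censored_right)
  expect_equal(e$right, 650)
  k_oracle <- hmm_oracle(match = carrier[-1] == 1L, bg = rep(0.5, 10),
                         eps = 0.01, p_sw = 0.05)
  expect_equal(k_oracle, 6)

  # a single isolated mismatch deep inside a matching side is absorbed
  # as error, not as a recombination switch
  carrier2 <- c(1L, rep(1L, 4), 0L, rep(1L, 5))
  e2 <- hmm_segment_endpoints(carrier2, anc, pos, 1,
                              bg_freq = rep(0.5, 11),
                              switch_prob = 0.05, window = c(0, 1000))
  expect_true(e2$censored_right)
  expect_equal(hmm_oracle(carrier2[-1] == 1L, rep(0.5, 10), 0.01, 0.05), 10)

  # perfect match: censored at both edges
  e3 <- hmm_segment_endpoints(rep(1L, 11), anc, pos, 6,
                              bg_freq = rep(0.5, 11),
                              switch_prob = 0.05, window = c(-100, 1100))
  expect_true(e3$censored_left && e3$censored_right)
  expect_equal(c(e3$left, e3$right), c(-100, 1100))

  expect_error(hmm_segment_endpoints(c(0L, 1L), c(1L, 1L), c(0, 1), 1,
                                     rep(0.5, 2), switch_prob = 0.1),
               "core")
})

test_that("sweep duration follows the logistic closed form", {
  # direct evaluation oracle
  T_oracle <- log(0.97 * (1 - 5e-5) / (0.03 * 5e-5)) / 0.01
  expect_equal(sweep_duration(0.01, 0.97, 1e4), T_oracle, tolerance = 1e-12)
  expect_equal(round(T_oracle), 1338)
  # doubling s halves T
  expect_equal(sweep_duration(0.02, 0.97, 1e4),
               sweep_duration(0.01, 0.97, 1e4) / 2, tolerance = 1e-12)
  # p -> x0+ gives T -> 0
  expect_lt(sweep_duration(0.01, 1 / (2 * 1e4) * 1.01, 1e4), 2)
  expect_error(sweep_duration(0.01, 1e-6, 1e4), "between")
  expect_error(sweep_duration(-0.1, 0.5, 1e4), "positive")
})

test_that("breakpoint intensity decreases in s", {
  s_grid <- exp(seq(log(1e-3), log(1e-1), length.out = 50))
  lam <- vapply(s_grid, sweepsel:::sweep_lambda, numeric(1),
                p_now = 0.95, N = 1e4)
  expect_true(all(diff(lam) < 0))
})

test_that("fit_sweep recovers parameters from model-simulated endpoints", {
  map <- recomb_map(2e6, rho = 800)      # 1 cM/Mb at N = 1e4
  set.seed(601)
  cover <- logical(20)
  for (i in 1:20) {
    seg <- simulate_endpoints(200, 0.02, 0.95, 1e4, map, 1e6)
    fit <- fit_sweep(seg, map, 0.95, 1e4)
    expect_gt(fit$s_hat, 0.01)
    expect_lt(fit$s_hat, 0.04)
    expect_true(fit$ci_95[1] <= fit$s_hat && fit$s_hat <= fit$ci_95[2])
    cover[i] <- fit$ci_95[1] <= 0.02 && fit$ci_95[2] >= 0.02
  }
  expect_gte(mean(cover), 0.7)
  # age bookkeeping: years = generations x generation time
  expect_equal(fit$age_years, fit$T_gen * 29, tolerance = 1e-12)
  f2 <- fit_sweep(seg, map, 0.95, 1e4, gen_time = 25)
  expect_equal(f2$age_years, f2$T_gen * 25, tolerance = 1e-12)
})

test_that("all-censored input pins the estimate at the grid maximum with a flag", {
  map <- recomb_map(2e6, rho = 800)
  seg <- structure(
    data.frame(left = rep(0, 20), right = rep(2e6, 20),
               censored_left = TRUE, censored_right = TRUE),
    core_pos = 1e6, window = c(0, 2e6),
    class = c("ancestral_segments", "data.frame"))
  fit <- suppressWarnings(fit_sweep(seg, map, 0.95, 1e4))
  expect_true(fit$all_censored)
  expect_equal(fit$s_hat, max(fit$loglik$s))
})

test_that("estimates order correctly across true s on full simulated sweeps", {
  # end to end: sweep coalescent -> carrier consensus -> HMM endpoints ->
  # composite likelihood; medians must be monotone in the generating s
  map <- recomb_map(2e6, rho = 800)
  set.seed(602)
  med <- vapply(c(0.005, 0.02, 0.05), function(s_true) {
    fits <- vapply(1:4, function(i) {
      sw <- simulate_sweep(40, map, theta = 120,
                           sweep_spec(s_true, 0.95, 1e6), reps = 1)[[1]]
      fit_sweep_from_haplotypes(sw, attr(sw, "core_index"), map,
                                N = 1e4)$s_hat
    }, numeric(1))
    median(fits)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})
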