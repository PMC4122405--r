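test_that("Jukes-Cantor mutation-rate estimation matches the closed form", {
  expect_equal(jc69_rate(0, 6e6), 0)
  # p = 0.05 -> d = 0.051745 (high-precision closed form)
  d <- -0.75 * log(1 - 4 * 0.05 / 3)
  expect_equal(jc69_rate(0.05, 6e6), d / 1.2e7, tolerance = 1e-12)
  expect_equal(round(d, 6), 0.051745)
  # d = 0.012 over 6 Myr -> 1e-9 per site per year
  p <- 0.75 * (1 - exp(-4 * 0.012 / 3))
  expect_equal(jc69_rate(p, 6e6), 1e-9, tolerance = 1e-12)
  # per-generation conversion
  expect_equal(jc69_rate(p, 6e6, per_generation = TRUE, gen_time = 29),
               29e-9, tolerance = 1e-12)
  expect_error(jc69_rate(0.8, 6e6), "saturat")
})

test_that("EHH is the pair-homozygosity of extended haplotypes", {
  # 4 carriers with extended haplotypes {x, x, y, y} -> (1 + 1)/6
  h <- toy_hap(c("10", "10", "11", "11", "00"))
  expect_equal(ehh_at(h, 1, 1L, 2), 2 / 6)
  expect_equal(ehh_at(h, 1, 1L, 1), 1)          # target = core
  h2 <- toy_hap(c("10", "10", "10", "00"))      # identical carriers
  expect_equal(ehh_at(h2, 1, 1L, 2), 1)
  expect_error(ehh_at(toy_hap(c("10", "00", "00")), 1, 1L, 2),
               "carriers")
})

test_that("EHH curves are non-increasing away from the core", {
  set.seed(401)
  for (i in 1:15) {
    n <- sample(6:20, 1); S <- sample(5:15, 1)
    m <- matrix(rbinom(n * S, 1, 0.5), n, S)
    core <- sample(seq_len(S), 1)
    m[, core] <- rbinom(n, 1, 0.6)
    if (sum(m[, core]) < 2) m[1:2, core] <- 1L
    h <- hap_matrix(m, seq_len(S) - 1, polarized = TRUE)
    for (side in c("downstream", "upstream")) {
      cv <- ehh_curve(h, core, 1L, side)
      expect_true(all(diff(cv$ehh) <= 1e-12))
      expect_equal(cv$ehh[1], 1)
    }
  }
})

make_env_rep <- function(site1, site2) {
  hap_matrix(cbind(rep(1L, 4), site1, site2),
             positions = c(0, 1000, 2000), polarized = TRUE)
}

test_that("the envelope matches a hand percentile-and-monotone computation", {
  # five replicates with known EHH values at the two distances
  reps <- list(
    make_env_rep(c(0L, 0L, 0L, 0L), c(1L, 1L, 0L, 0L)),  # (1,   1/3)
    make_env_rep(c(0L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L)),  # (1,   1)
    make_env_rep(c(1L, 1L, 0L, 0L), c(1L, 1L, 0L, 0L)),  # (1/3, 1/3)
    make_env_rep(c(1L, 0L, 0L, 0L), c(0L, 1L, 0L, 0L)),  # (1/2, 1/6)
    make_env_rep(c(1L, 1L, 0L, 0L), c(1L, 1L, 0L, 0L)))  # (1/3, 1/3)
  observed <- reps[[1]]
  env <- build_envelope(reps, observed, core_site = 1,
                        distances = c(0.5, 1), snp_tol = 0.5,
                        min_accepted = 5L)
  # oracle: 95th percentile (type 1) at d = 0.5 is 1 (reps 1, 2), at
  # d = 1 is 1 (rep 2); pooled points deduped with the max kept, then
  # the monotone pass: cutoffs are 1 at 0, 0.5, 1
  expect_equal(env$distance, c(0, 0.5, 1))
  expect_equal(env$cutoff, c(1, 1, 1))
  expect_equal(attr(env, "n_accepted"), 5L)

  # all replicates identical: the envelope is that replicate's curve
  same <- reps[c(3, 3, 3, 3, 3)]
  env2 <- build_envelope(same, reps[[3]], core_site = 1,
                         distances = c(0.5, 1), min_accepted = 5L)
  expect_equal(env2$cutoff, c(1, 1 / 3, 1 / 3))

  # envelope output is monotone non-increasing and deduplicated
  expect_true(all(diff(env2$cutoff) <= 1e-12))
  expect_false(any(duplicated(env2$distance)))

  # too few accepted replicates is an error reporting the acceptance rate
  expect_error(build_envelope(reps[1:2], observed, core_site = 1,
                              min_accepted = 5L), "passed the filters")
})

test_that("exceedance flags compare the curve against the interpolated envelope", {
  obs <- structure(data.frame(distance = c(0, 0.5, 1),
                              ehh = c(1, 0.8, 0.6)),
                   class = c("ehh_curve", "data.frame"))
  env <- structure(data.frame(distance = c(0, 0.5, 1),
                              cutoff = c(1, 0.9, 0.4)),
                   class = c("ehh_envelope", "data.frame"))
  sig <- ehh_significance(obs, env)
  expect_equal(sig$exceeds, c(FALSE, FALSE, TRUE))  # single crossing

  # observed identical to the envelope: no strict exceedance
  obs2 <- obs; obs2$ehh <- c(1, 0.9, 0.4)
  expect_false(any(ehh_significance(obs2, env)$exceeds))

  # observed at 1 everywhere exceeds wherever the envelope is below 1
  obs3 <- obs; obs3$ehh <- c(1, 1, 1)
  expect_equal(ehh_significance(obs3, env)$exceeds, c(FALSE, TRUE, TRUE))

  env_far <- env; env_far$distance <- env$distance + 5
  expect_error(ehh_significance(obs, env_far), "disjoint")
})
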