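test_that("scaled-parameter draws follow the positive-truncated normal", {
  s <- scaled_param_sampler(10, 10)
  set.seed(201)
  d <- sample_scaled_params(s, 10000)
  # oracle: closed-form mean of N(m, m) truncated to > 0:
  # m * (1 + dnorm(1) / pnorm(1))
  mu_trunc <- 10 * (1 + dnorm(1) / pnorm(1))
  se <- sd(d$theta) / sqrt(nrow(d))
  expect_lt(abs(mean(d$theta) - mu_trunc), 3 * se)
  expect_true(all(d$theta > 0) && all(d$rho > 0))

  # degenerate sd: all draws equal the mean
  expect_equal(unique(sample_scaled_params(s, 50, sd_frac = 0)$theta), 10)

  # same seed, same draws
  set.seed(5); a <- sample_scaled_params(s, 20)
  set.seed(5); b <- sample_scaled_params(s, 20)
  expect_identical(a, b)
  expect_error(scaled_param_sampler(-1, 2), "positive")
})

test_that("neutral simulation matches Watterson's expectation", {
  map <- recomb_map(1000, 0)
  # theta -> 0: no segregating sites
  sims0 <- simulate_neutral(demographic_model(5L), map, theta = 0, reps = 5)
  expect_true(all(vapply(sims0, n_site, integer(1)) == 0L))

  # n = 10, theta = 5: E[S] = 5 * sum(1/1:9) = 14.14, 2000 reps
  set.seed(202)
  sims <- simulate_neutral(demographic_model(10L), map, theta = 5,
                           reps = 2000)
  S <- vapply(sims, n_site, integer(1))
  expected <- 5 * sum(1 / (1:9))
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 3 * se)
})

test_that("the printed European configuration yields 224 haplotypes", {
  set.seed(203)
  sims <- simulate_neutral(ooa_model(224), slc45a2_flank_map("downstream"),
                           theta = 20, reps = 2)
  expect_equal(vapply(sims, n_hap, integer(1)), c(224L, 224L))
  expect_true(all(vapply(sims, function(h)
    all(h$positions >= 0 & h$positions < 1e5), logical(1))))
})

test_that("two-deme island model has the size-invariant mean coalescence time", {
  # classic result: E[T2, same deme] = (number of demes) * 0.5 scaled
  # units regardless of the migration rate; with theta per region = 1 and
  # n = 2 this gives E[S] = 2 * theta
  set.seed(204)
  mig <- matrix(c(0, 2, 2, 0), 2, 2)
  sims <- simulate_neutral(demographic_model(c(2L, 0L), migration = mig),
                           recomb_map(1000, 0), theta = 1, reps = 3000)
  S <- vapply(sims, n_site, integer(1))
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - 2), 4 * se)
})

test_that("hotspot intervals attract proportionally more breakpoints", {
  set.seed(205)
  map <- recomb_map(1000, rho = 10,
                    hotspots = data.frame(start = 400, end = 500,
                                          mult = 10))
  sims <- simulate_neutral(demographic_model(20L), map, theta = 5,
                           reps = 400)
  bp <- unlist(lapply(sims, attr, "breakpoints"))
  # compare two equal-length interior windows: hotspot vs basal
  hot <- sum(bp >= 400 & bp < 500)
  basal <- sum(bp >= 600 & bp < 700)
  expect_gt(hot, basal)                       # strictly enriched
  ratio <- hot / basal
  expect_gt(ratio, 10 * 0.6)                  # ~multiplier, generous band
  expect_lt(ratio, 10 * 1.6)
})

test_that("model construction validates inputs", {
  expect_error(demographic_model(5L, migration = matrix(-1, 1, 1)),
               "non-negative")
  expect_error(recomb_map(100, 1, data.frame(start = 50, end = 150,
                                             mult = 2)), "within")
  expect_error(recomb_map(100, 1, data.frame(start = c(10, 15),
                                             end = c(20, 30),
                                             mult = c(2, 2))), "overlap")
  expect_error(recomb_map(100, 1, data.frame(start = 10, end = 20,
                                             mult = 0.5)), ">= 1")
})

test_that("sweep simulation reduces diversity and hits the target frequency", {
  map <- recomb_map(10000, rho = 5)
  # requested frequency 0.96 with n = 50: realised fraction in 0.94-0.98
  set.seed(206)
  sw <- simulate_sweep(50, map, theta = 8, sweep_spec(0.05, 0.96, 5000),
                       reps = 10)
  fr <- vapply(sw, function(h)
    mean(h$alleles[, attr(h, "core_index")]), numeric(1))
  expect_true(all(fr >= 0.94 & fr <= 0.98))

  # s = 0.02 vs neutral: paired comparison of mean Tajima's D
  set.seed(207)
  sw2 <- simulate_sweep(30, map, theta = 8, sweep_spec(0.02, 0.9, 5000),
                        reps = 60)
  ne2 <- simulate_neutral(demographic_model(30L), map, theta = 8,
                          reps = 60)
  D_sw <- vapply(sw2, function(h) tajimas_d(h), numeric(1))
  D_ne <- vapply(ne2, function(h) tajimas_d(h), numeric(1))
  expect_lt(mean(D_sw, na.rm = TRUE), mean(D_ne, na.rm = TRUE))

  # very strong selection: carriers are near-identical over the region
  set.seed(208)
  sw3 <- simulate_sweep(30, map, theta = 8, sweep_spec(0.5, 0.9, 5000),
                        reps = 5)
  ehh_far <- vapply(sw3, function(h) {
    ci <- attr(h, "core_index")
    cv <- ehh_curve(h, ci, 1L, "downstream")
    min(cv$ehh)
  }, numeric(1))
  expect_gt(mean(ehh_far), 0.8)
})
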