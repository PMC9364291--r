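small_ctrl <- list(chains = 2L, iter = 3000L, burnin = 1500L, thin = 3L)

test_that("run-length presets echo the retained-draw arithmetic", {
  desk <- hb_control("desk")
  expect_equal(desk$retained_per_chain, (20000 - 10000) / 5)
  prod <- hb_control("production")
  expect_equal(prod$retained_per_chain, 25000)
  expect_equal(prod$iter, 500000L)
  expect_equal(prod$burnin, 250000L)
  expect_equal(prod$thin, 10L)
})

test_that("the sampler smoke-runs on a single flat participant", {
  tb <- frequency_table(matrix(4L, 3, 3))
  fit <- fit_hb(list(tb), control = small_ctrl, seed = 1)
  S <- (small_ctrl$iter - small_ctrl$burnin) / small_ctrl$thin
  expect_length(fit$chains, 2)
  expect_equal(dim(fit$chains[[1]]$mu), c(S, 6))
  expect_equal(dim(fit$chains[[1]]$sigma_lt), c(S, 21))
  expect_equal(dim(fit$chains[[1]]$theta), c(1, 6, S))
  th <- phi_mu_draws(fit)
  expect_true(all(th > 0 & th < 1))
})

test_that("fits are deterministic given the master seed", {
  sim <- simulate_hb_dataset(hb_test_means, rep(0.4, 6), 6, seed = 2)
  f1 <- fit_hb(sim$tables, control = small_ctrl, seed = 10)
  f2 <- fit_hb(sim$tables, control = small_ctrl, seed = 10)
  expect_identical(f1$chains[[2]]$mu, f2$chains[[2]]$mu)
  f3 <- fit_hb(sim$tables, control = small_ctrl, seed = 11)
  expect_false(identical(f1$chains[[1]]$mu, f3$chains[[1]]$mu))
})

test_that("input validation: chains, empty tables, zero totals", {
  tb <- frequency_table(matrix(4L, 3, 3))
  expect_error(fit_hb(list(tb), control = list(chains = 1, iter = 100,
                                               burnin = 50, thin = 1)),
               "2 chains")
  expect_error(fit_hb(list(), control = small_ctrl), "non-empty")
  expect_error(fit_hb(list(frequency_table(matrix(0L, 3, 3))),
                      control = small_ctrl), "zero total")
})

test_that("posterior summaries use central 95% quantiles", {
  # degenerate posterior
  m <- matrix(0.5, 100, 2, dimnames = list(NULL, c("d_E", "d_U")))
  s <- summarize_posterior(m)
  expect_equal(s$estimate, c(0.5, 0.5))
  expect_equal(s$bci_low, c(0.5, 0.5))
  expect_equal(s$bci_high, c(0.5, 0.5))
  # Beta(2,2) draws against a brute-force percentile oracle
  set.seed(8)
  x <- rbeta(10000, 2, 2)
  s2 <- summarize_posterior(matrix(x, ncol = 1,
                                   dimnames = list(NULL, "g")))
  xs <- sort(x)
  expect_equal(s2$bci_low, xs[ceiling(0.025 * length(x))], tolerance = 5e-3)
  expect_equal(s2$bci_high, xs[ceiling(0.975 * length(x))], tolerance = 5e-3)
  expect_equal(s2$estimate, median(x), tolerance = 1e-12)
})

test_that("split R-hat behaves on constructed chains", {
  # identical constant chains: 1 by convention
  expect_equal(gelman_rubin(list(rep(2, 100), rep(2, 100))), 1)
  # iid same-distribution chains: close to 1
  set.seed(5)
  expect_lt(gelman_rubin(list(rnorm(10000), rnorm(10000))), 1.01)
  # a 5-SD offset blows R-hat up
  expect_gt(gelman_rubin(list(rnorm(1000), rnorm(1000) + 5)), 1.2)
  # single chain is a usage error
  expect_error(gelman_rubin(list(rnorm(100))), ">= 2 chains")
})

test_that("R-hat never decreases as the between-chain offset grows", {
  set.seed(6)
  base <- list(rnorm(2000), rnorm(2000))
  rh <- vapply(c(0, 0.5, 1, 2, 4), function(off) {
    gelman_rubin(list(base[[1]], base[[2]] + off))
  }, numeric(1))
  expect_true(all(diff(rh) > 0))
})

test_that("group means are recovered from latent-trait data (reduced run)", {
  sim <- simulate_hb_dataset(hb_test_means, rep(0.4, 6), 24, seed = 42)
  fit <- fit_hb(sim$tables,
                control = list(chains = 2L, iter = 6000L, burnin = 3000L,
                               thin = 3L), seed = 7)
  s <- summarize_posterior(fit)
  truth <- pnorm(hb_test_means)
  expect_lt(max(abs(s$estimate - truth)), 0.2)
  # most intervals should cover at this scale
  expect_gte(sum(s$bci_low <= truth & truth <= s$bci_high), 5)
})

test_that("contrasts: identity, injected normals, and the significance rule", {
  set.seed(13)
  draws <- cbind(d_E = rnorm(5000, .6, .01), d_U = rnorm(5000, .8, .01))
  c0 <- parameter_contrast(draws, expr = "d_U - d_U")
  expect_equal(c0$mean, 0)
  expect_equal(c0$bci, c(0, 0))
  expect_false(c0$significant)
  c1 <- parameter_contrast(draws, expr = "d_U - d_E")
  expect_equal(c1$mean, 0.2, tolerance = 0.005)
  # closed form: difference ~ N(.2, sqrt(2)*.01), central interval
  expect_equal(c1$bci, 0.2 + qnorm(c(.025, .975)) * sqrt(2) * .01,
               tolerance = 0.005)
  expect_true(c1$significant)
  expect_identical(c1$significant,
                   unname(c1$bci[1] > 0 || c1$bci[2] < 0))
})

test_that("between-posterior contrasts subsample mismatched draw counts", {
  set.seed(14)
  a <- cbind(d_E = rnorm(1000, .5, .02), d_U = rnorm(1000, .7, .02))
  b <- cbind(d_E = rnorm(700, .5, .02), d_U = rnorm(700, .7, .02))
  ct <- parameter_contrast(a, b, "(d_U_1 - d_E_1) - (d_U_2 - d_E_2)")
  expect_length(ct$draws, 700)
  expect_false(ct$significant)
  expect_equal(ct$mean, 0, tolerance = 0.01)
})

test_that("null difference-of-differences is rarely significant (calibration)", {
  ctrl <- list(chains = 2L, iter = 4000L, burnin = 2000L, thin = 2L)
  hits <- 0
  n_rep <- 12
  for (r in seq_len(n_rep)) {
    sa <- simulate_hb_dataset(hb_test_means, rep(0.4, 6), 14,
                              seed = 1000 + r)
    sb <- simulate_hb_dataset(hb_test_means, rep(0.4, 6), 14,
                              seed = 2000 + r)
    fa <- fit_hb(sa$tables, control = ctrl, seed = 300 + r)
    fb <- fit_hb(sb$tables, control = ctrl, seed = 400 + r)
    ct <- parameter_contrast(fa, fb, "(d_U_1 - d_E_1) - (d_U_2 - d_E_2)")
    if (!ct$significant) hits <- hits + 1
  }
  expect_gte(hits, ceiling(0.9 * n_rep))
})

test_that("posterior predictive checks produce sane p-values", {
  sim <- simulate_hb_dataset(hb_test_means, rep(0.4, 6), 12, seed = 55)
  fit <- fit_hb(sim$tables,
                control = list(chains = 2L, iter = 4000L, burnin = 2000L,
                               thin = 2L), seed = 9)
  ppc <- posterior_predictive_check(fit, sim$tables, n_rep = 100, seed = 1)
  expect_true(ppc$T1_p >= 0 && ppc$T1_p <= 1)
  expect_true(ppc$T2_p >= 0 && ppc$T2_p <= 1)
  # identical tables for everyone: zero observed covariance, still computable
  same <- replicate(5, sim$tables[[1]], simplify = FALSE)
  ppc2 <- posterior_predictive_check(fit_hb(same, control = small_ctrl,
                                            seed = 2),
                                     same, n_rep = 50, seed = 3)
  expect_true(ppc2$T2_p >= 0 && ppc2$T2_p <= 1)
  # single participant: T2 undefined
  one <- sim$tables[1]
  ppc1 <- posterior_predictive_check(fit_hb(one, control = small_ctrl,
                                            seed = 4),
                                     one, n_rep = 50, seed = 5)
  expect_true(is.na(ppc1$T2_p))
})
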