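test_that("paired t test matches hand arithmetic and the d_z identity", {
  # differences 1,2,3,4: mean 2.5, sd ~1.2910
  res <- paired_t(c(2, 4, 6, 8), c(1, 2, 3, 4))
  expect_equal(res$effect_size, 2.5 / sd(c(1, 2, 3, 4)), tolerance = 1e-12)
  expect_equal(res$effect_size, 1.9365, tolerance = 1e-4)
  expect_equal(res$t, res$effect_size * sqrt(4), tolerance = 1e-12)
  expect_equal(res$t, 3.873, tolerance = 1e-3)
  # identity data
  x <- rnorm(10)
  res0 <- paired_t(x, x)
  expect_equal(res0$t, 0)
  expect_equal(res0$effect_size, 0)
  # d_z = t / sqrt(n) holds on random draws
  set.seed(3)
  for (i in 1:20) {
    n <- sample(5:80, 1)
    a <- rnorm(n); b <- rnorm(n)
    r <- paired_t(a, b)
    expect_lt(abs(r$effect_size - r$t / sqrt(n)), 1e-9)
    # p agrees with stats::t.test
    expect_equal(r$p, t.test(a, b, paired = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("zero-variance differences are handled per contract", {
  r <- paired_t(c(2, 3, 4), c(1, 2, 3))
  expect_true(is.infinite(r$t))
  expect_match(r$flag, "zero variance")
})

test_that("independent t test agrees with the pooled-variance reference", {
  set.seed(4)
  for (i in 1:10) {
    a <- rnorm(sample(5:40, 1), mean = 0.3)
    b <- rnorm(sample(5:40, 1))
    r <- independent_t(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$df, unname(ref$parameter))
    expect_equal(r$p, ref$p.value, tolerance = 1e-12)
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    expect_equal(r$effect_size, (mean(a) - mean(b)) / sp, tolerance = 1e-12)
  }
})

test_that("gamma reproduces hand-enumerated pair counts", {
  r <- goodman_kruskal_gamma(c(10, 20, 30, 40), c(1, 1, 0, 0))
  expect_equal(r$gamma, -1)
  expect_equal(r$concordant, 0L)
  expect_equal(r$discordant, 4L)
  r2 <- goodman_kruskal_gamma(c(10, 20, 30, 40), c(1, 0, 1, 0))
  expect_equal(r2$concordant, 1L)
  expect_equal(r2$discordant, 3L)
  expect_equal(r2$gamma, -0.5)
  r3 <- goodman_kruskal_gamma(c(10, 20, 30), c(0, 0, 0))
  expect_false(r3$defined)
  expect_true(is.na(r3$gamma))
})

test_that("gamma is antisymmetric in the choice coding and drops ties", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    s <- sample(0:100, n, replace = TRUE)  # ties on scores likely
    ch <- rbinom(n, 1, 0.5)
    if (length(unique(ch)) < 2) next
    g1 <- goodman_kruskal_gamma(s, ch)
    g2 <- goodman_kruskal_gamma(s, 1 - ch)
    if (g1$defined) expect_equal(g1$gamma, -g2$gamma, tolerance = 1e-12)
    br <- gamma_brute(s, ch)
    expect_equal(g1$concordant, br$C)
    expect_equal(g1$discordant, br$D)
  }
})

test_that("gamma group test drops undefined values (df reflects exclusions)", {
  set.seed(12)
  g <- c(rnorm(71, -0.5, 0.2), NA)  # one undefined participant of 72
  r <- gamma_group_test(g)
  expect_equal(r$df, 70)
  expect_equal(r$n, 71)
  expect_lt(abs(r$mean_gamma - (-0.5)), 4 * 0.2 / sqrt(71))
  expect_equal(r$effect_size, abs(mean(g, na.rm = TRUE)) / sd(g, na.rm = TRUE),
               tolerance = 1e-12)
  # degenerate: all equal
  rz <- gamma_group_test(c(-1, -1, -1))
  expect_true(is.infinite(rz$t))
  expect_match(rz$flag, "zero variance")
  expect_error(gamma_group_test(c(NA_real_, NA_real_)), "defined gamma")
})

test_that("mixed 2x2 ANOVA matches the means-based sums-of-squares oracle", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 8
    d <- expand.grid(participant = 1:(2 * n), w = c("e", "u"),
                     stringsAsFactors = FALSE)
    d$g <- ifelse(d$participant <= n, "imm", "del")
    d$value <- rnorm(nrow(d)) + 2 * (d$w == "e") * (d$g == "imm")
    an <- anova_2x2(d, dv = "value", between = "g", within = "w")
    or <- mixed_ss_oracle(d, "value", "participant", "g", "w")
    expect_equal(an$SS, c(or$between, or$within, or$interaction),
                 tolerance = 1e-8)
    expect_equal(an$SS_error,
                 c(or$error_between, or$error_within, or$error_within),
                 tolerance = 1e-8)
    # sum-of-squares conservation
    expect_equal(sum(an$SS[1]) + or$error_between + sum(an$SS[2:3]) +
                   or$error_within, or$total, tolerance = 1e-8)
    expect_equal(an$df1, c(1, 1, 1))
    expect_equal(an$df2, c(2 * n - 2, 2 * n - 2, 2 * n - 2))
  }
})

test_that("null data give zero F and zero partial eta squared", {
  d <- expand.grid(participant = 1:6, w = c("a", "b"),
                   stringsAsFactors = FALSE)
  d$g <- ifelse(d$participant <= 3, "x", "y")
  d$value <- d$participant  # participant effect only, no condition effects
  an <- anova_2x2(d, dv = "value", between = "g", within = "w")
  expect_equal(an$F[an$effect == "w"], 0)
  expect_equal(an$pes[an$effect == "w"], 0)
  expect_equal(an$p[an$effect == "w"], 1)
})

test_that("fully within 2x2 ANOVA uses effect-specific error terms", {
  set.seed(31)
  n <- 10
  d <- expand.grid(participant = 1:n, acc = c("cor", "inc"),
                   att = c("exp", "une"), stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d)) + 1.5 * (d$acc == "cor")
  an <- anova_2x2(d, dv = "value", within = c("acc", "att"))
  expect_equal(an$df1, c(1, 1, 1))
  expect_equal(an$df2, rep(n - 1, 3))
  # acc effect against its own participant-interaction error (oracle)
  wide_c <- tapply(d$value[d$acc == "cor"], d$participant[d$acc == "cor"],
                   mean)
  wide_i <- tapply(d$value[d$acc == "inc"], d$participant[d$acc == "inc"],
                   mean)
  tt <- paired_t(wide_c, wide_i)
  expect_equal(an$F[1], tt$t^2, tolerance = 1e-8)
  expect_equal(an$p[1], tt$p, tolerance = 1e-8)
})

test_that("unbalanced designs are rejected", {
  d <- expand.grid(participant = 1:6, w = c("a", "b"),
                   stringsAsFactors = FALSE)
  d$g <- ifelse(d$participant <= 3, "x", "y")
  d$value <- rnorm(nrow(d))
  expect_error(anova_2x2(d[-1, ], dv = "value", between = "g", within = "w"),
               "unbalanced|balanced")
  d2 <- d; d2$g <- ifelse(d2$participant <= 2, "x", "y")
  expect_error(anova_2x2(d2, dv = "value", between = "g", within = "w"),
               "equal group sizes")
})

test_that("Loftus-Masson half-width matches a hand two-way decomposition", {
  m <- matrix(c(10, 12,
                14, 17,
                9, 12,
                13, 14), 4, 2, byrow = TRUE)
  ci <- loftus_masson_ci(m)
  # hand decomposition: residual after removing row and column means
  n <- 4; k <- 2
  res <- m - rowMeans(m) - rep(colMeans(m), each = n) + mean(m)
  ms <- sum(res^2) / ((n - 1) * (k - 1))
  expect_equal(ci$df, (n - 1) * (k - 1))
  expect_equal(ci$half_width, qt(.975, 3) * sqrt(ms / 4), tolerance = 1e-12)
  expect_equal(unname(ci$means), colMeans(m))
  # identical condition differences: zero interaction error
  m0 <- cbind(1:5, (1:5) + 3)
  expect_equal(loftus_masson_ci(m0)$half_width, 0)
  # df formula at the study scale
  expect_equal(loftus_masson_ci(matrix(rnorm(144), 72, 2))$df, 71)
})

test_that("power search satisfies the boundary property on a grid", {
  for (dz in c(0.2, 0.35, 0.5, 0.8)) {
    for (al in c(0.01, 0.05)) {
      for (pw in c(0.8, 0.9)) {
        for (sided in c(1, 2)) {
          r <- required_n_paired_t(dz, al, pw, sided)
          expect_gte(r$achieved_power, pw)
          expect_lt(r$power_at_n_minus_1, pw)
        }
      }
    }
  }
  # two-sided reference case
  expect_equal(required_n_paired_t(0.5, 0.05, 0.80, sided = 2)$n, 34)
  # power is nondecreasing in n
  pow <- vapply(5:200, function(n) {
    pt(qt(.95, n - 1), n - 1, ncp = 0.35 * sqrt(n), lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(diff(pow) > -1e-12))
  expect_error(required_n_paired_t(0), "positive")
})

test_that("power search agrees with the stats::power.t.test reference", {
  ref <- power.t.test(delta = 0.35, sd = 1, sig.level = 0.05, power = 0.90,
                      type = "one.sample", alternative = "one.sided")
  r <- required_n_paired_t(0.35, 0.05, 0.90, sided = 1)
  expect_equal(r$n, ceiling(ref$n))
})

test_that("restudy rates per cell match a hand tally", {
  trials <- data.frame(
    participant = rep(c("p1", "p2", "p3"), times = c(4, 4, 2)),
    attribution_accuracy = c("cor", "cor", "inc", "inc",
                             "cor", "cor", "cor", "inc",
                             "cor", "cor"),
    source_attribution = "expected",
    restudy_choice = c(1, 0, 1, 1,
                       0, 0, 1, NA,
                       1, 1))
  r <- restudy_rates_by_cell(trials)
  p1c <- r[r$participant == "p1" & r$attribution_accuracy == "cor", ]
  expect_equal(p1c$rate, 0.5)   # 1 of 2 chosen
  p1i <- r[r$participant == "p1" & r$attribution_accuracy == "inc", ]
  expect_equal(p1i$rate, 1)     # 2 of 2
  p2c <- r[r$participant == "p2" & r$attribution_accuracy == "cor", ]
  expect_equal(p2c$rate, 1 / 3) # NA-choice trial excluded
  expect_false(any(r$participant == "p2" & r$attribution_accuracy == "inc"))
  # the published worked example: 12 of 24 -> .50
  tr <- data.frame(participant = "p", attribution_accuracy = "cor",
                   source_attribution = "expected",
                   restudy_choice = rep(c(1, 0), each = 12))
  expect_equal(restudy_rates_by_cell(tr)$rate, 0.5)
})
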