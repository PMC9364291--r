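small_cfg <- experiment_config(n_per_group = 6L)

test_that("simulation is bit-identical under a fixed seed", {
  t1 <- simulate_experiment(small_cfg, seed = 3)
  t2 <- simulate_experiment(small_cfg, seed = 3)
  expect_identical(t1, t2)
  t3 <- simulate_experiment(small_cfg, seed = 4)
  expect_false(identical(t1, t3))
})

test_that("record structure honors the phase contracts", {
  tr <- simulate_experiment(small_cfg, seed = 11)
  # JOSs only at study (immediate) or delayed judgment (delayed)
  expect_true(all(is.na(tr$jos[tr$group == "immediate" &
                                 tr$phase != "study"])))
  expect_true(all(!is.na(tr$jos[tr$group == "immediate" &
                                  tr$phase == "study"])))
  expect_true(all(is.na(tr$jos[tr$group == "delayed" &
                                 tr$phase != "delayed_judgment"])))
  # new items only in the test phase
  expect_true(all(tr$phase[tr$expectancy == "new"] == "test"))
  # JOS range
  jos <- tr$jos[!is.na(tr$jos)]
  expect_true(all(jos >= 0 & jos <= 100 & jos == round(jos)))
})

test_that("the restudy cap binds: exactly 32 restudied, at most 32 chosen", {
  tr <- simulate_experiment(experiment_config(n_per_group = 10L), seed = 21)
  for (d in split(tr, tr$participant)) {
    expect_equal(sum(d$phase == "restudy"), 32)
    chosen <- sum(d$restudy_choice, na.rm = TRUE)
    expect_lte(chosen, 32)
    # chosen pairs are all among the restudied ones
    chosen_items <- d$item[!is.na(d$restudy_choice) & d$restudy_choice == 1]
    expect_true(all(chosen_items %in% d$item[d$phase == "restudy"]))
  }
})

test_that("substitution fills to 16 expected + 16 unexpected when nothing is chosen", {
  cfg <- experiment_config(n_per_group = 5L,
                           restudy = list(cap = 32L, intercept = -30,
                                          slope = 0))
  tr <- simulate_experiment(cfg, seed = 31)
  for (d in split(tr[tr$phase == "restudy", ], tr[tr$phase == "restudy",
                                                  "participant"])) {
    expect_equal(sum(d$expectancy == "expected"), 16)
    expect_equal(sum(d$expectancy == "unexpected"), 16)
  }
})

test_that("aggregation conserves totals and matches a hand tally", {
  tr <- simulate_experiment(small_cfg, seed = 41)
  agg <- aggregate_frequencies(tr)
  for (grp in c("immediate", "delayed")) {
    expect_equal(sum(agg[[grp]]$afc3), 6 * 96)
    expect_equal(unname(rowSums(agg[[grp]]$afc3)), rep(6 * 32, 3))
    # per-participant tables sum to the group table
    expect_equal(Reduce(`+`, lapply(agg[[grp]]$by_participant, unclass)),
                 unclass(agg[[grp]]$afc3), ignore_attr = TRUE)
  }
  expect_equal(unname(rowSums(agg$delayed$afc2)), rep(6 * 32, 2))
  expect_null(agg$immediate$afc2)
  # hand tally for one participant
  pid <- tr$participant[1]
  d <- tr[tr$participant == pid & tr$phase == "test", ]
  hand <- table(factor(d$expectancy, c("expected", "unexpected", "new")),
                factor(d$response, c("expected", "unexpected", "new")))
  expect_equal(unclass(agg$immediate$by_participant[[pid]]),
               unclass(hand), ignore_attr = TRUE)
  # unknown phases are rejected
  bad <- tr; bad$phase[1] <- "mystery"
  expect_error(aggregate_frequencies(bad), "unknown phase")
})

test_that("aggregate proportions converge to the tree probabilities without heterogeneity", {
  cfg <- experiment_config(n_per_group = 400L, mpt_sd = 0,
                           restudy_boost = 0)
  tr <- simulate_experiment(cfg, seed = 51)
  agg <- aggregate_frequencies(tr)
  for (grp in c("immediate", "delayed")) {
    P <- category_probabilities(do.call(mpt_params,
                                        as.list(cfg$mpt_means[[grp]])))
    obs <- sweep(unclass(agg[[grp]]$afc3), 1,
                 rowSums(agg[[grp]]$afc3), "/")
    n_row <- 400 * 32
    se <- sqrt(P * (1 - P) / n_row)
    expect_true(all(abs(obs - P) < 4 * se + 1e-12))
  }
})

test_that("default generator reproduces the qualitative monitoring pattern", {
  for (seed in c(61, 62, 63)) {
    tr <- simulate_experiment(experiment_config(n_per_group = 36L),
                              seed = seed)
    jos <- mptsource:::jos_cell_means(tr, "jos")
    imm <- tapply(jos$value[jos$group == "immediate"],
                  jos$expectancy[jos$group == "immediate"], mean)
    del <- tapply(jos$value[jos$group == "delayed"],
                  jos$expectancy[jos$group == "delayed"], mean)
    expect_gt(imm[["expected"]] - imm[["unexpected"]], 5)
    expect_lt(abs(del[["expected"]] - del[["unexpected"]]), 5)
    gam <- mptsource:::per_participant_gammas(tr)
    expect_gt(mean(gam$gamma < 0, na.rm = TRUE), 0.8)
  }
})

test_that("exclusion screening flags non-choosers and undefined gammas", {
  cfg <- experiment_config(n_per_group = 4L,
                           restudy = list(cap = 32L, intercept = -30,
                                          slope = 0))
  tr <- simulate_experiment(cfg, seed = 71)
  rep <- validate_dataset(tr)
  expect_equal(sum(rep$reason == "no_restudy_choices"), 8)
  # all-yes chooser: gamma undefined but choices present
  hand <- data.frame(
    participant = "p9", group = "immediate", phase = "study",
    item = paste0("i", 1:4), expectancy = "expected",
    response = NA_character_, jos = c(10, 40, 60, 90),
    restudy_choice = 1L, restudied = NA)
  rep2 <- validate_dataset(hand)
  expect_true("gamma_undefined" %in% rep2$reason)
  expect_false("no_restudy_choices" %in% rep2$reason)
  # clean data: empty report
  tr_ok <- simulate_experiment(small_cfg, seed = 72)
  expect_equal(nrow(validate_dataset(tr_ok)), 0)
})

test_that("restudy boost raises source memory for restudied items", {
  cfg <- experiment_config(n_per_group = 150L, mpt_sd = 0,
                           restudy_boost = 1.5)
  tr <- simulate_experiment(cfg, seed = 81)
  test_imm <- tr[tr$group == "immediate" & tr$phase == "test" &
                   tr$expectancy != "new", ]
  correct <- test_imm$response == test_imm$expectancy
  acc_re <- mean(correct[test_imm$restudied])
  acc_no <- mean(correct[!test_imm$restudied])
  expect_gt(acc_re, acc_no + 0.03)
})

test_that("trial records round-trip through delimited text", {
  tr <- simulate_experiment(small_cfg, seed = 91)
  f <- tempfile(fileext = ".csv")
  write_trials(tr, f)
  back <- read_trials(f)
  expect_equal(back, tr)
  # missing required column
  f2 <- tempfile(fileext = ".csv")
  write.csv(tr[, -3], f2, row.names = FALSE)
  expect_error(read_trials(f2), "missing required columns")
  unlink(c(f, f2))
})
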