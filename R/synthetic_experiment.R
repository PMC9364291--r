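#' Configuration of the simulated two-group judgment-of-source experiment
#'
#' Defines the generative model for a 2 (judgment timing: immediate vs.
#' delayed, between subjects) x 2 (source-item expectancy: expected vs.
#' unexpected, within subjects) experiment: 72 participants per group study
#' 32 expected and 32 unexpected source-item pairs, judge their future source
#' memory (JOS, 0-100) and choose pairs for restudy (immediately at study or
#' after a delayed 2AFC source-attribution attempt), restudy exactly 32
#' pairs, and complete a 3AFC source-monitoring test over the 64 studied
#' items plus 32 distractors.
#'
#' Defaults are calibrated once to the published study conditions:
#' group-level memory parameters at the hierarchical estimates of the
#' corresponding groups; 2AFC retrieval parameters solved from the printed
#' correct-attribution rates (75% expected, 61% unexpected) with
#' schema-consistent guessing `g' = .69`; an expectancy effect of +15 JOS
#' points in the immediate group and a weak inverse effect (-2) in the
#' delayed group; and restudy choices that decrease with the JOS, producing
#' predominantly negative JOS-restudy gamma correlations and a near-binding
#' 32-pair cap.
#'
#' @param n_per_group participants per group.
#' @param n_items named vector: studied `expected` and `unexpected` pairs and
#'   `new` distractors.
#' @param mpt_means list with elements `immediate` and `delayed`, each a
#'   probability-scale named 6-vector (`D_E, D_U, d_E, d_U, b, g`) of
#'   group-level means.
#' @param mpt_sd probit-scale heterogeneity SDs (length 6 or scalar).
#' @param afc2 delayed-group source-retrieval model: `dprime_E`, `dprime_U`
#'   (retrieval probabilities) and `gprime` (guess-expected probability);
#'   P(correct | expected) = `dprime_E + (1 - dprime_E) * gprime`,
#'   P(correct | unexpected) = `dprime_U + (1 - dprime_U) * (1 - gprime)`.
#' @param jos JOS linear model: `intercept`; `expectancy_immediate` and
#'   `expectancy_delayed` (mean JOS difference expected - unexpected);
#'   `accuracy_effect` (JOS boost after a correct 2AFC attribution, delayed
#'   group); `intercept_sd` and `slope_sd` (participant random intercept and
#'   random expectancy-slope SDs); `resid_sd`. JOSs are rounded and clamped
#'   to 0-100.
#' @param restudy choice model: `cap` (32), `intercept` and `slope` of the
#'   logistic choice probability `plogis(intercept + slope * (jos - 50))`;
#'   choices are offered sequentially and stop once the cap is reached; if
#'   fewer than `cap` pairs are chosen the remainder is substituted with a
#'   random 50/50 split of unchosen expected and unexpected pairs.
#' @param restudy_boost additive probit shift applied to the item- and
#'   source-memory parameters of restudied items at test (default 0).
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(
    n_per_group = 72L,
    n_items = c(expected = 32L, unexpected = 32L, new = 32L),
    mpt_means = list(
      immediate = c(D_E = .71, D_U = .73, d_E = .48, d_U = .83,
                    b = .33, g = .75),
      delayed = c(D_E = .78, D_U = .83, d_E = .31, d_U = .64,
                  b = .39, g = .61)),
    mpt_sd = 0.5,
    afc2 = list(dprime_E = (0.75 - 0.69) / (1 - 0.69),
                dprime_U = (0.61 - 0.31) / 0.69,
                gprime = 0.69),
    jos = list(intercept = 50, expectancy_immediate = 15,
               expectancy_delayed = -2, accuracy_effect = 20,
               intercept_sd = 10, slope_sd = 10, resid_sd = 12),
    restudy = list(cap = 32L, intercept = 0, slope = -1 / 15),
    restudy_boost = 0) {
  if (length(mpt_sd) == 1) mpt_sd <- rep(mpt_sd, 6)
  names(mpt_sd) <- MPT_PARAM_NAMES
  for (grp in c("immediate", "delayed")) {
    v <- mpt_means[[grp]][MPT_PARAM_NAMES]
    if (any(is.na(v)) || any(v <= 0) || any(v >= 1)) {
      stop("mpt_means$", grp, " must be probabilities in (0, 1) named ",
           paste(MPT_PARAM_NAMES, collapse = ", "), call. = FALSE)
    }
    mpt_means[[grp]] <- v
  }
  with(afc2, {
    stopifnot(dprime_E >= 0, dprime_E <= 1, dprime_U >= 0, dprime_U <= 1,
              gprime >= 0, gprime <= 1)
  })
  n_items <- n_items[c("expected", "unexpected", "new")]
  if (any(is.na(n_items)) || any(n_items < 1)) {
    stop("n_items must name positive expected/unexpected/new counts",
         call. = FALSE)
  }
  if (restudy$cap > n_items[["expected"]] + n_items[["unexpected"]]) {
    stop("restudy cap exceeds the number of studied pairs", call. = FALSE)
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 n_items = n_items, mpt_means = mpt_means, mpt_sd = mpt_sd,
                 afc2 = afc2, jos = jos, restudy = restudy,
                 restudy_boost = restudy_boost),
            class = "experiment_config")
}

# one participant's trial records; rng state is consumed sequentially
simulate_participant <- function(pid, group, config) {
  ni <- config$n_items
  n_stud <- ni[["expected"]] + ni[["unexpected"]]
  expectancy <- rep(c("expected", "unexpected"),
                    c(ni[["expected"]], ni[["unexpected"]]))
  item <- paste0(substr(expectancy, 1, 1), seq_len(n_stud))

  # individual memory parameters on the probit scale
  mu_z <- qnorm(config$mpt_means[[group]])
  z <- mu_z + rnorm(6, 0, config$mpt_sd)
  u_i <- rnorm(1, 0, config$jos$intercept_sd)
  v_i <- rnorm(1, 0, config$jos$slope_sd)

  # study order is random; JOS/choices follow this order in the immediate
  # group, a fresh order in the delayed-judgment phase
  study_order <- sample.int(n_stud)

  beta_exp <- if (group == "immediate") config$jos$expectancy_immediate
              else config$jos$expectancy_delayed
  x_e <- as.numeric(expectancy == "expected")

  attribution <- rep(NA_character_, n_stud)
  accuracy <- rep(NA, n_stud)
  if (group == "delayed") {
    p_exp_resp <- ifelse(
      expectancy == "expected",
      config$afc2$dprime_E + (1 - config$afc2$dprime_E) * config$afc2$gprime,
      (1 - config$afc2$dprime_U) * config$afc2$gprime)
    to_expected <- runif(n_stud) < p_exp_resp
    attribution <- ifelse(to_expected, "expected", "unexpected")
    accuracy <- attribution == expectancy
  }

  jos <- config$jos$intercept + u_i + (beta_exp + v_i) * x_e +
    rnorm(n_stud, 0, config$jos$resid_sd)
  if (group == "delayed") {
    jos <- jos + config$jos$accuracy_effect * as.numeric(accuracy)
  }
  jos <- pmin(pmax(round(jos), 0), 100)

  # sequential restudy choices with the cap; NA = choice not offered
  judge_order <- if (group == "immediate") study_order else sample.int(n_stud)
  choice <- rep(NA_integer_, n_stud)
  chosen <- 0L
  for (ix in judge_order) {
    if (chosen >= config$restudy$cap) break
    p <- plogis(config$restudy$intercept +
                  config$restudy$slope * (jos[ix] - 50))
    choice[ix] <- as.integer(runif(1) < p)
    chosen <- chosen + choice[ix]
  }

  # substitution: fill to the cap with a 50/50 expected/unexpected split
  restudied <- !is.na(choice) & choice == 1L
  deficit <- config$restudy$cap - sum(restudied)
  if (deficit > 0) {
    half <- deficit %/% 2
    want <- c(expected = half + (deficit %% 2) * as.integer(runif(1) < 0.5),
              unexpected = 0L)
    want[["unexpected"]] <- deficit - want[["expected"]]
    pool_e <- which(!restudied & expectancy == "expected")
    pool_u <- which(!restudied & expectancy == "unexpected")
    take_e <- min(want[["expected"]], length(pool_e))
    take_u <- min(want[["unexpected"]], length(pool_u))
    sub <- c(pool_e[sample.int(length(pool_e), take_e)],
             pool_u[sample.int(length(pool_u), take_u)])
    short <- deficit - take_e - take_u
    if (short > 0) {  # one pool exhausted; top up from the other
      rest <- setdiff(c(pool_e, pool_u), sub)
      sub <- c(sub, rest[sample.int(length(rest), short)])
    }
    restudied[sub] <- TRUE
  }

  # test-phase parameters, with an optional probit boost for restudied items
  theta_base <- pnorm(z)
  names(theta_base) <- MPT_PARAM_NAMES
  boost <- config$restudy_boost
  test_expectancy <- c(expectancy, rep("new", ni[["new"]]))
  test_item <- c(item, paste0("n", seq_len(ni[["new"]])))
  test_restudied <- c(restudied, rep(FALSE, ni[["new"]]))
  resp <- character(length(test_item))
  P_base <- category_probabilities(as_mpt_params(theta_base))
  P_boost <- if (boost != 0) {
    zb <- z
    zb[c(1, 2, 3, 4)] <- zb[c(1, 2, 3, 4)] + boost  # D_E, D_U, d_E, d_U
    category_probabilities(as_mpt_params(pnorm(zb)))
  } else P_base
  rows <- match(test_expectancy, c("expected", "unexpected", "new"))
  for (k in seq_along(resp)) {
    P <- if (test_restudied[k]) P_boost else P_base
    resp[k] <- sample(c("expected", "unexpected", "new"), 1,
                      prob = P[rows[k], ])
  }

  # assemble the per-phase records
  study <- data.frame(
    participant = pid, group = group, phase = "study",
    item = item[study_order], expectancy = expectancy[study_order],
    response = NA_character_,
    jos = if (group == "immediate") jos[study_order] else NA_integer_,
    restudy_choice = if (group == "immediate") choice[study_order]
                     else NA_integer_,
    restudied = NA, stringsAsFactors = FALSE)
  delayed <- NULL
  if (group == "delayed") {
    dj_order <- sample.int(n_stud)
    delayed <- data.frame(
      participant = pid, group = group, phase = "delayed_judgment",
      item = item[dj_order], expectancy = expectancy[dj_order],
      response = attribution[dj_order], jos = jos[dj_order],
      restudy_choice = choice[dj_order], restudied = NA,
      stringsAsFactors = FALSE)
  }
  restudy_rows <- which(restudied)
  restudy_df <- data.frame(
    participant = pid, group = group, phase = "restudy",
    item = item[restudy_rows], expectancy = expectancy[restudy_rows],
    response = NA_character_, jos = NA_integer_, restudy_choice = NA_integer_,
    restudied = TRUE, stringsAsFactors = FALSE)
  test_order <- sample.int(length(test_item))
  test <- data.frame(
    participant = pid, group = group, phase = "test",
    item = test_item[test_order], expectancy = test_expectancy[test_order],
    response = resp[test_order], jos = NA_integer_,
    restudy_choice = NA_integer_, restudied = test_restudied[test_order],
    stringsAsFactors = FALSE)
  rbind(study, delayed, restudy_df, test)
}

#' Simulate the full two-group experiment
#'
#' Generates trial-level records for every phase of the experiment (study,
#' delayed judgment for the delayed group, restudy, test) under the
#' generative model described in [experiment_config]. Deterministic given
#' `seed`.
#'
#' @param config an [experiment_config].
#' @param seed master integer seed.
#' @return a data.frame of trial records with columns `participant`, `group`,
#'   `phase`, `item`, `expectancy`, `response`, `jos`, `restudy_choice`,
#'   `restudied`.
#' @examples
#' tr <- simulate_experiment(experiment_config(n_per_group = 4), seed = 1)
#' table(tr$group, tr$phase)
#' @export
simulate_experiment <- function(config = experiment_config(), seed = 1L) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(seed)
  recs <- vector("list", 2 * config$n_per_group)
  k <- 0
  for (group in c("immediate", "delayed")) {
    for (i in seq_len(config$n_per_group)) {
      k <- k + 1
      pid <- sprintf("%s_%02d", substr(group, 1, 3), i)
      recs[[k]] <- simulate_participant(pid, group, config)
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Aggregate trial records into frequency tables
#'
#' Builds, per group, the 3x3 test-phase response-frequency table (aggregated
#' over items and participants), the per-participant 3x3 tables used for
#' hierarchical fitting, and — for the delayed group — the 2x2 table of the
#' delayed-judgment 2AFC source attributions.
#'
#' @param trials trial records as produced by [simulate_experiment] or
#'   [read_trials].
#' @return a named list per group present in the data; each element is a list
#'   with `afc3` ([frequency_table]), `by_participant` (list of
#'   [frequency_table]), and `afc2` (delayed group only).
#' @export
aggregate_frequencies <- function(trials) {
  known <- c("study", "delayed_judgment", "restudy", "test")
  if (any(!trials$phase %in% known)) {
    stop("records with unknown phase: ",
         paste(unique(setdiff(trials$phase, known)), collapse = ", "),
         call. = FALSE)
  }
  lv <- c("expected", "unexpected", "new")
  out <- list()
  for (grp in unique(trials$group)) {
    g3 <- trials[trials$group == grp & trials$phase == "test", ]
    cnt <- table(factor(g3$expectancy, lv), factor(g3$response, lv))
    res <- list(afc3 = frequency_table(unclass(cnt), "3AFC", label = grp))
    res$by_participant <- lapply(split(g3, g3$participant), function(d) {
      frequency_table(unclass(table(factor(d$expectancy, lv),
                                    factor(d$response, lv))),
                      "3AFC", label = d$participant[1])
    })
    g2 <- trials[trials$group == grp & trials$phase == "delayed_judgment", ]
    if (nrow(g2) > 0) {
      cnt2 <- table(factor(g2$expectancy, lv[1:2]),
                    factor(g2$response, lv[1:2]))
      res$afc2 <- frequency_table(unclass(cnt2), "2AFC", label = grp)
    }
    out[[grp]] <- res
  }
  out
}

#' Screen a data set for participants to exclude
#'
#' Flags participants who chose no source-item pairs for restudy (the
#' published exclusion rule) and participants whose JOS-restudy gamma
#' correlation is undefined (no concordant or discordant pairs, e.g. all
#' offered choices identical), who must be excluded listwise from the
#' gamma group tests.
#'
#' @param trials trial records.
#' @return a data.frame with columns `participant`, `group`, `reason`;
#'   zero rows when nothing is flagged.
#' @export
validate_dataset <- function(trials) {
  jos_phase <- ifelse(trials$group == "immediate", "study",
                      "delayed_judgment")
  jt <- trials[trials$phase == jos_phase, ]
  out <- data.frame(participant = character(), group = character(),
                    reason = character(), stringsAsFactors = FALSE)
  for (d in split(jt, jt$participant)) {
    off <- d[!is.na(d$restudy_choice), ]
    if (nrow(off) == 0 || sum(off$restudy_choice) == 0) {
      out <- rbind(out, data.frame(participant = d$participant[1],
                                   group = d$group[1],
                                   reason = "no_restudy_choices"))
    }
    if (nrow(off) >= 2) {
      gr <- goodman_kruskal_gamma(off$jos, off$restudy_choice)
      if (!gr$defined) {
        out <- rbind(out, data.frame(participant = d$participant[1],
                                     group = d$group[1],
                                     reason = "gamma_undefined"))
      }
    } else {
      out <- rbind(out, data.frame(participant = d$participant[1],
                                   group = d$group[1],
                                   reason = "gamma_undefined"))
    }
  }
  rownames(out) <- NULL
  out
}

#' Read / write trial records as delimited text
#'
#' @param path file path.
#' @param trials trial-record data.frame.
#' @return `read_trials` returns the trial data.frame; `write_trials`
#'   invisibly returns `path`.
#' @export
read_trials <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "group", "phase", "item", "expectancy",
            "response", "jos", "restudy_choice", "restudied")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing required columns in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), need)
  if (length(extra)) {
    warning("ignoring unknown columns: ", paste(extra, collapse = ", "))
    df <- df[, need]
  }
  df$response[!is.na(df$response) & df$response == ""] <- NA_character_
  df$jos <- as.integer(df$jos)
  df$restudy_choice <- as.integer(df$restudy_choice)
  df$restudied <- as.logical(df$restudied)
  df
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
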