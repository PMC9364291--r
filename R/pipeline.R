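# md5 of the JSON-serialized configuration; provenance for reports
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

# per-participant cell means of a trial column, immediate group from the
# study phase, delayed group from the delayed-judgment phase
jos_cell_means <- function(trials, what = c("jos", "choice")) {
  what <- match.arg(what)
  jt <- trials[(trials$group == "immediate" & trials$phase == "study") |
                 (trials$group == "delayed" &
                    trials$phase == "delayed_judgment"), ]
  v <- if (what == "jos") jt$jos else jt$restudy_choice
  keep <- !is.na(v)
  agg <- stats::aggregate(
    v[keep],
    by = list(participant = jt$participant[keep], group = jt$group[keep],
              expectancy = jt$expectancy[keep]),
    FUN = if (what == "jos") mean else sum)
  names(agg)[4] <- "value"
  agg
}

per_participant_gammas <- function(trials) {
  jt <- trials[(trials$group == "immediate" & trials$phase == "study") |
                 (trials$group == "delayed" &
                    trials$phase == "delayed_judgment"), ]
  jt <- jt[!is.na(jt$restudy_choice), ]
  res <- lapply(split(jt, jt$participant), function(d) {
    g <- if (nrow(d) >= 2) goodman_kruskal_gamma(d$jos, d$restudy_choice)
         else list(gamma = NA_real_, defined = FALSE)
    data.frame(participant = d$participant[1], group = d$group[1],
               gamma = g$gamma, defined = g$defined,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# descriptive + inferential statistics computed from trial-level records
behavioral_report <- function(trials) {
  jos <- jos_cell_means(trials, "jos")
  cho <- jos_cell_means(trials, "choice")
  an_jos <- anova_2x2(jos, dv = "value", between = "group",
                      within = "expectancy")
  an_cho <- anova_2x2(cho, dv = "value", between = "group",
                      within = "expectancy")
  follow <- list()
  for (grp in c("immediate", "delayed")) {
    for (nm in c("jos", "choice")) {
      d <- if (nm == "jos") jos else cho
      d <- d[d$group == grp, ]
      wide <- merge(d[d$expectancy == "expected", c("participant", "value")],
                    d[d$expectancy == "unexpected", c("participant", "value")],
                    by = "participant")
      follow[[paste(grp, nm, sep = "_")]] <- paired_t(wide$value.x,
                                                      wide$value.y)
    }
  }
  gam <- per_participant_gammas(trials)
  gtests <- list(
    immediate = gamma_group_test(gam$gamma[gam$group == "immediate"]),
    delayed = gamma_group_test(gam$gamma[gam$group == "delayed"]),
    between = independent_t(gam$gamma[gam$group == "immediate" & gam$defined],
                            gam$gamma[gam$group == "delayed" & gam$defined]))
  # within-subjects error bars for the JOS cell means, per group
  ci <- lapply(c("immediate", "delayed"), function(grp) {
    d <- jos[jos$group == grp, ]
    m <- cbind(expected = d$value[d$expectancy == "expected"][
                 order(d$participant[d$expectancy == "expected"])],
               unexpected = d$value[d$expectancy == "unexpected"][
                 order(d$participant[d$expectancy == "unexpected"])])
    loftus_masson_ci(m)
  })
  names(ci) <- c("immediate", "delayed")
  # delayed-group 2AFC summary
  afc2 <- NULL
  dj <- trials[trials$phase == "delayed_judgment", ]
  if (nrow(dj) > 0) {
    correct <- dj$response == dj$expectancy
    by_part <- stats::aggregate(correct, list(participant = dj$participant),
                                mean)
    by_exp <- stats::aggregate(
      correct, list(participant = dj$participant,
                    expectancy = dj$expectancy), mean)
    wide <- merge(by_exp[by_exp$expectancy == "expected",
                         c("participant", "x")],
                  by_exp[by_exp$expectancy == "unexpected",
                         c("participant", "x")],
                  by = "participant")
    afc2 <- list(
      pct_correct = 100 * mean(correct),
      pct_correct_expected = 100 * mean(correct[dj$expectancy == "expected"]),
      pct_correct_unexpected =
        100 * mean(correct[dj$expectancy == "unexpected"]),
      t_vs_chance = paired_t(by_part$x, 1 - by_part$x),
      t_expected_vs_unexpected = paired_t(wide$x.x, wide$x.y))
  }
  list(anova_jos = an_jos, anova_choices = an_cho, follow_up = follow,
       gammas = gam, gamma_tests = gtests, jos_within_ci = ci, afc2 = afc2)
}

ordering_checks <- function(ml_fits) {
  do.call(rbind, lapply(names(ml_fits), function(grp) {
    p <- ml_fits[[grp]]$params
    data.frame(group = grp,
               inconsistency_effect = unname(p["d_U"] > p["d_E"]),
               schema_consistent_guessing = unname(p["g"] > 0.5))
  }))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> validate -> aggregate -> fit (aggregate ML and,
#' optionally, hierarchical Bayes) -> diagnostics -> behavioral statistics,
#' and collects everything in a reproducible report. Three input modes are
#' supported: `"synthetic"` (simulate trial records from `config` and
#' `seed`), `"trials"` (trial-level records from `trials` or `trials_file`),
#' and `"frequencies"` (aggregate tables only; behavioral statistics and
#' hierarchical fitting are skipped because they require trial- or
#' participant-level data).
#'
#' @param input one of `"synthetic"`, `"trials"`, `"frequencies"`.
#' @param config an [experiment_config] (synthetic mode).
#' @param seed master seed; controls simulation, hierarchical fitting and
#'   posterior predictive checks.
#' @param trials trial-record data.frame (trials mode).
#' @param trials_file path to a trial-record CSV (trials mode).
#' @param freq_files named list of frequency-table CSV paths; names are taken
#'   as group labels, and a name ending in `_2afc` attaches a 2AFC table to
#'   the group named by its stem (frequencies mode).
#' @param hb fit the hierarchical model (modes with individual data).
#' @param hb_ctrl run-length settings for the hierarchical fit, see
#'   [hb_control].
#' @param rhat_warn threshold above which a convergence warning is recorded
#'   in the report.
#' @return an object of class `pipeline_report`; see [write_report].
#' @export
run_pipeline <- function(input = c("synthetic", "trials", "frequencies"),
                         config = experiment_config(), seed = 1L,
                         trials = NULL, trials_file = NULL, freq_files = NULL,
                         hb = TRUE, hb_ctrl = hb_control("desk"),
                         rhat_warn = 1.05) {
  input <- match.arg(input)
  report <- list(input = input, seed = seed, warnings = character(),
                 versions = list(
                   mptsource = as.character(utils::packageVersion("mptsource")),
                   R = paste(R.version$major, R.version$minor, sep = ".")))

  if (input == "frequencies") {
    if (is.null(freq_files)) stop("freq_files required", call. = FALSE)
    tabs <- lapply(freq_files, read_frequency_table)
    names(tabs) <- names(freq_files)
    is2 <- grepl("_2afc$", names(tabs))
    groups <- names(tabs)[!is2]
    report$frequency_tables <- tabs
    report$ml_fits <- lapply(tabs[groups], fit_mpt_ml)
    report$ordering <- ordering_checks(report$ml_fits)
    for (nm in names(tabs)[is2]) {
      tb <- tabs[[nm]]
      report$afc2_percent <- list(
        group = sub("_2afc$", "", nm),
        pct_correct = 100 * sum(diag(unclass(tb))) / sum(tb),
        pct_correct_expected = 100 * tb[1, 1] / sum(tb[1, ]),
        pct_correct_unexpected = 100 * tb[2, 2] / sum(tb[2, ]))
    }
    report$provenance <- list(config_hash = config_hash(freq_files),
                              seed = seed)
    class(report) <- "pipeline_report"
    return(report)
  }

  if (input == "synthetic") {
    trials <- simulate_experiment(config, seed = seed)
    report$provenance <- list(config_hash = config_hash(config), seed = seed)
  } else {
    if (is.null(trials)) {
      if (is.null(trials_file)) stop("trials or trials_file required",
                                     call. = FALSE)
      trials <- read_trials(trials_file)
    }
    report$provenance <- list(config_hash = config_hash(trials_file %||% ""),
                              seed = seed)
  }

  report$exclusions <- validate_dataset(trials)
  agg <- aggregate_frequencies(trials)
  report$frequency_tables <- lapply(agg, `[[`, "afc3")
  for (grp in names(agg)) {
    if (!is.null(agg[[grp]]$afc2)) {
      tb <- agg[[grp]]$afc2
      report$afc2_percent <- list(
        group = grp,
        pct_correct = 100 * sum(diag(unclass(tb))) / sum(tb),
        pct_correct_expected = 100 * tb[1, 1] / sum(tb[1, ]),
        pct_correct_unexpected = 100 * tb[2, 2] / sum(tb[2, ]))
    }
  }
  report$ml_fits <- lapply(report$frequency_tables, fit_mpt_ml)
  report$ordering <- ordering_checks(report$ml_fits)
  report$behavioral <- behavioral_report(trials)

  if (hb) {
    groups <- names(agg)
    fits <- diags <- ppc <- list()
    for (k in seq_along(groups)) {
      grp <- groups[k]
      fits[[grp]] <- fit_hb(agg[[grp]]$by_participant, control = hb_ctrl,
                            seed = seed + k)
      diags[[grp]] <- gelman_rubin(fits[[grp]])
      ppc[[grp]] <- posterior_predictive_check(fits[[grp]],
                                               agg[[grp]]$by_participant,
                                               seed = seed + k)
      if (max(diags[[grp]]$rhat) >= rhat_warn) {
        report$warnings <- c(report$warnings, sprintf(
          "group %s: max R-hat %.3f >= %.2f", grp,
          max(diags[[grp]]$rhat), rhat_warn))
      }
    }
    report$hb_summaries <- lapply(fits, summarize_posterior)
    report$diagnostics <- list(
      rhat_max = vapply(diags, function(d) max(d$rhat), numeric(1)),
      rhat = diags,
      T1_p = vapply(ppc, `[[`, numeric(1), "T1_p"),
      T2_p = vapply(ppc, `[[`, numeric(1), "T2_p"))
    if (length(groups) == 2) {
      a <- fits[[groups[1]]]; b <- fits[[groups[2]]]
      report$contrasts <- list(
        delta_d_E = parameter_contrast(a, b, "d_E_1 - d_E_2",
                                       label = "delta_d_E"),
        delta_d_U = parameter_contrast(a, b, "d_U_1 - d_U_2",
                                       label = "delta_d_U"),
        delta_d_group1 = parameter_contrast(a, expr = "d_U - d_E",
                                            label = paste0("delta_d_",
                                                           groups[1])),
        delta_d_group2 = parameter_contrast(b, expr = "d_U - d_E",
                                            label = paste0("delta_d_",
                                                           groups[2])),
        delta_inconsistency = parameter_contrast(
          a, b, "(d_U_1 - d_E_1) - (d_U_2 - d_E_2)",
          label = "delta_inconsistency"))
    }
    report$hb_fits <- fits
  }
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (input:", x$input, ", seed:", x$seed, ")\n\n")
  for (grp in names(x$frequency_tables)) {
    print(x$frequency_tables[[grp]])
  }
  cat("\nAggregate ML parameter estimates:\n")
  for (grp in names(x$ml_fits)) {
    cat(" ", grp, ": ")
    cat(paste(sprintf("%s=%.3f", MPT_PARAM_NAMES,
                      unclass(x$ml_fits[[grp]]$params)[1:6]),
              collapse = " "), "\n")
  }
  print(x$ordering)
  if (!is.null(x$afc2_percent)) {
    cat(sprintf("\n2AFC correct: %.0f%% overall, %.0f%% expected, %.0f%% unexpected\n",
                x$afc2_percent$pct_correct,
                x$afc2_percent$pct_correct_expected,
                x$afc2_percent$pct_correct_unexpected))
  }
  if (!is.null(x$hb_summaries)) {
    cat("\nHierarchical posterior summaries:\n")
    for (grp in names(x$hb_summaries)) {
      cat(" group", grp, "\n")
      print(x$hb_summaries[[grp]], digits = 3)
    }
    cat("\nContrasts:\n")
    for (ct in x$contrasts) print(ct)
    cat(sprintf("\nDiagnostics: max R-hat %s; T1 p = %s; T2 p = %s\n",
                paste(sprintf("%.3f", x$diagnostics$rhat_max),
                      collapse = "/"),
                paste(sprintf("%.3f", x$diagnostics$T1_p), collapse = "/"),
                paste(sprintf("%.3f", x$diagnostics$T2_p), collapse = "/")))
  }
  if (length(x$warnings)) {
    cat("\nWARNINGS:\n", paste(" -", x$warnings, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits the report's tables as comma-separated files plus a machine-readable
#' `report.json` carrying every scalar result and the provenance (seed,
#' configuration hash, package versions).
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (grp in names(report$frequency_tables)) {
    write_frequency_table(report$frequency_tables[[grp]],
                          file.path(dir, paste0("frequencies_", grp, ".csv")))
  }
  ml <- do.call(rbind, lapply(names(report$ml_fits), function(grp) {
    f <- report$ml_fits[[grp]]
    data.frame(group = grp, parameter = MPT_PARAM_NAMES,
               estimate = unname(unclass(f$params)[1:6]),
               G2 = f$G2, boundary = f$boundary, method = f$method)
  }))
  write.csv(ml, file.path(dir, "ml_estimates.csv"), row.names = FALSE)
  if (!is.null(report$hb_summaries)) {
    hb <- do.call(rbind, lapply(names(report$hb_summaries), function(grp) {
      cbind(group = grp, report$hb_summaries[[grp]])
    }))
    write.csv(hb, file.path(dir, "hb_estimates.csv"), row.names = FALSE)
    ct <- do.call(rbind, lapply(report$contrasts, function(x) {
      data.frame(label = x$label, mean = x$mean, bci_low = x$bci[1],
                 bci_high = x$bci[2], significant = x$significant)
    }))
    write.csv(ct, file.path(dir, "contrasts.csv"), row.names = FALSE)
  }
  json <- report
  json$frequency_tables <- lapply(report$frequency_tables,
                                  function(tb) unclass(tb)[, , drop = FALSE])
  json$hb_fits <- NULL
  json$behavioral$gammas <- NULL
  writeLines(jsonlite::toJSON(json, auto_unbox = TRUE, digits = NA,
                              force = TRUE, na = "null"),
             file.path(dir, "report.json"))
  invisible(dir)
}

#' Bundled example frequency tables
#'
#' Paths to the aggregate response-frequency tables bundled with the package:
#' group-level 3AFC source-monitoring counts for an immediate-judgment and a
#' delayed-judgment group (72 participants each, 32 items per trial type,
#' 2,304 observations per row) and the delayed group's 2AFC
#' source-attribution counts from a schema-expectancy source-monitoring
#' study.
#'
#' @return named character vector of file paths (`immediate`, `delayed`,
#'   `delayed_2afc`).
#' @export
example_frequency_files <- function() {
  c(immediate = system.file("extdata", "immediate_3afc.csv",
                            package = "mptsource"),
    delayed = system.file("extdata", "delayed_3afc.csv",
                          package = "mptsource"),
    delayed_2afc = system.file("extdata", "delayed_2afc.csv",
                               package = "mptsource"))
}
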