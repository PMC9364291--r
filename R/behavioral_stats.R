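#' 2x2 ANOVA with partial eta squared
#'
#' Least-squares decomposition for the two balanced designs used in
#' judgment-of-source experiments: a mixed design with one between-subjects
#' and one within-subjects factor (each participant contributes one mean per
#' within level), and a fully within-subjects design (one mean per cell).
#' The mixed design tests the between factor against the between-participant
#' error and the within factor and interaction against the
#' participant-by-within interaction error; the fully within design uses
#' effect-specific participant-interaction error terms. Partial eta squared
#' is `SS_effect / (SS_effect + SS_error)` with the error term of that
#' effect.
#'
#' @param data long-format data.frame with one row per participant x cell.
#' @param dv name of the value column.
#' @param id name of the participant column.
#' @param between name of the between-subjects factor column (mixed design),
#'   or `NULL` for the fully within design.
#' @param within character vector of within-subjects factor column names:
#'   one for the mixed design, two for the fully within design.
#' @return a data.frame of class `anova_2x2` with columns `effect`, `df1`,
#'   `df2`, `SS`, `SS_error`, `F`, `p`, `pes` (partial eta squared).
#' @examples
#' d <- expand.grid(participant = 1:6, w = c("a", "b"))
#' d$g <- rep(c("x", "y"), each = 3)[d$participant]
#' d$value <- rnorm(nrow(d))
#' anova_2x2(d, dv = "value", between = "g", within = "w")
#' @export
anova_2x2 <- function(data, dv = "value", id = "participant",
                      between = NULL, within) {
  data <- as.data.frame(data)
  need <- c(dv, id, between, within)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(data[[dv]]))) {
    stop("non-finite values in the dependent variable", call. = FALSE)
  }
  data[[id]] <- factor(data[[id]])
  for (f in c(between, within)) data[[f]] <- factor(data[[f]])
  design <- if (!is.null(between)) "mixed" else "within"

  if (design == "mixed") {
    if (length(within) != 1) {
      stop("mixed design needs exactly one within factor", call. = FALSE)
    }
    tab <- table(data[[id]], data[[within]])
    if (any(tab != 1)) {
      stop("unbalanced design: each participant needs exactly one value per within level",
           call. = FALSE)
    }
    # each participant must sit in exactly one between group
    gtab <- table(data[[id]], data[[between]])
    if (any(rowSums(gtab > 0) != 1)) {
      stop("each participant must belong to exactly one between-subjects group",
           call. = FALSE)
    }
    if (length(unique(table(data[[between]]))) != 1 ||
        nlevels(data[[between]]) != 2 || nlevels(data[[within]]) != 2) {
      stop("unbalanced design: 2x2 with equal group sizes required",
           call. = FALSE)
    }
    n_per_group <- nlevels(droplevels(data[[id]])) / 2
    if (n_per_group < 2) stop("need >= 2 participants per group", call. = FALSE)
    fml <- stats::as.formula(sprintf("%s ~ %s * %s + Error(%s)",
                                     dv, between, within, id))
    fit <- aov(fml, data = data)
    sm <- summary(fit)
    # strata come back in order: participant stratum, then Within
    strata <- lapply(sm, function(s) as.data.frame(s[[1]]))
    sb <- strata[[1]]; sw <- strata[[2]]
    rn <- function(d) trimws(rownames(d))
    eff_b <- which(rn(sb) == between)
    res_b <- which(rn(sb) == "Residuals")
    eff_w <- which(rn(sw) == within)
    eff_i <- which(rn(sw) == paste0(between, ":", within))
    res_w <- which(rn(sw) == "Residuals")
    out <- rbind(
      data.frame(effect = between,
                 df1 = sb$Df[eff_b], df2 = sb$Df[res_b],
                 SS = sb$`Sum Sq`[eff_b], SS_error = sb$`Sum Sq`[res_b]),
      data.frame(effect = within,
                 df1 = sw$Df[eff_w], df2 = sw$Df[res_w],
                 SS = sw$`Sum Sq`[eff_w], SS_error = sw$`Sum Sq`[res_w]),
      data.frame(effect = paste0(between, ":", within),
                 df1 = sw$Df[eff_i], df2 = sw$Df[res_w],
                 SS = sw$`Sum Sq`[eff_i], SS_error = sw$`Sum Sq`[res_w]))
  } else {
    if (length(within) != 2) {
      stop("fully within design needs exactly two within factors",
           call. = FALSE)
    }
    tab <- table(data[[id]], data[[within[1]]], data[[within[2]]])
    if (any(tab != 1)) {
      stop("unbalanced design: each participant needs exactly one value per cell",
           call. = FALSE)
    }
    if (nlevels(data[[within[1]]]) != 2 || nlevels(data[[within[2]]]) != 2) {
      stop("both within factors must have two levels", call. = FALSE)
    }
    if (nlevels(data[[id]]) < 2) stop("need >= 2 participants", call. = FALSE)
    fml <- stats::as.formula(sprintf("%s ~ %s * %s + Error(%s / (%s * %s))",
                                     dv, within[1], within[2], id,
                                     within[1], within[2]))
    fit <- aov(fml, data = data)
    sm <- summary(fit)
    strata <- lapply(sm, function(s) as.data.frame(s[[1]]))
    nm <- names(sm)
    pick <- function(effect) {
      stratum_name <- sprintf("Error: %s:%s", id, effect)
      s <- strata[[which(nm == stratum_name)]]
      rn <- trimws(rownames(s))
      i <- which(rn == effect); r <- which(rn == "Residuals")
      data.frame(effect = effect, df1 = s$Df[i], df2 = s$Df[r],
                 SS = s$`Sum Sq`[i], SS_error = s$`Sum Sq`[r])
    }
    out <- rbind(pick(within[1]), pick(within[2]),
                 pick(paste0(within[1], ":", within[2])))
  }
  # clamp floating-point dust so exact-null effects report F = 0, not 0/0
  tol <- 1e-10 * (sum(abs(out$SS)) + sum(abs(out$SS_error)) + 1)
  out$SS[out$SS < tol] <- 0
  out$SS_error[out$SS_error < tol] <- 0
  ms <- out$SS / out$df1
  mse <- out$SS_error / out$df2
  out$F <- ifelse(mse > 0, ms / mse, ifelse(out$SS > 0, Inf, 0))
  out$p <- stats::pf(out$F, out$df1, out$df2, lower.tail = FALSE)
  out$p[out$F == 0] <- 1
  out$pes <- ifelse(out$SS + out$SS_error > 0,
                    out$SS / (out$SS + out$SS_error), 0)
  class(out) <- c("anova_2x2", "data.frame")
  attr(out, "design") <- design
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

t_result <- function(t, df, p, effect, effect_label, n, flag = "") {
  structure(list(t = t, df = df, p = p, effect_size = effect,
                 effect_label = effect_label, n = n, flag = flag),
            class = "t_result")
}

#' @export
print.t_result <- function(x, ...) {
  cat(sprintf("t(%s) = %.3f, p = %.4g, %s = %.3f%s\n",
              format(x$df), x$t, x$p, x$effect_label, x$effect_size,
              if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Paired-samples t test with the d_z effect size
#'
#' Exact paired t test: `t = mean(x - y) / (sd(x - y) / sqrt(n))` with
#' `n - 1` degrees of freedom. The within-subjects effect size is
#' `d_z = mean(x - y) / sd(x - y)`, which satisfies `d_z = t / sqrt(n)`.
#' Differences with zero variance give `t = 0` when the mean difference is
#' zero and an infinite, flagged `t` otherwise.
#'
#' @param x,y paired numeric vectors of equal length (n >= 2).
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return a `t_result`: list with `t`, `df`, `p`, `effect_size` (d_z),
#'   `effect_label`, `n`, `flag`.
#' @export
paired_t <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  d <- x - y
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  m <- mean(d); s <- sd(d)
  flag <- ""
  if (s == 0) {
    if (m == 0) {
      t <- 0; dz <- 0
    } else {
      t <- sign(m) * Inf; dz <- sign(m) * Inf; flag <- "zero variance"
    }
  } else {
    t <- m / (s / sqrt(n)); dz <- m / s
  }
  df <- n - 1
  p <- switch(alternative,
              two.sided = 2 * pt(abs(t), df, lower.tail = FALSE),
              greater = pt(t, df, lower.tail = FALSE),
              less = pt(t, df))
  t_result(t, df, p, dz, "d_z", n, flag)
}

#' Independent-samples t test with Cohen's d
#'
#' Pooled-variance t test with `n_a + n_b - 2` degrees of freedom; the effect
#' size is Cohen's d, the mean difference divided by the pooled SD.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return a `t_result` with `effect_size` = Cohen's d.
#' @export
independent_t <- function(a, b,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("need at least 2 observations per group",
                             call. = FALSE)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  flag <- ""
  md <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (md == 0) { t <- 0; d <- 0 }
    else { t <- sign(md) * Inf; d <- sign(md) * Inf; flag <- "zero variance" }
  } else {
    t <- md / sqrt(sp2 * (1 / na + 1 / nb))
    d <- md / sqrt(sp2)
  }
  df <- na + nb - 2
  p <- switch(alternative,
              two.sided = 2 * pt(abs(t), df, lower.tail = FALSE),
              greater = pt(t, df, lower.tail = FALSE),
              less = pt(t, df))
  t_result(t, df, p, d, "d", c(na, nb), flag)
}

#' Goodman-Kruskal gamma between judgments and binary choices
#'
#' Ordinal association over all pairs of observations: a pair is concordant
#' if `(score_i - score_j) * (choice_i - choice_j) > 0` and discordant if
#' `< 0`; pairs tied on either variable are dropped. Gamma is
#' `(C - D) / (C + D)`. With all choices identical (or all scores tied)
#' no informative pairs exist and gamma is undefined; such participants must
#' be excluded listwise from group-level tests.
#'
#' @param scores numeric judgments (e.g. 0-100 source-memory predictions).
#' @param choices binary choices coded 0/1 (e.g. restudy yes = 1).
#' @return a list of class `gamma_result`: `gamma`, `concordant`,
#'   `discordant`, `ties`, `defined`.
#' @examples
#' goodman_kruskal_gamma(c(10, 20, 30, 40), c(1, 1, 0, 0))  # gamma = -1
#' @export
goodman_kruskal_gamma <- function(scores, choices) {
  if (length(scores) != length(choices)) {
    stop("scores and choices must have equal length", call. = FALSE)
  }
  keep <- is.finite(scores) & is.finite(choices)
  scores <- scores[keep]; choices <- choices[keep]
  n <- length(scores)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  ds <- sign(outer(scores, scores, "-"))
  dc <- sign(outer(choices, choices, "-"))
  prod <- ds * dc
  up <- upper.tri(prod)
  C <- sum(prod[up] > 0)
  D <- sum(prod[up] < 0)
  ties <- sum(up) - C - D
  defined <- (C + D) > 0
  structure(list(gamma = if (defined) (C - D) / (C + D) else NA_real_,
                 concordant = C, discordant = D, ties = ties,
                 defined = defined),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("gamma = %.3f (C = %d, D = %d, ties = %d)\n",
                x$gamma, x$concordant, x$discordant, x$ties))
  } else {
    cat("gamma undefined (no concordant or discordant pairs)\n")
  }
  invisible(x)
}

#' One-sample t test of per-participant gamma correlations
#'
#' Tests the mean of the defined per-participant gamma correlations against
#' zero (no transformation is applied; the raw mean gamma is reported).
#' The effect size is `d = |mean| / SD`. Undefined gammas (`NA`) are dropped,
#' so the degrees of freedom reflect only participants with defined
#' correlations.
#'
#' @param gammas numeric vector of per-participant gamma values; `NA` for
#'   undefined ones.
#' @param alternative passed to the t test; default two-sided.
#' @return a `t_result` with `effect_size` = d and `n` = number of defined
#'   gammas.
#' @export
gamma_group_test <- function(gammas,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  g <- gammas[is.finite(gammas)]
  n <- length(g)
  if (n < 2) stop("need at least 2 defined gamma values", call. = FALSE)
  m <- mean(g); s <- sd(g)
  flag <- ""
  if (s == 0) {
    if (m == 0) { t <- 0; d <- 0 }
    else { t <- sign(m) * Inf; d <- Inf; flag <- "zero variance" }
  } else {
    t <- m / (s / sqrt(n)); d <- abs(m) / s
  }
  df <- n - 1
  p <- switch(alternative,
              two.sided = 2 * pt(abs(t), df, lower.tail = FALSE),
              greater = pt(t, df, lower.tail = FALSE),
              less = pt(t, df))
  out <- t_result(t, df, p, d, "d", n, flag)
  out$mean_gamma <- m
  out
}

#' Loftus-Masson within-subjects confidence intervals
#'
#' Error bars for within-subjects designs: after removing participant means,
#' the shared half-width of the per-condition CIs is
#' `t(conf, (n-1)(k-1)) * sqrt(MS_interaction / n)`, where
#' `MS_interaction` is the mean square of the participant-by-condition
#' interaction.
#'
#' @param m complete numeric matrix, participants x conditions (n >= 2,
#'   k >= 2).
#' @param conf confidence level (default 0.95).
#' @return a list of class `within_ci`: condition `means`, shared
#'   `half_width`, `t_crit`, `df`, `ms_error`.
#' @export
loftus_masson_ci <- function(m, conf = 0.95) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("matrix must be complete", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need >= 2 participants and >= 2 conditions",
                           call. = FALSE)
  grand <- mean(m)
  resid <- m - rowMeans(m) - rep(colMeans(m), each = n) + grand
  ss_int <- sum(resid^2)
  df <- (n - 1) * (k - 1)
  ms <- ss_int / df
  tcrit <- qt(1 - (1 - conf) / 2, df)
  structure(list(means = colMeans(m), half_width = tcrit * sqrt(ms / n),
                 t_crit = tcrit, df = df, ms_error = ms),
            class = "within_ci")
}

#' @export
print.within_ci <- function(x, ...) {
  cat(sprintf("within-subjects CI half-width = %.4f (t = %.3f, df = %d)\n",
              x$half_width, x$t_crit, x$df))
  print(round(x$means, 4))
  invisible(x)
}

#' A-priori sample size for a paired t test
#'
#' Smallest `n` at which the paired (one-sample) t test of a within-subjects
#' effect of size `d_z` reaches the target power. Power at a given `n` is
#' computed exactly from the noncentral t distribution:
#' `P(T' > t_crit(n - 1, alpha))` with noncentrality `d_z * sqrt(n)` (for
#' two-sided tests the criterion uses `alpha / 2`; the minuscule lower-tail
#' rejection region is ignored, as is conventional).
#'
#' @param d_z within-subjects effect size (> 0).
#' @param alpha type-I error rate.
#' @param power target power.
#' @param sided 1 (one-sided, default) or 2.
#' @param n_max search ceiling.
#' @return a list of class `power_result`: `n`, `achieved_power`,
#'   `power_at_n_minus_1`, and the inputs.
#' @examples
#' required_n_paired_t(0.35, alpha = 0.05, power = 0.90, sided = 1)  # n = 72
#' @export
required_n_paired_t <- function(d_z, alpha = 0.05, power = 0.90, sided = 1,
                                n_max = 1e5) {
  if (!is.finite(d_z) || d_z <= 0) {
    stop("d_z must be positive (power unreachable otherwise)", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!sided %in% c(1, 2)) stop("sided must be 1 or 2", call. = FALSE)
  pow <- function(n) {
    crit <- qt(1 - alpha / sided, n - 1)
    pt(crit, n - 1, ncp = d_z * sqrt(n), lower.tail = FALSE)
  }
  n <- 2
  while (pow(n) < power) {
    n <- n + 1
    if (n > n_max) stop("required n exceeds n_max", call. = FALSE)
  }
  structure(list(n = n, achieved_power = pow(n),
                 power_at_n_minus_1 = if (n > 2) pow(n - 1) else NA_real_,
                 d_z = d_z, alpha = alpha, target_power = power,
                 sided = sided),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "required n = %d (power %.4f at n, %.4f at n - 1; d_z = %g, alpha = %g, %d-sided)\n",
    x$n, x$achieved_power, x$power_at_n_minus_1, x$d_z, x$alpha, x$sided))
  invisible(x)
}

#' Relative restudy frequencies per participant and cell
#'
#' For each participant and each combination of the cell-key columns,
#' computes the relative frequency of restudy choices: chosen / total among
#' trials with an offered choice. Cells with zero trials are absent from the
#' output (and must be excluded listwise from downstream ANOVAs).
#'
#' @param trials data.frame of trial records containing `participant`, a
#'   binary `restudy_choice` column (NA = choice not offered), and the
#'   columns named in `keys`.
#' @param keys character vector of cell-key column names.
#' @return a data.frame with `participant`, the key columns, `n_trials`,
#'   `n_chosen`, `rate`.
#' @export
restudy_rates_by_cell <- function(trials,
                                  keys = c("attribution_accuracy",
                                           "source_attribution")) {
  need <- c("participant", "restudy_choice", keys)
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  tr <- trials[!is.na(trials$restudy_choice), , drop = FALSE]
  agg <- stats::aggregate(tr$restudy_choice,
                          by = c(list(participant = tr$participant),
                                 lapply(keys, function(k) tr[[k]])),
                          FUN = function(v) c(sum(v), length(v)))
  names(agg)[2:(1 + length(keys))] <- keys
  out <- agg[, 1:(1 + length(keys)), drop = FALSE]
  out$n_chosen <- agg$x[, 1]
  out$n_trials <- agg$x[, 2]
  out$rate <- out$n_chosen / out$n_trials
  out[order(out$participant), , drop = FALSE]
}
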