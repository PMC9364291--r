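# index of the diagonal elements within the packed lower triangle
# (column-major) of a 6x6 matrix
.sig_diag_idx <- local({
  p <- 6L
  idx <- integer(p)
  k <- 1L
  for (cc in 1:p) {
    idx[cc] <- k
    k <- k + (p - cc + 1L)
  }
  idx
})

#' MCMC run-length configuration for the hierarchical model
#'
#' Two presets are provided. `"desk"` (the default used by [fit_hb]) runs
#' 20,000 iterations with 10,000 burn-in and thinning 5 per chain, which
#' mixes well for the group sizes this package targets. `"production"` is the
#' long final-report configuration: 500,000 iterations, 250,000 burn-in and
#' thinning 10 (25,000 retained draws per chain).
#'
#' @param preset `"desk"` or `"production"`.
#' @param chains number of chains (>= 2 so that split R-hat is defined).
#' @return a list with `chains`, `iter`, `burnin`, `thin`, and
#'   `retained_per_chain = (iter - burnin) / thin`.
#' @export
hb_control <- function(preset = c("desk", "production"), chains = 4L) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    desk = list(iter = 20000L, burnin = 10000L, thin = 5L),
    production = list(iter = 500000L, burnin = 250000L, thin = 10L))
  cfg$chains <- as.integer(chains)
  cfg$retained_per_chain <- (cfg$iter - cfg$burnin) %/% cfg$thin
  cfg$preset <- preset
  cfg
}

#' Hierarchical Bayesian latent-trait estimation
#'
#' Fits the two-high-threshold source-monitoring model hierarchically:
#' each participant's probit-transformed parameter vector is drawn from a
#' multivariate normal distribution, `z_i ~ MVN(mu, Sigma)`, and the
#' individual parameters are `theta_i = Phi(z_i)` (elementwise standard
#' normal CDF). Individual 3x3 response-frequency tables are multinomial
#' given `theta_i`.
#'
#' Sampling is Metropolis-within-Gibbs: each participant's 6-dimensional
#' probit vector is updated by a random-walk Metropolis step whose scale
#' adapts during burn-in only; the group mean `mu` (prior `N(0, mu_sd^2)`
#' per component) and the covariance `Sigma` are updated by conjugate Gibbs
#' steps. `Sigma` carries a Huang-Wand hierarchical inverse-Wishart prior
#' (`nu`, `A`), giving half-t(`nu`, `A`) marginal priors on the individual
#' standard deviations — a weakly informative default.
#'
#' One master `seed` deterministically derives an independent stream per
#' chain; identical inputs reproduce identical draws.
#'
#' @param tables list of per-participant 3x3 [frequency_table]s.
#' @param control run-length settings, see [hb_control].
#' @param restriction identifiability restriction, `"D_N=D_U"` (default) or
#'   `"D_N=D_E"`.
#' @param prior list with `mu_sd` (default 1), `nu` (default 2), `A`
#'   (default 2.5).
#' @param seed master integer seed.
#' @param store_theta keep individual-parameter draws (needed for
#'   [posterior_predictive_check]).
#' @param init_jitter SD of the chain-specific jitter applied to the probit
#'   starting values (overdispersed initialization).
#' @return an object of class `mpt_hb_fit`: per-chain draws of `mu`
#'   (retained x 6), the packed lower triangle of `Sigma`, optionally
#'   `theta` (participants x 6 x retained), plus acceptance rates and the
#'   full configuration.
#' @export
fit_hb <- function(tables, control = hb_control("desk"),
                   restriction = c("D_N=D_U", "D_N=D_E"),
                   prior = list(mu_sd = 1, nu = 2, A = 2.5),
                   seed = 1L, store_theta = TRUE, init_jitter = 0.25) {
  restriction <- match.arg(restriction)
  if (!is.list(tables) || length(tables) < 1) {
    stop("tables must be a non-empty list of 3x3 frequency tables",
         call. = FALSE)
  }
  for (tb in tables) {
    stopifnot(inherits(tb, "freq_table"))
    if (attr(tb, "task") != "3AFC") {
      stop("hierarchical fitting requires 3AFC tables", call. = FALSE)
    }
    if (sum(tb) == 0) {
      stop("participant table with zero total observations", call. = FALSE)
    }
  }
  if (control$chains < 2) {
    stop("at least 2 chains are required (split R-hat is undefined for 1)",
         call. = FALSE)
  }
  counts <- t(vapply(tables, function(tb) as.numeric(t(unclass(tb))),
                     numeric(9)))
  # pooled closed-form fit gives the probit starting point
  pooled <- frequency_table(Reduce(`+`, lapply(tables, unclass)))
  start <- tryCatch(unclass(fit_mpt_ml(pooled, restriction)$params)[1:6],
                    error = function(e) rep(0.5, 6))
  start <- qnorm(pmin(pmax(start, 0.02), 0.98))
  prior <- utils::modifyList(list(mu_sd = 1, nu = 2, A = 2.5), prior)

  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, control$chains)
  rmask <- if (restriction == "D_N=D_E") 1L else 0L
  chains <- vector("list", control$chains)
  for (ch in seq_len(control$chains)) {
    set.seed(chain_seeds[ch])
    mu_init <- start + rnorm(6, 0, init_jitter)
    chains[[ch]] <- lt_mpt_chain(counts, rmask,
                                 control$iter, control$burnin, control$thin,
                                 mu_init, 0.25,
                                 prior$mu_sd, prior$nu, prior$A,
                                 store_theta)
    colnames(chains[[ch]]$mu) <- MPT_PARAM_NAMES
  }
  structure(list(chains = chains, n_participants = length(tables),
                 param_names = MPT_PARAM_NAMES, restriction = restriction,
                 control = control, prior = prior, seed = seed,
                 chain_seeds = chain_seeds, store_theta = store_theta),
            class = "mpt_hb_fit")
}

#' @export
print.mpt_hb_fit <- function(x, ...) {
  cat(sprintf(
    "Hierarchical latent-trait fit: %d participants, %d chains x %d retained draws (%s)\n",
    x$n_participants, length(x$chains), nrow(x$chains[[1]]$mu),
    x$restriction))
  print(summarize_posterior(x))
  invisible(x)
}

#' Pooled group-level parameter draws on the probability scale
#'
#' @param fit an `mpt_hb_fit` object.
#' @return a matrix (draws x 6) of `Phi(mu)` pooled across chains, columns
#'   named by parameter.
#' @export
phi_mu_draws <- function(fit) {
  stopifnot(inherits(fit, "mpt_hb_fit"))
  m <- do.call(rbind, lapply(fit$chains, `[[`, "mu"))
  pm <- pnorm(m)
  colnames(pm) <- fit$param_names
  pm
}

#' Posterior summaries with 95% credibility intervals
#'
#' For each group-level parameter of the source-monitoring model
#' (`D_E`, `D_U` — which also stands for the tied `D_N` —, `d_E`, `d_U`,
#' `b`, `g`) reports the posterior median and mean of `Phi(mu)` and the
#' central 95% Bayesian credibility interval (2.5% and 97.5% quantiles).
#'
#' @param fit an `mpt_hb_fit` object, or a draws matrix with named columns
#'   already on the probability scale.
#' @return a data.frame with columns `parameter`, `estimate` (median),
#'   `mean`, `bci_low`, `bci_high`.
#' @export
summarize_posterior <- function(fit) {
  draws <- if (inherits(fit, "mpt_hb_fit")) phi_mu_draws(fit)
           else as.matrix(fit)
  if (nrow(draws) < 1) stop("empty posterior", call. = FALSE)
  qs <- apply(draws, 2, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  data.frame(parameter = colnames(draws),
             estimate = qs[2, ],
             mean = colMeans(draws),
             bci_low = qs[1, ],
             bci_high = qs[3, ],
             row.names = NULL)
}

# split each chain in half and compute the between/within variance ratio
split_rhat <- function(chains) {
  chains <- lapply(chains, as.numeric)
  if (length(chains) < 2) {
    stop("at least 2 chains are required; rerun with >= 2 chains",
         call. = FALSE)
  }
  n <- min(lengths(chains))
  halves <- list()
  h <- n %/% 2
  for (ch in chains) {
    halves <- c(halves, list(ch[1:h], ch[(h + 1):(2 * h)]))
  }
  m <- length(halves)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- h * var(means)
  if (W <= .Machine$double.eps) {
    # degenerate chains: identical constants converge by convention
    return(if (B <= .Machine$double.eps) 1.0 else Inf)
  }
  sqrt(((h - 1) / h * W + B / h) / W)
}

# crude effective sample size: pooled within-chain autocorrelation, summed
# until the first non-positive value
ess_basic <- function(chains) {
  n <- min(lengths(chains))
  m <- length(chains)
  if (n < 4) return(NA_real_)
  acfs <- vapply(chains, function(ch) {
    a <- stats::acf(ch[1:n], lag.max = min(n - 2, 200), plot = FALSE,
                    demean = TRUE)$acf[-1]
    as.numeric(a)
  }, numeric(min(n - 2, 200)))
  rho <- rowMeans(acfs)
  s <- 0
  for (k in seq_along(rho)) {
    if (rho[k] <= 0) break
    s <- s + rho[k]
  }
  m * n / (1 + 2 * s)
}

#' Gelman-Rubin convergence diagnostics
#'
#' Computes the split R-hat statistic (each chain is split in half; R-hat is
#' the square root of the ratio of the pooled-variance estimate to the mean
#' within-sequence variance). For a fitted hierarchical model the monitored
#' quantities are the six group-level probit means and the six diagonal
#' elements of the covariance; individual parameters are not monitored.
#' Chains that are identical constant sequences report R-hat = 1 by
#' convention.
#'
#' @param x an `mpt_hb_fit` object, or a list of numeric vectors (one chain
#'   each) for a single monitored scalar.
#' @return for a fit, a data.frame with `quantity`, `rhat`, `ess`;
#'   for a list of chains, the scalar split R-hat.
#' @export
gelman_rubin <- function(x) UseMethod("gelman_rubin")

#' @export
gelman_rubin.list <- function(x) split_rhat(x)

#' @export
gelman_rubin.mpt_hb_fit <- function(x) {
  if (length(x$chains) < 2) {
    stop("at least 2 chains are required; rerun with >= 2 chains",
         call. = FALSE)
  }
  if (nrow(x$chains[[1]]$mu) < 10) {
    stop("need at least 10 retained draws per chain", call. = FALSE)
  }
  qty <- c(paste0("mu_", x$param_names), paste0("sigma2_", x$param_names))
  res <- lapply(1:12, function(k) {
    chains <- lapply(x$chains, function(ch) {
      if (k <= 6) ch$mu[, k] else ch$sigma_lt[, .sig_diag_idx[k - 6]]
    })
    c(split_rhat(chains), ess_basic(chains))
  })
  res <- do.call(rbind, res)
  data.frame(quantity = qty, rhat = res[, 1], ess = res[, 2],
             row.names = NULL)
}

# vectorized category probabilities for a matrix of parameter rows
cat_probs_matrix <- function(th, restriction = "D_N=D_U") {
  DE <- th[, 1]; DU <- th[, 2]; dE <- th[, 3]; dU <- th[, 4]
  b <- th[, 5]; g <- th[, 6]
  DN <- if (restriction == "D_N=D_E") DE else DU
  cbind(DE * dE + DE * (1 - dE) * g + (1 - DE) * b * g,
        DE * (1 - dE) * (1 - g) + (1 - DE) * b * (1 - g),
        (1 - DE) * (1 - b),
        DU * (1 - dU) * g + (1 - DU) * b * g,
        DU * dU + DU * (1 - dU) * (1 - g) + (1 - DU) * b * (1 - g),
        (1 - DU) * (1 - b),
        (1 - DN) * b * g,
        (1 - DN) * b * (1 - g),
        DN + (1 - DN) * (1 - b))
}

#' Posterior predictive fit statistics T1 and T2
#'
#' T1 measures the discrepancy between observed and posterior-predictive mean
#' category frequencies: a chi-square-type distance over the nine cells of
#' the across-participant mean table. T2 measures the discrepancy between the
#' observed and predicted across-participant covariance matrices of the nine
#' category counts (Frobenius distance). For each retained posterior draw a
#' replicate data set is simulated from the individual parameters of that
#' draw; the posterior predictive p-value is the fraction of replicates whose
#' statistic exceeds the observed-data statistic. Non-significant (moderate)
#' p-values indicate good fit.
#'
#' @param fit an `mpt_hb_fit` fitted with `store_theta = TRUE`.
#' @param tables the per-participant tables the model was fitted to (or any
#'   data set to check against the posterior).
#' @param n_rep number of posterior draws used (subsampled without
#'   replacement from the pooled retained draws).
#' @param seed integer seed for the subsampling and replicate simulation.
#' @return a list with `T1_p`, `T2_p` (NA when fewer than 2 participants),
#'   and the per-draw statistics.
#' @export
posterior_predictive_check <- function(fit, tables, n_rep = 300, seed = 1L) {
  stopifnot(inherits(fit, "mpt_hb_fit"))
  if (!fit$store_theta) {
    stop("fit was run with store_theta = FALSE", call. = FALSE)
  }
  obs <- t(vapply(tables, function(tb) as.numeric(t(unclass(tb))),
                  numeric(9)))
  n <- nrow(obs)
  row_tot <- t(vapply(tables, function(tb) as.numeric(rowSums(tb)),
                      numeric(3)))
  theta_all <- lapply(fit$chains, `[[`, "theta")  # n x 6 x S each
  S_per <- dim(theta_all[[1]])[3]
  total <- S_per * length(theta_all)
  set.seed(seed)
  pick <- sort(sample.int(total, min(n_rep, total)))
  ybar <- colMeans(obs)
  cov_obs <- if (n >= 2) cov(obs) else NULL
  T1_obs <- T1_rep <- T2_obs <- T2_rep <- numeric(length(pick))
  for (s in seq_along(pick)) {
    ch <- (pick[s] - 1) %/% S_per + 1
    ix <- (pick[s] - 1) %% S_per + 1
    th <- theta_all[[ch]][, , ix, drop = FALSE]
    dim(th) <- c(n, 6)
    P <- cat_probs_matrix(th, fit$restriction)  # n x 9
    E <- P * row_tot[, c(1, 1, 1, 2, 2, 2, 3, 3, 3)]
    ebar <- pmax(colMeans(E), 1e-12)
    T1_obs[s] <- sum((ybar - ebar)^2 / ebar)
    # replicate data
    yr <- matrix(0, n, 9)
    for (i in seq_len(n)) {
      for (r in 1:3) {
        cols <- (3 * r - 3 + 1):(3 * r)
        yr[i, cols] <- rmultinom(1, row_tot[i, r], P[i, cols])[, 1]
      }
    }
    T1_rep[s] <- sum((colMeans(yr) - ebar)^2 / ebar)
    if (n >= 2) {
      # model covariance: between-participant spread of expected counts
      # plus the mean within-participant multinomial covariance
      M <- cov(E)
      for (r in 1:3) {
        cols <- (3 * r - 3 + 1):(3 * r)
        for (i in seq_len(n)) {
          p <- P[i, cols]
          M[cols, cols] <- M[cols, cols] +
            (row_tot[i, r] * (diag(p) - tcrossprod(p))) / n
        }
      }
      T2_obs[s] <- sqrt(sum((cov_obs - M)^2))
      T2_rep[s] <- sqrt(sum((cov(yr) - M)^2))
    }
  }
  list(T1_p = mean(T1_rep >= T1_obs),
       T2_p = if (n >= 2) mean(T2_rep >= T2_obs) else NA_real_,
       T1_obs = T1_obs, T1_rep = T1_rep,
       T2_obs = if (n >= 2) T2_obs else NULL,
       T2_rep = if (n >= 2) T2_rep else NULL)
}

#' Posterior contrasts of group-level parameters
#'
#' Evaluates an arbitrary expression over the group-level probability-scale
#' parameters of one or two posteriors, draw by draw, and summarizes the
#' resulting contrast posterior. With a single posterior the parameter names
#' `D_E, D_U, d_E, d_U, b, g` are available directly; with two posteriors
#' they carry suffixes `_1` and `_2` (e.g.
#' `"(d_U_1 - d_E_1) - (d_U_2 - d_E_2)"` for a difference of inconsistency
#' effects between groups). Draws of independent groups are paired by index;
#' if the posteriors hold different numbers of draws the longer one is
#' subsampled (seeded) to the shorter.
#'
#' A contrast is flagged significant exactly when its central 95% credibility
#' interval excludes zero.
#'
#' @param a,b `mpt_hb_fit` objects or probability-scale draws matrices with
#'   named columns; `b` may be `NULL` for within-posterior contrasts.
#' @param expr contrast expression as a string.
#' @param label optional label, defaults to `expr`.
#' @param seed seed used only when subsampling mismatched draw counts.
#' @return an object of class `parameter_contrast`: list with `label`,
#'   `mean`, `median`, `bci` (length-2), `significant`, and the draws.
#' @export
parameter_contrast <- function(a, b = NULL, expr, label = expr, seed = 1L) {
  get_draws <- function(x) {
    if (inherits(x, "mpt_hb_fit")) phi_mu_draws(x) else as.matrix(x)
  }
  da <- get_draws(a)
  env <- list()
  if (is.null(b)) {
    for (nm in colnames(da)) env[[nm]] <- da[, nm]
  } else {
    db <- get_draws(b)
    S <- min(nrow(da), nrow(db))
    if (nrow(da) != nrow(db)) {
      set.seed(seed)
      if (nrow(da) > S) da <- da[sort(sample.int(nrow(da), S)), , drop = FALSE]
      if (nrow(db) > S) db <- db[sort(sample.int(nrow(db), S)), , drop = FALSE]
    }
    for (nm in colnames(da)) env[[paste0(nm, "_1")]] <- da[, nm]
    for (nm in colnames(db)) env[[paste0(nm, "_2")]] <- db[, nm]
  }
  vals <- eval(parse(text = expr), envir = env, enclos = baseenv())
  bci <- unname(quantile(vals, c(0.025, 0.975)))
  structure(list(label = label, mean = mean(vals), median = median(vals),
                 bci = bci, significant = bci[1] > 0 || bci[2] < 0,
                 draws = vals),
            class = "parameter_contrast")
}

#' @export
print.parameter_contrast <- function(x, ...) {
  cat(sprintf("%s = %.3f [%.3f, %.3f]%s\n", x$label, x$mean,
              x$bci[1], x$bci[2],
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Simulate individual frequency tables from a latent-trait population
#'
#' Draws per-participant probit parameter vectors from
#' `MVN(mu_probit, Sigma)`, transforms them to probabilities, and simulates
#' one 3x3 response-frequency table per participant. Used for parameter
#' recovery and calibration studies.
#'
#' @param mu_probit group-level probit means, length 6 in the order
#'   `D_E, D_U, d_E, d_U, b, g`.
#' @param sigma either a length-6 vector of probit SDs (diagonal covariance)
#'   or a 6x6 covariance matrix.
#' @param n_participants number of participants.
#' @param n_per_type items per trial type (default 32).
#' @param restriction identifiability restriction for the new-item tree.
#' @param seed integer seed.
#' @return list with `tables` (list of [frequency_table]) and `theta`
#'   (participants x 6 matrix of generating probabilities).
#' @export
simulate_hb_dataset <- function(mu_probit, sigma, n_participants,
                                n_per_type = 32L,
                                restriction = "D_N=D_U", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.matrix(sigma)) {
    L <- chol(sigma)
    z <- matrix(rnorm(n_participants * 6), n_participants) %*% L
  } else {
    z <- matrix(rnorm(n_participants * 6), n_participants) *
      rep(sigma, each = n_participants)
  }
  z <- sweep(z, 2, mu_probit, "+")
  theta <- pnorm(z)
  colnames(theta) <- MPT_PARAM_NAMES
  tables <- lapply(seq_len(n_participants), function(i) {
    simulate_frequencies(as_mpt_params(theta[i, ], restriction),
                         n_per_type = n_per_type)
  })
  list(tables = tables, theta = theta)
}
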