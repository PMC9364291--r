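# Shared fixtures and independent oracle implementations used across tests.

# random interior parameter sets
rand_theta <- function(n, lo = 0.05, hi = 0.95) {
  m <- matrix(runif(n * 6, lo, hi), n, 6)
  colnames(m) <- c("D_E", "D_U", "d_E", "d_U", "b", "g")
  m
}

# closed-form ML solution of the immediate-group bundled counts, computed
# independently (moment inversion by hand) and frozen
IMMEDIATE_ML <- c(D_E = 0.71721500, D_U = 0.71788194, d_E = 0.62921891,
                  d_U = 0.79585097, b = 0.34923077, g = 0.70484581)

bundled_table <- function(which = c("immediate", "delayed", "delayed_2afc")) {
  which <- match.arg(which)
  read_frequency_table(example_frequency_files()[[which]])
}

# triple-loop Goodman-Kruskal gamma, deliberately naive
gamma_brute <- function(scores, choices) {
  C <- 0L; D <- 0L
  n <- length(scores)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- (scores[i] - scores[j]) * (choices[i] - choices[j])
      if (p > 0) C <- C + 1L
      if (p < 0) D <- D + 1L
    }
  }
  if (C + D == 0) return(list(gamma = NA_real_, C = C, D = D,
                              defined = FALSE))
  list(gamma = (C - D) / (C + D), C = C, D = D, defined = TRUE)
}

# textbook means-based sums of squares for the balanced mixed 2x2 design
# (one between-subjects factor, one within-subjects factor, one observation
# per participant x within cell)
mixed_ss_oracle <- function(d, dv, id, between, within) {
  y <- d[[dv]]
  grand <- mean(y)
  n_id <- length(unique(d[[id]]))
  k <- length(unique(d[[within]]))
  pm <- tapply(y, d[[id]], mean)             # participant means
  gm <- tapply(y, d[[between]], mean)        # group means
  wm <- tapply(y, d[[within]], mean)         # within-level means
  cm <- tapply(y, list(d[[between]], d[[within]]), mean)
  n_per_group <- n_id / length(gm)
  SS_between <- k * n_per_group * sum((gm - grand)^2)
  SS_subj <- k * sum((pm - grand)^2)
  SS_error_between <- SS_subj - SS_between
  SS_within <- n_id * sum((wm - grand)^2)
  SS_cells <- n_per_group * sum((cm - grand)^2)
  SS_inter <- SS_cells - SS_between - SS_within
  SS_total <- sum((y - grand)^2)
  SS_error_within <- SS_total - SS_subj - SS_within - SS_inter
  list(between = SS_between, within = SS_within, interaction = SS_inter,
       error_between = SS_error_between, error_within = SS_error_within,
       total = SS_total)
}

# small latent-trait recovery dataset shared by hierarchical unit tests
hb_test_means <- qnorm(c(.71, .73, .48, .83, .33, .75))
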