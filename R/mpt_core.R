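#' @useDynLib mptsource, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aov cov median optim pnorm pt qlogis qnorm qt quantile
#'   rmultinom rnorm plogis runif sd var
#' @importFrom utils read.csv write.csv
NULL

# canonical parameter order used everywhere in the package
MPT_PARAM_NAMES <- c("D_E", "D_U", "d_E", "d_U", "b", "g")

MPT_RESTRICTIONS <- c("D_N=D_U", "D_N=D_E", "none")

#' Parameters of the two-high-threshold source-monitoring model
#'
#' Constructs and validates the parameter set of the two-high-threshold
#' multinomial processing-tree (MPT) model of source monitoring with two
#' sources (one schematically expected, one unexpected per item) and new
#' items.
#'
#' The parameters are: `D_E`/`D_U`, the probabilities that an item studied
#' with its expected/unexpected source is recognized as old; `D_N`, the
#' probability that a new item is detected as new; `d_E`/`d_U`, the
#' probabilities of remembering the expected/unexpected source given the item
#' was recognized; `b`, the probability of guessing "old" for an
#' unrecognized item; and `g`, the probability of guessing the expected
#' source when source memory fails. With a single 3x3 frequency table the
#' model is identifiable only under an equality restriction on `D_N`,
#' conventionally `D_N = D_U`.
#'
#' @param D_E,D_U,d_E,d_U,b,g probabilities in `[0, 1]`.
#' @param D_N probability that a new item is detected as new; ignored (tied)
#'   unless `restriction = "none"`.
#' @param restriction identifiability restriction: `"D_N=D_U"` (default),
#'   `"D_N=D_E"`, or `"none"` (requires `D_N`).
#' @return an object of class `mpt_params`: a named numeric vector with the
#'   six free parameters plus `D_N`, and a `restriction` attribute.
#' @examples
#' p <- mpt_params(D_E = .72, D_U = .72, d_E = .63, d_U = .80, b = .35, g = .70)
#' category_probabilities(p)
#' @export
mpt_params <- function(D_E, D_U, d_E, d_U, b, g, D_N = NULL,
                       restriction = c("D_N=D_U", "D_N=D_E", "none")) {
  restriction <- match.arg(restriction)
  if (restriction == "D_N=D_U") D_N <- D_U
  if (restriction == "D_N=D_E") D_N <- D_E
  if (is.null(D_N)) {
    stop("D_N must be supplied when restriction = \"none\"", call. = FALSE)
  }
  theta <- c(D_E = D_E, D_U = D_U, d_E = d_E, d_U = d_U, b = b, g = g,
             D_N = D_N)
  for (nm in names(theta)) {
    v <- theta[[nm]]
    if (!is.finite(v) || v < 0 || v > 1) {
      stop(sprintf("parameter %s = %s is outside [0, 1]", nm, format(v)),
           call. = FALSE)
    }
  }
  structure(theta, restriction = restriction, class = "mpt_params")
}

#' @export
print.mpt_params <- function(x, ...) {
  cat("Two-high-threshold source-monitoring parameters (",
      attr(x, "restriction"), ")\n", sep = "")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Coerce a numeric vector to model parameters
#'
#' Interprets a length-6 numeric vector in the order
#' `D_E, D_U, d_E, d_U, b, g` under the given identifiability restriction.
#' `mpt_params` objects pass through unchanged.
#'
#' @param x numeric vector of the six free parameters, or an [mpt_params].
#' @param restriction `"D_N=D_U"` (default) or `"D_N=D_E"`.
#' @return an [mpt_params] object.
#' @export
as_mpt_params <- function(x, restriction = "D_N=D_U") {
  if (inherits(x, "mpt_params")) return(x)
  x <- as.numeric(x)
  mpt_params(x[1], x[2], x[3], x[4], x[5], x[6], restriction = restriction)
}

#' Category probabilities of the source-monitoring tree
#'
#' Computes the 3x3 matrix of response probabilities P(response | trial type)
#' under the two-high-threshold source-monitoring model. Trial types (rows)
#' are items studied with the expected source, items studied with the
#' unexpected source, and new items; responses (columns) are attributions to
#' the expected source, the unexpected source, or "new". Recognized items are
#' never called "new": source memory or source guessing resolves every
#' recognized item to one of the two sources.
#'
#' @param params an [mpt_params] object (or coercible numeric vector).
#' @return a 3x3 numeric matrix with rows `expected`, `unexpected`, `new` and
#'   columns `expected`, `unexpected`, `new`; each row sums to 1.
#' @export
category_probabilities <- function(params) {
  params <- as_mpt_params(params)
  D_E <- params[["D_E"]]; D_U <- params[["D_U"]]; D_N <- params[["D_N"]]
  d_E <- params[["d_E"]]; d_U <- params[["d_U"]]
  b <- params[["b"]]; g <- params[["g"]]
  P <- matrix(0, 3, 3, dimnames = list(
    trial_type = c("expected", "unexpected", "new"),
    response = c("expected", "unexpected", "new")))
  P[1, 1] <- D_E * d_E + D_E * (1 - d_E) * g + (1 - D_E) * b * g
  P[1, 2] <- D_E * (1 - d_E) * (1 - g) + (1 - D_E) * b * (1 - g)
  P[1, 3] <- (1 - D_E) * (1 - b)
  P[2, 1] <- D_U * (1 - d_U) * g + (1 - D_U) * b * g
  P[2, 2] <- D_U * d_U + D_U * (1 - d_U) * (1 - g) + (1 - D_U) * b * (1 - g)
  P[2, 3] <- (1 - D_U) * (1 - b)
  P[3, 1] <- (1 - D_N) * b * g
  P[3, 2] <- (1 - D_N) * b * (1 - g)
  P[3, 3] <- D_N + (1 - D_N) * (1 - b)
  P
}

#' Aggregate response-frequency table
#'
#' Container for response counts of the three-alternative (3AFC:
#' expected / unexpected / new) source-monitoring test or the
#' two-alternative (2AFC: expected / unexpected) source-attribution task,
#' aggregated over items for one participant or over items and participants
#' for a group.
#'
#' @param counts a 3x3 (3AFC) or 2x2 (2AFC) matrix of non-negative counts;
#'   rows are trial types, columns responses.
#' @param task `"3AFC"` or `"2AFC"`; inferred from the shape if missing.
#' @param label provenance label (e.g. group or participant id).
#' @return an integer matrix of class `freq_table` with `task` and `label`
#'   attributes.
#' @export
frequency_table <- function(counts, task = NULL, label = "") {
  counts <- as.matrix(counts)
  if (is.null(task)) {
    task <- if (ncol(counts) == 3) "3AFC" else "2AFC"
  }
  task <- match.arg(task, c("3AFC", "2AFC"))
  k <- if (task == "3AFC") 3L else 2L
  if (!all(dim(counts) == c(k, k))) {
    stop(sprintf("a %s table must be %dx%d, got %dx%d",
                 task, k, k, nrow(counts), ncol(counts)), call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  types <- c("expected", "unexpected", "new")[seq_len(k)]
  resps <- c("expected", "unexpected", "new")[seq_len(k)]
  dimnames(counts) <- list(trial_type = types, response = resps)
  structure(counts, task = task, label = label, class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("%s response frequencies%s\n", attr(x, "task"),
              if (nzchar(attr(x, "label"))) paste0(" [", attr(x, "label"), "]")
              else ""))
  print(matrix(as.integer(x), nrow(x), ncol(x), dimnames = dimnames(x)))
  invisible(x)
}

#' Read / write frequency tables as delimited text
#'
#' Frequency tables are stored as comma-separated files with the header
#' `trial_type,resp_expected,resp_unexpected,resp_new`; the `trial_type`
#' column takes values `expected`, `unexpected`, `new`. Files for the 2AFC
#' task omit both the `resp_new` column and the `new` row.
#'
#' @param path file path.
#' @param x a [frequency_table].
#' @return `read_frequency_table` returns a [frequency_table];
#'   `write_frequency_table` invisibly returns `path`.
#' @export
read_frequency_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  cols3 <- c("trial_type", "resp_expected", "resp_unexpected", "resp_new")
  cols2 <- cols3[1:3]
  task <- if (identical(names(df), cols3)) "3AFC"
          else if (identical(names(df), cols2)) "2AFC"
          else stop("unrecognized frequency-table header in ", path,
                    " (a 2AFC file must not contain a resp_new column)",
                    call. = FALSE)
  if (task == "3AFC" && nrow(df) == 2) {
    stop("2AFC tables must not contain a resp_new column (", path, ")",
         call. = FALSE)
  }
  types <- c("expected", "unexpected", if (task == "3AFC") "new")
  if (!identical(df$trial_type, types)) {
    stop("trial_type column must be exactly: ", paste(types, collapse = ", "),
         call. = FALSE)
  }
  cnt <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!is.finite(cnt) | cnt < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("negative or missing count at line %d of %s",
                 bad[1, 1] + 1L, path), call. = FALSE)
  }
  frequency_table(cnt, task = task,
                  label = sub("\\.csv$", "", basename(path)))
}

#' @rdname read_frequency_table
#' @export
write_frequency_table <- function(x, path) {
  stopifnot(inherits(x, "freq_table"))
  df <- data.frame(trial_type = rownames(x))
  for (j in seq_len(ncol(x))) {
    df[[paste0("resp_", colnames(x)[j])]] <- as.integer(x[, j])
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Multinomial log-likelihood of a frequency table
#'
#' Sum over cells of `count * log(probability)` under the category
#' probabilities implied by `params`. Returns `-Inf` when any cell with a
#' positive count has probability zero.
#'
#' @param params an [mpt_params] object.
#' @param freq a 3x3 [frequency_table].
#' @return the log-likelihood (a scalar).
#' @export
mpt_loglik <- function(params, freq) {
  stopifnot(inherits(freq, "freq_table"))
  if (attr(freq, "task") != "3AFC") {
    stop("log-likelihood is defined for 3AFC tables", call. = FALSE)
  }
  P <- category_probabilities(params)
  n <- as.numeric(freq)
  p <- as.numeric(P)
  if (any(n > 0 & p <= 0)) return(-Inf)
  sum(n[n > 0] * log(p[n > 0]))
}

# closed-form moment inversion for one 3x3 table under an equality
# restriction on D_N; returns NULL when any value leaves [0,1]
closed_form_inversion <- function(freq, restriction) {
  p <- sweep(unclass(freq), 1, rowSums(freq), "/")
  q <- p[3, 1] + p[3, 2]              # (1 - D_N) * b
  if (q <= 0) return(NULL)            # b at boundary; no unique g
  g <- p[3, 1] / q
  if (restriction == "D_N=D_U") {
    one_minus_D <- q + p[2, 3]        # (1-D_U)b + (1-D_U)(1-b)
    D_U <- 1 - one_minus_D
    b <- q / one_minus_D
    D_E <- 1 - p[1, 3] / (1 - b)
  } else {
    one_minus_D <- q + p[1, 3]
    D_E <- 1 - one_minus_D
    b <- q / one_minus_D
    D_U <- 1 - p[2, 3] / (1 - b)
  }
  if (D_E <= 0 || D_U <= 0 || g >= 1 || g <= 0) return(NULL)
  d_E <- ((p[1, 1] - (1 - D_E) * b * g) / D_E - g) / (1 - g)
  d_U <- ((p[2, 2] - (1 - D_U) * b * (1 - g)) / D_U - (1 - g)) / g
  theta <- c(D_E = D_E, D_U = D_U, d_E = d_E, d_U = d_U, b = b, g = g)
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > 1)) return(NULL)
  theta
}

# likelihood maximization on the logit scale (bounds respected implicitly)
numeric_ml <- function(freq, restriction, start = NULL) {
  if (is.null(start)) start <- rep(0.5, 6)
  start <- pmin(pmax(start, 1e-4), 1 - 1e-4)
  negll <- function(eta) {
    eta <- pmin(pmax(eta, -15), 15)
    th <- plogis(eta)
    -mpt_loglik(as_mpt_params(th, restriction), freq)
  }
  fit <- optim(qlogis(start), negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  # polish with Nelder-Mead in case BFGS stalled on a flat logit region
  fit2 <- optim(fit$par, negll, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-12))
  if (fit2$value < fit$value) fit <- fit2
  list(theta = plogis(pmin(pmax(fit$par, -15), 15)),
       converged = fit$convergence == 0)
}

#' Maximum-likelihood fit of the source-monitoring model to one table
#'
#' Fits the six free parameters of the restricted two-high-threshold model to
#' a single aggregate 3x3 frequency table. The model is exactly identified
#' (six parameters, six free data proportions), so an interior solution
#' reproduces the observed proportions exactly and has G-squared of zero.
#' The fit first attempts the closed-form moment inversion (solve `g` from
#' the new-item row, then `b` and the item-recognition parameters from the
#' "new"-response proportions, then the source-memory parameters from the
#' remaining cells) and falls back to bounded numeric likelihood
#' maximization on the logit scale when any closed-form value leaves
#' `[0, 1]`.
#'
#' @param freq a 3x3 [frequency_table] with positive row totals.
#' @param restriction `"D_N=D_U"` (default) or `"D_N=D_E"`.
#' @return an object of class `mpt_ml_fit`: a list with elements `params`
#'   ([mpt_params]), `loglik`, `G2`, `df`, `converged`, `boundary`, `method`.
#' @examples
#' p <- mpt_params(D_E = .7, D_U = .7, d_E = .6, d_U = .8, b = .35, g = .7)
#' f <- simulate_frequencies(p, n_per_type = 32, n_participants = 72, seed = 1)
#' fit_mpt_ml(f)
#' @export
fit_mpt_ml <- function(freq, restriction = c("D_N=D_U", "D_N=D_E")) {
  restriction <- match.arg(restriction)
  stopifnot(inherits(freq, "freq_table"))
  if (attr(freq, "task") != "3AFC") {
    stop("ML fitting requires a 3AFC table", call. = FALSE)
  }
  if (any(rowSums(freq) == 0)) {
    stop("every trial type must have a positive row total", call. = FALSE)
  }
  theta <- closed_form_inversion(freq, restriction)
  method <- "closed_form"
  converged <- TRUE
  if (is.null(theta)) {
    nf <- numeric_ml(freq, restriction)
    theta <- nf$theta
    names(theta) <- MPT_PARAM_NAMES
    converged <- nf$converged
    method <- "numeric"
  }
  params <- as_mpt_params(theta, restriction)
  ll <- mpt_loglik(params, freq)
  # G2 = 2 * sum obs * log(obs / expected)
  expd <- category_probabilities(params) * rowSums(freq)
  obs <- as.numeric(freq); expv <- as.numeric(expd)
  keep <- obs > 0
  G2 <- 2 * sum(obs[keep] * log(obs[keep] / expv[keep]))
  boundary <- any(theta < 1e-4 | theta > 1 - 1e-4)
  structure(list(params = params, loglik = ll, G2 = max(G2, 0), df = 0L,
                 converged = converged, boundary = boundary, method = method),
            class = "mpt_ml_fit")
}

#' @export
print.mpt_ml_fit <- function(x, ...) {
  cat(sprintf("ML fit (%s), logLik = %.3f, G2 = %.4g (df %d)%s\n",
              x$method, x$loglik, x$G2, x$df,
              if (x$boundary) ", boundary solution" else ""))
  print(x$params)
  invisible(x)
}

#' Simulate an aggregate frequency table from the model
#'
#' Draws multinomial response counts for each trial type from the category
#' probabilities implied by `params`. Row totals equal
#' `n_per_type * n_participants`.
#'
#' @param params an [mpt_params] object.
#' @param n_per_type items per trial type per participant (>= 1).
#' @param n_participants number of participants aggregated over.
#' @param seed optional integer seed for reproducibility.
#' @return a 3x3 [frequency_table].
#' @export
simulate_frequencies <- function(params, n_per_type, n_participants = 1L,
                                 seed = NULL) {
  if (n_per_type < 1) stop("n_per_type must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  P <- category_probabilities(params)
  n <- as.integer(round(n_per_type * n_participants))
  cnt <- t(vapply(1:3, function(r) rmultinom(1, n, P[r, ])[, 1],
                  numeric(3)))
  frequency_table(cnt, task = "3AFC")
}
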