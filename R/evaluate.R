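## Repeated random-split evaluation of the nearest-neighbour models.
##
## Protocol: split the perfect-match set uniformly at random into 67%
## training / 33% testing, fit on the training set, score Pearson r and
## RMSE between estimated and experimental dG on the test set; repeat.
## The r and RMSE vectors over iterations characterise the model, and
## the best split's parameters are retained.

#' Absolute free-energy difference
#'
#' @param dg_exp,dg_est Experimental and estimated free energies
#'   (kcal/mol); vectorized.
#' @return `abs(dg_exp - dg_est)`.
#' @export
mfe_ad <- function(dg_exp, dg_est) {
  stopifnot(is.numeric(dg_exp), is.numeric(dg_est))
  abs(dg_exp - dg_est)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation coefficient in \[-1, 1\]; `NA` with a warning
#'   when either vector has zero variance (the coefficient is undefined
#'   there).
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: Pearson correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "pearson")
}

#' Root mean squared error
#'
#' @param x,y Paired numeric vectors of equal length >= 1.
#' @return `sqrt(mean((x - y)^2))`, in the data's units (kcal/mol for
#'   free energies).
#' @export
rmse <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  sqrt(mean((x - y)^2))
}

## One master seed; iteration i runs on its own derived stream so
## iterations are independent and individually reproducible.  Kept
## below 2^31 - 1 (R seeds are 32-bit integers).
derive_seed <- function(master, i) {
  as.integer((abs(as.numeric(master)) * 48271 + as.numeric(i) * 16807) %%
               2147483629)
}

#' Random training/testing split of a duplex dataset
#'
#' Samples `round(train_fraction * N)` records (half-up rounding)
#' uniformly without replacement as the training set; the complement is
#' the test set.  The split is reproducible from `(seed, iteration)`,
#' and different iterations use independent derived streams.
#'
#' @param d A [duplex_dataset()] with at least 3 records.
#' @param train_fraction Training proportion in (0, 1); default 0.67.
#' @param seed Master RNG seed.
#' @param iteration Iteration index (>= 1).
#' @return List with `train` and `test` datasets and the `train_idx`.
#' @examples
#' # 340 duplexes at the default 67% train fraction -> 228 / 112
#' @export
random_split <- function(d, train_fraction = 0.67, seed = 1, iteration = 1) {
  stopifnot(inherits(d, "duplex_dataset"), nrow(d) >= 3L,
            train_fraction > 0, train_fraction < 1)
  n <- nrow(d)
  n_train <- floor(train_fraction * n + 0.5)
  idx <- local({
    set.seed(derive_seed(seed, iteration))
    sort(sample.int(n, n_train))
  })
  train <- d[idx, , drop = FALSE]
  test <- d[-idx, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test, train_idx = idx)
}

#' Repeated random-split evaluation of a nearest-neighbour model
#'
#' Runs the full evaluation protocol: for each of `iterations` random
#' 67/33 splits, fit the doublet or triplet model on the training set
#' and record the Pearson correlation and RMSE between estimated and
#' experimental free energies over the whole test set.  An iteration
#' whose test energies have zero variance gets `NA` correlation (with
#' the RMSE kept).  The best parameter set across iterations is the one
#' with highest test r, ties broken by lowest test RMSE, then lowest
#' iteration index.
#'
#' @param d A perfect-match [duplex_dataset()].
#' @param order Motif order, 2 or 3.
#' @param iterations Number of random splits (the reference protocol
#'   uses 10000).
#' @param train_fraction Training proportion; default 0.67.
#' @param seed Master RNG seed; same seed reproduces the result
#'   bit-identically.
#' @return An object of class `tnn_eval`: list with `r_values`,
#'   `rmse_values` (length-`iterations` vectors), `best_params`
#'   ([nn_params()]), `best_iteration`, `order`, `iterations`,
#'   `train_fraction`, `seed`, `n`.
#' @seealso [summarize_stats()] for the quartile summaries reported for
#'   these vectors.
#' @export
tnn_evaluate <- function(d, order = 3, iterations = 100,
                         train_fraction = 0.67, seed = 1) {
  stopifnot(iterations >= 1L)
  order <- check_order(order)
  pm <- is_perfect_match(d)
  if (!all(pm)) stop("evaluation requires a perfect-match dataset")
  counts <- motif_count_matrix(d$seq1, order)   # count once, reuse per split
  response <- d$dg_exp
  n <- nrow(d)
  n_train <- floor(train_fraction * n + 0.5)
  r_values <- rmse_values <- numeric(iterations)
  best <- list(r = -Inf, rmse = Inf, iter = NA_integer_, coefs = NULL)
  for (i in seq_len(iterations)) {
    set.seed(derive_seed(seed, i))
    idx <- sample.int(n, n_train)
    sol <- lsq_minnorm(counts[idx, , drop = FALSE], response[idx])
    est <- drop(counts[-idx, , drop = FALSE] %*% sol$x)
    obs <- response[-idx]
    rmse_values[i] <- rmse(obs, est)
    r_values[i] <- if (stats::sd(obs) == 0 || stats::sd(est) == 0)
      NA_real_ else stats::cor(obs, est)
    better <- !is.na(r_values[i]) &&
      (r_values[i] > best$r ||
         (r_values[i] == best$r && rmse_values[i] < best$rmse))
    if (better)
      best <- list(r = r_values[i], rmse = rmse_values[i], iter = i,
                   coefs = sol$x)
  }
  if (is.null(best$coefs)) {   # all-NA correlations: fall back to full fit
    best$coefs <- lsq_minnorm(counts, response)$x
    best$iter <- NA_integer_
  }
  coefs <- best$coefs
  names(coefs) <- colnames(counts)
  structure(list(r_values = r_values, rmse_values = rmse_values,
                 best_params = nn_params(
                   coefs, order,
                   provenance = sprintf("best of %d random splits", iterations)),
                 best_iteration = best$iter,
                 order = order, iterations = iterations,
                 train_fraction = train_fraction, seed = seed, n = n),
            class = "tnn_eval")
}

#' Seven-number summary of a metric vector
#'
#' Minimum, first quartile, median, mean, third quartile, maximum and
#' standard deviation — the statistics reported for every comparison
#' measure.  Quartiles use the linear-interpolation convention
#' (`quantile` type 7).  `NA` entries are dropped.
#'
#' @param values Numeric vector of length >= 1.
#' @return Named numeric vector `min, q1, median, mean, q3, max, stddev`.
#' @export
summarize_stats <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  v <- values[!is.na(values)]
  if (!length(v)) return(c(min = NA, q1 = NA, median = NA, mean = NA,
                           q3 = NA, max = NA, stddev = NA))
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(min = min(v), q1 = q[1], median = q[2], mean = mean(v), q3 = q[3],
    max = max(v), stddev = if (length(v) > 1L) stats::sd(v) else 0)
}

#' @export
print.tnn_eval <- function(x, ...) {
  cat(sprintf("Repeated-split evaluation: %s model, %d duplexes, %d iteration(s)\n",
              if (x$order == 2L) "doublet" else "triplet", x$n,
              x$iterations))
  cat(sprintf("  train fraction %.2f (%d/%d), master seed %d\n",
              x$train_fraction, floor(x$train_fraction * x$n + 0.5),
              x$n - floor(x$train_fraction * x$n + 0.5), x$seed))
  cat("  Pearson r:  ")
  print(round(summarize_stats(x$r_values), 4))
  cat("  RMSE [kcal/mol]:  ")
  print(round(summarize_stats(x$rmse_values), 4))
  invisible(x)
}

#' @export
summary.tnn_eval <- function(object, ...) {
  list(r = summarize_stats(object$r_values),
       rmse = summarize_stats(object$rmse_values),
       best_iteration = object$best_iteration)
}

#' @export
plot.tnn_eval <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::boxplot(x$r_values, main = "Pearson r", ylab = "r", ...)
  graphics::boxplot(x$rmse_values, main = "RMSE",
                    ylab = "RMSE [kcal/mol]", ...)
  invisible(x)
}

#' Export an experimental-versus-estimated free-energy table
#'
#' One row per duplex with its id, source, experimental and estimated
#' free energy — the table behind correlation scatter plots grouped by
#' data source.
#'
#' @param d A [duplex_dataset()].
#' @param params An [nn_params()] object used for the estimates.
#' @return data.frame with columns `duplex_id`, `source`, `dg_exp`,
#'   `dg_est`.
#' @export
export_correlation_table <- function(d, params) {
  stopifnot(inherits(d, "duplex_dataset"))
  if (nrow(d) == 0L)
    return(data.frame(duplex_id = character(0), source = character(0),
                      dg_exp = numeric(0), dg_est = numeric(0)))
  data.frame(duplex_id = d$duplex_id,
             source = duplex_source(d),
             dg_exp = d$dg_exp,
             dg_est = estimate_free_energy(d$seq1, params),
             stringsAsFactors = FALSE)
}
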