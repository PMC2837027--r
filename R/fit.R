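## Fitting the nearest-neighbour model.
##
## For N perfect-match duplexes the model is linear: F X = R, where F is
## the N x K matrix of motif counts (K = 10 doublet or 32 triplet
## classes), X the unknown free-energy weights and R the experimental
## dG values.  X is estimated as the minimum-norm least-squares
## solution, so rank-deficient designs (random training subsets can miss
## rare motifs) are handled gracefully: classes absent from the data get
## weight 0 and are flagged rather than raising an error.

#' Build the least-squares fit problem for a perfect-match dataset
#'
#' Row i of the design matrix holds the motif counts of `seq1` of record
#' i (one strand only; the complementary strand is implied by the
#' rotational classes); the response is the experimental free energy.
#'
#' @param d A [duplex_dataset()] of perfect-match duplexes.
#' @param order Motif order, 2 or 3.
#' @return A list of class `fit_problem` with elements `counts`
#'   (N x K integer matrix), `response` (numeric N-vector, kcal/mol),
#'   `duplex_ids` and `order`.
#' @export
build_fit_problem <- function(d, order) {
  stopifnot(inherits(d, "duplex_dataset"))
  order <- check_order(order)
  if (nrow(d) == 0L) stop("empty dataset")
  pm <- is_perfect_match(d)
  if (!all(pm))
    stop("non-perfect-match duplex in fit data: ",
         paste(utils::head(d$duplex_id[!pm], 3L), collapse = ", "))
  if (anyNA(d$dg_exp))
    stop("missing experimental free energy for duplex ",
         d$duplex_id[which(is.na(d$dg_exp))[1]])
  structure(list(counts = motif_count_matrix(d$seq1, order),
                 response = d$dg_exp,
                 duplex_ids = d$duplex_id,
                 order = order),
            class = "fit_problem")
}

## Minimum-norm least squares via SVD.  Singular values below
## tol * max(d) are treated as zero; rank and residual are reported.
lsq_minnorm <- function(A, b, tol = 1e-10) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  sv <- svd(A)
  keep <- sv$d > tol * max(sv$d, .Machine$double.eps)
  r <- sum(keep)
  x <- if (r == 0L) rep(0, ncol(A)) else
    drop(sv$v[, keep, drop = FALSE] %*%
           (crossprod(sv$u[, keep, drop = FALSE], b) / sv$d[keep]))
  list(x = x, rank = r, residual_norm = sqrt(sum((A %*% x - b)^2)))
}

#' Fit a nearest-neighbour free-energy model
#'
#' Estimates doublet or triplet stacking free energies by minimum-norm
#' least squares on motif counts versus experimental duplex free
#' energies.  No initiation, symmetry, temperature or salt terms are
#' included: the duplex energy is modelled purely as the sum of its
#' stack contributions.
#'
#' @param data A perfect-match [duplex_dataset()], or a `fit_problem`
#'   from [build_fit_problem()].
#' @param order Motif order, 2 (doublets) or 3 (triplets); ignored when
#'   `data` is already a `fit_problem`.
#' @param tol Relative singular-value tolerance for the rank decision.
#' @return An object of class `tnn_fit` with components `coefficients`
#'   (an [nn_params()] vector; classes unseen in the data have weight 0
#'   and are listed in `unseen_classes`), `fitted.values`, `residuals`,
#'   `rank`, `residual_norm`, `order`, `problem`.
#' @seealso [predict.tnn_fit()], [simulate.tnn_fit()], [tnn_evaluate()]
#' @examples
#' d <- generate_duplexes(n = 60, noise_sd = 0, seed = 1)
#' fit <- tnn_fit(d, order = 3)
#' coef(fit)[1:4]
#' max(abs(residuals(fit)))   # exact interpolation of noise-free data
#' @export
tnn_fit <- function(data, order = 3, tol = 1e-10) {
  problem <- if (inherits(data, "fit_problem")) data else
    build_fit_problem(data, order)
  sol <- lsq_minnorm(problem$counts, problem$response, tol = tol)
  unseen <- colnames(problem$counts)[colSums(problem$counts) == 0L]
  coefs <- sol$x
  names(coefs) <- colnames(problem$counts)
  coefs[unseen] <- 0
  fitted <- drop(problem$counts %*% coefs)
  structure(list(
    coefficients = nn_params(coefs, problem$order,
                             provenance = sprintf("least-squares fit, N = %d",
                                                  length(problem$response))),
    fitted.values = fitted,
    residuals = problem$response - fitted,
    rank = sol$rank,
    residual_norm = sol$residual_norm,
    unseen_classes = unseen,
    order = problem$order,
    problem = problem),
    class = "tnn_fit")
}

#' Predict duplex free energies from a parameter set
#'
#' The estimate for a duplex is the dot product of the motif counts of
#' its top strand with the class weights — no initiation or
#' environmental correction terms.
#'
#' @param seq Character vector of DNA sequences (top strands, 5'->3'),
#'   each at least as long as the motif order.
#' @param params An [nn_params()] object.
#' @return Numeric vector of estimated free energies, kcal/mol.
#' @examples
#' estimate_free_energy("AAAA", duplexnn_params(3))
#' @export
estimate_free_energy <- function(seq, params) {
  stopifnot(inherits(params, "nn_params"))
  order <- attr(params, "order")
  drop(motif_count_matrix(seq, order) %*% as.numeric(params))
}

#' @export
coef.tnn_fit <- function(object, ...) object$coefficients

#' Predict method for nearest-neighbour fits
#'
#' @param object A [tnn_fit()] object.
#' @param newdata Character vector of sequences or a [duplex_dataset()];
#'   omitted, the fitted values are returned.
#' @param ... Unused.
#' @return Numeric vector of free-energy estimates, kcal/mol.
#' @export
predict.tnn_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  seqs <- if (inherits(newdata, "duplex_dataset") ||
              is.data.frame(newdata)) newdata$seq1 else newdata
  estimate_free_energy(seqs, coef(object))
}

#' @export
residuals.tnn_fit <- function(object, ...) object$residuals

#' @export
fitted.tnn_fit <- function(object, ...) object$fitted.values

#' @export
print.tnn_fit <- function(x, ...) {
  cat(sprintf("Nearest-neighbour %s model, fitted to %d perfect-match duplexes\n",
              if (x$order == 2L) "doublet" else "triplet",
              length(x$problem$response)))
  cat(sprintf("  design rank %d/%d, residual RMSE %.4f kcal/mol\n",
              x$rank, ncol(x$problem$counts),
              sqrt(mean(x$residuals^2))))
  if (length(x$unseen_classes))
    cat("  classes unseen in training (weight fixed at 0): ",
        paste(x$unseen_classes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.tnn_fit <- function(object, ...) {
  r <- if (stats::sd(object$problem$response) > 0 &&
           stats::sd(object$fitted.values) > 0)
    stats::cor(object$problem$response, object$fitted.values) else NA_real_
  out <- list(fit = object,
              n = length(object$problem$response),
              rmse = sqrt(mean(object$residuals^2)),
              pearson_r = r,
              coefficients = coef(object))
  class(out) <- "summary.tnn_fit"
  out
}

#' @export
print.summary.tnn_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  training Pearson r = %.4f\n", x$pearson_r))
  print(x$coefficients)
  invisible(x)
}

#' @export
plot.tnn_fit <- function(x, ...) {
  graphics::plot(x$problem$response, x$fitted.values,
                 xlab = expression(paste("experimental ", Delta,
                                         G * degree, " [kcal/mol]")),
                 ylab = expression(paste("estimated ", Delta,
                                         G * degree, " [kcal/mol]")),
                 main = sprintf("%s model fit",
                                if (x$order == 2L) "Doublet" else "Triplet"),
                 ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate duplex datasets from a fitted model
#'
#' Draws `nsim` synthetic perfect-match datasets whose ground truth is
#' the fitted parameter set, via [generate_duplexes()].
#'
#' @param object A [tnn_fit()] object.
#' @param nsim Number of datasets.
#' @param seed RNG seed.
#' @param n Duplexes per dataset (default: size of the training set).
#' @param noise_sd Gaussian noise on the simulated energies, kcal/mol
#'   (default: the fit's residual RMSE).
#' @param ... Unused.
#' @return A list of `nsim` [duplex_dataset()] objects.
#' @export
simulate.tnn_fit <- function(object, nsim = 1, seed = 1,
                             n = length(object$problem$response),
                             noise_sd = sqrt(mean(object$residuals^2)),
                             ...) {
  lapply(seq_len(nsim), function(i)
    generate_duplexes(n = n, truth_params = coef(object),
                      noise_sd = noise_sd,
                      seed = derive_seed(seed, i)))
}
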