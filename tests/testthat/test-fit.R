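test_that("the fit problem holds motif counts and experimental energies", {
  d <- filter_duplexes(toy_dataset(), perfect_only = TRUE)
  p <- build_fit_problem(d, 3)
  expect_equal(dim(p$counts), c(3, 32))
  expect_equal(unname(p$counts[1, "AAA/TTT"]), 2)   # AAAA
  expect_equal(sum(p$counts[1, ]), 2)
  expect_equal(p$response, d$dg_exp)
  expect_equal(rowSums(p$counts), nchar(d$seq1) - 3 + 1,
               ignore_attr = TRUE)

  p2 <- build_fit_problem(d, 2)
  expect_equal(unname(p2$counts[1, "AA/TT"]), 3)
  expect_equal(rowSums(p2$counts), nchar(d$seq1) - 2 + 1,
               ignore_attr = TRUE)

  expect_error(build_fit_problem(toy_dataset(), 3), "toy3")
})

test_that("a one-hot system gets the minimum-norm solution", {
  d <- filter_duplexes(toy_dataset(), perfect_only = TRUE)[1, ]
  fit <- tnn_fit(d, 3)   # single duplex AAAA, dG = -2.0, counts: AAA/TTT = 2
  expect_equal(unname(coef(fit)[["AAA/TTT"]]), -1.0)
  expect_equal(unname(coef(fit))[names(coef(fit)) != "AAA/TTT"],
               rep(0, 31))
  expect_equal(fit$rank, 1)
  expect_equal(fit$residual_norm, 0, tolerance = 1e-12)
  expect_length(fit$unseen_classes, 31)
})

test_that("noise-free synthetic data is recovered exactly", {
  truth <- duplexnn_params(3)
  d <- generate_duplexes(200, noise_sd = 0, seed = 9)
  fit <- tnn_fit(d, 3)
  expect_equal(fit$rank, 32)
  expect_lt(max(abs(coef(fit) - truth)), 1e-9)
  expect_lt(max(abs(residuals(fit))), 1e-9)
})

test_that("the least-squares solution beats random perturbations", {
  set.seed(31)
  d <- generate_duplexes(60, noise_sd = 1, seed = 13)
  fit <- tnn_fit(d, 3)
  x <- as.numeric(coef(fit))
  A <- fit$problem$counts
  b <- fit$problem$response
  base_rss <- sum((A %*% x - b)^2)
  worse <- replicate(1000, {
    sum((A %*% (x + rnorm(length(x), 0, 0.05)) - b)^2)
  })
  expect_true(all(worse >= base_rss - 1e-8))
})

test_that("free-energy estimates are count-weighted parameter sums", {
  expect_equal(estimate_free_energy("AAAA", duplexnn_params(3)),
               2 * -0.844597)
  expect_equal(estimate_free_energy("ATAT", duplexnn_params(2)),
               2 * -0.375235 + -0.144092)
  zero <- nn_params(setNames(rep(0, 32), enumerate_classes(3)), 3)
  expect_equal(estimate_free_energy(c("ACGTACGT", "TTTT"), zero), c(0, 0))
  expect_error(estimate_free_energy("AT", duplexnn_params(3)),
               "shorter than the motif order")
  # additivity over concatenation up to boundary windows
  s <- "ACGTT"; t <- "GGAAC"
  p <- duplexnn_params(3)
  boundary <- sum(count_motifs(paste0(s, t), 3) - count_motifs(s, 3) -
                    count_motifs(t, 3)) # two cross-boundary windows
  expect_equal(boundary, 2)
  cross <- estimate_free_energy(paste0(s, t), p) -
    estimate_free_energy(s, p) - estimate_free_energy(t, p)
  direct <- sum(as.numeric(p) *
                  (count_motifs(paste0(s, t), 3) - count_motifs(s, 3) -
                     count_motifs(t, 3)))
  expect_equal(cross, direct)
})

test_that("the reference triplet model is closely doublet-approximable", {
  # energies generated exactly from the bundled triplet parameters are
  # fitted by a doublet model to well under 1 kcal/mol RMS: the extra
  # context the triplets encode is a small correction on random
  # sequences
  d <- generate_duplexes(1000, noise_sd = 0, seed = 5)
  fit2 <- tnn_fit(d, 2)
  expect_lt(sqrt(mean(residuals(fit2)^2)), 1)
  expect_gt(sqrt(mean(residuals(fit2)^2)), 0.1)
})

test_that("fit methods behave like a classed model object", {
  d <- generate_duplexes(80, noise_sd = 0.3, seed = 21)
  fit <- tnn_fit(d, 2)
  expect_s3_class(coef(fit), "nn_params")
  expect_equal(attr(coef(fit), "order"), 2L)
  expect_equal(fitted(fit) + residuals(fit), d$dg_exp)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, d), fitted(fit))
  expect_equal(predict(fit, "AAAA"),
               unname(3 * coef(fit)[["AA/TT"]]))
  expect_output(print(fit), "doublet model")
  s <- summary(fit)
  expect_true(s$pearson_r <= 1 && s$pearson_r >= -1)
  expect_equal(s$rmse, sqrt(mean(residuals(fit)^2)))
})

test_that("parameter sets serialize to and from two-column tables", {
  p <- duplexnn_params(2)
  path <- tempfile(fileext = ".tsv")
  write_nn_params(p, path)
  p2 <- read_nn_params(path)
  expect_equal(as.numeric(p2), as.numeric(p), tolerance = 1e-9)
  expect_identical(names(p2), names(p))
  # incomplete sets are rejected
  writeLines(c("AA/TT\t-0.8", "AT/TA\t-0.3"), path)
  expect_error(read_nn_params(path), "canonical class labels")
})

test_that("simulate() draws datasets governed by the fitted parameters", {
  d <- generate_duplexes(150, noise_sd = 0, seed = 77)
  fit <- tnn_fit(d, 3)
  sims <- simulate(fit, nsim = 2, seed = 4, n = 40, noise_sd = 0)
  expect_length(sims, 2)
  for (s in sims) {
    expect_true(all(is_perfect_match(s)))
    expect_equal(s$dg_exp, estimate_free_energy(s$seq1, coef(fit)))
  }
  expect_false(identical(sims[[1]]$seq1, sims[[2]]$seq1))
})
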