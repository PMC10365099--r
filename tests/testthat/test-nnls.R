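test_that("NNLS handles identity designs and clips negatives", {
  expect_equal(nnls(diag(3), c(1, 0, 2)), c(1, 0, 2))
  expect_equal(nnls(diag(2), c(-1, 2)), c(0, 2))
  expect_error(nnls(diag(3), c(1, 2)))
})

test_that("NNLS objective matches exhaustive active-set enumeration", {
  set.seed(42)
  for (rep in 1:100) {
    A <- matrix(rnorm(24), 6, 4)
    y <- rnorm(6)
    x <- nnls(A, y)
    expect_true(all(x >= 0))
    obj <- sum((A %*% x - y)^2)
    expect_lt(abs(obj - nnls_exhaustive(A, y)$objective), 1e-8)
  }
})

test_that("NNLS agrees with an established Lawson-Hanson implementation", {
  skip_if_not_installed("pracma")
  set.seed(7)
  for (rep in 1:20) {
    A <- matrix(runif(80), 10, 8)
    y <- rnorm(10)
    obj <- sum((A %*% nnls(A, y) - y)^2)
    ref <- pracma::lsqnonneg(A, y)
    expect_lt(abs(obj - ref$resid.norm), 1e-8)
  }
})

test_that("regularized NNLS reduces to NNLS at zero and vanishes at huge lambda", {
  set.seed(3)
  A <- matrix(runif(30), 6, 5)
  y <- rnorm(6) + 1
  expect_equal(reg_nnls(A, y, 0)$weights, nnls(A, y))
  expect_true(all(reg_nnls(A, y, 1e9)$weights < 1e-6))
  expect_error(reg_nnls(A, y, -1))
})

test_that("regularized NNLS matches a projected-gradient oracle", {
  set.seed(11)
  for (rep in 1:5) {
    A <- matrix(runif(24), 6, 4)
    y <- rnorm(6) + 0.5
    fit <- reg_nnls(A, y, 1)
    xo <- projgrad_reg_nnls(A, y, 1)
    obj <- function(x) sum((A %*% x - y)^2) + sum(x^2)
    expect_lt(abs(obj(fit$weights) - obj(xo)), 1e-6)
  }
})

test_that("residual and solution norms are monotone along the lambda grid", {
  p <- default_protocol
  g <- default_grid
  A <- build_dictionary(p, g, 160)
  set.seed(5)
  Y <- sapply(1:20, function(i) {
    s <- A %*% lobe_spectrum(g, exp(runif(1, log(50), log(120))))
    add_rician_noise(drop(s), s[1] / 100)
  })
  path <- t2relax:::cpp_reg_path(A, Y, lambda_grid(A))
  for (v in 1:20) {
    expect_true(all(diff(path$resid2[, v]) >= -1e-8))
    expect_true(all(diff(path$xnorm2[, v]) <= 1e-8))
  }
})

test_that("chi-square criterion recovers noiseless single-T2 signals", {
  p <- default_protocol
  g <- default_grid
  A <- build_dictionary(p, g, 150)
  for (j in c(20, 30, 40)) {
    sel <- select_lambda_chi2(A, A[, j])
    mass <- sum(sel$weights[max(1, j - 1):min(60, j + 1)]) /
      sum(sel$weights)
    expect_gt(mass, 0.95)
  }
})

test_that("chi-square residual stays within the target factor on noisy data", {
  p <- default_protocol
  g <- default_grid
  A <- build_dictionary(p, g, 160)
  set.seed(9)
  cfg <- fit_config()
  lg <- lambda_grid(A, cfg)
  for (rep in 1:10) {
    s <- drop(A %*% lobe_spectrum(g, 80))
    y <- add_rician_noise(s, s[1] / 80)
    sel <- select_lambda_chi2(A, y, cfg)
    chi2min <- reg_nnls(A, y, 0)$resid2
    expect_lte(sel$resid2 / chi2min, cfg$chi2_factor * (1 + cfg$chi2_rtol))
    expect_gte(sel$lambda, lg[1])
    expect_lte(sel$lambda, lg[length(lg)])
  }
})

test_that("both criteria satisfy augmented-problem KKT conditions", {
  p <- default_protocol
  g <- default_grid
  A <- build_dictionary(p, g, 140)
  set.seed(13)
  s <- drop(A %*% lobe_spectrum(g, 70))
  y <- add_rician_noise(s, s[1] / 100)
  for (sel in list(select_lambda_chi2(A, y),
                   select_lambda_lcurve(A, y))) {
    x <- sel$weights
    grad <- drop(crossprod(A, A %*% x - y)) + sel$lambda^2 * x
    scale <- max(1, max(abs(crossprod(A, y))))
    expect_true(all(grad[x > 1e-12] / scale > -1e-8 &
                    grad[x > 1e-12] / scale < 1e-8))
    expect_true(all(grad[x <= 1e-12] / scale > -1e-8))
  }
})

test_that("L-curve criterion recovers noiseless signals and falls back on flat curves", {
  p <- default_protocol
  g <- default_grid
  A <- build_dictionary(p, g, 150)
  j <- 28
  sel <- select_lambda_lcurve(A, A[, j])
  mass <- sum(sel$weights[(j - 1):(j + 1)]) / sum(sel$weights)
  expect_gt(mass, 0.95)
  # a signal in the antipodal cone gives x = 0 for every lambda: the
  # residual curve is exactly flat (collinear in log-log) -> fallback
  y_neg <- -A[, j]
  self <- select_lambda_lcurve(A, y_neg)
  expect_true(self$fallback)
  expect_equal(self$lambda, lambda_grid(A)[1])
})

test_that("stronger noise drives the L-curve corner to larger lambda", {
  p <- default_protocol
  g <- default_grid
  A <- build_dictionary(p, g, 160)
  set.seed(21)
  s <- drop(A %*% lobe_spectrum(g, 90))
  clean <- select_lambda_lcurve(A, s)
  lam_noisy <- replicate(20, {
    select_lambda_lcurve(A, add_rician_noise(s, s[1] / 30))$lambda
  })
  expect_gt(median(lam_noisy), clean$lambda)
})

test_that("volume fitting recovers a noiseless phantom within 2 percent", {
  p <- default_protocol
  g <- default_grid
  bank <- shared_bank
  dims <- c(2, 2, 1)
  truths <- c(60, 75, 90, 110)
  img <- array(0, c(dims, 32))
  A <- bank_lookup(bank, 165)$A
  for (v in 1:4)
    img[((v - 1) %% 2) + 1, ((v - 1) %/% 2) + 1, 1, ] <-
      A %*% lobe_spectrum(g, truths[v])
  mask <- array(TRUE, dims)
  for (method in c("chi2", "lcurve")) {
    sm <- fit_volume(img, mask, 165, bank, fit_config(method = method))
    est <- t2ie_map(sm)[array(TRUE, dims)]
    expect_true(all(abs(sort(est) - truths) / truths < 0.02))
  }
  # methods agree on noiseless data
  s1 <- fit_volume(img, mask, 165, bank, fit_config("chi2"))
  s2 <- fit_volume(img, mask, 165, bank, fit_config("lcurve"))
  expect_true(all(abs(t2ie_map(s1) - t2ie_map(s2)) / t2ie_map(s1) < 0.02))
  # empty mask
  empty <- fit_volume(img, array(FALSE, dims), 165, bank)
  expect_length(empty$vox_idx, 0)
})

test_that("t2fit object supports the standard model-fit generics", {
  g <- default_grid
  bank <- shared_bank
  A <- bank_lookup(bank, 160)$A
  w <- lobe_spectrum(g, 85)
  y <- drop(A %*% w)
  f <- t2fit(y, fa = 160, bank = bank)
  expect_s3_class(f, "t2fit")
  expect_length(coef(f), 60)
  expect_equal(fitted(f), y, tolerance = 1e-6)
  expect_lt(max(abs(residuals(f))), 1e-4)
  expect_equal(predict(f), fitted(f))
  s <- summary(f)
  expect_lt(abs(s$t2ie - 85) / 85, 0.02)
  sim <- simulate(f, nsim = 3, seed = 1, snr = 50)
  expect_equal(dim(sim), c(32L, 3L))
  expect_output(print(f), "T2 fit")
})
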