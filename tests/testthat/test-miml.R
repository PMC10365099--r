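test_that("Wasserstein distance covers the closed-form cases", {
  p <- c(0.2, 0.3, 0.5)
  expect_equal(wasserstein_1d(p, p), 0)
  # deltas at adjacent bins, unit spacing
  expect_equal(wasserstein_1d(c(1, 0, 0), c(0, 1, 0)), 1)
  expect_equal(wasserstein_1d(c(1, 0, 0), c(0, 0, 1)), 2)
  expect_error(wasserstein_1d(p, c(0.5, 0.5)))
  expect_error(wasserstein_1d(p, c(0.2, 0.3, 0.6)))
})

test_that("Wasserstein distance equals the transport oracle on random pairs", {
  set.seed(29)
  for (rep in 1:30) {
    p <- runif(5); p <- p / sum(p)
    q <- runif(5); q <- q / sum(q)
    pos <- cumsum(runif(5, 0.5, 2))
    expect_lt(abs(wasserstein_1d(p, q, pos) -
                  wasserstein_greedy(p, q, pos)), 1e-8)
  }
})

test_that("Wasserstein distance is a metric on random triples", {
  set.seed(31)
  for (rep in 1:20) {
    p <- runif(8); p <- p / sum(p)
    q <- runif(8); q <- q / sum(q)
    r <- runif(8); r <- r / sum(r)
    dpq <- wasserstein_1d(p, q)
    expect_equal(dpq, wasserstein_1d(q, p))
    expect_gte(dpq, 0)
    expect_lt(wasserstein_1d(p, p), 1e-12)
    expect_lte(dpq, wasserstein_1d(p, r) + wasserstein_1d(r, q) + 1e-12)
  }
})

test_that("training pairs are reproducible and generatively consistent", {
  bank <- shared_bank
  p1 <- generate_training_pairs(3, bank, seed = 5)
  p2 <- generate_training_pairs(3, bank, seed = 5)
  expect_identical(p1$signals, p2$signals)
  expect_identical(p1$spectra, p2$spectra)
  # noiseless pairs equal the dictionary forward model, renormalized
  pn <- generate_training_pairs(4, bank, seed = 6,
                                snr_range = c(Inf, Inf))
  for (i in 1:4) {
    A <- bank_lookup(bank, pn$fa[i])$A
    s <- drop(A %*% pn$spectra[, i])
    expect_lt(max(abs(pn$signals[, i] - s / s[1])), 1e-12)
  }
  expect_true(all(abs(colSums(pn$spectra) - 1) < 1e-9))
  expect_true(all(pn$signals[1, ] == 1))
})

test_that("empirical first-echo SNR matches the requested level", {
  bank <- shared_bank
  pr <- generate_training_pairs(10000, bank, seed = 8,
                                snr_range = c(100, 100))
  # reconstruct the noiseless signals and compare first-echo fluctuations
  rel_err <- numeric(500)
  for (i in 1:500) {
    A <- bank_lookup(bank, pr$fa[i])$A
    strue <- drop(A %*% pr$spectra[, i])
    rel_err[i] <- pr$first_echo[i] / strue[1] - 1
  }
  snr_hat <- 1 / sd(rel_err)
  expect_lt(abs(snr_hat - 100) / 100, 0.05)
})

test_that("short training reduces the loss substantially", {
  bank <- shared_bank
  pairs <- generate_training_pairs(5000, bank, seed = 1)
  m <- train_mlp(pairs, cfg = train_config(n_pairs = 5000, epochs = 5,
                                           seed = 1))
  expect_lt(tail(m$loss, 1), 0.7 * m$loss[1])
  expect_true(all(is.finite(m$loss)))
})

test_that("a constant target spectrum is learned to high accuracy", {
  bank <- shared_bank
  g <- bank$grid
  w <- lobe_spectrum(g, 70, 0.15)
  n <- 256
  pairs <- generate_training_pairs(n, bank, seed = 3)
  pairs$spectra <- matrix(rep(w, n), 60)
  m <- train_mlp(pairs, spec = mlp_spec(n_hidden_layers = 2,
                                        units_per_layer = 64),
                 cfg = train_config(n_pairs = n, batch_size = 256,
                                    epochs = 300, learning_rate = 3e-3,
                                    seed = 1))
  P <- predict(m, pairs$signals[, 1:20])
  expect_lt(max(colSums((P - w)^2)), 1e-3)
})

test_that("predictions are unit-sum distributions invariant to signal scale", {
  bank <- shared_bank
  pairs <- generate_training_pairs(2000, bank, seed = 2)
  m <- train_mlp(pairs, cfg = train_config(n_pairs = 2000, epochs = 2,
                                           seed = 2))
  val <- generate_training_pairs(20, bank, seed = 9)
  P <- predict(m, val$signals)
  expect_true(all(P >= 0))
  expect_true(all(abs(colSums(P) - 1) < 1e-5))
  expect_equal(predict(m, 3 * val$signals), P)
  sm <- predict_spectrum_map(m, array(rep(t(val$signals[, 1]),
                                          each = 8), c(2, 2, 2, 32)),
                             array(TRUE, c(2, 2, 2)))
  expect_true(all(abs(colSums(sm$weights) - 1) < 1e-5))
})
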