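test_that("Gaussian smoothing preserves constants and respects fwhm = 0", {
  set.seed(1)
  v <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  expect_identical(gaussian_smooth_3d(v, 0), v)
  const <- array(3.7, c(6, 6, 6))
  expect_lt(max(abs(gaussian_smooth_3d(const, 4.8, 1.6) - const)), 1e-10)
  expect_error(gaussian_smooth_3d(v, -1))
})

test_that("smoothing a delta reproduces the separable Gaussian kernel", {
  d <- c(15, 15, 15)
  v <- array(0, d)
  v[8, 8, 8] <- 1
  fwhm <- 4.8; vox <- 1.6
  out <- gaussian_smooth_3d(v, fwhm, vox)
  sigma <- fwhm / 2.3548 / vox
  r <- max(1, ceiling(4 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  k0 <- k[r + 1]
  expect_lt(abs(out[8, 8, 8] - k0^3), 1e-12)
  expect_lt(abs(out[9, 8, 8] - k[r + 2] * k0^2), 1e-12)
})

test_that("flip angle is recovered on noiseless single-T2 voxels", {
  bank <- shared_bank
  g <- default_grid
  p <- default_protocol
  w <- lobe_spectrum(g, 80, 0.05)
  # coarse grid points recover within the fine-grid step
  for (fa in c(150, 96.42857142857143, 173.5714285714286)) {
    y <- drop(build_dictionary(p, g, fa) %*% w)
    expect_lt(abs(estimate_fa_voxel(y, bank) - fa), 0.33)
  }
  # boundary minimum at 180 is returned exactly
  y180 <- drop(build_dictionary(p, g, 180) %*% w)
  expect_equal(estimate_fa_voxel(y180, bank), 180)
  # off-grid angle recovered by spline interpolation
  y137 <- drop(build_dictionary(p, g, 137) %*% w)
  expect_lt(abs(estimate_fa_voxel(y137, bank) - 137), 1)
  # invariance to global signal scaling
  expect_equal(estimate_fa_voxel(3.2 * y137, bank),
               estimate_fa_voxel(y137, bank))
  expect_true(is.na(estimate_fa_voxel(rep(0, 32), bank)))
})

test_that("flip-angle map recovers a constant field at clinical SNR", {
  set.seed(31)
  bank <- shared_bank
  g <- default_grid
  dims <- c(8, 8, 8)
  s <- drop(bank_lookup(bank, 160)$A %*% lobe_spectrum(g, 75))
  img <- array(rep(s, each = prod(dims)), c(dims, 32))
  img <- add_rician_noise(img, s[1] / 100)
  fam <- estimate_fa_map(img, array(TRUE, dims), bank)
  expect_lt(abs(mean(fam$fa) - 160), 1)
})

test_that("a one-voxel mask reduces to the single-voxel estimator", {
  bank <- shared_bank
  g <- default_grid
  dims <- c(3, 3, 3)
  s <- drop(bank_lookup(bank, 145.2)$A %*% lobe_spectrum(g, 65))
  img <- array(rep(s, each = prod(dims)), c(dims, 32))
  mask <- array(FALSE, dims); mask[2, 2, 2] <- TRUE
  fam <- estimate_fa_map(img, mask, bank)
  # constant image: smoothing is a no-op at the centre voxel
  expect_equal(fam$fa[2, 2, 2], estimate_fa_voxel(s, bank))
  expect_true(all(is.na(fam$fa[!mask])))
})

test_that("a spatially linear flip-angle field stays monotone after mapping", {
  bank <- shared_bank
  g <- default_grid
  p <- default_protocol
  nx <- 12
  fa_true <- seq(120, 180, length.out = nx)
  w <- lobe_spectrum(g, 80)
  img <- array(0, c(nx, 4, 4, 32))
  for (i in seq_len(nx)) {
    s <- drop(build_dictionary(p, g, fa_true[i]) %*% w)
    img[i, , , ] <- rep(s, each = 16)
  }
  fam <- estimate_fa_map(img, array(TRUE, c(nx, 4, 4)), bank,
                         fwhm_mm = 4.8, voxel_mm = 1.6)
  prof <- apply(fam$fa, 1, mean)
  expect_true(all(diff(prof) > -0.34)) # monotone within grid tolerance
  expect_gt(prof[nx], prof[1] + 30)
})

test_that("an empty mask yields an empty map with a warning", {
  img <- array(1, c(2, 2, 2, 32))
  expect_warning(fam <- estimate_fa_map(img, array(FALSE, c(2, 2, 2)),
                                        shared_bank))
  expect_true(all(is.na(fam$fa)))
})
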