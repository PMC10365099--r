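test_that("the study design enumerates the full factorial", {
  d <- make_design()
  expect_equal(nrow(d), 160)
  expect_equal(length(unique(d$scan_id)), 160)
  expect_equal(nrow(make_design(1, 1, 1, 1)), 1)
  expect_equal(nrow(make_design(3, 2, 1, 2)), 12)
  expect_error(make_design(0, 2, 2, 2))
})

test_that("scan truths collapse to the baselines when all SDs vanish", {
  d <- make_design(3, 2, 2, 2)
  vc0 <- variance_components(0, 0, 0, 0)
  ph <- phantom_spec()
  tr <- sample_scan_truth(d, vc0, ph, seed = 4)
  for (r in 1:3)
    expect_true(all(tr$true_t2ie[tr$region == r] == ph$mu_t2ie[r]))
})

test_that("the subject effect SD is recovered empirically", {
  d <- make_design(1000, 1, 1, 1)
  vc <- variance_components(sd_subject = 5, sd_site = 0, sd_session = 0,
                            sd_run = 0)
  tr <- sample_scan_truth(d, vc, phantom_spec(), seed = 10)
  s_hat <- sd(tr$true_t2ie[tr$region == 1])
  expect_lt(abs(s_hat - 5) / 5, 0.05)
})

test_that("truth sampling is reproducible by seed", {
  d <- make_design(4, 2, 2, 2)
  vc <- variance_components()
  t1 <- sample_scan_truth(d, vc, phantom_spec(), seed = 11)
  t2 <- sample_scan_truth(d, vc, phantom_spec(), seed = 11)
  expect_identical(t1, t2)
  t3 <- sample_scan_truth(d, vc, phantom_spec(), seed = 12)
  expect_false(identical(t1$true_t2ie, t3$true_t2ie))
})

test_that("region spectra hit the requested windowed geometric mean", {
  g <- default_grid
  for (target in c(55, 71, 88, 140)) {
    for (mf in c(0, 0.06, 0.15)) {
      w <- region_spectrum(target, mf, g)
      expect_lt(abs(t2ie(w, g) - target) / target, 0.01)
      expect_lt(abs(mwf(w, g) - mf), 0.02)
    }
  }
  expect_warning(region_spectrum(250, 0.1, g), "clipping")
})

test_that("a noise-free 180-degree scan equals the analytic multiexponential", {
  ph <- phantom_spec(region_dim = 3)
  vc <- variance_components(0, 0, 0, 0, snr_first_echo = Inf,
                            fa_mean = 180, fa_sd = 0)
  d <- make_design(1, 1, 1, 1)
  tr <- sample_scan_truth(d, vc, ph, seed = 1)
  bank <- shared_bank
  sc <- synthesize_scan(tr, ph, vc, bank, seed = 1)
  te <- echo_times(bank$protocol)
  g <- bank$grid
  for (r in 1:3) {
    w <- region_spectrum(ph$mu_t2ie[r], ph$myelin_fraction[r], g)
    analytic <- drop(exp(-outer(te, 1 / g)) %*% w)
    vox <- which(sc$labels == r)[1]
    sig <- sc$img[arrayInd(vox, dim(sc$labels))[1],
                  arrayInd(vox, dim(sc$labels))[2],
                  arrayInd(vox, dim(sc$labels))[3], ]
    expect_lt(max(abs(sig - analytic)), 1e-9)
  }
})

test_that("same truth with different noise seeds changes only the image", {
  ph <- phantom_spec(region_dim = 3)
  vc <- variance_components()
  d <- make_design(1, 1, 1, 1)
  tr <- sample_scan_truth(d, vc, ph, seed = 2)
  bank <- shared_bank
  s1 <- synthesize_scan(tr, ph, vc, bank, seed = 100)
  s2 <- synthesize_scan(tr, ph, vc, bank, seed = 200)
  expect_false(identical(s1$img, s2$img))
  expect_identical(s1$labels, s2$labels)
})

test_that("generated first-echo SNR matches the request", {
  ph <- phantom_spec(region_dim = 8)
  vc <- variance_components(snr_first_echo = 100)
  d <- make_design(1, 1, 1, 1)
  tr <- sample_scan_truth(d, vc, ph, seed = 3)
  bank <- shared_bank
  vc_inf <- variance_components(snr_first_echo = Inf)
  clean <- synthesize_scan(tr, ph, vc_inf, bank, seed = 7)
  noisy <- synthesize_scan(tr, ph, vc, bank, seed = 7)
  resid <- (noisy$img[, , , 1] - clean$img[, , , 1])[ph_lab <- clean$labels > 0]
  snr_hat <- mean(clean$img[, , , 1][ph_lab]) / sd(resid)
  expect_lt(abs(snr_hat - 100) / 100, 0.05)
})

test_that("study files round-trip and the ground truth is byte-stable", {
  d <- make_design(2, 1, 1, 2)
  vc <- variance_components()
  ph <- phantom_spec(region_dim = 3)
  bank <- shared_bank
  dir1 <- tempfile(); dir2 <- tempfile()
  st1 <- generate_study(d, vc, ph, bank, seed = 21, out_dir = dir1)
  st2 <- generate_study(d, vc, ph, bank, seed = 21, out_dir = dir2)
  expect_equal(nrow(st1$design), 4)
  expect_true(all(file.exists(st1$design$path)))
  expect_identical(readBin(file.path(dir1, "ground_truth.csv"), "raw", 1e6),
                   readBin(file.path(dir2, "ground_truth.csv"), "raw", 1e6))
  # written image round-trips through NIfTI
  rt <- read_multiecho_nifti(st1$design$path[1], bank$protocol)
  expect_equal(rt$data, st1$scans[[1]]$img, tolerance = 1e-6)
  expect_equal(unname(rt$voxel_mm), rep(1.6, 3))
  unlink(c(dir1, dir2), recursive = TRUE)
})
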