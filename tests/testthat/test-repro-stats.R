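test_that("ROI means average the right voxels and skip undefined ones", {
  lab <- array(0L, c(4, 4, 1))
  lab[1:2, , 1] <- 1L
  lab[3, , 1] <- 2L
  m <- array(NA_real_, c(4, 4, 1))
  m[1:2, , 1] <- 70
  m[3, 1:2, 1] <- c(10, 20)
  tab <- roi_means(m, lab)
  expect_equal(tab$value[tab$roi == 1], 70)
  expect_equal(tab$value[tab$roi == 2], 15)  # NAs excluded
  # label absent from the image: no row
  expect_false(3 %in% tab$roi)
  # label with zero valid voxels: warning + omitted
  m[3, , 1] <- NA
  expect_warning(tab2 <- roi_means(m, lab), "no valid voxels")
  expect_false(2 %in% tab2$roi)
})

test_that("CoV is the sample SD over mean in percent, scale-invariant", {
  expect_equal(cov_percent(c(71, 71, 71)), 0)
  expect_equal(cov_percent(c(70, 72)), sqrt(2) / 71 * 100)
  set.seed(59)
  v <- rlnorm(30, log(70), 0.1)
  expect_equal(cov_percent(v), sd(v) / mean(v) * 100)
  expect_equal(cov_percent(5 * v), cov_percent(v))
  expect_error(cov_percent(70))
  expect_true(is.na(cov_percent(c(-1, 1))))
})

test_that("effect groupings match the design combinatorics", {
  d <- make_design(20, 2, 2, 2)
  tab <- d
  tab$roi <- 1L
  set.seed(61)
  tab$value <- rnorm(nrow(tab), 70, 1)
  expect_length(group_by_effect(tab, "inter_run"), 80)
  expect_length(group_by_effect(tab, "inter_session"), 40)
  expect_length(group_by_effect(tab, "inter_scanner"), 20)
  expect_length(group_by_effect(tab, "inter_subject"), 2)
  # permuting rows leaves the groups unchanged
  perm <- tab[sample(nrow(tab)), ]
  g1 <- group_by_effect(tab, "inter_session")
  g2 <- group_by_effect(perm, "inter_session")
  expect_equal(lapply(g1, sort), lapply(g2, sort))
  # group sizes: runs pairs; subject groups hold all 20 subjects
  expect_true(all(lengths(group_by_effect(tab, "inter_run")) == 2))
  expect_true(all(lengths(group_by_effect(tab, "inter_subject")) == 20))
})

test_that("degenerate designs drop groups instead of failing", {
  d <- make_design(1, 1, 1, 2)
  tab <- d
  tab$roi <- 1L
  tab$value <- c(70, 71)
  expect_length(group_by_effect(tab, "inter_run"), 1)
  expect_message(g <- group_by_effect(tab, "inter_subject"), "dropped")
  expect_length(g, 0)
})

test_that("ICC is exact on its closed-form cases", {
  # identical columns with differing rows: perfect consistency
  m <- cbind(c(1, 5, 9), c(1, 5, 9), c(1, 5, 9))
  expect_equal(icc_consistency_single(m)$icc, 1)
  # constant column offsets are invisible to the consistency form
  m2 <- cbind(c(1, 5, 9), c(3, 7, 11), c(0, 4, 8))
  expect_equal(icc_consistency_single(m2)$icc, 1)
  expect_error(icc_consistency_single(m[1, , drop = FALSE]))
  m3 <- m; m3[1, 1] <- NA
  expect_error(icc_consistency_single(m3), "missing")
})

test_that("ICC equals the two-way ANOVA oracle on random matrices", {
  set.seed(67)
  for (rep in 1:20) {
    n <- sample(4:10, 1); k <- sample(2:6, 1)
    m <- matrix(rnorm(n * k, 50, 5), n, k) +
      rnorm(n, 0, 2) + rep(rnorm(k, 0, 1), each = n)
    expect_lt(abs(icc_consistency_single(m)$icc - icc_aov_oracle(m)),
              1e-10)
  }
})

test_that("ICC estimates approach the population value under the model", {
  set.seed(71)
  n <- 20; k <- 8
  est <- replicate(200, {
    subj <- rnorm(n, 0, 2)
    y <- outer(subj, rep(1, k)) + matrix(rnorm(n * k, 0, 1), n, k)
    icc_consistency_single(y)$icc
  })
  expect_lt(abs(mean(est) - 0.8), 0.05)
})

test_that("ICC confidence bounds bracket the estimate at 95 percent", {
  set.seed(73)
  m <- outer(rnorm(10, 0, 2), rep(1, 4)) + matrix(rnorm(40), 10, 4)
  r <- icc_consistency_single(m)
  expect_lt(r$lower, r$icc)
  expect_gt(r$upper, r$icc)
  expect_gte(r$icc, icc_agreement_single(m)) # agreement penalizes shifts
})

test_that("pairwise rank-sum tests match closed forms and count pairs", {
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  t1 <- pairwise_ranksum_bonferroni(same)
  expect_equal(t1$p_adj, 1)
  sep <- list(a = c(1, 2, 3, 4), b = c(101, 102, 103, 104))
  t2 <- pairwise_ranksum_bonferroni(sep)
  p_exact <- ranksum_exact_p(sep$a, sep$b)
  expect_equal(p_exact, 2 / 70, tolerance = 1e-12)
  expect_lt(abs(t2$p_raw - p_exact), 0.005) # normal approx vs enumeration
  four <- list(a = 1:4, b = 2:5, c = 3:6, d = 4:7)
  t4 <- pairwise_ranksum_bonferroni(lapply(four, as.numeric))
  expect_equal(nrow(t4), 6)
  expect_equal(t4$p_adj, pmin(1, t4$p_raw * 6))
})

test_that("the reproducibility report assembles consistent tables", {
  d <- make_design(6, 2, 2, 2)
  set.seed(79)
  tabs <- lapply(1:2, function(r) {
    tab <- d
    tab$roi <- r
    subj <- rnorm(6, 70 + 2 * r, 1.5)
    tab$value <- subj[tab$subject] + rnorm(nrow(tab), 0, 0.3)
    tab
  })
  tab <- do.call(rbind, tabs)
  rep1 <- repro_report(tab)
  expect_s3_class(rep1, "repro_report")
  expect_equal(sort(unique(rep1$cov$effect)),
               sort(c("inter_run", "inter_session", "inter_scanner",
                      "inter_subject")))
  expect_equal(rep1$icc$roi, c(1L, 2L))
  expect_equal(rep1$icc$k, c(8L, 8L))
  expect_true(all(rep1$icc$icc > 0.5)) # strong subject effect by design
  expect_equal(nrow(rep1$tests), 6)
  # regenerating from the same table is bit-identical
  expect_identical(rep1, repro_report(tab))
  dir <- tempfile()
  write_report(rep1, dir)
  expect_true(all(file.exists(file.path(dir,
    c("cov_by_effect.csv", "icc_by_roi.csv", "pairwise_tests.csv")))))
  unlink(dir, recursive = TRUE)
})

test_that("single-measurement tables yield no ICC section", {
  d <- make_design(4, 1, 1, 1)
  tab <- d
  tab$roi <- 1L
  tab$value <- rnorm(4, 70, 1)
  expect_length(icc_matrices(tab), 0)
})
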