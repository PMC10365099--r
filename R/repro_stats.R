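#' Per-ROI means of a scalar map
#'
#' Arithmetic mean of the scalar map over the voxels of each positive
#' label; voxels flagged undefined (`NA`) are excluded. Labels left with no
#' valid voxel are omitted with a warning.
#'
#' @param scalar_map 3D array (e.g. a T2IE map), `NA` where undefined
#' @param labels integer 3D label array of the same shape
#' @return data frame with columns `roi`, `value`
#' @export
roi_means <- function(scalar_map, labels) {
  if (!all(dim(scalar_map) == dim(labels)))
    stop("scalar map and labels shapes differ")
  rois <- sort(unique(labels[labels > 0]))
  out <- data.frame(roi = integer(0), value = numeric(0))
  for (r in rois) {
    v <- scalar_map[labels == r]
    v <- v[!is.na(v)]
    if (!length(v)) {
      warning(sprintf("ROI %d has no valid voxels; omitted", r))
      next
    }
    out <- rbind(out, data.frame(roi = r, value = mean(v)))
  }
  out
}

#' Coefficient of variation in percent
#'
#' Sample standard deviation (n-1 denominator) divided by the mean, times
#' 100. Undefined (`NA`) for a zero mean.
#'
#' @param values numeric vector of length >= 2
#' @return CoV in percent
#' @export
cov_percent <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) return(NA_real_)
  stats::sd(values) / m * 100
}

#' Group ROI values by variability effect
#'
#' Forms the scan groups over which each effect's variability is computed,
#' within each ROI: `inter_run` groups the runs of one
#' (subject, site, session) cell; `inter_session` the per-session means
#' (runs averaged first) of one (subject, site); `inter_scanner` the
#' per-site means (sessions and runs averaged) of one subject;
#' `inter_subject` the per-subject means (all of a subject's scans on one
#' site averaged) within each site. Groups with fewer than two members are
#' dropped.
#'
#' @param tab data frame with columns `subject`, `site`, `session`, `run`,
#'   `roi`, `value` (one row per scan x ROI)
#' @param effect one of `"inter_run"`, `"inter_session"`,
#'   `"inter_scanner"`, `"inter_subject"`
#' @return named list of numeric value vectors (one per group)
#' @export
group_by_effect <- function(tab, effect = c("inter_run", "inter_session",
                                            "inter_scanner",
                                            "inter_subject")) {
  effect <- match.arg(effect)
  need <- c("subject", "site", "session", "run", "roi", "value")
  if (!all(need %in% names(tab)))
    stop("table must have columns ", paste(need, collapse = ", "))
  agg <- function(d, by) {
    stats::aggregate(d["value"], by = d[by], FUN = mean)
  }
  groups <- switch(effect,
    inter_run = split(tab$value,
                      interaction(tab$roi, tab$subject, tab$site,
                                  tab$session, drop = TRUE)),
    inter_session = {
      d <- agg(tab, c("roi", "subject", "site", "session"))
      split(d$value, interaction(d$roi, d$subject, d$site, drop = TRUE))
    },
    inter_scanner = {
      d <- agg(tab, c("roi", "subject", "site"))
      split(d$value, interaction(d$roi, d$subject, drop = TRUE))
    },
    inter_subject = {
      d <- agg(tab, c("roi", "subject", "site"))
      split(d$value, interaction(d$roi, d$site, drop = TRUE))
    })
  keep <- vapply(groups, length, integer(1)) >= 2
  if (any(!keep))
    message(sprintf("%s: dropped %d group(s) with < 2 members", effect,
                    sum(!keep)))
  groups[keep]
}

#' CoV distributions for all four effects
#'
#' @param tab scan x ROI table as in [group_by_effect()]
#' @return data frame with columns `effect`, `group`, `cov`
#' @export
cov_by_effect <- function(tab) {
  effects <- c("inter_run", "inter_session", "inter_scanner",
               "inter_subject")
  out <- lapply(effects, function(e) {
    g <- group_by_effect(tab, e)
    if (!length(g)) return(NULL)
    data.frame(effect = e, group = names(g),
               cov = vapply(g, cov_percent, numeric(1)),
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Two-way random-effects ICC, single measurement, consistency
#'
#' From the two-way ANOVA decomposition of a complete subjects x
#' measurements matrix, `ICC(C,1) = (MS_rows - MS_err) /
#' (MS_rows + (k - 1) MS_err)`, with the standard F-based confidence
#' interval at level `conf`.
#'
#' @param m numeric matrix, rows = subjects (n >= 2), columns = repeated
#'   measurements (k >= 2); no missing cells
#' @param conf confidence level
#' @return object of class `"icc_result"`: `icc`, `lower`, `upper`,
#'   `n_subjects`, `k_measurements`, `conf`
#' @export
icc_consistency_single <- function(m, conf = 0.95) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 measurements")
  if (anyNA(m)) stop("matrix has missing cells; drop incomplete subjects")
  gm <- mean(m)
  ssr <- k * sum((rowMeans(m) - gm)^2)       # subjects
  ssc <- n * sum((colMeans(m) - gm)^2)       # measurements
  sse <- sum((m - outer(rowMeans(m), colMeans(m), "+") + gm)^2)
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse)
  fv <- msr / mse
  alpha <- 1 - conf
  fl <- fv / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
  fu <- fv * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
  structure(list(icc = icc, lower = (fl - 1) / (fl + k - 1),
                 upper = (fu - 1) / (fu + k - 1), n_subjects = n,
                 k_measurements = k, conf = conf,
                 ms_rows = msr, ms_error = mse, ms_cols = ssc / (k - 1)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(C,1) = %.3f  [%.3f, %.3f] (%g%%), n = %d, k = %d\n",
              x$icc, x$lower, x$upper, 100 * x$conf, x$n_subjects,
              x$k_measurements))
  invisible(x)
}

#' Absolute-agreement single-measurement ICC (cross-check hook)
#'
#' `ICC(A,1)` from the same two-way decomposition; provided for
#' comparison with the consistency form, not used by the main report.
#'
#' @inheritParams icc_consistency_single
#' @return the ICC(A,1) point estimate
#' @export
icc_agreement_single <- function(m) {
  r <- icc_consistency_single(m)
  n <- r$n_subjects; k <- r$k_measurements
  (r$ms_rows - r$ms_error) /
    (r$ms_rows + (k - 1) * r$ms_error +
       k / n * (r$ms_cols - r$ms_error))
}

#' Pairwise rank-sum tests between effect CoV distributions
#'
#' Two-sided Wilcoxon rank-sum tests (normal approximation with tie and
#' continuity correction) for every pair of effects, Bonferroni-adjusted
#' by the number of pairs.
#'
#' @param cov_lists named list of CoV vectors, one per effect (each >= 2
#'   values; shorter entries are skipped)
#' @return data frame: `effect_a`, `effect_b`, `p_raw`, `p_adj`,
#'   `significant` (at 0.05)
#' @export
pairwise_ranksum_bonferroni <- function(cov_lists) {
  if (length(cov_lists) < 2) stop("need at least two effects")
  nm <- names(cov_lists)
  pairs <- utils::combn(length(cov_lists), 2)
  n_pairs <- ncol(pairs)
  rows <- vector("list", n_pairs)
  for (j in seq_len(n_pairs)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    va <- cov_lists[[a]]; vb <- cov_lists[[b]]
    if (length(va) < 2 || length(vb) < 2) {
      message(sprintf("skipping pair %s vs %s (< 2 values)", nm[a], nm[b]))
      next
    }
    p <- stats::wilcox.test(va, vb, exact = FALSE, correct = TRUE)$p.value
    rows[[j]] <- data.frame(effect_a = nm[a], effect_b = nm[b], p_raw = p,
                            p_adj = min(1, p * n_pairs),
                            significant = min(1, p * n_pairs) < 0.05)
  }
  do.call(rbind, rows)
}

#' Subjects x measurements matrices per ROI
#'
#' Arranges the scan x ROI table into one complete matrix per ROI with
#' rows = subjects and columns = the (site, session, run) repeated
#' measurements; subjects with incomplete cells are dropped.
#'
#' @param tab scan x ROI table as in [group_by_effect()]
#' @return named list of matrices, one per ROI
#' @export
icc_matrices <- function(tab) {
  tab$meas <- paste(tab$site, tab$session, tab$run, sep = "_")
  out <- list()
  for (r in sort(unique(tab$roi))) {
    d <- tab[tab$roi == r, ]
    m <- stats::xtabs(value ~ subject + meas, data = d)
    cnt <- stats::xtabs(~ subject + meas, data = d) # absent cells are 0
    keep <- apply(cnt == 1, 1, all)
    m <- as.matrix(m[keep, , drop = FALSE])
    if (nrow(m) >= 2 && ncol(m) >= 2) out[[as.character(r)]] <- m
  }
  out
}

#' Full reproducibility report
#'
#' Bundles the CoV-by-effect distributions, the per-ROI ICC (consistency,
#' single measurement) and the pairwise rank-sum table for one scan x ROI
#' value table.
#'
#' @param tab scan x ROI table (columns `subject`, `site`, `session`,
#'   `run`, `roi`, `value`)
#' @param conf ICC confidence level
#' @return object of class `"repro_report"`: `cov` (data frame), `icc`
#'   (data frame per ROI), `tests` (pairwise table), `mean_sd` (per-ROI
#'   mean and SD of the values)
#' @export
repro_report <- function(tab, conf = 0.95) {
  cov_tab <- cov_by_effect(tab)
  mats <- icc_matrices(tab)
  icc_tab <- do.call(rbind, lapply(names(mats), function(r) {
    x <- icc_consistency_single(mats[[r]], conf)
    data.frame(roi = as.integer(r), icc = x$icc, lower = x$lower,
               upper = x$upper, n = x$n_subjects, k = x$k_measurements)
  }))
  cov_lists <- split(cov_tab$cov, cov_tab$effect)
  tests <- if (length(cov_lists) >= 2)
    pairwise_ranksum_bonferroni(cov_lists) else NULL
  mean_sd <- do.call(rbind, lapply(split(tab$value, tab$roi), function(v)
    data.frame(mean = mean(v), sd = stats::sd(v))))
  mean_sd$roi <- as.integer(rownames(mean_sd))
  structure(list(cov = cov_tab, icc = icc_tab, tests = tests,
                 mean_sd = mean_sd[, c("roi", "mean", "sd")]),
            class = "repro_report")
}

#' @export
print.repro_report <- function(x, ...) {
  cat("Reproducibility report\n")
  cat("  median CoV (%) by effect:\n")
  med <- tapply(x$cov$cov, x$cov$effect, stats::median)
  for (e in c("inter_run", "inter_session", "inter_scanner",
              "inter_subject"))
    if (e %in% names(med)) cat(sprintf("    %-14s %.3f\n", e, med[[e]]))
  if (!is.null(x$icc)) {
    cat("  ICC(C,1) by ROI:\n")
    for (i in seq_len(nrow(x$icc)))
      cat(sprintf("    ROI %d: %.3f [%.3f, %.3f]\n", x$icc$roi[i],
                  x$icc$icc[i], x$icc$lower[i], x$icc$upper[i]))
  }
  if (!is.null(x$tests)) {
    cat("  pairwise rank-sum (Bonferroni):\n")
    for (i in seq_len(nrow(x$tests)))
      cat(sprintf("    %s vs %s: p_adj = %.4g%s\n", x$tests$effect_a[i],
                  x$tests$effect_b[i], x$tests$p_adj[i],
                  ifelse(x$tests$significant[i], " *", "")))
  }
  invisible(x)
}

#' Write a reproducibility report to CSV files
#'
#' Writes `cov_by_effect.csv`, `icc_by_roi.csv`, `pairwise_tests.csv` and
#' `mean_sd_by_roi.csv` to a directory.
#'
#' @param report a [repro_report()]
#' @param dir output directory
#' @return invisibly, the directory
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$cov, file.path(dir, "cov_by_effect.csv"),
                   row.names = FALSE)
  if (!is.null(report$icc))
    utils::write.csv(report$icc, file.path(dir, "icc_by_roi.csv"),
                     row.names = FALSE)
  if (!is.null(report$tests))
    utils::write.csv(report$tests, file.path(dir, "pairwise_tests.csv"),
                     row.names = FALSE)
  utils::write.csv(report$mean_sd, file.path(dir, "mean_sd_by_roi.csv"),
                   row.names = FALSE)
  invisible(dir)
}
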