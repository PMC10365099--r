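#' Multi-site, multi-session, multi-run study design
#'
#' Enumerates one scan record per subject x site x session x run cell.
#' Defaults emulate a 20-subject, 2-site, 2-session, 2-run design (160
#' scans, eight per subject).
#'
#' @param n_subjects,n_sites,n_sessions,n_runs design counts (all >= 1)
#' @return data frame with columns `scan_id`, `subject`, `site`,
#'   `session`, `run`
#' @export
make_design <- function(n_subjects = 20, n_sites = 2, n_sessions = 2,
                        n_runs = 2) {
  counts <- c(n_subjects, n_sites, n_sessions, n_runs)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all design counts must be positive integers")
  g <- expand.grid(run = seq_len(n_runs), session = seq_len(n_sessions),
                   site = seq_len(n_sites), subject = seq_len(n_subjects))
  g <- g[, c("subject", "site", "session", "run")]
  g$scan_id <- sprintf("sub%02d_site%d_ses%d_run%d", g$subject, g$site,
                       g$session, g$run)
  rownames(g) <- NULL
  g[, c("scan_id", "subject", "site", "session", "run")]
}

#' Variance components and noise settings of the synthetic study
#'
#' Additive random-effect standard deviations (in ms of regional T2IE) for
#' the subject, site-within-subject, session-within-site and run effects,
#' plus the first-echo SNR of the Rician noise and the smooth refocusing
#' flip-angle field (mean, spatial SD, smoothness).
#'
#' @param sd_subject,sd_site,sd_session,sd_run effect SDs in ms (>= 0)
#' @param snr_first_echo first-echo signal-to-noise ratio (`Inf` = no noise)
#' @param fa_mean,fa_sd,fa_fwhm_mm flip-angle field: mean (deg), spatial SD
#'   (deg) and smoothness (FWHM in mm)
#' @return object of class `"variance_components"`
#' @export
variance_components <- function(sd_subject = 1.0, sd_site = 0.35,
                                sd_session = 0.35, sd_run = 0.15,
                                snr_first_echo = 100, fa_mean = 165,
                                fa_sd = 5, fa_fwhm_mm = 12) {
  sds <- c(sd_subject, sd_site, sd_session, sd_run)
  if (any(sds < 0)) stop("effect SDs must be non-negative")
  if (snr_first_echo <= 0) stop("snr_first_echo must be positive")
  structure(list(sd_subject = sd_subject, sd_site = sd_site,
                 sd_session = sd_session, sd_run = sd_run,
                 snr_first_echo = snr_first_echo, fa_mean = fa_mean,
                 fa_sd = fa_sd, fa_fwhm_mm = fa_fwhm_mm),
            class = "variance_components")
}

#' Geometry and tissue parameters of the block phantom
#'
#' The phantom is a row of cubic labeled regions, each with a baseline
#' intra/extra-cellular T2 and a myelin water fraction. Baselines sit in
#' the range typical of brain tissue at 3T (~60-80 ms) with myelin
#' fractions spanning white-matter-like to gray-matter-like values.
#'
#' @param region_dim edge length of each cubic region in voxels
#' @param mu_t2ie per-region baseline T2IE in ms (inside (40, 200))
#' @param myelin_fraction per-region myelin water fraction
#' @param voxel_mm isotropic voxel size in mm
#' @return object of class `"phantom_spec"`
#' @export
phantom_spec <- function(region_dim = 8, mu_t2ie = c(71, 76, 68),
                         myelin_fraction = c(0.15, 0.10, 0.06),
                         voxel_mm = 1.6) {
  if (length(mu_t2ie) != length(myelin_fraction))
    stop("mu_t2ie and myelin_fraction lengths differ")
  if (any(mu_t2ie <= 40 | mu_t2ie >= 200))
    stop("baseline T2IE must lie inside (40, 200) ms")
  structure(list(region_dim = as.integer(region_dim), mu_t2ie = mu_t2ie,
                 myelin_fraction = myelin_fraction,
                 n_regions = length(mu_t2ie), voxel_mm = voxel_mm),
            class = "phantom_spec")
}

#' Label volume of the block phantom
#'
#' @param phantom a [phantom_spec()]
#' @return 3D integer array of region labels (regions stacked along x)
#' @export
phantom_labels <- function(phantom) {
  rd <- phantom$region_dim
  lab <- array(0L, c(rd * phantom$n_regions, rd, rd))
  for (r in seq_len(phantom$n_regions))
    lab[(r - 1) * rd + seq_len(rd), , ] <- r
  lab
}

#' Ground-truth regional T2IE per scan
#'
#' Realizes the additive random-effects hierarchy: for every scan and
#' region, `truth = mu_r + a[subject] + b[subject, site] +
#' c[subject, site, session] + d[scan]`, each effect drawn once per index
#' tuple from a zero-mean normal with the corresponding SD. Reproducible
#' given `seed`.
#'
#' @param design a [make_design()] table
#' @param vc a [variance_components()]
#' @param phantom a [phantom_spec()]
#' @param seed RNG seed
#' @return data frame: design columns plus `region` and `true_t2ie`
#' @export
sample_scan_truth <- function(design, vc, phantom, seed = 1) {
  set.seed(seed)
  subj_key <- unique(design$subject)
  site_key <- unique(design[, c("subject", "site")])
  sess_key <- unique(design[, c("subject", "site", "session")])
  a <- stats::setNames(stats::rnorm(length(subj_key), 0, vc$sd_subject),
                       subj_key)
  b <- stats::setNames(stats::rnorm(nrow(site_key), 0, vc$sd_site),
                       paste(site_key$subject, site_key$site))
  cc <- stats::setNames(stats::rnorm(nrow(sess_key), 0, vc$sd_session),
                        paste(sess_key$subject, sess_key$site,
                              sess_key$session))
  d <- stats::rnorm(nrow(design), 0, vc$sd_run)
  eff <- a[as.character(design$subject)] +
    b[paste(design$subject, design$site)] +
    cc[paste(design$subject, design$site, design$session)] + d
  out <- design[rep(seq_len(nrow(design)), each = phantom$n_regions), ]
  out$region <- rep(seq_len(phantom$n_regions), nrow(design))
  out$true_t2ie <- rep(phantom$mu_t2ie, nrow(design)) +
    rep(eff, each = phantom$n_regions)
  rownames(out) <- NULL
  out
}

#' Two-lobe ground-truth spectrum with an exact windowed geometric mean
#'
#' Builds a spectrum with a myelin lobe (lognormal in T2, centered below
#' the myelin bound, carrying `myelin_fraction` of the mass) and an
#' intra/extra-cellular lobe whose center is iteratively adjusted so the
#' windowed weighted geometric mean of the *whole* spectrum equals
#' `target_t2ie`.
#'
#' @param target_t2ie desired T2IE in ms, inside the window
#' @param myelin_fraction mass fraction of the myelin lobe
#' @param grid T2 grid
#' @param myelin_center,myelin_width myelin lobe center (ms) / log-width
#' @param ie_width intra/extra-cellular lobe log-width
#' @param windows a [compartment_windows()]
#' @return unit-sum weight vector on `grid`
#' @export
region_spectrum <- function(target_t2ie, myelin_fraction, grid,
                            myelin_center = 22, myelin_width = 0.15,
                            ie_width = 0.12,
                            windows = compartment_windows()) {
  if (target_t2ie <= windows$myelin_upper ||
      target_t2ie >= windows$free_water_lower) {
    warning("target T2IE outside the window; clipping")
    target_t2ie <- min(max(target_t2ie, windows$myelin_upper + 1),
                       windows$free_water_lower - 1)
  }
  lg <- log(grid)
  ml <- stats::dnorm(lg, log(myelin_center), myelin_width)
  ml <- myelin_fraction * ml / sum(ml)
  ctr <- log(target_t2ie)
  w <- NULL
  for (it in 1:8) {
    ie <- stats::dnorm(lg, ctr, ie_width)
    ie <- (1 - myelin_fraction) * ie / sum(ie)
    w <- ml + ie
    cur <- t2ie(w, grid, windows)
    if (abs(log(target_t2ie) - log(cur)) < 1e-10) break
    ctr <- ctr + (log(target_t2ie) - log(cur))
  }
  w / sum(w)
}

# smooth random flip-angle field over the phantom, clipped to [90, 180]
fa_field <- function(dims, vc, voxel_mm, seed) {
  set.seed(seed)
  f <- array(stats::rnorm(prod(dims)), dims)
  f <- gaussian_smooth_3d(f, vc$fa_fwhm_mm, voxel_mm)
  s <- stats::sd(f)
  if (s > 0 && vc$fa_sd > 0) f <- f / s * vc$fa_sd else f <- f * 0
  pmin(pmax(vc$fa_mean + f, 90), 180)
}

#' Synthesize one multi-echo scan of the phantom
#'
#' Per voxel the ground-truth spectrum is the two-lobe construction of
#' [region_spectrum()] for the voxel's region (using the scan's true
#' regional T2IE), the noiseless signal is the EPG dictionary at the
#' voxel's flip angle (smooth random field) applied to the spectrum, and
#' Rician magnitude noise is added at the configured first-echo SNR
#' (sigma = scan-mean true first echo / SNR).
#'
#' @param truth_rows rows of [sample_scan_truth()] for one scan
#' @param phantom a [phantom_spec()]
#' @param vc a [variance_components()]
#' @param bank an [fa_bank()]
#' @param seed RNG seed for the flip-angle field and the noise
#' @return list with `img` (4D array), `labels`, `fa_field`, `sigma`
#' @export
synthesize_scan <- function(truth_rows, phantom, vc, bank, seed = 1) {
  labels <- phantom_labels(phantom)
  dims <- dim(labels)
  ne <- bank$protocol$n_echoes
  fa <- fa_field(dims, vc, phantom$voxel_mm, seed)
  spectra <- lapply(seq_len(phantom$n_regions), function(r) {
    region_spectrum(truth_rows$true_t2ie[truth_rows$region == r],
                    phantom$myelin_fraction[r], bank$grid)
  })
  img <- array(0, c(dims, ne))
  flat <- matrix(0, prod(dims), ne)
  keys <- array(vapply(fa, function(f) bank_key(bank, f), numeric(1)), dims)
  for (k in unique(as.vector(keys))) {
    A <- bank_matrix(bank, k)
    for (r in seq_len(phantom$n_regions)) {
      vox <- which(keys == k & labels == r)
      if (length(vox))
        flat[vox, ] <- matrix(rep(drop(A %*% spectra[[r]]),
                                  each = length(vox)), length(vox))
    }
  }
  sigma <- 0
  if (is.finite(vc$snr_first_echo)) {
    sigma <- mean(flat[labels > 0, 1]) / vc$snr_first_echo
    set.seed(child_seed(seed, 2))
    flat <- add_rician_noise(flat, sigma)
  }
  img <- array(flat, c(dims, ne))
  list(img = img, labels = labels, fa_field = fa, sigma = sigma)
}

#' Generate a full synthetic study
#'
#' Draws the ground-truth table, synthesizes every scan, and (optionally)
#' writes per-scan 4D and label NIfTI images plus design and ground-truth
#' CSV files to `out_dir`. Scans are seeded individually from `seed`, so
#' the ground truth and images are reproducible.
#'
#' @param design a [make_design()] table
#' @param vc a [variance_components()]
#' @param phantom a [phantom_spec()]
#' @param bank an [fa_bank()]
#' @param seed RNG seed
#' @param out_dir output directory, or `NULL` to keep scans in memory only
#' @return object of class `"t2_study"`: list with `design` (with `path`
#'   column when written), `truth`, `scans` (list of [synthesize_scan()]
#'   outputs), `labels`, `phantom`, `vc`, `protocol`
#' @export
generate_study <- function(design, vc, phantom, bank, seed = 1,
                           out_dir = NULL) {
  truth <- sample_scan_truth(design, vc, phantom, seed)
  scans <- vector("list", nrow(design))
  names(scans) <- design$scan_id
  for (i in seq_len(nrow(design))) {
    rows <- truth[truth$scan_id == design$scan_id[i], ]
    scans[[i]] <- synthesize_scan(rows, phantom, vc, bank,
                                  seed = child_seed(seed, 1000 + i))
  }
  labels <- phantom_labels(phantom)
  design_out <- design
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    vox <- phantom$voxel_mm
    paths <- character(nrow(design))
    for (i in seq_len(nrow(design))) {
      paths[i] <- file.path(out_dir, paste0(design$scan_id[i], ".nii"))
      nif <- RNifti::asNifti(scans[[i]]$img)
      RNifti::pixdim(nif) <- c(vox, vox, vox, 1)
      RNifti::writeNifti(nif, paths[i])
    }
    nif <- RNifti::asNifti(labels + 0)
    RNifti::pixdim(nif) <- c(vox, vox, vox)
    RNifti::writeNifti(nif, file.path(out_dir, "labels.nii"))
    design_out$path <- paths
    utils::write.csv(design_out, file.path(out_dir, "design.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  structure(list(design = design_out, truth = truth, scans = scans,
                 labels = labels, phantom = phantom, vc = vc,
                 protocol = bank$protocol),
            class = "t2_study")
}

#' @export
print.t2_study <- function(x, ...) {
  cat(sprintf("Synthetic T2 study: %d scans (%d subjects), %d regions, SNR %s\n",
              nrow(x$design), length(unique(x$design$subject)),
              x$phantom$n_regions, format(x$vc$snr_first_echo)))
  invisible(x)
}
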