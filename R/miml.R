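#' First Wasserstein distance between distributions on an ordered grid
#'
#' For two probability vectors on a common ordered 1D support, the
#' 1-Wasserstein (earth mover's) distance reduces to the area between the
#' CDFs: `sum_k |CDF_p(k) - CDF_q(k)| * (pos[k+1] - pos[k])`. By default
#' positions are bin indices (unit spacing); pass `log(grid)` for the
#' log-T2 ground distance used in training.
#'
#' @param p,q non-negative vectors summing to 1 (within 1e-6), same length
#' @param positions ordered bin positions (defaults to `seq_along(p)`)
#' @return non-negative distance
#' @export
wasserstein_1d <- function(p, q, positions = NULL) {
  if (length(p) != length(q)) stop("p and q must share the same grid")
  if (is.null(positions)) positions <- seq_along(p)
  if (length(positions) != length(p)) stop("positions must match the grid")
  if (any(p < 0) || any(q < 0)) stop("p and q must be non-negative")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("p and q must each sum to 1")
  n <- length(p)
  cd <- cumsum(p - q)[-n]
  sum(abs(cd) * diff(positions))
}

#' MLP architecture for spectrum prediction
#'
#' A multilayer perceptron mapping an `input_length`-echo signal to an
#' `output_units`-bin T2 distribution: rectifier hidden layers, softmax
#' output (non-negative, unit sum).
#'
#' @param n_hidden_layers number of hidden layers
#' @param units_per_layer width of each hidden layer
#' @param output_units output bins (must match the companion T2 grid)
#' @param input_length echo count
#' @return object of class `"mlp_spec"`
#' @export
mlp_spec <- function(n_hidden_layers = 6, units_per_layer = 256,
                     output_units = 60, input_length = 32) {
  stopifnot(n_hidden_layers >= 1, units_per_layer >= 1, output_units >= 2,
            input_length >= 1)
  structure(list(n_hidden_layers = as.integer(n_hidden_layers),
                 units_per_layer = as.integer(units_per_layer),
                 output_units = as.integer(output_units),
                 input_length = as.integer(input_length)),
            class = "mlp_spec")
}

#' Training configuration for the spectrum MLP
#'
#' Hyperparameters of the adaptive-moment (Adam) optimization of the
#' combined loss: per-sample squared L2 distance between predicted and true
#' spectra plus `loss_weights["wasserstein"]` times their 1-Wasserstein
#' distance on the log-T2 axis.
#'
#' @param n_pairs training-corpus size drawn by [generate_training_pairs()]
#' @param learning_rate Adam step size
#' @param batch_size minibatch size
#' @param epochs passes over the corpus
#' @param seed RNG seed controlling initialization and shuffling
#' @param loss_weights named weights of the two loss terms
#' @param snr_range first-echo SNR range of the synthetic corpus
#' @return object of class `"train_config"`
#' @export
train_config <- function(n_pairs = 50000, learning_rate = 5e-4,
                         batch_size = 2000, epochs = 30, seed = 1,
                         loss_weights = c(l2 = 1, wasserstein = 1),
                         snr_range = c(40, 200)) {
  stopifnot(n_pairs >= 1, learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(n_pairs = as.integer(n_pairs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 loss_weights = loss_weights, snr_range = snr_range),
            class = "train_config")
}

#' Synthetic signal/spectrum training pairs
#'
#' Draws random ground-truth spectra (1-3 lognormal-shaped lobes with
#' random centers, log-widths and fractions on the grid), a random
#' refocusing flip angle in \[90, 180\] degrees, synthesizes the EPG signal
#' through the dictionary bank, adds Rician noise at a first-echo SNR drawn
#' uniformly from `snr_range` (`Inf` disables noise), then normalizes the
#' signal to unit first echo and the spectrum to unit sum. Fully
#' reproducible given `seed`.
#'
#' @param n number of pairs
#' @param bank an [fa_bank()] providing protocol, grid and dictionaries
#' @param seed RNG seed
#' @param snr_range first-echo SNR range (use `c(Inf, Inf)` for noiseless)
#' @param lobe_count_range range of lobe counts
#' @param lobe_center_range range of lobe centers in ms (log-uniform draw)
#' @return list with `signals` (`n_echoes x n`), `spectra` (`n_t2 x n`),
#'   `fa`, `snr`, `first_echo` (raw amplitude used for normalization) and
#'   the `grid`
#' @export
generate_training_pairs <- function(n, bank, seed = 1,
                                    snr_range = c(40, 200),
                                    lobe_count_range = c(1L, 3L),
                                    lobe_center_range = c(15, 1000)) {
  stopifnot(n >= 1)
  set.seed(seed)
  grid <- bank$grid
  nt <- length(grid)
  lg <- log(grid)
  W <- matrix(0, nt, n)
  for (i in seq_len(n)) {
    nl <- sample(lobe_count_range[1]:lobe_count_range[2], 1)
    frac <- stats::runif(nl); frac <- frac / sum(frac)
    w <- numeric(nt)
    for (l in seq_len(nl)) {
      ctr <- stats::runif(1, log(lobe_center_range[1]),
                          log(lobe_center_range[2]))
      wid <- stats::runif(1, 0.05, 0.3)
      lobe <- stats::dnorm(lg, ctr, wid)
      w <- w + frac[l] * lobe / sum(lobe)
    }
    W[, i] <- w / sum(w)
  }
  fa <- stats::runif(n, 90, 180)
  snr <- if (any(is.infinite(snr_range))) rep(Inf, n)
         else stats::runif(n, snr_range[1], snr_range[2])
  keys <- vapply(fa, function(f) bank_key(bank, f), numeric(1))
  S <- matrix(0, bank$protocol$n_echoes, n)
  for (k in unique(keys)) {
    sel <- keys == k
    S[, sel] <- bank_matrix(bank, k) %*% W[, sel, drop = FALSE]
  }
  noisy <- !is.infinite(snr)
  if (any(noisy)) {
    sigma <- S[1, ] / snr
    nn <- sum(noisy)
    ne <- nrow(S)
    S[, noisy] <- sqrt(
      (S[, noisy] + matrix(stats::rnorm(ne * nn), ne) *
         rep(sigma[noisy], each = ne))^2 +
      (matrix(stats::rnorm(ne * nn), ne) * rep(sigma[noisy], each = ne))^2)
  }
  first_echo <- S[1, ]
  S <- sweep(S, 2, first_echo, "/") # unit first-echo convention
  list(signals = S, spectra = W, fa = fa, snr = snr,
       first_echo = first_echo, grid = grid)
}

relu <- function(x) (x + abs(x)) / 2

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_init <- function(spec, seed) {
  set.seed(seed)
  sizes <- c(spec$input_length,
             rep(spec$units_per_layer, spec$n_hidden_layers),
             spec$output_units)
  W <- vector("list", length(sizes) - 1)
  b <- vector("list", length(sizes) - 1)
  for (l in seq_along(W)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X) {
  L <- length(par$W)
  H <- vector("list", L + 1)
  H[[1]] <- X
  for (l in seq_len(L - 1))
    H[[l + 1]] <- relu(sweep(H[[l]] %*% par$W[[l]], 2, par$b[[l]], "+"))
  z <- sweep(H[[L]] %*% par$W[[L]], 2, par$b[[L]], "+")
  list(H = H, P = softmax_rows(z))
}

# combined loss and its gradient wrt the softmax output, batched (rows)
miml_loss_grad <- function(P, Q, d, wt) {
  Dm <- P - Q
  l2 <- rowSums(Dm^2)
  Cd <- t(apply(Dm, 1, cumsum))[, -ncol(P), drop = FALSE]
  w1 <- as.vector(abs(Cd) %*% d)
  loss <- mean(wt[1] * l2 + wt[2] * w1)
  gW <- cbind(t(apply(sweep(sign(Cd), 2, d, "*"), 1,
                      function(r) rev(cumsum(rev(r))))), 0)
  g <- (wt[1] * 2 * Dm + wt[2] * gW) / nrow(P)
  list(loss = loss, g = g)
}

#' Train the spectrum MLP on synthetic pairs
#'
#' Minimizes the combined L2 + Wasserstein loss with Adam at the configured
#' hyperparameters. Training aborts with diagnostics if the loss becomes
#' non-finite. Deterministic for a fixed seed and numeric backend.
#'
#' @param pairs output of [generate_training_pairs()]
#' @param spec an [mlp_spec()]
#' @param cfg a [train_config()]
#' @return object of class `"miml_model"` carrying the weights, grid,
#'   normalization convention and per-epoch training loss
#' @export
train_mlp <- function(pairs, spec = mlp_spec(), cfg = train_config()) {
  X <- t(pairs$signals)            # batch rows
  Q <- t(pairs$spectra)
  if (ncol(X) != spec$input_length) stop("signal length != input_length")
  if (ncol(Q) != spec$output_units) stop("spectrum length != output_units")
  n <- nrow(X)
  d <- diff(log(pairs$grid))       # log-T2 ground distance
  wt <- c(cfg$loss_weights[["l2"]], cfg$loss_weights[["wasserstein"]])
  par <- mlp_init(spec, cfg$seed)
  L <- length(par$W)
  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(w) w * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; epsa <- 1e-8
  step <- 0
  loss_hist <- numeric(cfg$epochs)
  set.seed(child_seed(cfg$seed, 1))
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      rows <- ord[start:min(start + cfg$batch_size - 1, n)]
      Xb <- X[rows, , drop = FALSE]; Qb <- Q[rows, , drop = FALSE]
      fw <- mlp_forward(par, Xb)
      lg <- miml_loss_grad(fw$P, Qb, d, wt)
      if (!is.finite(lg$loss))
        stop(sprintf("training diverged at epoch %d (non-finite loss)", ep))
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1
      # softmax backward then backprop through the stack
      gP <- lg$g
      dz <- fw$P * (gP - rowSums(gP * fw$P))
      gW <- vector("list", L); gb <- vector("list", L)
      delta <- dz
      for (l in L:1) {
        gW[[l]] <- crossprod(fw$H[[l]], delta)
        gb[[l]] <- colSums(delta)
        if (l > 1) {
          delta <- delta %*% t(par$W[[l]])
          delta <- delta * (fw$H[[l]] > 0)
        }
      }
      step <- step + 1
      c1 <- 1 - beta1^step; c2 <- 1 - beta2^step
      for (l in seq_len(L)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
        par$W[[l]] <- par$W[[l]] - cfg$learning_rate * (mW[[l]] / c1) /
          (sqrt(vW[[l]] / c2) + epsa)
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
        par$b[[l]] <- par$b[[l]] - cfg$learning_rate * (mb[[l]] / c1) /
          (sqrt(vb[[l]] / c2) + epsa)
      }
    }
    loss_hist[ep] <- ep_loss / nb
  }
  structure(list(W = par$W, b = par$b, spec = spec, cfg = cfg,
                 grid = pairs$grid, normalization = "first_echo",
                 loss = loss_hist),
            class = "miml_model")
}

#' Predict T2 spectra with a trained MLP
#'
#' Signals are normalized with the training convention (unit first echo)
#' before the forward pass, so predictions are invariant to global signal
#' scaling; outputs are unit-sum distributions.
#'
#' @param object a `"miml_model"`
#' @param signals matrix `n_echoes x n_vox` (or a single vector)
#' @param ... unused
#' @return matrix `n_t2 x n_vox` of predicted spectra
#' @export
predict.miml_model <- function(object, signals, ...) {
  if (is.vector(signals)) signals <- matrix(signals, ncol = 1)
  if (nrow(signals) != object$spec$input_length)
    stop("signal length != model input_length")
  s1 <- signals[1, ]
  s1[s1 == 0] <- 1
  X <- t(sweep(signals, 2, s1, "/"))
  t(mlp_forward(list(W = object$W, b = object$b), X)$P)
}

#' Spectrum map prediction for a masked volume
#'
#' @param model a `"miml_model"`
#' @param img4d 4D multi-echo array
#' @param mask 3D mask
#' @return a `"t2spectrum_map"` (unit-sum spectra); all-zero voxels skipped
#' @export
predict_spectrum_map <- function(model, img4d, mask) {
  d <- dim(img4d)
  if (d[4] != model$spec$input_length)
    stop("echo count != model input_length")
  mask <- array(as.logical(mask), d[1:3])
  idx <- which(mask)
  Y <- t(matrix(img4d, prod(d[1:3]), d[4])[idx, , drop = FALSE])
  ok <- colSums(Y != 0) > 0
  W <- predict(model, Y[, ok, drop = FALSE])
  structure(list(weights = W, vox_idx = idx[ok], dims = d[1:3],
                 grid = model$grid, lambda = rep(NA_real_, sum(ok)),
                 method = "miml", skipped = idx[!ok]),
            class = "t2spectrum_map")
}

#' @export
print.miml_model <- function(x, ...) {
  cat(sprintf(
    "Spectrum MLP: %d -> %s -> %d (softmax), trained %d epochs, loss %.4g\n",
    x$spec$input_length,
    paste(rep(x$spec$units_per_layer, x$spec$n_hidden_layers),
          collapse = "-"),
    x$spec$output_units, x$cfg$epochs, utils::tail(x$loss, 1)))
  invisible(x)
}
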