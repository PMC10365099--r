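# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the isochromat simulator integrates Bloch
# rotations over a dephasing ensemble, the NNLS oracle enumerates active
# sets, the transport oracle moves sorted mass greedily.

# Bloch-rotation isochromat ensemble for a CPMG train: 90y excitation,
# refocusing about x, dephasing uniform over the unit circle per half
# interval. Equals EPG exactly for n_iso > max configuration order.
isochromat_cpmg <- function(t2, t1, fa, protocol, n_iso = 10000) {
  ph <- 2 * pi * (seq_len(n_iso) - 0.5) / n_iso
  E2 <- exp(-protocol$delta_te / 2 / t2)
  E1 <- exp(-protocol$delta_te / 2 / t1)
  a <- fa * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  M <- rbind(rep(1, n_iso), rep(0, n_iso), rep(0, n_iso)) # after 90y: +x
  half <- function(M) {
    mx <- M[1, ] * cos(ph) - M[2, ] * sin(ph)
    my <- M[1, ] * sin(ph) + M[2, ] * cos(ph)
    rbind(mx * E2, my * E2, M[3, ] * E1)
  }
  out <- numeric(protocol$n_echoes)
  for (e in seq_len(protocol$n_echoes)) {
    M <- half(M)
    M <- Rx %*% M
    M <- half(M)
    out[e] <- Mod(mean(complex(real = M[1, ], imaginary = M[2, ])))
  }
  out
}

# Exhaustive active-set NNLS oracle: for every subset of columns solve the
# unconstrained least squares on that subset, keep feasible candidates
# (x >= 0), return the best objective. Exponential; tiny problems only.
nnls_exhaustive <- function(A, y) {
  n <- ncol(A)
  best <- sum(y^2) # empty set
  xbest <- rep(0, n)
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    z <- tryCatch(qr.solve(A[, idx, drop = FALSE], y),
                  error = function(e) NULL)
    if (is.null(z) || any(z < 0)) next
    obj <- sum((A[, idx, drop = FALSE] %*% z - y)^2)
    if (obj < best) {
      best <- obj
      xbest <- rep(0, n)
      xbest[idx] <- z
    }
  }
  list(objective = best, x = xbest)
}

# Projected-gradient solver for min ||Ax-y||^2 + lam^2 ||x||^2, x >= 0.
projgrad_reg_nnls <- function(A, y, lam, iters = 200000) {
  G <- crossprod(A) + lam^2 * diag(ncol(A))
  b <- crossprod(A, y)
  step <- 1 / (2 * norm(G, "2"))
  x <- rep(0, ncol(A))
  for (i in seq_len(iters)) {
    xn <- pmax(0, x - step * 2 * (G %*% x - b))
    if (max(abs(xn - x)) < 1e-12) { x <- xn; break }
    x <- xn
  }
  drop(x)
}

# Greedy sorted-mass transport: exact 1-Wasserstein on an ordered support.
wasserstein_greedy <- function(p, q, positions) {
  i <- 1; j <- 1
  p <- p; q <- q
  cost <- 0
  while (i <= length(p) && j <= length(q)) {
    m <- min(p[i], q[j])
    cost <- cost + m * abs(positions[i] - positions[j])
    p[i] <- p[i] - m
    q[j] <- q[j] - m
    if (p[i] <= 1e-15) i <- i + 1
    if (q[j] <= 1e-15) j <- j + 1
  }
  cost
}

# two-way ANOVA mean squares via stats::aov (independent ICC route)
icc_aov_oracle <- function(m) {
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(nrow(m)), ncol(m))),
                  meas = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(y ~ subj + meas, data = d))[[1]]
  msr <- tab["subj", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse)
}

# exact two-sided rank-sum p-value by complete enumeration (no ties)
ranksum_exact_p <- function(x, y) {
  n <- length(x); m <- length(y)
  all <- c(x, y)
  combs <- utils::combn(n + m, n)
  W_obs <- sum(rank(all)[seq_len(n)]) - n * (n + 1) / 2
  Ws <- apply(combs, 2, function(idx)
    sum(rank(all)[idx]) - n * (n + 1) / 2)
  mean(Ws <= min(W_obs, n * m - W_obs) | Ws >= max(W_obs, n * m - W_obs))
}

# narrow single-lobe spectrum centered at `t2c`, unit sum
lobe_spectrum <- function(grid, t2c, width = 0.1) {
  w <- stats::dnorm(log(grid), log(t2c), width)
  w / sum(w)
}

default_protocol <- t2_protocol()
default_grid <- t2_grid()

# one shared bank per test run; dictionaries accumulate in its cache
shared_bank <- fa_bank(default_protocol)
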