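# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Best rigid superposition found by random quaternion search + Nelder-Mead
# polish; returns the minimized RMSD. Independent of the SVD-based solver.
oracle_best_rmsd <- function(mobile, ref, n_random = 2000) {
  q_to_R <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  ca <- colMeans(mobile); cb <- colMeans(ref)
  a <- sweep(mobile, 2, ca); b <- sweep(ref, 2, cb)
  obj <- function(q) {
    r <- q_to_R(q)
    sqrt(mean(rowSums((a %*% t(r) - b)^2)))
  }
  qs <- matrix(rnorm(4 * n_random), ncol = 4)
  vals <- apply(qs, 1, obj)
  best <- qs[which.min(vals), ]
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  opt2 <- optim(opt$par, obj, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-14))
  opt2$value
}

# Fully iterated align-and-average structure (10 iterations), written
# directly against the public kabsch/transform primitives frame by frame.
oracle_iterated_average <- function(traj, frames, selection, n_iter = 10) {
  ref <- frame_coords(traj, frames[1])
  for (it in seq_len(n_iter)) {
    acc <- 0
    for (f in frames) {
      m <- frame_coords(traj, f)
      fit <- kabsch_fit(m[selection, , drop = FALSE],
                        ref[selection, , drop = FALSE])
      acc <- acc + apply_transform(fit, m)
    }
    ref <- acc / length(frames)
  }
  ref
}

# Closed-form expectation for the windowed RMSF of isotropic Gaussian
# fluctuations of amplitude sigma with n frames per window (no alignment
# losses): sqrt(3) * sigma * sqrt((n - 1) / n).
expected_windowed_rmsf <- function(sigma, n_frames_per_window) {
  sqrt(3) * sigma * sqrt((n_frames_per_window - 1) / n_frames_per_window)
}

# Monte-Carlo estimate of the same quantity from raw normal draws.
mc_windowed_rmsf <- function(sigma, n_frames_per_window, n_windows = 400) {
  vals <- replicate(n_windows, {
    m <- matrix(rnorm(n_frames_per_window * 3, sd = sigma), ncol = 3)
    d <- sweep(m, 2, colMeans(m))
    sqrt(mean(rowSums(d^2)))
  })
  mean(vals)
}

# A standard alpha-carbon-only helix reference with channel-like Phe
# side-chain anchors, reused by several suites.
fixture_reference <- function(n_residues = 50, seed = 1) {
  sc <- c("10" = "CZ", "20" = "CD1", "30" = "CB", "40" = "CZ")
  sc <- sc[as.integer(names(sc)) <= n_residues]
  synth_reference(n_residues, seed = seed,
                  sidechain_atoms = if (length(sc)) sc else NULL)
}
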