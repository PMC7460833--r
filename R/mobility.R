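# Windowed per-residue C-alpha RMSF and differential mobility calling.
#
# The fluctuation statistic is computed in fixed-duration time windows: each
# window gets its own average structure (iterated align-and-average), every
# frame is superposed onto that average on the C-alpha selection, and the
# per-residue RMSF of the window is the root-mean-square scatter of the
# aligned C-alpha about its window-mean position. The profile is the
# unweighted mean over windows. Windowing suppresses slow drift: motion on
# timescales much longer than the window contributes little to the
# within-window scatter.

#' Time span covering the last `ns` nanoseconds of a trajectory
#'
#' @param traj an `md_traj`.
#' @param ns duration in nanoseconds.
#' @return numeric `c(t_start_ps, t_end_ps)`, half-open on the right.
#' @export
span_last_ns <- function(traj, ns) {
  stopifnot(inherits(traj, "md_traj"))
  tmax <- traj$times[nframes(traj)]
  dt <- if (nframes(traj) > 1) stats::median(diff(traj$times)) else 0
  end <- tmax + dt
  start <- end - ns * 1000
  if (start < traj$times[1] - 1e-9)
    stop("requested span (", ns, " ns) longer than trajectory")
  c(start, end)
}

#' Partition trajectory frames into consecutive time windows
#'
#' Windows are half-open `[t0 + (k-1)*W, t0 + k*W)` by frame time; a trailing
#' partial window is dropped. Every window must contain at least 2 frames
#' (RMSF is undefined otherwise).
#'
#' @param traj an `md_traj`.
#' @param span `c(t_start_ps, t_end_ps)`; NULL means the full trajectory.
#' @param window_ps window duration in ps.
#' @return list of integer frame-index vectors.
#' @export
window_partition <- function(traj, span = NULL, window_ps) {
  stopifnot(inherits(traj, "md_traj"))
  if (window_ps <= 0) stop("window_ps must be positive")
  tm <- traj$times
  dt <- if (length(tm) > 1) stats::median(diff(tm)) else 0
  if (is.null(span)) span <- c(tm[1], tm[length(tm)] + dt)
  if (length(span) != 2 || span[2] <= span[1]) stop("invalid span")
  if (span[1] < tm[1] - 1e-9 || span[2] > tm[length(tm)] + dt + 1e-9)
    stop("span [", span[1], ", ", span[2], ") ps exceeds trajectory times")
  n_win <- floor((span[2] - span[1]) / window_ps + 1e-9)
  if (n_win < 1) stop("span shorter than one window")
  windows <- vector("list", n_win)
  for (k in seq_len(n_win)) {
    lo <- span[1] + (k - 1) * window_ps
    hi <- lo + window_ps
    windows[[k]] <- which(tm >= lo - 1e-9 & tm < hi - 1e-9)
  }
  nfr <- lengths(windows)
  if (any(nfr < 2))
    stop("window(s) ", paste(utils::head(which(nfr < 2), 5), collapse = ", "),
         " contain fewer than 2 frames (RMSF undefined); ",
         "use a longer window_ps or a denser trajectory")
  windows
}

#' Average structure of a set of frames
#'
#' Two-pass procedure: align every frame to the window's first frame on the
#' selection and average, then re-align the original frames to that mean and
#' average once more. For well-equilibrated windows this is within numerical
#' noise of fully iterated align-and-average.
#'
#' @param traj an `md_traj`.
#' @param frames integer frame indices (>= 2).
#' @param selection atom indices used for the superposition (default: all
#'   C-alpha atoms).
#' @return N x 3 matrix of average coordinates (all atoms).
#' @export
window_average_structure <- function(traj, frames, selection = NULL) {
  stopifnot(inherits(traj, "md_traj"))
  if (length(frames) < 2) stop("need at least 2 frames to average")
  if (is.null(selection)) selection <- select_atoms(traj$topology)
  ref <- frame_coords(traj, frames[1])
  avg <- .align_mean(traj, frames, ref, selection)
  .align_mean(traj, frames, avg, selection)
}

.align_mean <- function(traj, frames, ref, selection) {
  acc <- 0
  for (f in frames) {
    m <- frame_coords(traj, f)
    fit <- kabsch_fit(m[selection, , drop = FALSE],
                      ref[selection, , drop = FALSE])
    acc <- acc + apply_transform(fit, m)
  }
  acc / length(frames)
}

#' Windowed per-residue RMSF profile
#'
#' @param traj an `md_traj`.
#' @param selection atom indices, one atom per residue (C-alpha); default all
#'   C-alpha atoms.
#' @param span `c(t_start_ps, t_end_ps)` or NULL for the full trajectory; see
#'   [span_last_ns()] for the usual "last 40 ns" span.
#' @param window_ps window duration in ps (default 100).
#' @return an `rmsf_profile`: list with `residue_ids`, `rmsf` (Angstrom, mean
#'   over windows), `n_windows`, `window_ps`, `span`.
#' @export
windowed_rmsf <- function(traj, selection = NULL, span = NULL,
                          window_ps = 100) {
  stopifnot(inherits(traj, "md_traj"))
  if (is.null(selection)) selection <- select_atoms(traj$topology)
  res_ids <- attr(selection, "residue_ids")
  if (is.null(res_ids)) res_ids <- traj$topology$atom$resno[selection]
  if (anyDuplicated(res_ids))
    stop("selection must contain one atom per residue")
  windows <- window_partition(traj, span, window_ps)
  acc <- numeric(length(selection))
  for (w in windows) {
    avg <- window_average_structure(traj, w, selection)
    avg_sel <- avg[selection, , drop = FALSE]
    aligned <- array(NA_real_, dim = c(length(w), length(selection), 3))
    for (j in seq_along(w)) {
      m <- frame_coords(traj, w[j])[selection, , drop = FALSE]
      fit <- kabsch_fit(m, avg_sel)
      aligned[j, , ] <- apply_transform(fit, m)
    }
    mu <- apply(aligned, c(2, 3), mean)
    dev2 <- sweep(aligned, c(2, 3), mu)^2
    acc <- acc + sqrt(apply(dev2, 2, mean) * 3)  # mean over frames of |d|^2
  }
  if (is.null(span)) {
    dt <- if (nframes(traj) > 1) stats::median(diff(traj$times)) else 0
    span <- c(traj$times[1], traj$times[nframes(traj)] + dt)
  }
  structure(list(residue_ids = res_ids, rmsf = acc / length(windows),
                 n_windows = length(windows), window_ps = window_ps,
                 span = span),
            class = "rmsf_profile")
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat(sprintf(
    "rmsf_profile: %d residues, %d windows of %g ps over [%g, %g) ps\n",
    length(x$residue_ids), x$n_windows, x$window_ps, x$span[1], x$span[2]))
  cat(sprintf("  RMSF (A): min %.3f / median %.3f / max %.3f\n",
              min(x$rmsf), stats::median(x$rmsf), max(x$rmsf)))
  invisible(x)
}

#' @export
as.data.frame.rmsf_profile <- function(x, ...) {
  data.frame(residue_id = x$residue_ids, rmsf_A = x$rmsf)
}

#' @export
plot.rmsf_profile <- function(x, ...) {
  graphics::plot(x$residue_ids, x$rmsf, type = "h", xlab = "residue",
                 ylab = "RMSF (A)", ...)
  invisible(x)
}

#' Differential mobility calls between a variant and a reference profile
#'
#' Per residue, `delta = variant - reference` RMSF. A residue is called
#' `increased` when `delta > mean(delta) + k * sd(delta)` and `decreased`
#' when `delta < mean(delta) - k * sd(delta)` (population SD over all
#' residues), else `unchanged`. With `k = 1` this is the one-standard-
#' deviation rule; under a pure-noise null it flags about 32% of residues
#' (2 * (1 - pnorm(1))).
#'
#' @param profile_variant,profile_ref `rmsf_profile` objects over the same
#'   residue set.
#' @param threshold_k multiple of the SD used as threshold (default 1).
#' @return a `mobility_calls` data frame with columns `residue_id`,
#'   `delta_A`, `label`, and attributes `mean_delta`, `sd_delta`,
#'   `threshold_k`.
#' @export
differential_mobility <- function(profile_variant, profile_ref,
                                  threshold_k = 1) {
  stopifnot(inherits(profile_variant, "rmsf_profile"),
            inherits(profile_ref, "rmsf_profile"))
  a <- profile_variant$residue_ids; b <- profile_ref$residue_ids
  if (length(a) != length(b) || any(a != b)) {
    diffres <- union(setdiff(a, b), setdiff(b, a))
    stop("profiles cover different residues; symmetric difference: ",
         paste(diffres, collapse = ", "))
  }
  delta <- profile_variant$rmsf - profile_ref$rmsf
  mu <- mean(delta)
  sdp <- sqrt(mean((delta - mu)^2))  # population SD, fixed for determinism
  lab <- rep("unchanged", length(delta))
  if (sdp > 0) {
    lab[delta > mu + threshold_k * sdp] <- "increased"
    lab[delta < mu - threshold_k * sdp] <- "decreased"
  }
  out <- data.frame(residue_id = a, delta_A = delta,
                    label = factor(lab, levels = c("decreased", "unchanged",
                                                   "increased")))
  structure(out, mean_delta = mu, sd_delta = sdp, threshold_k = threshold_k,
            class = c("mobility_calls", "data.frame"))
}

#' Residues flagged by a set of mobility calls
#' @param calls a `mobility_calls` object.
#' @return data frame restricted to increased/decreased residues.
#' @export
flagged_residues <- function(calls) {
  stopifnot(inherits(calls, "mobility_calls"))
  as.data.frame(calls)[calls$label != "unchanged", , drop = FALSE]
}

#' @export
print.mobility_calls <- function(x, ...) {
  up <- x$residue_id[x$label == "increased"]
  dn <- x$residue_id[x$label == "decreased"]
  cat(sprintf(
    "mobility_calls: %d residues; threshold |delta - %.4f| > %g x %.4f A\n",
    nrow(x), attr(x, "mean_delta"), attr(x, "threshold_k"),
    attr(x, "sd_delta")))
  cat("  increased:", if (length(up)) paste(up, collapse = ", ") else "none",
      "\n  decreased:", if (length(dn)) paste(dn, collapse = ", ") else "none",
      "\n")
  invisible(x)
}
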