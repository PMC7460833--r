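# Residue-pair distance time series and frequency distributions.
# Distances are invariant under rigid motion, so no superposition is needed.

#' Distance between two residues' atoms along a trajectory
#'
#' @param traj an `md_traj`.
#' @param id_a,id_b residue ids.
#' @param atom_name atom measured in both residues (default "CA").
#' @param span optional `c(t_start_ps, t_end_ps)` restricting the frames
#'   (half-open on the right); see [span_last_ns()].
#' @return a `distance_series`: data frame with `frame`, `time_ps`,
#'   `distance_A`, with attributes `residue_pair` and `atom_name`.
#' @export
pair_distance_series <- function(traj, id_a, id_b, atom_name = "CA",
                                 span = NULL) {
  stopifnot(inherits(traj, "md_traj"))
  ia <- select_atoms(traj$topology, id_a, atom_name)
  ib <- select_atoms(traj$topology, id_b, atom_name)
  frames <- seq_len(nframes(traj))
  if (!is.null(span)) {
    if (length(span) != 2 || span[2] <= span[1]) stop("invalid span")
    frames <- which(traj$times >= span[1] - 1e-9 &
                    traj$times < span[2] - 1e-9)
    if (!length(frames)) stop("span contains no frames")
  }
  d <- vapply(frames, function(f) {
    m <- frame_coords(traj, f)
    sqrt(sum((m[ia, ] - m[ib, ])^2))
  }, numeric(1))
  structure(data.frame(frame = frames, time_ps = traj$times[frames],
                       distance_A = d),
            residue_pair = c(id_a, id_b), atom_name = atom_name,
            class = c("distance_series", "data.frame"))
}

#' @export
print.distance_series <- function(x, ...) {
  rp <- attr(x, "residue_pair")
  cat(sprintf(
    "distance_series %d-%d (%s): %d frames, %.2f +/- %.2f A\n",
    rp[1], rp[2], attr(x, "atom_name"), nrow(x), mean(x$distance_A),
    stats::sd(x$distance_A)))
  invisible(x)
}

#' Frequency distribution of a distance series
#'
#' Bins are half-open `[lo, hi)` except the final bin, which is closed so
#' the maximum is counted; frequencies sum to the number of frames.
#'
#' @param series a `distance_series` (or bare numeric vector of distances).
#' @param bin_width bin width in Angstrom (default 0.25).
#' @return data frame with `bin_lo`, `bin_hi`, `count`.
#' @export
distance_histogram <- function(series, bin_width = 0.25) {
  v <- if (is.data.frame(series)) series$distance_A else as.numeric(series)
  if (!length(v)) stop("empty distance series")
  if (bin_width <= 0) stop("bin_width must be positive")
  lo <- floor(min(v) / bin_width) * bin_width
  hi <- ceiling(max(v) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < hi) edges <- c(edges, hi)
  cnt <- tabulate(pmin(findInterval(v, edges), length(edges) - 1),
                  nbins = length(edges) - 1)
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             count = cnt)
}
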