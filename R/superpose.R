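# Rigid-body least-squares superposition (Kabsch) and RMSD.
#
# Convention: a rigid_transform maps mobile coordinates onto the reference
# frame as  x' = x %*% t(R) + tr .  The reflection branch of the SVD solution
# is corrected via the sign of det so only proper rotations are returned.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the (optionally
#' weighted) sum of squared deviations between `mobile` and `ref`.
#'
#' @param mobile n x 3 coordinate matrix to be moved.
#' @param ref n x 3 reference coordinates.
#' @param weights optional non-negative per-point weights (default uniform).
#' @return an object of class `rigid_transform`: list with `rotation`
#'   (3 x 3, det +1) and `translation` (length 3, Angstrom).
#' @export
kabsch_fit <- function(mobile, ref, weights = NULL) {
  mobile <- as.matrix(mobile); ref <- as.matrix(ref)
  if (ncol(mobile) != 3 || ncol(ref) != 3 || nrow(mobile) != nrow(ref))
    stop("mobile and ref must be n x 3 matrices with equal n")
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs at least 3 points, got ", n)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative with positive sum")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(ref * w)
  a <- sweep(mobile, 2, cm); b <- sweep(ref, 2, cr)
  # degenerate (collinear / coincident) configurations have rank < 2
  if (sum(svd(a)$d > 1e-8 * max(1, max(abs(a)))) < 2)
    stop("degenerate (collinear) point configuration: rotation ill-defined")
  h <- crossprod(a * w, b)           # 3x3 cross-covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cr - as.vector(r %*% cm)
  structure(list(rotation = r, translation = as.numeric(tr)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a `rigid_transform`.
#' @param coords n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, coords) {
  stopifnot(inherits(transform, "rigid_transform"))
  sweep(as.matrix(coords) %*% t(transform$rotation), 2,
        transform$translation, `+`)
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("rigid_transform: rotation %.2f deg, translation (%.3f, %.3f, %.3f) A\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Root-mean-square deviation between two coordinate sets
#'
#' No superposition is performed; align first with [kabsch_fit()] /
#' [apply_transform()] if needed.
#'
#' @param coords_a,coords_b n x 3 matrices.
#' @param selection optional atom indices to restrict the comparison.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(coords_a, coords_b, selection = NULL) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b)))
    stop("coordinate sets differ in size: ", nrow(coords_a), " vs ",
         nrow(coords_b), " points")
  if (!is.null(selection)) {
    coords_a <- coords_a[selection, , drop = FALSE]
    coords_b <- coords_b[selection, , drop = FALSE]
  }
  if (nrow(coords_a) == 0) stop("empty selection")
  sqrt(mean(rowSums((coords_a - coords_b)^2)))
}

#' Per-frame RMSD series against a reference frame
#'
#' Each frame is Kabsch-aligned to the reference frame on `selection` before
#' the deviation is measured on the same selection.
#'
#' @param traj an `md_traj`.
#' @param ref_frame_index reference frame (default 1).
#' @param selection atom indices (default: all C-alpha atoms).
#' @return data frame with `frame`, `time_ps`, `rmsd_A`.
#' @export
rmsd_series <- function(traj, ref_frame_index = 1, selection = NULL) {
  stopifnot(inherits(traj, "md_traj"))
  if (ref_frame_index < 1 || ref_frame_index > nframes(traj))
    stop("reference frame index out of range")
  if (is.null(selection)) selection <- select_atoms(traj$topology)
  if (length(selection) == 0) stop("empty selection")
  ref <- frame_coords(traj, ref_frame_index)[selection, , drop = FALSE]
  vals <- vapply(seq_len(nframes(traj)), function(f) {
    mob <- frame_coords(traj, f)[selection, , drop = FALSE]
    fit <- kabsch_fit(mob, ref)
    rmsd(apply_transform(fit, mob), ref)
  }, numeric(1))
  data.frame(frame = seq_len(nframes(traj)), time_ps = traj$times,
             rmsd_A = vals)
}
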