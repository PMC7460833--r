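# Grid-based cavity volume inside atom-anchored inclusion spheres.
#
# The measurement follows the POVME recipe: lay a regular grid over the
# inclusion spheres' bounding box, keep points inside the union of spheres,
# delete points clashing with any heavy atom (within vdW radius + probe
# pad), optionally keep only points 26-connected to the component holding a
# sphere center, and report count * spacing^3.

#' Define an inclusion sphere
#' @param center 3-vector, Angstrom.
#' @param radius radius > 0, Angstrom.
#' @return an `inclusion_sphere`.
#' @export
inclusion_sphere <- function(center, radius) {
  center <- as.numeric(center)
  if (length(center) != 3 || any(!is.finite(center)))
    stop("center must be a finite 3-vector")
  if (!is.finite(radius) || radius <= 0) stop("radius must be positive")
  structure(list(center = center, radius = radius),
            class = "inclusion_sphere")
}

#' Define a sphere recipe anchored to named atoms
#'
#' The sphere center is the unweighted centroid of the named atoms'
#' coordinates in each analyzed frame (for identical elements the centroid
#' equals the center of mass). The usual channel recipes are: a sphere on the
#' aromatic triad near the heme (CZ of Phe69/Phe121/Phe199) and a sphere at
#' the channel mouth between positions 76 and 191, whose reference atom
#' follows the residue actually present (Ala CB, Leu CD1, Phe CZ).
#'
#' @param residue_ids integer residue ids.
#' @param atom_names atom name per residue (recycled if length 1).
#' @param radius sphere radius, Angstrom (default 4).
#' @return a `sphere_recipe`.
#' @export
sphere_recipe <- function(residue_ids, atom_names, radius = 4) {
  residue_ids <- as.integer(residue_ids)
  if (length(residue_ids) < 1) stop("recipe needs at least one atom spec")
  atom_names <- rep_len(as.character(atom_names), length(residue_ids))
  if (!is.finite(radius) || radius <= 0) stop("radius must be positive")
  structure(list(residue_ids = residue_ids, atom_names = atom_names,
                 radius = radius),
            class = "sphere_recipe")
}

#' Resolve a sphere recipe against a coordinate frame
#'
#' @param recipe a `sphere_recipe`.
#' @param coords N x 3 frame coordinates (row order = topology atoms).
#' @param topology an `md_structure`.
#' @return an `inclusion_sphere` centered on the centroid of the named atoms.
#' @export
resolve_sphere <- function(recipe, coords, topology) {
  stopifnot(inherits(recipe, "sphere_recipe"),
            inherits(topology, "md_structure"))
  at <- topology$atom
  idx <- integer(length(recipe$residue_ids))
  for (k in seq_along(idx)) {
    hit <- which(at$resno == recipe$residue_ids[k] &
                 at$elety == recipe$atom_names[k])
    if (!length(hit))
      stop("atom ", recipe$atom_names[k], " not found in residue ",
           recipe$residue_ids[k],
           " — sphere recipes must name the atom the variant actually has ",
           "(Ala: CB, Leu: CD1, Phe: CZ)")
    idx[k] <- hit[1]
  }
  ctr <- colMeans(as.matrix(coords)[idx, , drop = FALSE])
  inclusion_sphere(ctr, recipe$radius)
}

#' Cavity volume of one frame inside inclusion spheres
#'
#' @param coords N x 3 frame coordinates, Angstrom.
#' @param topology an `md_structure` supplying elements and vdW radii.
#' @param spheres an `inclusion_sphere` or list of them.
#' @param grid_spacing grid step, Angstrom (default 1.0).
#' @param probe_pad extra clash padding added to each vdW radius (default 0).
#' @param contiguity if TRUE, keep only grid points 26-connected to the
#'   component(s) containing a sphere center (default FALSE).
#' @return volume in cubic Angstrom. If contiguity is on and every sphere
#'   center is itself buried in an atom, 0 is returned with a warning.
#' @export
frame_cavity_volume <- function(coords, topology, spheres,
                                grid_spacing = 1.0, probe_pad = 0,
                                contiguity = FALSE) {
  stopifnot(inherits(topology, "md_structure"))
  if (inherits(spheres, "inclusion_sphere")) spheres <- list(spheres)
  if (!length(spheres) || !all(vapply(spheres, inherits, TRUE,
                                      "inclusion_sphere")))
    stop("spheres must be inclusion_sphere objects")
  if (grid_spacing <= 0) stop("grid_spacing must be positive")
  if (probe_pad < 0) stop("probe_pad must be non-negative")
  coords <- as.matrix(coords)

  centers <- do.call(rbind, lapply(spheres, `[[`, "center"))
  radii <- vapply(spheres, `[[`, numeric(1), "radius")
  lo <- floor((apply(centers - radii, 2, min)) / grid_spacing) * grid_spacing
  hi <- ceiling((apply(centers + radii, 2, max)) / grid_spacing) * grid_spacing
  # sample at voxel centers: each kept point represents one voxel
  gx <- seq(lo[1] + grid_spacing / 2, hi[1], by = grid_spacing)
  gy <- seq(lo[2] + grid_spacing / 2, hi[2], by = grid_spacing)
  gz <- seq(lo[3] + grid_spacing / 2, hi[3], by = grid_spacing)
  nx <- length(gx); ny <- length(gy); nz <- length(gz)

  # occupancy over the full box as a logical array (needed for connectivity)
  inside <- array(FALSE, dim = c(nx, ny, nz))
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  in_any <- rep(FALSE, nrow(pts))
  for (s in seq_along(spheres)) {
    d2 <- (pts[, 1] - centers[s, 1])^2 + (pts[, 2] - centers[s, 2])^2 +
      (pts[, 3] - centers[s, 3])^2
    in_any <- in_any | d2 <= radii[s]^2 + 1e-12
  }
  inside[] <- in_any

  # heavy atoms close enough to the box to possibly clash
  heavy <- topology$atom$elesy != "H"
  vdw <- topology$atom$vdw + probe_pad
  reach <- max(vdw) + grid_spacing
  near <- heavy &
    coords[, 1] > lo[1] - reach & coords[, 1] < hi[1] + reach &
    coords[, 2] > lo[2] - reach & coords[, 2] < hi[2] + reach &
    coords[, 3] > lo[3] - reach & coords[, 3] < hi[3] + reach
  live <- which(in_any)
  if (any(near) && length(live)) {
    p <- pts[live, , drop = FALSE]
    ok <- rep(TRUE, nrow(p))
    for (a in which(near)) {
      d2 <- (p[, 1] - coords[a, 1])^2 + (p[, 2] - coords[a, 2])^2 +
        (p[, 3] - coords[a, 3])^2
      ok <- ok & d2 > vdw[a]^2
      if (!any(ok)) break
    }
    inside[] <- FALSE
    inside[live[ok]] <- TRUE
  }

  if (contiguity) {
    seeds <- matrix(0L, nrow = nrow(centers), ncol = 3)
    for (s in seq_len(nrow(centers))) {
      seeds[s, ] <- c(which.min(abs(gx - centers[s, 1])),
                      which.min(abs(gy - centers[s, 2])),
                      which.min(abs(gz - centers[s, 3])))
    }
    seed_ok <- inside[seeds]
    if (!any(seed_ok)) {
      warning("all sphere centers are occluded; contiguous volume is 0")
      return(0)
    }
    inside <- .flood26(inside, seeds[seed_ok, , drop = FALSE])
  }
  sum(inside) * grid_spacing^3
}

# 26-connected flood fill from seed voxels over a logical 3-d array.
.flood26 <- function(mask, seeds) {
  d <- dim(mask)
  lab <- array(FALSE, dim = d)
  idx <- function(i, j, k) i + (j - 1) * d[1] + (k - 1) * d[1] * d[2]
  queue <- unique(idx(seeds[, 1], seeds[, 2], seeds[, 3]))
  lab[queue] <- TRUE
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  while (length(queue)) {
    k0 <- (queue - 1) %/% (d[1] * d[2]) + 1
    r <- (queue - 1) %% (d[1] * d[2])
    j0 <- r %/% d[1] + 1
    i0 <- r %% d[1] + 1
    nxt <- integer(0)
    for (o in seq_len(nrow(off))) {
      i <- i0 + off[o, 1]; j <- j0 + off[o, 2]; k <- k0 + off[o, 3]
      keep <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
      if (!any(keep)) next
      cand <- idx(i[keep], j[keep], k[keep])
      cand <- cand[mask[cand] & !lab[cand]]
      if (length(cand)) {
        lab[cand] <- TRUE
        nxt <- c(nxt, cand)
      }
    }
    queue <- unique(nxt)
  }
  lab
}

#' Cavity volume series over the last frames of a trajectory
#'
#' Sphere recipes are re-resolved in every analyzed frame so the inclusion
#' region follows the protein.
#'
#' @param traj an `md_traj`.
#' @param recipes a `sphere_recipe` or list of them.
#' @param last_n_frames number of trailing frames to analyze (default 100).
#' @param grid_spacing,probe_pad,contiguity passed to
#'   [frame_cavity_volume()].
#' @return a `cavity_volumes` object: data frame with `frame`, `time_ps`,
#'   `volume_A3` plus attributes `grid_spacing`, `probe_pad`, `contiguity`.
#' @export
volume_series <- function(traj, recipes, last_n_frames = 100,
                          grid_spacing = 1.0, probe_pad = 0,
                          contiguity = FALSE) {
  stopifnot(inherits(traj, "md_traj"))
  if (inherits(recipes, "sphere_recipe")) recipes <- list(recipes)
  nf <- nframes(traj)
  if (last_n_frames < 1 || last_n_frames > nf)
    stop("last_n_frames must be in 1..", nf)
  frames <- seq(nf - last_n_frames + 1, nf)
  vols <- vapply(frames, function(f) {
    m <- frame_coords(traj, f)
    sph <- lapply(recipes, resolve_sphere, coords = m,
                  topology = traj$topology)
    frame_cavity_volume(m, traj$topology, sph, grid_spacing = grid_spacing,
                        probe_pad = probe_pad, contiguity = contiguity)
  }, numeric(1))
  structure(data.frame(frame = frames, time_ps = traj$times[frames],
                       volume_A3 = vols),
            grid_spacing = grid_spacing, probe_pad = probe_pad,
            contiguity = contiguity,
            class = c("cavity_volumes", "data.frame"))
}

#' @export
print.cavity_volumes <- function(x, ...) {
  cat(sprintf(
    "cavity_volumes: %d frames, grid %.2f A%s; volume %.1f +/- %.1f A^3\n",
    nrow(x), attr(x, "grid_spacing"),
    if (attr(x, "contiguity")) ", contiguous" else "",
    mean(x$volume_A3), stats::sd(x$volume_A3)))
  invisible(x)
}

#' @export
plot.cavity_volumes <- function(x, ...) {
  graphics::plot(x$time_ps, x$volume_A3, type = "l", xlab = "time (ps)",
                 ylab = expression(volume ~ (ring(A)^3)), ...)
  invisible(x)
}
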