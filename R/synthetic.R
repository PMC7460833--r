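# Synthetic inputs with known ground truth.
#
# Trajectories are built as isotropic Gaussian fluctuations about a
# folded-like C-alpha reference (ideal helix, 3.8 A consecutive spacing),
# optionally composed with a rigid-body random walk (which alignment must
# remove) and/or a slow coherent drift mode (which windowing must
# suppress). Cavity phantoms are shells of carbon atoms around an empty
# void of analytically known volume. Kinetic datasets are exact model
# curves with optional multiplicative Gaussian noise. Every generator is
# deterministic under its seed and stores its ground truth as attributes.

.helix_ca <- function(n) {
  # alpha-helix-like trace: rise 1.5 A, 100 deg/residue; radius chosen so
  # consecutive C-alpha spacing is exactly 3.8 A
  rise <- 1.5; dphi <- 100 * pi / 180
  radius <- sqrt(3.8^2 - rise^2) / (2 * sin(dphi / 2))
  i <- seq_len(n) - 1
  cbind(radius * cos(i * dphi), radius * sin(i * dphi), rise * i)
}

#' Generate a synthetic C-alpha reference structure
#'
#' An ideal-helix C-alpha trace (consecutive spacing 3.8 A) with optional
#' side-chain reference pseudo-atoms (CB/CD1/CZ) on designated residues so
#' that channel sphere recipes resolve. Residues carrying CZ are typed PHE,
#' CD1 LEU, CB ALA; all others ALA.
#'
#' @param n_residues number of residues (>= 4).
#' @param seed RNG seed (the construction is deterministic; the seed is
#'   consumed for reproducibility of any future stochastic placement).
#' @param sidechain_atoms named character vector mapping residue id to the
#'   side-chain atom to add, e.g. `c("76" = "CZ", "191" = "CZ")`.
#' @return an `md_structure`.
#' @export
synth_reference <- function(n_residues, seed = 1, sidechain_atoms = NULL) {
  if (n_residues < 4) stop("need at least 4 residues, got ", n_residues)
  set.seed(seed)
  ca <- .helix_ca(n_residues)
  sc_len <- c(CB = 1.53, CD1 = 2.6, CZ = 3.4)
  sc_res <- c(CB = "ALA", CD1 = "LEU", CZ = "PHE")
  if (!is.null(sidechain_atoms)) {
    bad <- setdiff(sidechain_atoms, names(sc_len))
    if (length(bad)) stop("unsupported side-chain atom(s): ",
                          paste(bad, collapse = ", "))
    ids <- as.integer(names(sidechain_atoms))
    if (any(is.na(ids)) || any(ids < 1) || any(ids > n_residues))
      stop("sidechain_atoms names must be residue ids in 1..", n_residues)
  }
  rows <- list(); xyz <- list(); serial <- 0
  for (r in seq_len(n_residues)) {
    sc <- if (!is.null(sidechain_atoms) &&
              as.character(r) %in% names(sidechain_atoms))
      sidechain_atoms[[as.character(r)]] else NA
    resid <- if (is.na(sc)) "ALA" else sc_res[[sc]]
    serial <- serial + 1
    rows[[length(rows) + 1]] <- data.frame(
      serial = serial, elety = "CA", resid = resid, chain = "A",
      resno = r, elesy = "C", vdw = 1.7, stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1]] <- ca[r, ]
    if (!is.na(sc)) {
      # side chain points radially outward from the helix axis
      dir <- c(ca[r, 1], ca[r, 2], 0)
      dir <- dir / sqrt(sum(dir^2))
      serial <- serial + 1
      rows[[length(rows) + 1]] <- data.frame(
        serial = serial, elety = sc, resid = resid, chain = "A",
        resno = r, elesy = "C", vdw = 1.7, stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1]] <- ca[r, ] + sc_len[[sc]] * dir
    }
  }
  atom <- do.call(rbind, rows)
  m <- do.call(rbind, xyz)
  colnames(m) <- c("x", "y", "z")
  .new_md_structure(atom, m, title = sprintf("synthetic helix n=%d",
                                             n_residues))
}

#' Per-residue fluctuation specification for synthetic trajectories
#'
#' @param residue_ids residues covered.
#' @param sigma isotropic Gaussian amplitude per residue, Angstrom
#'   (recycled).
#' @param rigid_body NULL or `list(step_deg =, step_A =)`: per-frame
#'   rigid-body random-walk increments.
#' @param slow_drift NULL or `list(amplitude_A =, period_ps =)`: coherent
#'   slow mode (per-residue fixed random directions, common sinusoidal time
#'   factor).
#' @return a `fluc_spec`.
#' @export
fluc_spec <- function(residue_ids, sigma, rigid_body = NULL,
                      slow_drift = NULL) {
  sigma <- rep_len(as.numeric(sigma), length(residue_ids))
  if (any(sigma < 0)) stop("sigma must be >= 0")
  if (!is.null(rigid_body))
    stopifnot(is.list(rigid_body), rigid_body$step_deg >= 0,
              rigid_body$step_A >= 0)
  if (!is.null(slow_drift))
    stopifnot(is.list(slow_drift), slow_drift$amplitude_A >= 0,
              slow_drift$period_ps > 0)
  structure(list(residue_ids = as.integer(residue_ids), sigma = sigma,
                 rigid_body = rigid_body, slow_drift = slow_drift),
            class = "fluc_spec")
}

.rand_rotation <- function(angle_rad) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  c_ <- cos(angle_rad); s_ <- sin(angle_rad)
  k <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  diag(3) + s_ * k + (1 - c_) * (k %*% k)
}

#' Generate a synthetic trajectory with known fluctuation amplitudes
#'
#' Frame coordinates are `RigidBody_t(ref_i + drift_i(t) + sigma_i *
#' eta_{i,t})` with `eta` i.i.d. standard 3-vectors. All atoms of a residue
#' share that residue's sigma.
#'
#' @param reference an `md_structure` (see [synth_reference()]).
#' @param spec a `fluc_spec`, or a numeric sigma (single value or one per
#'   residue).
#' @param n_frames number of frames.
#' @param frame_interval_ps frame spacing, ps (default 10, i.e. 10 frames
#'   per 100-ps analysis window).
#' @param seed RNG seed.
#' @return an `md_traj` with attribute `fluc_spec` holding the ground
#'   truth.
#' @export
synth_trajectory <- function(reference, spec, n_frames,
                             frame_interval_ps = 10, seed = 1) {
  stopifnot(inherits(reference, "md_structure"))
  res_ids <- sort(unique(reference$atom$resno))
  if (!inherits(spec, "fluc_spec")) {
    spec <- fluc_spec(res_ids, spec)
  }
  if (!all(spec$residue_ids %in% res_ids))
    stop("fluc_spec covers residues absent from the reference")
  sig_res <- stats::setNames(rep(0, length(res_ids)), res_ids)
  sig_res[as.character(spec$residue_ids)] <- spec$sigma
  sig_atom <- sig_res[as.character(reference$atom$resno)]
  n <- nrow(reference$atom)
  set.seed(seed)
  times <- (seq_len(n_frames) - 1) * frame_interval_ps
  # draw the internal-motion noise first so that, for a given seed, the
  # internal dynamics are identical with and without rigid-body motion or
  # drift (lets tests compare the two directly)
  noise <- array(stats::rnorm(n_frames * n * 3), dim = c(n_frames, n, 3))
  drift_dir <- NULL
  if (!is.null(spec$slow_drift)) {
    d <- matrix(stats::rnorm(3 * length(res_ids)), ncol = 3)
    d <- d / sqrt(rowSums(d^2))
    drift_dir <- d[match(reference$atom$resno, res_ids), , drop = FALSE]
  }
  coords <- array(NA_real_, dim = c(n_frames, n, 3))
  rot <- diag(3); trans <- c(0, 0, 0)
  for (f in seq_len(n_frames)) {
    m <- reference$xyz + matrix(noise[f, , ], ncol = 3) * sig_atom
    if (!is.null(drift_dir)) {
      amp <- spec$slow_drift$amplitude_A *
        sin(2 * pi * times[f] / spec$slow_drift$period_ps)
      m <- m + amp * drift_dir
    }
    if (!is.null(spec$rigid_body)) {
      rot <- .rand_rotation(spec$rigid_body$step_deg * pi / 180) %*% rot
      step <- stats::rnorm(3)
      trans <- trans + spec$rigid_body$step_A * step / sqrt(sum(step^2))
      m <- m %*% t(rot) + matrix(trans, n, 3, byrow = TRUE)
    }
    coords[f, , ] <- m
  }
  tr <- .new_md_traj(reference, coords, times)
  attr(tr, "fluc_spec") <- spec
  tr
}

#' Specification of a cavity phantom
#'
#' A spherical void of known radius surrounded by a shell of carbon
#' pseudo-atoms: every grid point within `void_radius` of the center is
#' guaranteed clash-free because the shell is farther than `void_radius +
#' vdw`.
#'
#' @param void_radius radius of the empty void, Angstrom.
#' @param shell_radius radius of the atom shell; must exceed
#'   `void_radius + vdw`.
#' @param shell_atom_count atoms on the shell (Fibonacci lattice; default
#'   500 keeps the shell gap-free at these radii).
#' @param vdw van der Waals radius of the shell atoms (default 1.7).
#' @param breathing NULL or `list(amplitude_A =, period_ps =)` sinusoidal
#'   modulation of the shell radius.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(void_radius = 4, shell_radius = 6,
                         shell_atom_count = 500, vdw = 1.7,
                         breathing = NULL) {
  if (shell_radius <= void_radius + vdw)
    stop("shell_radius (", shell_radius, ") must exceed void_radius + vdw (",
         void_radius + vdw, "): the void would not be empty")
  if (shell_atom_count < 50) stop("need at least 50 shell atoms")
  if (!is.null(breathing))
    stopifnot(is.list(breathing), breathing$amplitude_A >= 0,
              breathing$period_ps > 0)
  structure(list(void_radius = void_radius, shell_radius = shell_radius,
                 shell_atom_count = shell_atom_count, vdw = vdw,
                 breathing = breathing),
            class = "phantom_spec")
}

# Fibonacci sphere lattice: near-uniform deterministic point coverage.
.fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Generate a cavity-phantom trajectory
#'
#' Shell atoms sit on a Fibonacci lattice (uniform coverage) at
#' `shell_radius`, randomly re-oriented once per run (seeded); breathing
#' scales the shell radius sinusoidally over frames. Atoms 1 and 2 are
#' placed antipodally on the x-axis so a two-atom sphere recipe resolves to
#' the void center.
#'
#' @param spec a `phantom_spec`.
#' @param n_frames number of frames.
#' @param frame_interval_ps frame spacing, ps.
#' @param seed RNG seed.
#' @return an `md_traj` with attribute `phantom_spec`.
#' @export
synth_cavity_phantom <- function(spec, n_frames = 1, frame_interval_ps = 10,
                                 seed = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(seed)
  n <- spec$shell_atom_count
  dirs <- .fib_sphere(n - 2)
  rot <- .rand_rotation(stats::runif(1, 0, 2 * pi))
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), dirs %*% t(rot))
  atom <- data.frame(
    serial = seq_len(n), elety = "C", resid = "SHL", chain = "A",
    resno = seq_len(n), elesy = "C", vdw = spec$vdw,
    stringsAsFactors = FALSE)
  topo <- .new_md_structure(atom, dirs * spec$shell_radius,
                            title = "cavity phantom")
  times <- (seq_len(n_frames) - 1) * frame_interval_ps
  coords <- array(NA_real_, dim = c(n_frames, n, 3))
  for (f in seq_len(n_frames)) {
    r <- spec$shell_radius
    if (!is.null(spec$breathing))
      r <- r + spec$breathing$amplitude_A *
        sin(2 * pi * times[f] / spec$breathing$period_ps)
    coords[f, , ] <- dirs * r
  }
  tr <- .new_md_traj(topo, coords, times)
  attr(tr, "phantom_spec") <- spec
  tr
}

#' Expected phantom volume inside an inclusion sphere
#'
#' The measurable void is the inclusion sphere clipped by the shell's clash
#' surface: radius `min(inclusion_radius, shell_radius - vdw - probe_pad)`.
#'
#' @param spec a `phantom_spec`.
#' @param inclusion_radius inclusion sphere radius (default: the void
#'   radius).
#' @param shell_radius shell radius at the evaluated instant (default: the
#'   spec's static radius).
#' @param probe_pad clash padding used in the measurement.
#' @return volume in cubic Angstrom.
#' @export
phantom_expected_volume <- function(spec, inclusion_radius = NULL,
                                    shell_radius = NULL, probe_pad = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(inclusion_radius)) inclusion_radius <- spec$void_radius
  if (is.null(shell_radius)) shell_radius <- spec$shell_radius
  r <- min(inclusion_radius, shell_radius - spec$vdw - probe_pad)
  if (r <= 0) return(0)
  4 / 3 * pi * r^3
}

#' Generate a synthetic Michaelis-Menten initial-rate dataset
#'
#' `v = kcat * [E] * S / (Km + S) * (1 + rel_noise * zeta)` with standard
#' normal `zeta`, seeded.
#'
#' @param kcat turnover number, 1/s.
#' @param Km Michaelis constant, uM.
#' @param enzyme_nM enzyme concentration, nM.
#' @param concs substrate concentrations, uM.
#' @param rel_noise relative noise SD (default 0).
#' @param seed RNG seed.
#' @return a `rate_dataset` (rates in uM/s) with attribute `truth`.
#' @export
synth_mm_data <- function(kcat, Km, enzyme_nM, concs, rel_noise = 0,
                          seed = 1) {
  stopifnot(kcat > 0, Km > 0, enzyme_nM > 0, all(concs >= 0),
            rel_noise >= 0)
  set.seed(seed)
  v <- kcat * (enzyme_nM * 1e-3) * concs / (Km + concs)
  if (rel_noise > 0)
    v <- v * (1 + rel_noise * stats::rnorm(length(concs)))
  out <- rate_dataset(concs, v, enzyme_nM)
  attr(out, "truth") <- list(kcat = kcat, Km = Km, enzyme_nM = enzyme_nM,
                             rel_noise = rel_noise, seed = seed)
  out
}

#' Generate a synthetic first-order inactivation dataset
#'
#' `A(t) = A0 * exp(-k t) * (1 + rel_noise * zeta)`, seeded.
#'
#' @param k_inact rate constant, 1/min.
#' @param times_min sampling times, minutes.
#' @param rel_noise relative noise SD (default 0).
#' @param seed RNG seed.
#' @param A0 initial activity (default 1).
#' @return data frame `(time_min, activity)` with attribute `truth`.
#' @export
synth_inactivation_data <- function(k_inact, times_min, rel_noise = 0,
                                    seed = 1, A0 = 1) {
  stopifnot(k_inact > 0, all(times_min >= 0), rel_noise >= 0, A0 > 0)
  set.seed(seed)
  a <- A0 * exp(-k_inact * times_min)
  if (rel_noise > 0)
    a <- a * (1 + rel_noise * stats::rnorm(length(times_min)))
  out <- data.frame(time_min = times_min, activity = a)
  attr(out, "truth") <- list(k_inact = k_inact, rel_noise = rel_noise,
                             seed = seed, A0 = A0)
  out
}
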