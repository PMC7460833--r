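# Structure and trajectory I/O.
#
# Containers are deliberately small: an `md_structure` is an atom table plus
# reference coordinates; an `md_traj` is a topology plus an F x N x 3
# coordinate array with per-frame times in picoseconds. PDB parsing and
# writing are delegated to bio3d; the multi-frame XYZ dialect is read and
# written directly (three columns of Angstroms per atom, frame blocks headed
# by an atom count and a comment line).

# Bondi-style van der Waals radii (Angstrom) for the elements that occur in
# protein/heme systems. Unknown elements fall back to 1.7 A with a warning.
.VDW_TABLE <- c(
  "H" = 1.20, "C" = 1.70, "N" = 1.55, "O" = 1.52, "S" = 1.80, "P" = 1.80,
  "F" = 1.47, "CL" = 1.75, "BR" = 1.85, "I" = 1.98, "FE" = 2.00,
  "SE" = 1.90, "ZN" = 1.39, "MG" = 1.73, "NA" = 2.27, "K" = 2.75,
  "CA" = 2.31, "MN" = 2.05, "CU" = 1.40
)

# Residue names treated as solvent/ions and dropped on read by default.
.SOLVENT_RESID <- c("HOH", "WAT", "TIP", "TIP3", "SOL", "SPC",
                    "NA", "CL", "K", "MG", "ZN", "CA", "SO4", "PO4")

#' Look up van der Waals radii by element symbol
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of radii in Angstrom. Unrecognized symbols get
#'   1.7 A with a warning.
#' @export
vdw_radius <- function(element) {
  key <- toupper(trimws(element))
  r <- .VDW_TABLE[key]
  miss <- is.na(r)
  if (any(miss)) {
    warning("unknown element(s) ", paste(unique(key[miss]), collapse = ", "),
            "; using default vdW radius 1.7 A")
    r[miss] <- 1.7
  }
  unname(r)
}

.infer_element <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  bad <- is.na(el) | el == ""
  if (any(bad)) {
    # atom-name convention: strip digits, take leading character(s); two-letter
    # elements in proteins are rare outside heme Fe.
    nm <- toupper(gsub("[0-9']", "", trimws(elety[bad])))
    two <- substr(nm, 1, 2)
    el[bad] <- ifelse(two %in% c("FE", "CL", "BR", "ZN", "MG", "SE", "MN", "CU"),
                      two, substr(nm, 1, 1))
  }
  el
}

.new_md_structure <- function(atom, xyz, title = "") {
  stopifnot(is.data.frame(atom), nrow(atom) >= 1,
            is.matrix(xyz), nrow(xyz) == nrow(atom), ncol(xyz) == 3)
  if (any(!is.finite(xyz))) stop("non-finite coordinates in structure")
  structure(list(atom = atom, xyz = xyz, title = title),
            class = "md_structure")
}

#' Read a protein structure from a PDB file
#'
#' Parses fixed-column ATOM/HETATM records (via bio3d), infers element
#' symbols from the element column with a fall-back to the atom-name
#' convention, and assigns van der Waals radii from a bundled element table.
#' HETATM records (e.g. the heme group) are retained; water and buffer ions
#' are dropped by default.
#'
#' @param path path to a PDB file.
#' @param drop_solvent drop waters/ions (default TRUE).
#' @return an object of class `md_structure`: a list with `atom` (data frame
#'   with columns serial, elety, resid, chain, resno, elesy, vdw), `xyz`
#'   (N x 3 matrix, Angstrom) and `title`.
#' @export
read_pdb <- function(path, drop_solvent = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (nrow(at) == 0) stop("no ATOM/HETATM records in ", path)
  keep <- rep(TRUE, nrow(at))
  if (drop_solvent) keep <- !(toupper(at$resid) %in% .SOLVENT_RESID)
  if (!any(keep)) stop("no atoms left after solvent removal in ", path)
  at <- at[keep, , drop = FALSE]
  el <- .infer_element(at$elesy, at$elety)
  atom <- data.frame(
    serial = at$eleno, elety = trimws(at$elety), resid = trimws(at$resid),
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    resno = at$resno, elesy = el,
    vdw = suppressWarnings(vdw_radius(el)),
    stringsAsFactors = FALSE)
  xyz <- cbind(at$x, at$y, at$z)
  colnames(xyz) <- c("x", "y", "z")
  .new_md_structure(atom, xyz, title = basename(path))
}

.bio3d_pdb <- function(structure, xyz_frames = NULL) {
  at <- structure$atom
  n <- nrow(at)
  xyz <- if (is.null(xyz_frames)) {
    matrix(t(structure$xyz), nrow = 1)
  } else {
    t(apply(xyz_frames, 1, function(fr) as.vector(t(fr))))
  }
  utils::capture.output(pdb <- bio3d::as.pdb(
    xyz = bio3d::as.xyz(xyz),
    type = rep("ATOM", n),
    eleno = at$serial, elety = at$elety, resid = at$resid,
    chain = at$chain, resno = at$resno, elesy = at$elesy))
  pdb
}

#' Write a structure to a PDB file
#'
#' @param structure an `md_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "md_structure"))
  suppressWarnings(bio3d::write.pdb(.bio3d_pdb(structure), file = path))
  invisible(path)
}

.new_md_traj <- function(topology, coords, times) {
  stopifnot(inherits(topology, "md_structure"))
  n <- nrow(topology$atom)
  d <- dim(coords)
  if (length(d) != 3 || d[2] != n || d[3] != 3)
    stop("coords must be an F x ", n, " x 3 array")
  if (d[1] < 1) stop("trajectory needs at least one frame")
  if (length(times) != d[1]) stop("frame_times length must equal frame count")
  if (d[1] > 1 && any(diff(times) <= 0))
    stop("frame_times must be strictly increasing")
  if (any(!is.finite(coords))) stop("non-finite coordinates in trajectory")
  structure(list(topology = topology, coords = coords, times = as.numeric(times)),
            class = "md_traj")
}

#' @export
print.md_traj <- function(x, ...) {
  cat(sprintf("md_traj: %d frames x %d atoms, t = %.1f..%.1f ps\n",
              nframes(x), nrow(x$topology$atom),
              x$times[1], x$times[nframes(x)]))
  invisible(x)
}

#' @export
print.md_structure <- function(x, ...) {
  cat(sprintf("md_structure: %d atoms, %d residues%s\n",
              nrow(x$atom), length(unique(x$atom$resno)),
              if (nzchar(x$title)) paste0(" (", x$title, ")") else ""))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_traj`.
#' @export
nframes <- function(traj) dim(traj$coords)[1]

#' Extract one frame's coordinates
#' @param traj an `md_traj`.
#' @param i frame index (1-based).
#' @return N x 3 coordinate matrix.
#' @export
frame_coords <- function(traj, i) {
  if (i < 1 || i > nframes(traj)) stop("frame index out of range: ", i)
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(traj$coords)[2:3]
  colnames(m) <- c("x", "y", "z")
  m
}

#' Build a trajectory from a topology and a coordinate array
#'
#' @param topology an `md_structure`.
#' @param coords F x N x 3 array (Angstrom).
#' @param times frame times in ps; defaults to `0, dt, 2*dt, ...`.
#' @param frame_interval_ps spacing used when `times` is NULL.
#' @return an `md_traj`.
#' @export
as_md_traj <- function(topology, coords, times = NULL, frame_interval_ps = 10) {
  if (is.null(times)) times <- (seq_len(dim(coords)[1]) - 1) * frame_interval_ps
  .new_md_traj(topology, coords, times)
}

#' Read a trajectory from a multi-model PDB or multi-frame XYZ file
#'
#' All models/frames must share the atom count and order. Frame times are
#' assigned as `0, dt, 2*dt, ...` from `frame_interval_ps` unless the XYZ
#' comment lines carry `time = <ps>` stamps.
#'
#' @param path input file.
#' @param format `"multimodel_pdb"` or `"xyz"`.
#' @param frame_interval_ps frame spacing in ps (default 10).
#' @param topology for `"xyz"` input, an optional `md_structure` supplying
#'   atom metadata (elements in the XYZ file must match it); by default a
#'   C-alpha pseudo-topology is built from the element column.
#' @param drop_solvent passed through to the PDB reader.
#' @return an `md_traj`.
#' @export
read_trajectory <- function(path, format = c("multimodel_pdb", "xyz"),
                            frame_interval_ps = 10, topology = NULL,
                            drop_solvent = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "multimodel_pdb") {
    pdb <- tryCatch(
      suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
      error = function(e) stop("failed to parse PDB '", path, "': ",
                               conditionMessage(e), call. = FALSE))
    topo <- read_pdb(path, drop_solvent = drop_solvent)
    keep <- if (drop_solvent)
      !(toupper(trimws(pdb$atom$resid)) %in% .SOLVENT_RESID)
    else rep(TRUE, nrow(pdb$atom))
    xyz <- pdb$xyz
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
    nf <- nrow(xyz)
    natom_all <- ncol(xyz) / 3
    if (natom_all != nrow(pdb$atom))
      stop("inconsistent atom count across models in ", path)
    keep_cols <- rep(keep, each = 3)
    coords <- array(NA_real_, dim = c(nf, nrow(topo$atom), 3))
    for (f in seq_len(nf)) {
      m <- matrix(xyz[f, keep_cols], ncol = 3, byrow = TRUE)
      coords[f, , ] <- m
    }
    times <- (seq_len(nf) - 1) * frame_interval_ps
    return(.new_md_traj(topo, coords, times))
  }
  # multi-frame XYZ
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty file: ", path)
  frames <- list(); times <- numeric(); elems <- NULL
  i <- 1; f <- 0
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      stop("malformed XYZ frame header at line ", i, " of ", path)
    if (i + 1 + n > length(lines))
      stop("truncated XYZ frame starting at line ", i, " of ", path)
    f <- f + 1
    comment <- lines[i + 1]
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, 1L) < 4)
    if (length(bad))
      stop("malformed XYZ atom record at line ", i + 1 + bad[1], " of ", path)
    el <- vapply(parts, `[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      stop("non-numeric coordinates in XYZ frame ", f, " of ", path)
    if (is.null(elems)) elems <- el
    else if (length(el) != length(elems) || any(el != elems))
      stop("inconsistent atom count/order at model ", f, " in ", path)
    tm <- regmatches(comment,
                     regexpr("time\\s*=\\s*[-0-9.eE+]+", comment))
    times <- c(times, if (length(tm))
      as.numeric(sub("time\\s*=\\s*", "", tm)) else NA_real_)
    frames[[f]] <- xyz
    i <- i + 2 + n
  }
  if (f == 0) stop("no frames found in ", path)
  if (anyNA(times)) times <- (seq_len(f) - 1) * frame_interval_ps
  n <- length(elems)
  if (is.null(topology)) {
    atom <- data.frame(
      serial = seq_len(n), elety = "CA", resid = "ALA", chain = "A",
      resno = seq_len(n), elesy = toupper(elems),
      vdw = suppressWarnings(vdw_radius(elems)), stringsAsFactors = FALSE)
    topology <- .new_md_structure(atom, frames[[1]], title = basename(path))
  } else if (nrow(topology$atom) != n) {
    stop("topology atom count (", nrow(topology$atom),
         ") does not match XYZ frames (", n, ")")
  }
  coords <- array(NA_real_, dim = c(f, n, 3))
  for (k in seq_len(f)) coords[k, , ] <- frames[[k]]
  .new_md_traj(topology, coords, times)
}

#' Write a trajectory to a multi-model PDB or multi-frame XYZ file
#'
#' @param traj an `md_traj`.
#' @param path output path.
#' @param format `"multimodel_pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("multimodel_pdb", "xyz")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "md_traj"))
  if (format == "multimodel_pdb") {
    suppressWarnings(bio3d::write.pdb(
      .bio3d_pdb(traj$topology, xyz_frames = traj$coords), file = path))
    return(invisible(path))
  }
  con <- file(path, "w"); on.exit(close(con))
  el <- traj$topology$atom$elesy
  n <- length(el)
  for (f in seq_len(nframes(traj))) {
    m <- frame_coords(traj, f)
    writeLines(c(as.character(n),
                 sprintf("frame %d time = %.4f ps", f, traj$times[f]),
                 sprintf("%-2s %12.6f %12.6f %12.6f", el, m[, 1], m[, 2], m[, 3])),
               con)
  }
  invisible(path)
}

#' Select atoms by residue id and atom name
#'
#' Returns the indices (into the topology's atom table) of the requested
#' atoms, one per (residue, atom-name) match, ordered by residue id. A
#' residue that exists but lacks the named atom is an error: sphere recipes
#' must name the atom each variant actually has (Ala uses CB, Leu CD1,
#' Phe CZ).
#'
#' @param structure an `md_structure` (or the topology of an `md_traj`).
#' @param residue_ids integer residue ids (author/PDB numbering); NULL
#'   selects every residue that has the named atom type.
#' @param atom_names atom name(s) to pick within each residue (default "CA").
#' @param label optional label stored on the selection.
#' @return integer vector of atom indices with attributes `label` and
#'   `residue_ids`.
#' @export
select_atoms <- function(structure, residue_ids = NULL, atom_names = "CA",
                         label = NULL) {
  if (inherits(structure, "md_traj")) structure <- structure$topology
  stopifnot(inherits(structure, "md_structure"))
  at <- structure$atom
  if (is.null(residue_ids)) {
    residue_ids <- sort(unique(at$resno[at$elety %in% atom_names]))
  } else {
    residue_ids <- as.integer(residue_ids)
    missing_res <- setdiff(residue_ids, unique(at$resno))
    if (length(missing_res))
      stop("residue(s) not present: ", paste(missing_res, collapse = ", "))
  }
  idx <- integer(0); got <- integer(0)
  for (r in sort(residue_ids)) {
    hit <- integer(0)
    for (nm in atom_names) {
      hit <- which(at$resno == r & at$elety == nm)
      if (length(hit)) break
    }
    if (length(hit)) {
      idx <- c(idx, hit[1])
      got <- c(got, r)
    }
  }
  bad <- setdiff(sort(residue_ids), got)
  if (length(bad))
    stop("atom '", paste(atom_names, collapse = "/"),
         "' absent in residue(s): ", paste(bad, collapse = ", "),
         " (", paste(unique(at$resid[at$resno %in% bad]), collapse = ", "), ")")
  structure(idx, label = if (is.null(label))
    paste0(paste(atom_names, collapse = "/"), " selection") else label,
    residue_ids = got)
}
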