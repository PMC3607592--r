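#' @useDynLib clamshellfe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd var cor rnorm runif quantile setNames approx
#' @importFrom utils head tail
NULL

BACKBONE_NAMES <- c("N", "CA", "C", "O")

# standard atomic masses (u), keyed by element symbol
ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  "NA" = 22.990, MG = 24.305, K = 39.098, CA = 40.078, ZN = 65.38,
  FE = 55.845, MN = 54.938
)

#' Construct a molecular structure
#'
#' A `Structure` couples per-atom bookkeeping (names, residue numbers,
#' chains) with Cartesian coordinates in nanometres. It is the substrate
#' for all selection, superposition and collective-variable machinery.
#'
#' @param atoms data.frame with columns `serial`, `name`, `resid`,
#'   `resname`, `chain`, `element`, `het` (logical), and optionally
#'   `icode`.
#' @param xyz numeric matrix, one row per atom, columns x/y/z in nm.
#' @param label character tag carried through I/O round trips.
#' @return object of class `Structure`.
#' @export
new_structure <- function(atoms, xyz, label = "structure") {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (nrow(atoms) == 0L) stop("a Structure needs at least one atom")
  if (nrow(xyz) != nrow(atoms) || ncol(xyz) != 3L)
    stop("xyz must be an n_atoms x 3 matrix")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (any(atoms$resid < 1L)) stop("residue numbers must be >= 1")
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$element) || all(atoms$element == ""))
    atoms$element <- guess_element(atoms$name)
  atoms$is_backbone <- atoms$name %in% BACKBONE_NAMES & !atoms$het
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, xyz = xyz, label = label),
            class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure '%s': %d atoms, %d residues, chains: %s\n",
              x$label, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resid))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

n_atoms <- function(s) nrow(s$atoms)

guess_element <- function(name) {
  # first alphabetic character of the atom name; two-letter elements must
  # come through the PDB element column instead
  el <- toupper(sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", name))
  el[!nzchar(el)] <- "C"
  el
}

#' Atomic masses for a structure
#'
#' @param s a `Structure`.
#' @return numeric vector of masses in u, one per atom; unknown elements
#'   fall back to carbon.
#' @export
atom_masses <- function(s) {
  el <- toupper(s$atoms$element)
  m <- ATOMIC_MASSES[el]
  m[is.na(m)] <- ATOMIC_MASSES[["C"]]
  unname(m)
}

pdb_field <- function(lines, from, to) {
  substr(lines, from, to)
}

#' Read a structure from PDB text
#'
#' Parses the `ATOM`/`HETATM`/`MODEL`/`ENDMDL` subset of the PDB format.
#' Coordinates are converted from Angstrom to nm at the boundary; all
#' internal lengths are nm. For multi-model files only the first model is
#' returned (see [read_multimodel_pdb()] for trajectories). Alternate
#' location indicators keep the first conformer (blank or "A");
#' `HETATM` records are retained and flagged.
#'
#' @param text a file path, or PDB-format text (single string with
#'   newlines, or a character vector of lines).
#' @param label label for the returned structure; defaults to the file
#'   name when reading from a path.
#' @return a `Structure`.
#' @export
read_pdb <- function(text, label = NULL) {
  lines <- as_text_lines(text)
  if (is.null(label))
    label <- if (length(text) == 1L && file.exists(text)) basename(text) else "pdb"
  rec <- pdb_field(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") |
    grepl("^(ATOM|HETATM)\\b", lines)
  # first model only
  endmdl <- which(grepl("^ENDMDL", lines))
  if (length(endmdl) > 0L) is_atom[seq_along(lines) > endmdl[1L]] <- FALSE
  idx <- which(is_atom)
  if (length(idx) == 0L) stop("no ATOM/HETATM records found in PDB input")
  parsed <- parse_atom_lines(lines[idx], idx)
  keep <- parsed$altloc %in% c("", " ", "A")
  parsed <- parsed[keep, , drop = FALSE]
  if (nrow(parsed) == 0L) stop("no atoms left after altLoc filtering")
  atoms <- data.frame(
    serial = parsed$serial, name = parsed$name, resid = parsed$resid,
    resname = parsed$resname, chain = parsed$chain,
    element = parsed$element, het = parsed$het, icode = parsed$icode,
    stringsAsFactors = FALSE
  )
  new_structure(atoms, cbind(parsed$x, parsed$y, parsed$z) / 10, label)
}

as_text_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    return(readLines(text, warn = FALSE))
  if (length(text) == 1L) return(strsplit(text, "\n", fixed = TRUE)[[1L]])
  text
}

parse_atom_lines <- function(lines, line_numbers) {
  lines <- formatC(lines, width = 80, flag = "-")
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(trimws(pdb_field(lines, from, to))))
    if (anyNA(v))
      stop(sprintf("malformed ATOM record (bad %s) at line %d",
                   what, line_numbers[which(is.na(v))[1L]]))
    v
  }
  data.frame(
    serial = as.integer(num(7, 11, "serial")),
    name = trimws(pdb_field(lines, 13, 16)),
    altloc = trimws(pdb_field(lines, 17, 17)),
    resname = trimws(pdb_field(lines, 18, 20)),
    chain = trimws(pdb_field(lines, 22, 22)),
    resid = as.integer(num(23, 26, "residue number")),
    icode = trimws(pdb_field(lines, 27, 27)),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    element = trimws(pdb_field(lines, 77, 78)),
    het = grepl("^HETATM", lines),
    stringsAsFactors = FALSE
  )
}

format_atom_line <- function(atoms, xyz) {
  ang <- xyz * 10
  rec <- ifelse(atoms$het, "HETATM", "ATOM  ")
  name <- ifelse(nchar(atoms$name) < 4L,
                 sprintf(" %-3s", atoms$name), atoms$name)
  sprintf("%s%5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, atoms$serial %% 100000L, name, atoms$resname,
          substr(paste0(atoms$chain, "A"), 1, 1), atoms$resid %% 10000L,
          substr(paste0(atoms$icode, " "), 1, 1),
          ang[, 1], ang[, 2], ang[, 3], 1, 0, atoms$element)
}

#' Write a structure as PDB text
#'
#' Inverse of [read_pdb()]; nm are converted back to Angstrom with the
#' format's three decimals, so positions round-trip to 1e-4 nm.
#'
#' @param s a `Structure`.
#' @param path optional file path; when `NULL` the text is returned.
#' @return the PDB text, invisibly when writing to a file.
#' @export
write_pdb <- function(s, path = NULL) {
  txt <- c(format_atom_line(s$atoms, s$xyz), "END")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Construct a trajectory
#'
#' @param coords numeric array `[n_frames, n_atoms, 3]` in nm.
#' @param times numeric vector of per-frame timestamps, ps, strictly
#'   increasing.
#' @param topology a `Structure` providing per-atom bookkeeping shared by
#'   all frames.
#' @return object of class `Trajectory`.
#' @export
new_trajectory <- function(coords, times, topology) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be an [n_frames, n_atoms, 3] array")
  if (dim(coords)[2] != n_atoms(topology))
    stop("every frame must have exactly as many positions as the topology has atoms")
  if (dim(coords)[1] != length(times))
    stop("times must have one entry per frame")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  structure(list(coords = coords, times = as.numeric(times),
                 topology = topology),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, t = %g..%g ps\n",
              n_frames(x), dim(x$coords)[2], min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `Trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame of a trajectory as a coordinate matrix
#' @param traj a `Trajectory`.
#' @param i frame index.
#' @return n_atoms x 3 matrix, nm.
#' @export
frame_coords <- function(traj, i) {
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  colnames(m) <- c("x", "y", "z")
  m
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; the first model supplies
#' the topology. Files without MODEL records yield a 1-frame trajectory.
#'
#' @inheritParams read_pdb
#' @param dt_ps frame spacing in ps used to synthesise timestamps
#'   (the format itself carries none).
#' @return a `Trajectory`.
#' @export
read_multimodel_pdb <- function(text, dt_ps = 1) {
  lines <- as_text_lines(text)
  starts <- which(grepl("^MODEL", lines))
  if (length(starts) == 0L) {
    s <- read_pdb(lines)
    return(new_trajectory(array(s$xyz, c(1L, n_atoms(s), 3L)), 0, s))
  }
  ends <- which(grepl("^ENDMDL", lines))
  if (length(ends) != length(starts)) stop("unbalanced MODEL/ENDMDL records")
  frames <- lapply(seq_along(starts), function(k) {
    blk <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    read_pdb(blk)
  })
  topo <- frames[[1L]]
  nat <- n_atoms(topo)
  coords <- array(NA_real_, c(length(frames), nat, 3L))
  for (k in seq_along(frames)) {
    if (n_atoms(frames[[k]]) != nat)
      stop(sprintf("model %d has %d atoms; expected %d",
                   k, n_atoms(frames[[k]]), nat))
    coords[k, , ] <- frames[[k]]$xyz
  }
  new_trajectory(coords, (seq_along(frames) - 1) * dt_ps, topo)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a `Trajectory`.
#' @param path optional output path.
#' @return PDB text, invisibly when writing to a file.
#' @export
write_multimodel_pdb <- function(traj, path = NULL) {
  txt <- unlist(lapply(seq_len(n_frames(traj)), function(k) {
    c(sprintf("MODEL     %4d", k),
      format_atom_line(traj$topology$atoms, frame_coords(traj, k)),
      "ENDMDL")
  }))
  txt <- c(txt, "END")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a plain-text XYZ-per-frame trajectory
#'
#' Dialect: each frame is a header line `natoms time_ps` followed by
#' `natoms` lines of `x y z` in nm.
#'
#' @param text file path or text.
#' @param topology a `Structure` with matching atom count; when `NULL` a
#'   minimal carbon topology is synthesised.
#' @return a `Trajectory`.
#' @export
read_xyz_trajectory <- function(text, topology = NULL) {
  lines <- as_text_lines(text)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  frames <- list(); times <- numeric(); i <- 1L
  while (i <= length(lines)) {
    hdr <- scan(text = lines[i], quiet = TRUE)
    if (length(hdr) != 2L)
      stop(sprintf("bad frame header at record %d", i))
    nat <- as.integer(hdr[1])
    if (i + nat > length(lines)) stop("truncated trajectory frame")
    block <- scan(text = lines[(i + 1L):(i + nat)], quiet = TRUE)
    frames[[length(frames) + 1L]] <- matrix(block, nat, 3L, byrow = TRUE)
    times <- c(times, hdr[2])
    i <- i + nat + 1L
  }
  nat <- nrow(frames[[1L]])
  if (is.null(topology)) topology <- dummy_topology(nat)
  coords <- array(NA_real_, c(length(frames), nat, 3L))
  for (k in seq_along(frames)) coords[k, , ] <- frames[[k]]
  new_trajectory(coords, times, topology)
}

#' Write a trajectory in the plain-text XYZ-per-frame dialect
#'
#' @param traj a `Trajectory`.
#' @param path optional output path.
#' @return the text, invisibly when writing to a file.
#' @export
write_xyz_trajectory <- function(traj, path = NULL) {
  nat <- dim(traj$coords)[2]
  txt <- unlist(lapply(seq_len(n_frames(traj)), function(k) {
    m <- frame_coords(traj, k)
    c(sprintf("%d %.6f", nat, traj$times[k]),
      sprintf("%.9f %.9f %.9f", m[, 1], m[, 2], m[, 3]))
  }))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

dummy_topology <- function(nat, resid = seq_len(nat)) {
  new_structure(
    data.frame(serial = seq_len(nat), name = "CA", resid = resid,
               resname = "GLY", chain = "A", element = "C", het = FALSE,
               stringsAsFactors = FALSE),
    matrix(0, nat, 3L), "toy")
}

#' Construct an atom selection
#'
#' @param indices integer indices into the owning structure's atom list;
#'   must be unique and in range when `n` is given.
#' @param label descriptive label.
#' @param n optional atom count of the owning structure, for range checks.
#' @return object of class `Selection`.
#' @export
new_selection <- function(indices, label = "selection", n = NULL) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("selection indices must be unique")
  if (!is.null(n) && length(indices) > 0L &&
      (min(indices) < 1L || max(indices) > n))
    stop("selection index out of range")
  structure(list(indices = indices, label = label), class = "Selection")
}

#' @export
print.Selection <- function(x, ...) {
  cat(sprintf("Selection '%s': %d atoms\n", x$label, length(x$indices)))
  invisible(x)
}

sel_indices <- function(sel, n) {
  if (is.null(sel)) return(seq_len(n))
  if (inherits(sel, "Selection")) return(sel$indices)
  as.integer(sel)
}

#' Select atoms by residue-number ranges
#'
#' Inclusive, 1-based residue intervals; atoms are returned in file order
#' and each atom at most once even when intervals overlap. An interval
#' that selects nothing is an error, guarding against residue-numbering
#' drift between structures.
#'
#' @param s a `Structure`.
#' @param ranges a list of `c(lo, hi)` residue intervals (a single
#'   interval may be given directly), or an n x 2 matrix.
#' @param backbone_only keep only backbone atoms (N, CA, C, O)?
#' @param chain optional chain identifier to scope the selection; by
#'   default all chains (single-chain files need no scoping).
#' @param label label for the selection.
#' @return a `Selection`.
#' @export
select_residues <- function(s, ranges, backbone_only = FALSE,
                            chain = NULL, label = NULL) {
  if (is.matrix(ranges)) ranges <- split(ranges, row(ranges)[, 1])
  if (is.numeric(ranges) && length(ranges) == 2L) ranges <- list(ranges)
  ok_chain <- if (is.null(chain)) rep(TRUE, n_atoms(s))
              else s$atoms$chain == chain
  ok_bb <- if (backbone_only) s$atoms$is_backbone else rep(TRUE, n_atoms(s))
  hit <- rep(FALSE, n_atoms(s))
  for (r in ranges) {
    if (length(r) != 2L || r[1] > r[2]) stop("each range must be c(lo, hi)")
    this <- s$atoms$resid >= r[1] & s$atoms$resid <= r[2] & ok_chain & ok_bb
    if (!any(this))
      stop(sprintf("residue range %d-%d selects zero atoms", r[1], r[2]))
    hit <- hit | this
  }
  if (is.null(label))
    label <- paste(vapply(ranges, function(r) sprintf("%d-%d", r[1], r[2]),
                          ""), collapse = ",")
  new_selection(which(hit), label, n = n_atoms(s))
}

frame_matrix <- function(frame) {
  if (inherits(frame, "Structure")) return(frame$xyz)
  as.matrix(frame)
}

#' Center of mass of a selection
#'
#' @param frame a `Structure`, or an n x 3 coordinate matrix (nm).
#' @param sel a `Selection` (or integer indices); `NULL` selects all
#'   atoms.
#' @param mass_weighted use standard atomic masses (default)? Otherwise
#'   the unweighted geometric mean. Mass weighting needs `topology` when
#'   `frame` is a bare matrix.
#' @param topology `Structure` supplying elements for bare matrices.
#' @return length-3 numeric vector, nm.
#' @export
center_of_mass <- function(frame, sel = NULL, mass_weighted = TRUE,
                           topology = NULL) {
  xyz <- frame_matrix(frame)
  idx <- sel_indices(sel, nrow(xyz))
  if (length(idx) == 0L) stop("empty selection in center_of_mass")
  if (mass_weighted) {
    topo <- if (inherits(frame, "Structure")) frame else topology
    if (is.null(topo)) stop("mass-weighted COM of a bare matrix needs a topology")
    w <- atom_masses(topo)[idx]
  } else {
    w <- rep(1, length(idx))
  }
  drop(crossprod(xyz[idx, , drop = FALSE], w) / sum(w))
}

#' Kabsch least-squares rigid-body superposition
#'
#' Finds the proper rotation (determinant +1; reflections suppressed) and
#' translation minimising the RMSD of `mobile` onto `reference` over the
#' fit atoms, and applies it to all of `mobile`.
#'
#' @param mobile,reference n x 3 coordinate matrices or `Structure`s with
#'   equal atom counts over the fit set.
#' @param fit_sel `Selection`/indices defining the fit atoms (default:
#'   all). At least 3 non-collinear atoms are required.
#' @return list with `rotation` (3 x 3), `translation` (length 3),
#'   `coords` (transformed mobile), and `rmsd` over the fit atoms (nm).
#' @export
kabsch_superpose <- function(mobile, reference, fit_sel = NULL) {
  xm <- frame_matrix(mobile); xr <- frame_matrix(reference)
  idx <- sel_indices(fit_sel, nrow(xm))
  if (length(idx) < 3L) stop("need at least 3 fit atoms")
  pm <- xm[idx, , drop = FALSE]; pr <- xr[idx, , drop = FALSE]
  if (nrow(pm) != nrow(pr)) stop("fit sets differ in atom count")
  cm <- colMeans(pm); cr <- colMeans(pr)
  pm0 <- sweep(pm, 2, cm); pr0 <- sweep(pr, 2, cr)
  sv_fit <- svd(pm0)$d
  if (sv_fit[2] < 1e-9 * max(sv_fit[1], 1e-12))
    stop("degenerate (collinear) fit set in kabsch_superpose")
  h <- crossprod(pm0, pr0)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- cr - drop(rot %*% cm)
  coords <- sweep(xm %*% t(rot), 2, trans, "+")
  fit_rmsd <- sqrt(mean(rowSums((coords[idx, , drop = FALSE] - pr)^2)))
  list(rotation = rot, translation = trans, coords = coords,
       rmsd = fit_rmsd)
}

#' Root-mean-square deviation between two coordinate sets
#'
#' @param a,b n x 3 matrices or `Structure`s with equal atom counts over
#'   `sel`.
#' @param sel `Selection`/indices; `NULL` uses all atoms.
#' @param superpose Kabsch-fit `a` onto `b` over `sel` first?
#' @return RMSD in nm.
#' @export
rmsd <- function(a, b, sel = NULL, superpose = FALSE) {
  xa <- frame_matrix(a); xb <- frame_matrix(b)
  idx <- sel_indices(sel, nrow(xa))
  if (length(idx) < 1L) stop("empty selection in rmsd")
  if (max(idx) > nrow(xa) || max(idx) > nrow(xb))
    stop("selection exceeds coordinate set")
  if (superpose) xa <- kabsch_superpose(xa, xb, idx)$coords
  pa <- xa[idx, , drop = FALSE]; pb <- xb[idx, , drop = FALSE]
  if (nrow(pa) != nrow(pb)) stop("mismatched atom counts in rmsd")
  sqrt(mean(rowSums((pa - pb)^2)))
}

#' Per-atom root-mean-square fluctuation
#'
#' RMS deviation of each selected atom from its time-mean position.
#' Frames are assumed pre-aligned; superpose the trajectory first if
#' overall motion should be removed.
#'
#' @param traj a `Trajectory` with at least 2 frames.
#' @param sel `Selection`/indices; `NULL` uses all atoms.
#' @return numeric vector of per-atom fluctuations, nm.
#' @export
rmsf <- function(traj, sel = NULL) {
  if (n_frames(traj) < 2L) stop("rmsf needs at least 2 frames")
  idx <- sel_indices(sel, dim(traj$coords)[2])
  sub <- traj$coords[, idx, , drop = FALSE]
  mu <- apply(sub, c(2, 3), mean)
  dev2 <- sweep(sub, c(2, 3), mu)^2
  sqrt(apply(dev2, 2, mean) * 3)  # mean over frames of summed sq coords
}
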