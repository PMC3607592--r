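#' Two-rigid-domain model of a clamshell protein
#'
#' Declares which atoms form the two rigid lobes and the flexible hinge,
#' plus (optionally) a reference structure whose per-domain geometry is
#' taken as the rigid "optimized" shape. For iGluR2-like numbering the
#' lobes are residues 394-495 + 732-771 (domain 1) and 500-728
#' (domain 2), hinged at 496-499 and 729-731.
#'
#' @param dom1,dom2,hinge disjoint `Selection`s.
#' @param reference optional `Structure` supplying the rigid domain
#'   shapes; when `NULL`, the per-domain time average of the analysed
#'   trajectory is used.
#' @return object of class `RigidBodyModel`.
#' @export
rigid_body_model <- function(dom1, dom2, hinge, reference = NULL) {
  idx <- c(dom1$indices, dom2$indices, hinge$indices)
  if (anyDuplicated(idx))
    stop("dom1, dom2 and hinge selections must be disjoint")
  structure(list(dom1 = dom1, dom2 = dom2, hinge = hinge,
                 reference = reference),
            class = "RigidBodyModel")
}

domain_average_reference <- function(traj, model) {
  # per-domain time average after superposing every frame's domain onto
  # the first frame; the average is then the rigid "optimized" shape
  topo <- traj$topology
  xyz <- frame_coords(traj, 1L)
  for (dom in list(model$dom1, model$dom2)) {
    idx <- dom$indices
    ref <- frame_coords(traj, 1L)[idx, , drop = FALSE]
    acc <- matrix(0, length(idx), 3L)
    for (i in seq_len(n_frames(traj))) {
      fi <- frame_coords(traj, i)[idx, , drop = FALSE]
      acc <- acc + kabsch_superpose(fi, ref)$coords
    }
    xyz[idx, ] <- acc / n_frames(traj)
  }
  new_structure(topo$atoms, xyz, paste0(topo$label, "_domain_avg"))
}

#' Replace internal domain motion by rigid reference domains
#'
#' For each frame and each lobe independently, the reference domain is
#' Kabsch-fit onto that frame's domain atoms and substituted, so the
#' output trajectory carries only rigid-body (interdomain) motion of the
#' lobes; hinge atoms pass through unchanged. This is the preprocessing
#' step that makes the subsequent PCA a rigid-body PCA.
#'
#' @param traj a `Trajectory`.
#' @param model a `RigidBodyModel`; a `NULL` reference is replaced by the
#'   per-domain trajectory average.
#' @return a `Trajectory` with identical times and topology.
#' @export
strip_internal_motion <- function(traj, model) {
  ref <- model$reference
  if (is.null(ref)) ref <- domain_average_reference(traj, model)
  out <- traj$coords
  for (dname in c("dom1", "dom2")) {
    idx <- model[[dname]]$indices
    refd <- ref$xyz[idx, , drop = FALSE]
    for (i in seq_len(n_frames(traj))) {
      tgt <- frame_coords(traj, i)[idx, , drop = FALSE]
      fit <- tryCatch(kabsch_superpose(refd, tgt),
                      error = function(e)
                        stop(sprintf("degenerate fit in frame %d, %s: %s",
                                     i, dname, conditionMessage(e)),
                             call. = FALSE))
      out[i, idx, ] <- fit$coords
    }
  }
  new_trajectory(out, traj$times, traj$topology)
}

analysis_indices <- function(traj, model, backbone_only = TRUE) {
  idx <- sort(c(model$dom1$indices, model$dom2$indices,
                model$hinge$indices))
  if (backbone_only) {
    bb <- which(traj$topology$atoms$is_backbone)
    keep <- idx %in% bb
    if (any(keep)) idx <- idx[keep]
  }
  idx
}

align_frames <- function(traj, align_idx, ref_xyz) {
  if (is.null(align_idx)) return(traj$coords)
  out <- traj$coords
  for (i in seq_len(n_frames(traj))) {
    out[i, , ] <- kabsch_superpose(frame_coords(traj, i), ref_xyz,
                                   align_idx)$coords
  }
  out
}

#' Rigid-body principal component analysis
#'
#' Diagonalises the covariance of the 3N Cartesian coordinates of the
#' backbone atoms of both lobes plus the hinge, after (optionally)
#' stripping internal domain motion and globally superposing every frame
#' on `align_sel` (default: domain 1) to remove overall
#' rotation/translation. For two-lobe proteins the three leading modes
#' are the clamshell (opening/closing), twisting and rocking motions.
#'
#' Mode signs are deterministic: mode 1 is oriented so its projection
#' increases with the interdomain angle; other modes are oriented so
#' their largest-magnitude component is positive.
#'
#' @param traj a `Trajectory` with at least 2 frames.
#' @param model a `RigidBodyModel`.
#' @param align_sel `Selection` used for the global superposition
#'   (default the model's domain 1); `"none"` analyses the raw
#'   coordinates without removing overall rotation/translation (for
#'   trajectories that carry none, e.g. planted-mode fixtures).
#' @param strip run [strip_internal_motion()] first (default `TRUE`; set
#'   `FALSE` when the trajectory is already stripped)?
#' @param backbone_only restrict the analysed atoms to backbone (default)?
#' @return object of class `PCAResult` with fields `mean_coordinates`
#'   (n_sel x 3, nm), `eigenvectors` (3N x k, orthonormal columns),
#'   `eigenvalues` (nm^2, descending), `mode_labels`, `atom_indices`,
#'   and the alignment bookkeeping needed by [project_onto_modes()].
#' @export
rigid_pca <- function(traj, model, align_sel = NULL, strip = TRUE,
                      backbone_only = TRUE) {
  if (n_frames(traj) < 2L) stop("rigid_pca needs at least 2 frames")
  if (strip) traj <- strip_internal_motion(traj, model)
  if (is.null(align_sel)) align_sel <- model$dom1
  align_idx <- if (identical(align_sel, "none")) NULL
               else sel_indices(align_sel, dim(traj$coords)[2])
  ref_xyz <- frame_coords(traj, 1L)
  coords <- align_frames(traj, align_idx, ref_xyz)
  idx <- analysis_indices(traj, model, backbone_only)
  nt <- n_frames(traj); na <- length(idx)
  x <- matrix(coords[, idx, ], nt, 3L * na)  # columns: atom-major per axis
  mu <- colMeans(x)
  x0 <- sweep(x, 2, mu)
  sv <- svd(x0, nu = 0)
  eigenvalues <- sv$d^2 / (nt - 1)
  k <- sum(sv$d > max(sv$d[1], 1e-30) * 1e-10)
  k <- max(k, 1L)
  vecs <- sv$v[, seq_len(k), drop = FALSE]
  eigenvalues <- eigenvalues[seq_len(k)]
  labels <- c("clamshell", "twisting", "rocking")
  labels <- c(labels[seq_len(min(3L, k))],
              if (k > 3L) paste0("mode", 4:k))
  pca <- structure(list(
    mean_coordinates = matrix(mu, na, 3L),
    eigenvectors = vecs, eigenvalues = eigenvalues,
    mode_labels = labels, atom_indices = idx,
    align_indices = align_idx, reference_frame = ref_xyz,
    model = model, stripped = strip
  ), class = "PCAResult")
  fix_mode_signs(pca, traj)
}

fix_mode_signs <- function(pca, traj) {
  proj <- project_matrix(traj, pca, strip = FALSE)
  ang <- tryCatch(
    vapply(seq_len(n_frames(traj)), function(i)
      interdomain_angle(frame_coords(traj, i), pca$model$dom1,
                        pca$model$dom2, pca$model$hinge,
                        topology = traj$topology),
      numeric(1)),
    error = function(e) NULL)
  for (m in seq_len(ncol(pca$eigenvectors))) {
    flip <- FALSE
    if (m == 1L && !is.null(ang) && stats::sd(ang) > 1e-9 &&
        stats::sd(proj[, 1L]) > 1e-12) {
      flip <- stats::cor(proj[, 1L], ang) < 0
    } else {
      i <- which.max(abs(pca$eigenvectors[, m]))
      flip <- pca$eigenvectors[i, m] < 0
    }
    if (flip) pca$eigenvectors[, m] <- -pca$eigenvectors[, m]
  }
  pca
}

project_matrix <- function(traj, pca, strip = NULL) {
  if (is.null(strip)) strip <- pca$stripped
  if (strip) traj <- strip_internal_motion(traj, pca$model)
  if (dim(traj$coords)[2] < max(pca$atom_indices))
    stop("trajectory topology does not match the PCA result")
  coords <- align_frames(traj, pca$align_indices, pca$reference_frame)
  nt <- n_frames(traj)
  x <- matrix(coords[, pca$atom_indices, ], nt,
              3L * length(pca$atom_indices))
  sweep(x, 2, as.vector(pca$mean_coordinates)) %*% pca$eigenvectors
}

#' Project a trajectory onto PCA modes
#'
#' Per-frame dot product of the (aligned, mean-subtracted) coordinates
#' with each eigenvector — the collective-variable time series CV1..CVn
#' used to drive or analyse metadynamics.
#'
#' @param traj a `Trajectory` compatible with the PCA topology.
#' @param pca a `PCAResult`.
#' @param n_modes number of leading modes to project on.
#' @return list of `ColvarSeries`, one per mode, in nm (displacement
#'   along the unit 3N-mode).
#' @export
project_onto_modes <- function(traj, pca, n_modes = 3L) {
  if (n_modes > ncol(pca$eigenvectors))
    stop("n_modes exceeds the number of available modes")
  proj <- project_matrix(traj, pca)
  lapply(seq_len(n_modes), function(m)
    colvar_series(pca$mode_labels[m], traj$times, proj[, m]))
}

subset_structure <- function(s, idx, label = s$label) {
  new_structure(s$atoms[idx, , drop = FALSE],
                s$xyz[idx, , drop = FALSE], label)
}

#' Arrow-representation structures for a PCA mode
#'
#' Returns the mean structure displaced by plus and minus `scale` along
#' the unit mode — the pair conventionally rendered as arrows or as a
#' two-model PDB movie of the eigenmotion.
#'
#' @param pca a `PCAResult`.
#' @param topology the `Structure` the PCA was computed on.
#' @param mode mode index.
#' @param scale displacement amplitude along the unit mode, nm; must be
#'   positive.
#' @return list with `plus` and `minus` (`Structure`s over the analysed
#'   atoms) and `trajectory` (a 2-frame `Trajectory` ready for
#'   [write_multimodel_pdb()]).
#' @export
export_mode_arrows <- function(pca, topology, mode = 1L, scale = 0.1) {
  if (scale <= 0) stop("scale must be positive")
  if (mode < 1L || mode > ncol(pca$eigenvectors))
    stop("invalid mode index")
  na <- length(pca$atom_indices)
  disp <- matrix(pca$eigenvectors[, mode], na, 3L) * scale
  topo <- subset_structure(topology, pca$atom_indices)
  plus <- new_structure(topo$atoms, pca$mean_coordinates + disp,
                        paste0("mode", mode, "_plus"))
  minus <- new_structure(topo$atoms, pca$mean_coordinates - disp,
                         paste0("mode", mode, "_minus"))
  coords <- array(NA_real_, c(2L, na, 3L))
  coords[1L, , ] <- plus$xyz; coords[2L, , ] <- minus$xyz
  list(plus = plus, minus = minus,
       trajectory = new_trajectory(coords, c(0, 1), topo))
}

#' Serialize a PCA result as plain text
#'
#' Layout: a header with atom count and mode count, the eigenvalues, the
#' mean coordinates (3 columns per atom), then one block per eigenvector.
#'
#' @param pca a `PCAResult`.
#' @param path optional output path.
#' @return text lines, invisibly when writing to a file.
#' @export
write_pca_result <- function(pca, path = NULL) {
  na <- length(pca$atom_indices); k <- ncol(pca$eigenvectors)
  txt <- c(sprintf("# rigid-body PCA: %d atoms, %d modes", na, k),
           paste("atoms", na), paste("modes", k),
           paste("atom_indices", paste(pca$atom_indices, collapse = " ")),
           paste("eigenvalues", paste(sprintf("%.12g", pca$eigenvalues),
                                      collapse = " ")),
           paste("labels", paste(pca$mode_labels, collapse = " ")),
           "mean",
           sprintf("%.10f %.10f %.10f", pca$mean_coordinates[, 1],
                   pca$mean_coordinates[, 2], pca$mean_coordinates[, 3]))
  for (m in seq_len(k)) {
    v <- matrix(pca$eigenvectors[, m], na, 3L)
    txt <- c(txt, sprintf("mode %d", m),
             sprintf("%.12g %.12g %.12g", v[, 1], v[, 2], v[, 3]))
  }
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a PCA result written by [write_pca_result()]
#'
#' @param text file path or text lines.
#' @return a `PCAResult` (analysis fields only; alignment bookkeeping for
#'   re-projection is not serialized).
#' @export
read_pca_result <- function(text) {
  lines <- as_text_lines(text)
  lines <- lines[!grepl("^#", lines)]
  take <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)[1L]
    strsplit(trimws(sub(paste0("^", key), "", ln)), "\\s+")[[1L]]
  }
  na <- as.integer(take("atoms")); k <- as.integer(take("modes"))
  eigenvalues <- as.numeric(take("eigenvalues"))
  labels <- take("labels")
  idx <- as.integer(take("atom_indices"))
  mean_start <- which(lines == "mean")[1L] + 1L
  mu <- matrix(scan(text = lines[mean_start:(mean_start + na - 1L)],
                    quiet = TRUE), na, 3L, byrow = TRUE)
  vecs <- matrix(NA_real_, 3L * na, k)
  for (m in seq_len(k)) {
    st <- which(lines == sprintf("mode %d", m))[1L] + 1L
    v <- matrix(scan(text = lines[st:(st + na - 1L)], quiet = TRUE),
                na, 3L, byrow = TRUE)
    vecs[, m] <- as.vector(v)
  }
  structure(list(mean_coordinates = mu, eigenvectors = vecs,
                 eigenvalues = eigenvalues, mode_labels = labels,
                 atom_indices = idx),
            class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  k <- min(3L, length(x$eigenvalues))
  cat(sprintf("PCAResult: %d atoms, %d modes; leading eigenvalues (nm^2): %s\n",
              length(x$atom_indices), length(x$eigenvalues),
              paste(sprintf("%.4g", x$eigenvalues[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}
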