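#' Collective-variable specification
#'
#' Bundles a CV kind with the selections and parameters it needs, for
#' evaluation over trajectories with [colvar_timeseries()]. Supported
#' kinds mirror the reaction coordinates used for clamshell
#' ligand-binding domains: the domain-closure pair distance, the
#' in-plane ligand dissociation distance, the interdomain angle and
#' torsion, and projections on rigid-body PCA modes.
#'
#' @param kind one of `"pair_com_distance"`, `"projected_site_distance"`,
#'   `"interdomain_angle"`, `"interdomain_torsion"`, `"pca_projection"`.
#' @param selections named list of `Selection`s as required by the kind.
#' @param parameters kind-specific parameters (e.g. `plane_normal`,
#'   `pca`, `mode`, `mass_weighted`).
#' @param name name carried into the resulting series.
#' @return object of class `ColvarSpec`.
#' @export
colvar_spec <- function(kind = c("pair_com_distance",
                                 "projected_site_distance",
                                 "interdomain_angle",
                                 "interdomain_torsion",
                                 "pca_projection"),
                        selections = list(), parameters = list(),
                        name = NULL) {
  kind <- match.arg(kind)
  for (s in selections)
    if (inherits(s, "Selection") && length(s$indices) == 0L)
      stop("all selections referenced by a ColvarSpec must be non-empty")
  structure(list(kind = kind, selections = selections,
                 parameters = parameters,
                 name = if (is.null(name)) kind else name),
            class = "ColvarSpec")
}

#' Time series of a collective variable
#'
#' @param name CV name.
#' @param times timestamps, ps.
#' @param values CV values (nm or degrees depending on the CV).
#' @return object of class `ColvarSeries`.
#' @export
colvar_series <- function(name, times, values) {
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have the same length")
  if (!all(is.finite(values))) stop("non-finite CV values")
  structure(list(name = name, times = as.numeric(times), values = values),
            class = "ColvarSeries")
}

#' @export
print.ColvarSeries <- function(x, ...) {
  cat(sprintf("ColvarSeries '%s': %d points, range [%.4g, %.4g]\n",
              x$name, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Center-of-mass distance between two selections
#'
#' The domain-closure reaction coordinate: the COM distance between the
#' backbone atoms of a residue on each lobe (for iGluR2-like numbering,
#' Gly451 on lobe 1 and Ser652 on lobe 2 flank the binding cleft opposite
#' the hinge).
#'
#' @param frame `Structure` or n x 3 coordinate matrix (nm).
#' @param selA,selB non-empty `Selection`s.
#' @param mass_weighted mass-weight the COMs (default)?
#' @param topology topology for bare coordinate matrices.
#' @return distance in nm.
#' @export
pair_com_distance <- function(frame, selA, selB, mass_weighted = TRUE,
                              topology = NULL) {
  a <- center_of_mass(frame, selA, mass_weighted, topology)
  b <- center_of_mass(frame, selB, mass_weighted, topology)
  sqrt(sum((a - b)^2))
}

#' In-plane (projected) ligand-site distance
#'
#' Distance between the ligand COM and the binding-site COM after
#' projecting both onto the plane orthogonal to `plane_normal`. With the
#' receptor oriented so its two lobes stack along z, the default normal
#' `c(0,0,1)` yields the XY-plane dissociation coordinate; displacement
#' purely along the normal contributes nothing.
#'
#' @inheritParams pair_com_distance
#' @param ligand_sel,site_sel non-empty `Selection`s.
#' @param plane_normal non-zero 3-vector normal of the projection plane.
#' @return in-plane distance, nm.
#' @export
projected_site_distance <- function(frame, ligand_sel, site_sel,
                                    plane_normal = c(0, 0, 1),
                                    mass_weighted = TRUE, topology = NULL) {
  nn <- sqrt(sum(plane_normal^2))
  if (nn == 0) stop("plane_normal must be non-zero")
  u <- plane_normal / nn
  d <- center_of_mass(frame, ligand_sel, mass_weighted, topology) -
       center_of_mass(frame, site_sel, mass_weighted, topology)
  d_in_plane <- d - sum(d * u) * u
  sqrt(sum(d_in_plane^2))
}

#' Interdomain angle at the hinge
#'
#' Angle at the hinge-COM vertex between the rays to the two domain COMs,
#' in degrees within [0, 180]. This is the clamshell opening descriptor:
#' closed complexes sit near 100-112 degrees, the apo protein opens to
#' about 140 degrees.
#'
#' @inheritParams pair_com_distance
#' @param dom1,dom2,hinge non-empty `Selection`s for the two rigid lobes
#'   and the flexible hinge.
#' @return angle in degrees.
#' @export
interdomain_angle <- function(frame, dom1, dom2, hinge,
                              mass_weighted = TRUE, topology = NULL) {
  c1 <- center_of_mass(frame, dom1, mass_weighted, topology)
  c2 <- center_of_mass(frame, dom2, mass_weighted, topology)
  ch <- center_of_mass(frame, hinge, mass_weighted, topology)
  v1 <- c1 - ch; v2 <- c2 - ch
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-12 || n2 < 1e-12)
    stop("hinge COM coincides with a domain COM")
  ct <- sum(v1 * v2) / (n1 * n2)
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Interdomain torsion about the hinge axis
#'
#' Signed dihedral dom1COM - hingeTopCOM - hingeBottomCOM - dom2COM in
#' (-180, 180] degrees, right-hand rule about the hinge axis: the twist
#' descriptor of the two-lobe motion.
#'
#' @inheritParams pair_com_distance
#' @param dom1,hinge_top,hinge_bottom,dom2 non-empty `Selection`s; the
#'   two hinge selections define the rotatable axis and must not
#'   coincide.
#' @return signed torsion in degrees, (-180, 180].
#' @export
interdomain_torsion <- function(frame, dom1, hinge_top, hinge_bottom,
                                dom2, mass_weighted = TRUE,
                                topology = NULL) {
  p1 <- center_of_mass(frame, dom1, mass_weighted, topology)
  p2 <- center_of_mass(frame, hinge_top, mass_weighted, topology)
  p3 <- center_of_mass(frame, hinge_bottom, mass_weighted, topology)
  p4 <- center_of_mass(frame, dom2, mass_weighted, topology)
  dihedral_angle(p1, p2, p3, p4)
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sum(b2^2) < 1e-24) stop("degenerate hinge axis (coincident COMs)")
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-24 || sum(n2^2) < 1e-24)
    stop("degenerate (collinear) points in torsion")
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  # sign: positive = right-hand rotation of the far half-plane about the
  # p2 -> p3 axis (negated praxeolitic atan2)
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

eval_colvar_frame <- function(xyz, spec, topology) {
  s <- spec$selections; p <- spec$parameters
  mw <- if (is.null(p$mass_weighted)) TRUE else p$mass_weighted
  switch(spec$kind,
    pair_com_distance = pair_com_distance(xyz, s$a, s$b, mw, topology),
    projected_site_distance = {
      normal <- if (is.null(p$plane_normal)) c(0, 0, 1) else p$plane_normal
      projected_site_distance(xyz, s$ligand, s$site, normal, mw, topology)
    },
    interdomain_angle = interdomain_angle(xyz, s$dom1, s$dom2, s$hinge,
                                          mw, topology),
    interdomain_torsion = interdomain_torsion(xyz, s$dom1, s$hinge_top,
                                              s$hinge_bottom, s$dom2,
                                              mw, topology),
    pca_projection = stop("use project_onto_modes() for pca_projection series"),
    stop("unknown colvar kind: ", spec$kind)
  )
}

#' Evaluate a collective variable along a trajectory
#'
#' For the dissociation coordinate (`projected_site_distance`) each frame
#' is first superposed onto the reference frame over the site selection,
#' emulating the removal of overall receptor rotation/translation during
#' biased sampling; supply `parameters$align = FALSE` to disable.
#'
#' @param traj a `Trajectory`.
#' @param spec a `ColvarSpec` valid for the trajectory's topology.
#' @return a `ColvarSeries`, one value per frame.
#' @export
colvar_timeseries <- function(traj, spec) {
  topo <- traj$topology
  align <- isTRUE(spec$kind == "projected_site_distance") &&
    !isFALSE(spec$parameters$align)
  ref <- frame_coords(traj, 1L)
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    xyz <- frame_coords(traj, i)
    if (align)
      xyz <- kabsch_superpose(xyz, ref, spec$selections$site)$coords
    v <- tryCatch(eval_colvar_frame(xyz, spec, topo),
                  error = function(e)
                    stop(sprintf("frame %d: %s", i, conditionMessage(e)),
                         call. = FALSE))
    v
  }, numeric(1))
  colvar_series(spec$name, traj$times, vals)
}

#' Write a collective-variable series as two-column text
#'
#' The dialect (a `#` header naming the CV, then `time_ps value` rows) is
#' the same one consumed by the umbrella-sampling reader and is
#' column-compatible with PLUMED COLVAR files.
#'
#' @param series a `ColvarSeries`.
#' @param path optional output path.
#' @return the text lines, invisibly when writing to a file.
#' @export
write_colvar <- function(series, path = NULL) {
  txt <- c(sprintf("# time_ps %s", series$name),
           sprintf("%.6f %.10g", series$times, series$values))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a two-column collective-variable series
#'
#' @param text file path or text in the [write_colvar()] dialect.
#' @return a `ColvarSeries`.
#' @export
read_colvar <- function(text) {
  lines <- as_text_lines(text)
  name <- "cv"
  hdr <- grep("^#", lines, value = TRUE)
  if (length(hdr) > 0L) {
    toks <- strsplit(trimws(sub("^#", "", hdr[1L])), "\\s+")[[1L]]
    if (length(toks) >= 2L) name <- toks[2L]
  }
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty colvar file")
  m <- matrix(scan(text = lines, quiet = TRUE), ncol = 2, byrow = TRUE)
  colvar_series(name, m[, 1], m[, 2])
}
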