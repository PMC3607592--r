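#' Boltzmann constant in kcal/mol/K
#' @export
KB_KCAL <- 0.0019872041

#' Thermal energy kT in kcal/mol
#' @param temperature temperature in K.
#' @return kT in kcal/mol (0.596 at 300 K).
#' @export
kT_kcal <- function(temperature = 300) KB_KCAL * temperature

new_potential <- function(kernel, planted = list()) {
  kernel$centers <- as.matrix(kernel$centers)
  kernel$sigmas <- as.matrix(kernel$sigmas)
  if (is.null(kernel$wall_k)) kernel$wall_k <- 0
  if (is.null(kernel$wall_lo)) kernel$wall_lo <- rep(-1e9, kernel$d)
  if (is.null(kernel$wall_hi)) kernel$wall_hi <- rep(1e9, kernel$d)
  structure(list(dimension = kernel$d, kernel = kernel,
                 planted = planted),
            class = "AnalyticPotential")
}

as_point_matrix <- function(x, d) {
  if (is.matrix(x)) {
    if (ncol(x) != d) stop("point dimension mismatch")
    return(x)
  }
  if (d == 1L) return(matrix(as.numeric(x), ncol = 1L))
  matrix(as.numeric(x), ncol = d, byrow = TRUE)
}

#' Evaluate an analytic potential
#'
#' @param pot an `AnalyticPotential`.
#' @param x a point (length-d vector), many points (matrix with d
#'   columns), or for 1D potentials a plain numeric vector of positions.
#' @return potential values, kcal/mol.
#' @export
potential_value <- function(pot, x) {
  cpp_potential_value(pot$kernel, as_point_matrix(x, pot$dimension))
}

#' Gradient of an analytic potential
#'
#' @inheritParams potential_value
#' @return matrix of gradients (kcal/mol/nm), one row per point; dropped
#'   to a vector for 1D potentials.
#' @export
potential_gradient <- function(pot, x) {
  g <- cpp_potential_gradient(pot$kernel, as_point_matrix(x, pot$dimension))
  if (pot$dimension == 1L) drop(g) else g
}

#' @export
print.AnalyticPotential <- function(x, ...) {
  cat(sprintf("AnalyticPotential (%dD): %d Gaussian wells%s\n",
              x$dimension, nrow(x$kernel$centers),
              if (any(x$kernel$hk > 0)) " + harmonic term" else ""))
  invisible(x)
}

#' Harmonic potential
#'
#' U(x) = 1/2 k (x - x0)^2, the standard validation case: equilibrium
#' sampling has variance kT/k and the PMF is the potential itself.
#'
#' @param k force constant, kcal/mol/nm^2 (per dimension).
#' @param x0 minimum position, nm.
#' @return an `AnalyticPotential`.
#' @export
harmonic_potential <- function(k = 20, x0 = 0.75) {
  d <- max(length(k), length(x0))
  k <- rep_len(k, d); x0 <- rep_len(x0, d)
  new_potential(list(d = d, hk = k, hx0 = x0,
                     centers = matrix(0, 0, d), depths = numeric(),
                     sigmas = matrix(0, 0, d)),
                planted = list(k = k, x0 = x0))
}

#' General sum-of-Gaussian-wells potential
#'
#' U(x) = harmonic term - sum of Gaussian wells. The building block for
#' the double- and triple-well landscapes: with wells separated by
#' several widths, each minimum sits at its well center with depth equal
#' to the well amplitude, so asymmetries are planted exactly.
#'
#' @param centers well centers: m x d matrix (or vector for 1D).
#' @param depths well depths, kcal/mol (positive; wells are attractive).
#' @param sigmas per-well, per-dimension Gaussian widths, nm.
#' @param harmonic_k,harmonic_x0 optional confining harmonic term.
#' @param walls optional half-harmonic confining walls,
#'   `list(lo=, hi=, k=)`; Gaussian-well landscapes are flat far from
#'   the wells, so biased runs need walls to stay on the coordinate
#'   range of interest. Default: walls of 500 kcal/mol/nm^2 placed 0.3
#'   nm outside the outermost well centers.
#' @param planted optional list of planted ground-truth values carried
#'   for testing.
#' @return an `AnalyticPotential`.
#' @export
gaussian_wells_potential <- function(centers, depths, sigmas,
                                     harmonic_k = 0, harmonic_x0 = 0,
                                     walls = NULL, planted = list()) {
  centers <- if (is.matrix(centers)) centers else matrix(centers, ncol = 1)
  d <- ncol(centers)
  sigmas <- if (is.matrix(sigmas)) sigmas
            else matrix(rep_len(sigmas, nrow(centers) * d),
                        nrow(centers), d)
  if (any(depths <= 0) || any(sigmas <= 0))
    stop("well depths and widths must be positive")
  if (is.null(walls))
    walls <- list(lo = apply(centers, 2, min) - 0.3,
                  hi = apply(centers, 2, max) + 0.3, k = 500)
  new_potential(list(d = d, hk = rep_len(harmonic_k, d),
                     hx0 = rep_len(harmonic_x0, d),
                     centers = centers, depths = depths, sigmas = sigmas,
                     wall_k = walls$k, wall_lo = rep_len(walls$lo, d),
                     wall_hi = rep_len(walls$hi, d)),
                planted = planted)
}

#' Asymmetric double-well potential
#'
#' Two Gaussian wells at `wells`, the first `barrier` kcal/mol deep and
#' the second `delta` kcal/mol shallower. The second well's width is
#' scaled so both wells have equal curvature, which makes the planted
#' `delta` simultaneously the minimum-to-minimum potential difference,
#' the PMF well asymmetry, and (to harmonic accuracy) the basin free
#' energy difference, with equilibrium population ratio exp(-delta/kT).
#'
#' @param wells positions of the two minima, nm.
#' @param barrier depth of the deeper well below the inter-well plateau,
#'   kcal/mol (the barrier seen from the deep well).
#' @param delta planted well asymmetry, kcal/mol.
#' @param width Gaussian width of the deep well, nm.
#' @return an `AnalyticPotential` with planted `wells`, `delta`,
#'   `barrier`.
#' @export
double_well_potential <- function(wells = c(0.53, 1.12), barrier = 4,
                                  delta = 1.19, width = 0.1) {
  if (delta >= barrier) stop("delta must be smaller than barrier")
  depths <- c(barrier, barrier - delta)
  sigmas <- matrix(c(width, width * sqrt(depths[2] / depths[1])),
                   2, 1)
  gaussian_wells_potential(matrix(wells, 2, 1), depths, sigmas,
                           planted = list(wells = wells, delta = delta,
                                          barrier = barrier))
}

#' Triple-well clamshell landscape
#'
#' Three Gaussian wells along the domain-closure coordinate, by default
#' at 0.53, 0.76 and 1.12 nm — the closed, half-closed and open minima of
#' a ligand-bound clamshell domain — with configurable relative free
#' energies. Well widths are a few hundredths of a nm so the minima stay
#' put and the planted relative depths are exact to well below binning
#' resolution.
#'
#' @param minima positions of the three minima, nm.
#' @param rel_depths free energy of each minimum relative to the global
#'   one, kcal/mol (first entry usually 0).
#' @param barrier depth of the global minimum below the baseline,
#'   kcal/mol; sets the barrier scale.
#' @param widths per-well Gaussian widths, nm.
#' @return an `AnalyticPotential` with planted `minima` and `rel_depths`.
#' @export
clamshell_triple_well <- function(minima = c(0.53, 0.76, 1.12),
                                  rel_depths = c(0, 1.35, 2.5),
                                  barrier = 4,
                                  widths = c(0.05, 0.05, 0.08)) {
  if (any(rel_depths >= barrier))
    stop("all rel_depths must be smaller than barrier")
  depths <- barrier - rel_depths
  gaussian_wells_potential(matrix(minima, 3, 1), depths,
                           matrix(widths, 3, 1),
                           planted = list(minima = minima,
                                          rel_depths = rel_depths,
                                          barrier = barrier))
}

#' Parameters for the overdamped Langevin integrator
#'
#' @param temperature K.
#' @param friction friction coefficient gamma, 1/ps; the diffusion
#'   constant is D = kT/gamma.
#' @param timestep ps. The Euler-Maruyama update needs
#'   `timestep * k_max / friction` well below 1 for the stiffest
#'   restraint in play.
#' @param n_steps number of integration steps.
#' @param seed explicit RNG seed (required; no entropy default).
#' @param save_stride save every `save_stride`-th step.
#' @param guard divergence guard: positions beyond `guard` in magnitude
#'   abort with an error suggesting a smaller timestep.
#' @return object of class `LangevinParams`.
#' @export
langevin_params <- function(temperature = 300, friction = 1,
                            timestep = 2e-4, n_steps = 10000L,
                            seed, save_stride = 10L, guard = 1e3) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(timestep > 0, temperature > 0, n_steps >= 1, save_stride >= 1)
  structure(list(temperature = temperature, friction = friction,
                 timestep = timestep, n_steps = as.integer(n_steps),
                 seed = as.integer(seed),
                 save_stride = as.integer(save_stride), guard = guard),
            class = "LangevinParams")
}

#' Bias forces for biased sampling
#'
#' `bias_none()` is the unbiased run; `bias_harmonic(center, k)` is the
#' umbrella restraint V = 1/2 k |x - center|^2; `bias_hills(ledger)`
#' applies a static, already-deposited hill ledger.
#'
#' @param center umbrella center (length-d), nm.
#' @param k umbrella force constant, kcal/mol/nm^2.
#' @param ledger a `HillLedger`.
#' @return object of class `BiasForce` with `value(x, t)` and
#'   `gradient(x, t)` members.
#' @export
bias_none <- function() {
  structure(list(kind = "none",
                 value = function(x, t = 0) 0 * rowSums(as.matrix(x)),
                 gradient = function(x, t = 0) 0 * as.matrix(x)),
            class = "BiasForce")
}

#' @rdname bias_none
#' @export
bias_harmonic <- function(center, k) {
  if (k < 0) stop("umbrella force constant must be non-negative")
  force(center); force(k)
  structure(list(kind = "harmonic_umbrella", center = center, k = k,
                 value = function(x, t = 0) {
                   x <- as_point_matrix(x, length(center))
                   0.5 * k * rowSums(sweep(x, 2, center)^2)
                 },
                 gradient = function(x, t = 0) {
                   x <- as_point_matrix(x, length(center))
                   k * sweep(x, 2, center)
                 }),
            class = "BiasForce")
}

#' @rdname bias_none
#' @export
bias_hills <- function(ledger) {
  force(ledger)
  structure(list(kind = "metadynamics_ledger", ledger = ledger,
                 value = function(x, t = Inf)
                   bias_at(ledger, x, t),
                 gradient = function(x, t = Inf) {
                   x <- as_point_matrix(x, ledger$dimension)
                   h <- 1e-6
                   g <- x * 0
                   for (j in seq_len(ncol(x))) {
                     xp <- x; xp[, j] <- xp[, j] + h
                     xm <- x; xm[, j] <- xm[, j] - h
                     g[, j] <- (bias_at(ledger, xp, t) -
                                bias_at(ledger, xm, t)) / (2 * h)
                   }
                   g
                 }),
            class = "BiasForce")
}

default_start <- function(pot, bias) {
  if (!is.null(bias$center)) return(bias$center)
  if (nrow(pot$kernel$centers) > 0)
    return(pot$kernel$centers[which.max(pot$kernel$depths), ])
  pot$kernel$hx0
}

#' Overdamped Langevin simulation on an analytic potential
#'
#' Euler-Maruyama Brownian dynamics
#' `x <- x - (D/kT) grad(U + V_bias) dt + sqrt(2 D dt) xi`, with
#' D = kT/gamma and standard-normal `xi` from R's seeded generator;
#' bit-reproducible for a fixed seed. Positions are subsampled at
#' `save_stride`.
#'
#' @param pot an `AnalyticPotential`.
#' @param params a `LangevinParams` (the seed lives here).
#' @param bias a `BiasForce` (default unbiased). Harmonic umbrellas and
#'   static hill ledgers run in the compiled kernel.
#' @param x0 start position; defaults to the umbrella center or the
#'   deepest well.
#' @return for 1D potentials a `ColvarSeries` of positions; otherwise a
#'   list with `times` and a positions matrix `values`.
#' @export
simulate_langevin <- function(pot, params, bias = bias_none(), x0 = NULL) {
  d <- pot$dimension
  if (is.null(x0)) x0 <- default_start(pot, bias)
  if (length(x0) != d) stop("x0 dimension mismatch")
  kT <- kT_kcal(params$temperature)
  D <- kT / params$friction
  set.seed(params$seed)
  if (bias$kind == "metadynamics_ledger") {
    res <- run_metad_kernel(pot, params, sigma = rep(1, d),
                            schedule = hill_schedule(numeric(0),
                                                     numeric(0),
                                                     numeric(0)),
                            init_hills = bias$ledger$hills, x0 = x0)
    pos <- res$positions
  } else {
    bc <- if (bias$kind == "harmonic_umbrella") bias$center else numeric(0)
    bk <- if (bias$kind == "harmonic_umbrella") bias$k else 0
    res <- cpp_langevin(pot$kernel, as.numeric(x0), params$timestep,
                        params$n_steps, kT, D, params$save_stride,
                        as.numeric(bc), bk, params$guard)
    if (!isTRUE(res$ok))
      stop(sprintf(paste0("trajectory diverged at step %d; ",
                          "use a smaller timestep"), res$step))
    pos <- res$positions
  }
  times <- params$timestep * params$save_stride *
    seq_len(nrow(pos))
  if (d == 1L) colvar_series("x", times, pos[, 1])
  else list(times = times, values = pos)
}

#' Generate an umbrella-sampling dataset on an analytic potential
#'
#' One biased Langevin simulation per window, each initialised at its
#' center, with per-window seeds derived deterministically from the base
#' seed (`seed + window index`), so the whole dataset is a pure function
#' of its configuration.
#'
#' @param pot a 1D `AnalyticPotential`.
#' @param centers sorted window centers, nm.
#' @param k umbrella force constant, kcal/mol/nm^2 (scalar or per
#'   window).
#' @param params `LangevinParams` shared by all windows (its seed is the
#'   base seed).
#' @return list of `UmbrellaWindow` objects carrying their samples.
#' @export
generate_umbrella_dataset <- function(pot, centers, k, params) {
  if (is.unsorted(centers)) stop("window centers must be sorted")
  if (pot$dimension != 1L) stop("umbrella datasets are 1D")
  k <- rep_len(k, length(centers))
  lapply(seq_along(centers), function(i) {
    p <- params
    p$seed <- params$seed + i
    ser <- tryCatch(
      simulate_langevin(pot, p, bias_harmonic(centers[i], k[i]),
                        x0 = centers[i]),
      error = function(e)
        stop(sprintf("window %d (center %.3f): %s", i, centers[i],
                     conditionMessage(e)), call. = FALSE))
    umbrella_window(centers[i], k[i], ser$times, ser$values,
                    label = sprintf("w%02d", i))
  })
}

#' Parameters of the toy clamshell-structure generator
#'
#' Describes a desk-scale surrogate of a two-lobe ligand-binding domain:
#' two rigid point clouds joined at a hinge, with planted bending
#' (opening/closing), twisting and rocking rigid-body modes plus
#' internal Gaussian jitter.
#'
#' @param atoms_per_domain atoms in each rigid lobe.
#' @param hinge_atoms atoms in the hinge cluster.
#' @param arm_length hinge-to-lobe-COM distance, nm.
#' @param base_angle commanded mean interdomain angle, degrees, in
#'   (0, 180); closed complexes sit near 112, the apo form near 140.
#' @param bend_amplitude,twist_amplitude,rock_amplitude planted mode
#'   amplitudes, degrees (>= 0).
#' @param jitter per-coordinate internal Gaussian noise, nm.
#' @param angle_schedule optional explicit per-frame commanded angle
#'   (degrees); overrides the bend sinusoid.
#' @param periods sinusoid periods of the three modes, frames.
#' @param seed explicit RNG seed.
#' @return object of class `ClamshellToyParams`.
#' @export
clamshell_toy_params <- function(atoms_per_domain = 120L,
                                 hinge_atoms = 30L,
                                 arm_length = 1.2, base_angle = 112,
                                 bend_amplitude = 8, twist_amplitude = 5,
                                 rock_amplitude = 3, jitter = 0.01,
                                 angle_schedule = NULL,
                                 periods = c(25, 20, 10), seed) {
  if (missing(seed)) stop("an explicit seed is required")
  if (base_angle <= 0 || base_angle >= 180)
    stop("commanded angle must lie in (0, 180) degrees")
  if (any(c(bend_amplitude, twist_amplitude, rock_amplitude) < 0))
    stop("mode amplitudes must be >= 0")
  structure(as.list(environment()), class = "ClamshellToyParams")
}

rotation_about_axis <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  ct <- cos(theta); st <- sin(theta)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  diag(3) * ct + st * ux + (1 - ct) * tcrossprod(u)
}

#' Generate a synthetic clamshell trajectory with planted modes
#'
#' Builds two rigid anisotropic point clouds joined at a hinge cluster
#' centered at the origin, then per frame applies the commanded
#' interdomain angle (bend, rotation of lobe 2 about the hinge z-axis),
#' twist (rotation of lobe 2 about its own COM axis) and rock (rotation
#' about the lobe-1 axis), plus per-atom Gaussian jitter. Bend changes
#' the interdomain angle one-to-one; twist and rock leave it invariant
#' by construction, so the three planted generators are mutually
#' (near-)orthogonal displacement fields.
#'
#' Ground truth is attached as `attr(traj, "ground_truth")`: the
#' commanded angle series, the three mode time courses (degrees), and
#' the three unit 3N-space mode fields. The matching `RigidBodyModel`
#' selections are attached as `attr(traj, "model")`.
#'
#' @param p a `ClamshellToyParams`.
#' @param n_frames frames to generate.
#' @param dt_ps frame spacing, ps.
#' @return a `Trajectory`.
#' @export
generate_clamshell_trajectory <- function(p, n_frames = 200L, dt_ps = 10) {
  set.seed(p$seed)
  nd <- p$atoms_per_domain; nh <- p$hinge_atoms
  theta0 <- p$base_angle * pi / 180
  centered_cloud <- function(n, center, sds) {
    m <- cbind(rnorm(n, sd = sds[1]), rnorm(n, sd = sds[2]),
               rnorm(n, sd = sds[3]))
    sweep(m, 2, colMeans(m)) + rep(center, each = n)
  }
  dom1 <- centered_cloud(nd, p$arm_length * c(1, 0, 0), c(0.30, 0.20, 0.15))
  u2 <- c(cos(theta0), sin(theta0), 0)
  dom2 <- centered_cloud(nd, p$arm_length * u2, c(0.30, 0.20, 0.15))
  hinge <- centered_cloud(nh, c(0, 0, 0), c(0.05, 0.05, 0.05))
  base <- rbind(dom1, hinge, dom2)
  nat <- nrow(base)
  idx_d1 <- seq_len(nd); idx_h <- nd + seq_len(nh)
  idx_d2 <- nd + nh + seq_len(nd)

  tt <- seq_len(n_frames)
  if (!is.null(p$angle_schedule)) {
    ang <- rep_len(p$angle_schedule, n_frames)
    if (any(ang <= 0 | ang >= 180))
      stop("commanded angle must lie in (0, 180) degrees")
    bend <- ang - p$base_angle
  } else {
    bend <- p$bend_amplitude * sin(2 * pi * tt / p$periods[1])
    ang <- p$base_angle + bend
    if (any(ang <= 0 | ang >= 180))
      stop("commanded angle must lie in (0, 180) degrees")
  }
  twist <- p$twist_amplitude * sin(2 * pi * tt / p$periods[2])
  rock <- p$rock_amplitude * sin(2 * pi * tt / p$periods[3])

  com2 <- colMeans(base[idx_d2, ])
  coords <- array(NA_real_, c(n_frames, nat, 3L))
  for (i in seq_len(n_frames)) {
    fr <- base
    d2 <- base[idx_d2, ]
    # twist about the lobe axis through its own COM (angle-invariant)
    rt <- rotation_about_axis(u2, twist[i] * pi / 180)
    d2 <- sweep(sweep(d2, 2, com2) %*% t(rt), 2, com2, "+")
    # rock about the lobe-1 direction through the hinge (angle-invariant)
    rr <- rotation_about_axis(c(1, 0, 0), rock[i] * pi / 180)
    d2 <- d2 %*% t(rr)
    # bend about z through the hinge: changes the angle one-to-one
    rb <- rotation_about_axis(c(0, 0, 1), bend[i] * pi / 180)
    d2 <- d2 %*% t(rb)
    fr[idx_d2, ] <- d2
    if (p$jitter > 0)
      fr <- fr + matrix(rnorm(nat * 3L, sd = p$jitter), nat, 3L)
    coords[i, , ] <- fr
  }

  topo <- dummy_topology(nat)
  traj <- new_trajectory(coords, (tt - 1) * dt_ps, topo)
  model <- rigid_body_model(
    new_selection(idx_d1, "dom1", nat),
    new_selection(idx_d2, "dom2", nat),
    new_selection(idx_h, "hinge", nat),
    reference = new_structure(topo$atoms, base, "clamshell_reference"))
  unit_field <- function(m) {
    full <- matrix(0, nat, 3L)
    full[idx_d2, ] <- m
    as.vector(full) / sqrt(sum(m^2))
  }
  r2 <- base[idx_d2, ]
  f_bend <- t(apply(r2, 1, function(r) cross3(c(0, 0, 1), r)))
  f_twist <- t(apply(sweep(r2, 2, com2), 1,
                     function(q) cross3(u2, q)))
  f_rock <- t(apply(r2, 1, function(r) cross3(c(1, 0, 0), r)))
  # displacement amplitude along each unit mode = angle amplitude (rad)
  # times the lever-arm norm of the rotation field; eigenvalue order
  # follows these, not the raw angle amplitudes
  levers <- sqrt(c(sum(f_bend^2), sum(f_twist^2), sum(f_rock^2)))
  amp_deg <- c(if (is.null(p$angle_schedule)) p$bend_amplitude
               else stats::sd(bend) * sqrt(2),
               p$twist_amplitude, p$rock_amplitude)
  disp_amp <- amp_deg * pi / 180 * levers
  attr(traj, "ground_truth") <- list(
    angle = ang, bend = bend, twist = twist, rock = rock,
    mode_fields = cbind(bend = unit_field(f_bend),
                        twist = unit_field(f_twist),
                        rock = unit_field(f_rock)),
    displacement_amplitudes = setNames(disp_amp,
                                       c("bend", "twist", "rock")),
    mode_order = order(disp_amp, decreasing = TRUE))
  attr(traj, "model") <- model
  attr(traj, "params") <- p
  traj
}
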