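#' A metadynamics hill ledger
#'
#' Ordered record of the Gaussian hills deposited during a metadynamics
#' run; the accumulated bias `V(s,t)` approximates the negative free
#' energy surface once the landscape is filled.
#'
#' @param hills numeric matrix with columns `time` (ps), the `d` hill
#'   centers, the `d` hill widths (sigma), and `height` (kcal/mol), in
#'   deposition order (non-decreasing times).
#' @param dimension CV-space dimensionality `d`.
#' @param cv_names names of the collective variables.
#' @return object of class `HillLedger`.
#' @export
hill_ledger <- function(hills, dimension = 1L,
                        cv_names = paste0("cv", seq_len(dimension))) {
  hills <- as.matrix(hills)
  d <- as.integer(dimension)
  if (nrow(hills) > 0L) {
    if (ncol(hills) != 2L + 2L * d)
      stop("hills must have 2 + 2*d columns (time, centers, sigmas, height)")
    if (is.unsorted(hills[, 1L]))
      stop("hill deposit times must be non-decreasing")
    if (any(hills[, 2L + 2L * d] <= 0)) stop("hill heights must be positive")
    if (any(hills[, (2L + d):(1L + 2L * d)] <= 0))
      stop("hill widths must be positive")
  } else {
    hills <- matrix(0, 0L, 2L + 2L * d)
  }
  colnames(hills) <- c("time", paste0("c_", cv_names),
                       paste0("sigma_", cv_names), "height")
  structure(list(hills = hills, dimension = d, cv_names = cv_names),
            class = "HillLedger")
}

#' @export
print.HillLedger <- function(x, ...) {
  cat(sprintf("HillLedger: %d hills in %dD CV space (%s)\n",
              nrow(x$hills), x$dimension,
              paste(x$cv_names, collapse = ", ")))
  invisible(x)
}

#' Evaluate the accumulated metadynamics bias
#'
#' `V(s,t)` is the sum over all hills deposited up to time `t` of
#' `h exp(-sum_d (s_d - c_d)^2 / (2 sigma_d^2))`; hill contributions are
#' truncated to zero beyond 5 sigma in any dimension.
#'
#' @param ledger a `HillLedger`.
#' @param s a CV point (length-d vector) or matrix of points (d
#'   columns); plain numeric vectors are points for 1D ledgers.
#' @param t evaluation time, ps (default: after all hills).
#' @return bias values, kcal/mol.
#' @export
bias_at <- function(ledger, s, t = Inf) {
  pts <- as_point_matrix(s, ledger$dimension)
  cpp_bias_at(ledger$hills, ledger$dimension, pts, t)
}

#' Staged hill-deposition schedule
#'
#' Ordered phases of plain metadynamics, each with its own hill height
#' and deposition stride. The refined clamshell protocol is the
#' three-stage 0.5 -> 0.2 -> 0.05 kcal/mol sequence: coarse filling
#' first, then progressively finer hills so the reconstructed surface
#' stops rippling.
#'
#' @param heights hill heights per phase, kcal/mol.
#' @param strides deposition strides per phase, ps.
#' @param durations phase durations, ps.
#' @return object of class `HillSchedule`.
#' @export
hill_schedule <- function(heights, strides, durations) {
  n <- length(heights)
  if (length(strides) != n || length(durations) != n)
    stop("heights, strides and durations must have equal length")
  if (n > 0L && (any(heights <= 0) || any(strides <= 0) ||
                 any(durations < 0)))
    stop("heights and strides must be positive, durations non-negative")
  structure(list(heights = as.numeric(heights),
                 strides = as.numeric(strides),
                 durations = as.numeric(durations)),
            class = "HillSchedule")
}

default_metad_grid <- function(pot, sigma) {
  ker <- pot$kernel
  if (nrow(ker$centers) > 0L) {
    lo <- apply(ker$centers, 2, min)
    hi <- apply(ker$centers, 2, max)
  } else {
    lo <- ker$hx0; hi <- ker$hx0
  }
  pad <- pmax(0.4, 8 * sigma)
  lo <- lo - pad; hi <- hi + pad
  n <- pmin(2048L, pmax(64L, ceiling((hi - lo) / (sigma / 10))))
  if (pot$dimension >= 2L) n <- pmin(n, 128L)
  list(lo = lo, hi = hi, n = as.integer(n))
}

run_metad_kernel <- function(pot, params, sigma, schedule,
                             init_hills = NULL, x0 = NULL, grid = NULL) {
  d <- pot$dimension
  if (is.null(x0)) x0 <- default_start(pot, bias_none())
  if (is.null(grid)) grid <- default_metad_grid(pot, sigma)
  if (is.null(init_hills))
    init_hills <- matrix(0, 0L, 2L + 2L * d)
  kT <- kT_kcal(params$temperature)
  D <- kT / params$friction
  phase_steps <- as.integer(round(schedule$durations / params$timestep))
  phase_strides <- as.integer(round(schedule$strides / params$timestep))
  set.seed(params$seed)
  res <- cpp_metadynamics(pot$kernel, as.numeric(x0), params$timestep,
                          params$n_steps, kT, D, params$save_stride,
                          as.numeric(sigma), schedule$heights,
                          phase_strides, phase_steps,
                          as.numeric(grid$lo), as.numeric(grid$hi),
                          as.integer(rep_len(grid$n, d)),
                          init_hills, params$guard)
  if (!isTRUE(res$ok))
    stop(sprintf("trajectory diverged at step %d; use a smaller timestep",
                 res$step))
  res
}

#' Run metadynamics on an analytic potential
#'
#' Integrates overdamped Langevin dynamics under `U + V(s,t)` with the
#' identity CV map (the sampled coordinates are the CVs), depositing a
#' hill at the current position every stride of the active phase with
#' that phase's height. The ledger and trajectory share the time axis
#' and the whole run is reproducible for a fixed seed. The bias and its
#' gradient are accumulated on a fine grid (multilinear interpolation),
#' so the cost per step does not grow with the ledger.
#'
#' @param pot an `AnalyticPotential` (1-3 dimensions).
#' @param schedule a `HillSchedule`; with zero phases the run reduces to
#'   unbiased [simulate_langevin()].
#' @param sigma per-CV hill widths, nm. A common choice is about 1/5 of
#'   the CV's unbiased standard deviation ([suggest_hill_width()]).
#' @param params a `LangevinParams`.
#' @param x0 start point (default: deepest well).
#' @param grid optional bias grid `list(lo, hi, n)`.
#' @return list with `trajectory` (a `ColvarSeries` for 1D, else
#'   times/values) and `ledger` (a `HillLedger`).
#' @export
run_metadynamics <- function(pot, schedule, sigma, params, x0 = NULL,
                             grid = NULL) {
  d <- pot$dimension
  sigma <- rep_len(sigma, d)
  if (any(sigma <= 0)) stop("hill widths must be positive")
  res <- run_metad_kernel(pot, params, sigma, schedule, NULL, x0, grid)
  hills <- res$hills[seq_len(res$n_hills), , drop = FALSE]
  times <- params$timestep * params$save_stride *
    seq_len(nrow(res$positions))
  traj <- if (d == 1L) colvar_series("cv1", times, res$positions[, 1])
          else list(times = times, values = res$positions)
  list(trajectory = traj, ledger = hill_ledger(hills, d))
}

#' Suggest a hill width from a short unbiased pre-run
#'
#' One fifth of the CV standard deviation sampled in a short unbiased
#' simulation started from the deepest well — a common, reproducible
#' default when no width is prescribed.
#'
#' @param pot an `AnalyticPotential`.
#' @param params a `LangevinParams` for the pre-run.
#' @return per-CV width(s), nm.
#' @export
suggest_hill_width <- function(pot, params) {
  out <- simulate_langevin(pot, params)
  v <- if (inherits(out, "ColvarSeries")) matrix(out$values, ncol = 1L)
       else out$values
  apply(v, 2, stats::sd) / 5
}

#' Reconstruct a free-energy surface from a hill ledger
#'
#' `F(s) = -V(s, t_final)`, shifted so the minimum is zero. Plain
#' metadynamics oscillates around the true surface by about one hill
#' height, so an optional trailing-window time average of `-V` (over the
#' hill-deposition checkpoints in `[average_from, t_final]`) is provided
#' to damp the ripple; estimates from it are what the convergence tests
#' use.
#'
#' @param ledger a `HillLedger`.
#' @param grid grid specification `list(lo, hi, n)` per dimension; must
#'   cover every hill center +/- 3 sigma. 3D grids are capped at 128^3
#'   points.
#' @param t_final reconstruction time, ps.
#' @param average_from optional start (ps) of the trailing averaging
#'   window.
#' @return object of class `FreeEnergySurface`: `axes` (bin-center
#'   vectors), `values` (kcal/mol array, min = 0), `dimension`,
#'   `zero_convention`.
#' @export
reconstruct_fes <- function(ledger, grid, t_final = Inf,
                            average_from = NULL) {
  d <- ledger$dimension
  lo <- rep_len(grid$lo, d); hi <- rep_len(grid$hi, d)
  n <- as.integer(rep_len(grid$n, d))
  if (prod(n) > 128^3) stop("grid exceeds the 128^3 point cap")
  h <- ledger$hills
  if (nrow(h) > 0L) {
    hc <- h[, 1L + seq_len(d), drop = FALSE]
    hs <- h[, 1L + d + seq_len(d), drop = FALSE]
    for (j in seq_len(d)) {
      if (min(hc[, j] - 3 * hs[, j]) < lo[j] ||
          max(hc[, j] + 3 * hs[, j]) > hi[j])
        stop("grid does not cover all hills +/- 3 sigma in dimension ", j)
    }
  }
  axes <- lapply(seq_len(d), function(j) seq(lo[j], hi[j],
                                             length.out = n[j]))
  pts <- as.matrix(do.call(expand.grid, axes))
  if (is.null(average_from)) {
    v <- cpp_bias_at(h, d, pts, t_final)
  } else {
    cps <- h[h[, 1L] >= average_from & h[, 1L] <= t_final, 1L]
    if (length(cps) == 0L)
      stop("no hills inside the averaging window")
    if (length(cps) > 200L)
      cps <- cps[unique(as.integer(seq(1L, length(cps),
                                       length.out = 200L)))]
    snaps <- cpp_bias_snapshots(h, d, pts, sort(cps))
    v <- rowMeans(snaps)
  }
  f <- -v
  f <- f - min(f)
  values <- array(f, dim = n)
  structure(list(axes = axes, values = values, dimension = d,
                 zero_convention = "global minimum = 0"),
            class = "FreeEnergySurface")
}

#' @export
print.FreeEnergySurface <- function(x, ...) {
  cat(sprintf("FreeEnergySurface: %dD grid (%s), max %.3f kcal/mol\n",
              x$dimension,
              paste(vapply(x$axes, length, 1L), collapse = " x "),
              max(x$values)))
  invisible(x)
}

#' Project a free-energy surface onto one CV
#'
#' Boltzmann marginalisation: `F1(s) = -kT log sum_rest exp(-F/kT)`,
#' shifted so the minimum is zero — the projection used to display
#' multi-CV surfaces along a single coordinate.
#'
#' @param fes a `FreeEnergySurface` with dimension >= 2.
#' @param keep index of the CV to keep.
#' @param kT thermal energy, kcal/mol.
#' @return a 1D `FreeEnergySurface`.
#' @export
fes_project <- function(fes, keep = 1L, kT = kT_kcal(300)) {
  if (fes$dimension < 2L) stop("fes_project needs a multi-CV surface")
  w <- exp(-fes$values / kT)
  f1 <- -kT * log(apply(w, keep, sum))
  f1 <- f1 - min(f1)
  structure(list(axes = fes$axes[keep], values = array(f1),
                 dimension = 1L,
                 zero_convention = "global minimum = 0"),
            class = "FreeEnergySurface")
}

basin_mask <- function(fes, basin) {
  if (!is.list(basin)) basin <- list(basin)
  if (length(basin) != fes$dimension)
    stop("basin must give a c(lo, hi) range per CV dimension")
  masks <- lapply(seq_len(fes$dimension), function(j)
    fes$axes[[j]] >= basin[[j]][1] & fes$axes[[j]] <= basin[[j]][2])
  m <- masks[[1L]]
  if (fes$dimension > 1L)
    for (j in 2:fes$dimension) m <- outer(m, masks[[j]], `&`)
  array(m, dim = dim(fes$values))
}

#' Basin free-energy difference on a reconstructed surface
#'
#' Basin-integrated difference
#' `dG = -kT log(sum_A exp(-F/kT)) + kT log(sum_B exp(-F/kT))`
#' (positive when basin A lies above basin B), with the simple
#' minimum-to-minimum difference reported alongside; for deep, narrow
#' wells the two agree.
#'
#' @param fes a `FreeEnergySurface`.
#' @param basinA,basinB disjoint grid regions: `c(lo, hi)` per CV
#'   dimension (a plain range in 1D, a list of ranges otherwise).
#' @param kT thermal energy, kcal/mol.
#' @return list with `delta_g` (basin-integrated, kcal/mol) and
#'   `min_to_min`.
#' @export
basin_delta_g <- function(fes, basinA, basinB, kT = kT_kcal(300)) {
  ma <- basin_mask(fes, basinA); mb <- basin_mask(fes, basinB)
  if (!any(ma)) stop("basin A contains no grid points")
  if (!any(mb)) stop("basin B contains no grid points")
  if (any(ma & mb)) stop("basins must be disjoint")
  lse <- function(v) {
    mx <- max(-v / kT)
    mx + log(sum(exp(-v / kT - mx)))
  }
  ga <- -kT * lse(fes$values[ma])
  gb <- -kT * lse(fes$values[mb])
  list(delta_g = ga - gb,
       min_to_min = min(fes$values[ma]) - min(fes$values[mb]))
}

#' Count transitions between two basins in a CV series
#'
#' A transition is recorded every time the series, last seen at or below
#' `lo`, reaches at or above `hi` (or vice versa) — a two-threshold
#' scheme that ignores barrier-top recrossings.
#'
#' @param values CV time series.
#' @param lo,hi basin thresholds, `lo < hi`.
#' @return number of transitions.
#' @export
count_transitions <- function(values, lo, hi) {
  state <- 0L; n <- 0L
  for (v in values) {
    s <- if (v <= lo) -1L else if (v >= hi) 1L else 0L
    if (s != 0L) {
      if (state != 0L && s != state) n <- n + 1L
      state <- s
    }
  }
  n
}

#' Write a hill ledger as PLUMED-style HILLS text
#'
#' Column layout (documented and fixed): `time` (ps), the CV centers,
#' the per-CV sigmas, then `height` (kcal/mol), with a `#! FIELDS`
#' header naming the columns.
#'
#' @param ledger a `HillLedger`.
#' @param path optional output path.
#' @return text lines, invisibly when writing to a file.
#' @export
write_hills <- function(ledger, path = NULL) {
  hdr <- sprintf("#! FIELDS time %s %s height",
                 paste(ledger$cv_names, collapse = " "),
                 paste(paste0("sigma_", ledger$cv_names), collapse = " "))
  rows <- apply(ledger$hills, 1L, function(r)
    paste(sprintf("%.10g", r), collapse = " "))
  txt <- c(hdr, rows)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a PLUMED-style HILLS file
#'
#' @param text file path or text in the [write_hills()] layout; the
#'   dimensionality is inferred from the `#! FIELDS` header when
#'   present, else from the column count assuming 1D.
#' @return a `HillLedger`.
#' @export
read_hills <- function(text) {
  lines <- as_text_lines(text)
  hdr <- grep("^#!\\s*FIELDS", lines, value = TRUE)
  data_lines <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(data_lines) == 0L)
    return(hill_ledger(matrix(0, 0, 4), 1L))
  toks <- strsplit(trimws(lines[data_lines]), "\\s+")
  nc <- lengths(toks)
  if (length(unique(nc)) != 1L)
    stop(sprintf("ragged HILLS row at line %d (%d columns, expected %d)",
                 data_lines[which(nc != nc[1L])[1L]],
                 nc[which(nc != nc[1L])[1L]], nc[1L]))
  m <- matrix(as.numeric(unlist(toks)), length(toks), nc[1L],
              byrow = TRUE)
  if (anyNA(m)) stop("non-numeric value in HILLS data")
  d <- (nc[1L] - 2L) / 2L
  if (d != round(d)) stop("HILLS column count must be 2 + 2*d")
  cv_names <- paste0("cv", seq_len(d))
  if (length(hdr) > 0L) {
    fields <- strsplit(trimws(sub("^#!\\s*FIELDS", "", hdr[1L])),
                       "\\s+")[[1L]]
    if (length(fields) == nc[1L]) cv_names <- fields[1L + seq_len(d)]
  }
  hill_ledger(m, as.integer(d), cv_names)
}
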