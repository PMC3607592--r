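#' An umbrella-sampling window
#'
#' @param center restraint center, nm.
#' @param force_constant harmonic force constant, kcal/mol/nm^2 (zero is
#'   allowed and means an unbiased window).
#' @param times sample timestamps, ps.
#' @param samples reaction-coordinate values, nm.
#' @param label window label.
#' @return object of class `UmbrellaWindow`.
#' @export
umbrella_window <- function(center, force_constant, times, samples,
                            label = NULL) {
  if (force_constant < 0) stop("force_constant must be >= 0")
  if (length(samples) < 1L) stop("a window needs at least one sample")
  if (length(times) != length(samples))
    stop("times and samples must have the same length")
  structure(list(center = center, force_constant = force_constant,
                 times = as.numeric(times), samples = as.numeric(samples),
                 label = if (is.null(label)) sprintf("c%.3f", center)
                         else label),
            class = "UmbrellaWindow")
}

#' @export
print.UmbrellaWindow <- function(x, ...) {
  cat(sprintf("UmbrellaWindow '%s': center %.3f nm, k %.0f, %d samples\n",
              x$label, x$center, x$force_constant, length(x$samples)))
  invisible(x)
}

#' Bin window samples on a shared grid
#'
#' Half-open bins `[lo + i*w, lo + (i+1)*w)`: a sample exactly on an edge
#' goes to the right bin. Samples outside the range are counted and
#' reported per window, never silently dropped.
#'
#' @param windows list of `UmbrellaWindow`.
#' @param bin_width bin width, nm.
#' @param range `c(lo, hi)` of the shared grid, nm; defaults to the
#'   sample range padded by one bin.
#' @return object of class `WhamHistograms`: `bin_centers`, `counts`
#'   (n_windows x n_bins), `n_outside`, `edges`, `bin_width`.
#' @export
build_histograms <- function(windows, bin_width, range = NULL) {
  if (bin_width <= 0) stop("bin_width must be positive")
  all_s <- unlist(lapply(windows, `[[`, "samples"))
  if (is.null(range))
    range <- c(min(all_s) - bin_width, max(all_s) + bin_width)
  lo <- range[1]; hi <- range[2]
  if (hi <= lo) stop("range must satisfy hi > lo")
  nb <- max(1L, ceiling((hi - lo) / bin_width - 1e-9))
  edges <- lo + bin_width * (0:nb)
  counts <- t(vapply(windows, function(w) {
    j <- floor((w$samples - lo) / bin_width)
    j <- j[j >= 0 & j < nb]
    tabulate(j + 1L, nbins = nb)
  }, integer(nb)))
  n_outside <- vapply(windows, function(w)
    sum(w$samples < lo | w$samples >= edges[nb + 1L]), integer(1))
  if (all(rowSums(counts) == 0L))
    stop("all samples fall outside the histogram range")
  structure(list(bin_centers = edges[-(nb + 1L)] + bin_width / 2,
                 counts = counts, n_outside = n_outside, edges = edges,
                 bin_width = bin_width),
            class = "WhamHistograms")
}

logsumexp <- function(m, margin) {
  # numerically stable log(sum(exp)) along rows (margin=1) or cols (2)
  mx <- apply(m, margin, max)
  if (margin == 1L)
    mx + log(rowSums(exp(m - mx)))
  else
    mx + log(colSums(exp(sweep(m, 2, mx))))
}

window_bias_matrix <- function(hist, windows) {
  centers <- vapply(windows, `[[`, numeric(1), "center")
  ks <- vapply(windows, `[[`, numeric(1), "force_constant")
  0.5 * ks * outer(centers, hist$bin_centers, `-`)^2
}

check_window_connectivity <- function(counts) {
  nw <- nrow(counts)
  occupied <- counts > 0
  # windows are connected when their occupied bins overlap (shared bins)
  comp <- rep(NA_integer_, nw)
  cid <- 0L
  for (i in seq_len(nw)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    frontier <- i
    comp[i] <- cid
    while (length(frontier) > 0L) {
      cur <- frontier[1L]; frontier <- frontier[-1L]
      for (j in seq_len(nw)) {
        if (!is.na(comp[j])) next
        if (any(occupied[cur, ] & occupied[j, ])) {
          comp[j] <- cid
          frontier <- c(frontier, j)
        }
      }
    }
  }
  if (cid > 1L) {
    gap <- which(diff(comp[order(seq_len(nw))]) != 0)[1L]
    stop(sprintf(paste0("umbrella windows are disconnected (no histogram ",
                        "overlap between windows %d and %d); add windows ",
                        "or lengthen sampling"), gap, gap + 1L))
  }
  invisible(TRUE)
}

#' Solve the WHAM self-consistency equations
#'
#' Standard weighted-histogram iteration in log space: the unbiased bin
#' probability is `p_j ~ (sum_i n_ij) / (sum_i N_i exp((f_i - w_ij)/kT))`
#' with `w_i(x) = k_i (x - c_i)^2 / 2`, and window offsets
#' `f_i = -kT log sum_j p_j exp(-w_ij/kT)`, iterated until the largest
#' offset change drops below `tol`. Offsets are gauge-fixed to
#' `f_1 = 0`.
#'
#' @param hist a `WhamHistograms`.
#' @param windows the windows that produced `hist` (same order).
#' @param kT thermal energy, kcal/mol.
#' @param tol convergence tolerance on the offsets, kcal/mol.
#' @param max_iter maximum iterations.
#' @return object of class `WhamSolution`: `offsets` (f_i), `log_p`
#'   (unnormalised log bin probabilities), `n_iter`, `residual`.
#' @export
solve_wham <- function(hist, windows, kT = kT_kcal(300), tol = 1e-7,
                       max_iter = 1e5) {
  if (length(windows) < 1L) stop("need at least one window")
  if (tol <= 0) stop("tol must be positive")
  counts <- hist$counts
  check_window_connectivity(counts)
  w <- window_bias_matrix(hist, windows)      # n_win x n_bins
  ni <- rowSums(counts)
  mj <- colSums(counts)
  log_ni <- log(ni)
  log_mj <- ifelse(mj > 0, log(mj), -Inf)
  f <- numeric(length(windows))
  for (it in seq_len(max_iter)) {
    a <- (f - w) / kT + log_ni                 # broadcast f, log_ni by row
    log_denom <- logsumexp(a, 2L)
    log_p <- log_mj - log_denom
    f_new <- -kT * logsumexp(sweep(-w / kT, 2, log_p, `+`), 1L)
    f_new <- f_new - f_new[1L]
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid < tol) {
      return(structure(list(offsets = f, log_p = log_p, n_iter = it,
                            residual = resid, kT = kT),
                       class = "WhamSolution"))
    }
  }
  stop(sprintf("WHAM did not converge in %d iterations (residual %.3g)",
               as.integer(max_iter), resid))
}

#' Potential of mean force from a WHAM solution
#'
#' `G_j = -kT log p_j` on the shared grid, shifted so the global minimum
#' is zero. Bins with zero total counts are flagged `NA`, never silently
#' interpolated.
#'
#' @param sol a `WhamSolution`.
#' @param hist the `WhamHistograms` it was solved from.
#' @return object of class `PMFCurve`: `bin_centers`, `free_energy`
#'   (kcal/mol, min = 0), `sample_counts`, `bin_width`,
#'   `zero_convention`.
#' @export
pmf_from_wham <- function(sol, hist) {
  if (all(!is.finite(sol$log_p))) stop("empty histograms")
  g <- -sol$kT * sol$log_p
  g <- g - min(g[is.finite(g)])
  g[!is.finite(g)] <- NA_real_
  structure(list(bin_centers = hist$bin_centers, free_energy = g,
                 sample_counts = colSums(hist$counts),
                 bin_width = hist$bin_width,
                 zero_convention = "global minimum = 0"),
            class = "PMFCurve")
}

#' @export
print.PMFCurve <- function(x, ...) {
  ok <- is.finite(x$free_energy)
  cat(sprintf("PMFCurve: %d bins (%d sampled), range [%.3f, %.3f] nm, max %.3f kcal/mol\n",
              length(x$bin_centers), sum(ok), min(x$bin_centers),
              max(x$bin_centers), max(x$free_energy[ok])))
  invisible(x)
}

#' One-call umbrella-sampling PMF
#'
#' Convenience wrapper: histograms, WHAM solution and PMF in one step.
#'
#' @inheritParams build_histograms
#' @inheritParams solve_wham
#' @return a `PMFCurve` with the `WhamSolution` attached as attribute
#'   `"solution"` and the histograms as `"histograms"`.
#' @export
wham_pmf <- function(windows, bin_width = 0.01, range = NULL,
                     kT = kT_kcal(300), tol = 1e-7, max_iter = 1e5) {
  hist <- build_histograms(windows, bin_width, range)
  sol <- solve_wham(hist, windows, kT, tol, max_iter)
  pmf <- pmf_from_wham(sol, hist)
  attr(pmf, "solution") <- sol
  attr(pmf, "histograms") <- hist
  pmf
}

#' Maximum deviation of a PMF from an analytic reference
#'
#' A PMF is defined up to an additive constant, so the comparison uses
#' the constant that minimises the maximum absolute deviation (midrange
#' alignment) over bins with at least `min_counts` samples.
#'
#' @param pmf a `PMFCurve`.
#' @param pot an `AnalyticPotential` (1D) evaluated at the bin centers.
#' @param min_counts only compare bins with this many samples.
#' @return max |PMF - analytic| in kcal/mol, with the per-bin deviations
#'   as attribute `"deviations"`.
#' @export
pmf_deviation <- function(pmf, pot, min_counts = 100) {
  ok <- is.finite(pmf$free_energy) & pmf$sample_counts >= min_counts
  if (!any(ok)) stop("no bins with enough samples to compare")
  ref <- potential_value(pot, pmf$bin_centers[ok])
  dev <- pmf$free_energy[ok] - (ref - min(ref))
  dev <- dev - (max(dev) + min(dev)) / 2
  structure(max(abs(dev)), deviations = dev)
}

#' Pairwise histogram overlap matrix
#'
#' Overlap of normalised window histograms,
#' `sum_j min(p_ij, p_kj)` in [0, 1]; identical histograms give 1,
#' disjoint supports 0. Adjacent pairs below `threshold` are flagged in
#' the `"low_pairs"` attribute, the standard convergence red flag for an
#' umbrella run.
#'
#' @param hist a `WhamHistograms`.
#' @param threshold flag threshold for adjacent-window overlap.
#' @return symmetric n_windows x n_windows matrix.
#' @export
histogram_overlap <- function(hist, threshold = 0.05) {
  counts <- hist$counts
  nw <- nrow(counts)
  tot <- rowSums(counts)
  p <- counts / ifelse(tot > 0, tot, 1)
  ov <- matrix(1, nw, nw)
  for (i in seq_len(nw)) for (j in seq_len(nw)) {
    if (i < j) ov[i, j] <- ov[j, i] <- sum(pmin(p[i, ], p[j, ]))
  }
  low <- which(ov[cbind(seq_len(nw - 1L), seq_len(nw - 1L) + 1L)] <
                 threshold)
  attr(ov, "low_pairs") <- low
  ov
}

#' Batch (block-average) convergence analysis
#'
#' Splits every window's time series into `n_batches` sequential slices,
#' solves WHAM per slice and reports the per-batch PMFs together with
#' per-batch endpoint free-energy differences — the family-of-curves
#' convergence picture used for long umbrella runs.
#'
#' @param windows list of `UmbrellaWindow` (all spanning the same time
#'   range).
#' @param n_batches number of sequential slices (>= 2).
#' @param bin_width,range,kT,tol,max_iter passed to the WHAM machinery.
#' @param state_a,state_b endpoint definitions passed to
#'   [endpoint_delta_g()]: a position (nm) or an interval `c(lo, hi)`
#'   read as a plateau. Defaults: `state_a` the global PMF minimum of
#'   the full-data solve, `state_b` the final 15% of the range as a
#'   plateau.
#' @return object of class `ConvergenceReport`: `batch_pmfs`,
#'   `endpoint_dg` per batch, `max_dev_last_two` (max abs PMF deviation
#'   over bins finite in both of the last two batches), `overlap`
#'   (full-data overlap matrix), `drift` flag (monotone endpoint drift).
#' @export
batch_convergence <- function(windows, n_batches, bin_width = 0.01,
                              range = NULL, kT = kT_kcal(300),
                              tol = 1e-7, max_iter = 1e5,
                              state_a = NULL, state_b = NULL) {
  if (n_batches < 2L) stop("n_batches must be >= 2")
  full_hist <- build_histograms(windows, bin_width, range)
  range <- c(full_hist$edges[1L], full_hist$edges[length(full_hist$edges)])
  full_pmf <- wham_pmf(windows, bin_width, range, kT, tol, max_iter)
  # default endpoint states are read off the well-sampled part of the
  # full-data PMF so per-batch slices cannot lose them to empty bins
  solid <- is.finite(full_pmf$free_energy) &
    full_pmf$sample_counts >= pmax(10, 0.001 * sum(full_pmf$sample_counts))
  if (!any(solid)) stop("no well-sampled bins for endpoint states")
  if (is.null(state_a)) {
    g <- full_pmf$free_energy
    g[!solid] <- Inf
    state_a <- full_pmf$bin_centers[which.min(g)]
  }
  if (is.null(state_b)) {
    hi_sampled <- max(full_pmf$bin_centers[solid])
    state_b <- c(hi_sampled - 0.15 * diff(range), hi_sampled)
  }
  batch_pmfs <- vector("list", n_batches)
  endpoint_dg <- numeric(n_batches)
  for (b in seq_len(n_batches)) {
    sliced <- lapply(windows, function(w) {
      # sequential equal-count slices in time order
      ord <- order(w$times)
      slice_id <- ceiling(seq_along(ord) * n_batches / length(ord))
      keep <- ord[slice_id == b]
      if (length(keep) == 0L)
        stop(sprintf("window '%s' has no samples in batch %d",
                     w$label, b))
      umbrella_window(w$center, w$force_constant, w$times[keep],
                      w$samples[keep], w$label)
    })
    batch_pmfs[[b]] <- wham_pmf(sliced, bin_width, range, kT, tol,
                                max_iter)
    endpoint_dg[b] <- endpoint_delta_g(batch_pmfs[[b]], state_a, state_b)
  }
  g1 <- batch_pmfs[[n_batches - 1L]]$free_energy
  g2 <- batch_pmfs[[n_batches]]$free_energy
  # compare shapes over bins both batches sample decently, with the
  # gauge constant chosen to minimise the maximum deviation
  both <- is.finite(g1) & is.finite(g2) &
    batch_pmfs[[n_batches - 1L]]$sample_counts >= 50 &
    batch_pmfs[[n_batches]]$sample_counts >= 50
  if (!any(both)) stop("last two batches share no well-sampled bins")
  dev <- g1[both] - g2[both]
  max_dev <- max(abs(dev - (max(dev) + min(dev)) / 2))
  dd <- diff(endpoint_dg)
  structure(list(batch_pmfs = batch_pmfs, endpoint_dg = endpoint_dg,
                 max_dev_last_two = max_dev,
                 overlap = histogram_overlap(full_hist),
                 drift = all(dd > 0) || all(dd < 0),
                 state_a = state_a, state_b = state_b),
            class = "ConvergenceReport")
}

#' @export
print.ConvergenceReport <- function(x, ...) {
  cat(sprintf("ConvergenceReport: %d batches; endpoint dG per batch: %s kcal/mol\n",
              length(x$batch_pmfs),
              paste(sprintf("%.2f", x$endpoint_dg), collapse = ", ")))
  cat(sprintf("  max |dPMF| over last two batches: %.3f kcal/mol; %s\n",
              x$max_dev_last_two,
              if (x$drift) "WARNING: monotone endpoint drift"
              else "no monotone drift"))
  invisible(x)
}

#' Write a PMF curve as three-column text
#'
#' Columns: bin center (nm), free energy (kcal/mol, `NA` for unsampled
#' bins), sample count.
#'
#' @param pmf a `PMFCurve`.
#' @param path optional output path.
#' @return text lines, invisibly when writing to a file.
#' @export
write_pmf <- function(pmf, path = NULL) {
  txt <- c("# bin_center_nm dG_kcal_mol count",
           sprintf("%.6f %s %d", pmf$bin_centers,
                   ifelse(is.na(pmf$free_energy), "NA",
                          sprintf("%.8f", pmf$free_energy)),
                   pmf$sample_counts))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a PMF curve written by [write_pmf()]
#' @param text file path or text lines.
#' @return a `PMFCurve`.
#' @export
read_pmf <- function(text) {
  lines <- as_text_lines(text)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  parts <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
  bc <- as.numeric(parts[, 1])
  structure(list(bin_centers = bc,
                 free_energy = suppressWarnings(as.numeric(parts[, 2])),
                 sample_counts = as.integer(parts[, 3]),
                 bin_width = if (length(bc) > 1L) bc[2] - bc[1] else NA,
                 zero_convention = "global minimum = 0"),
            class = "PMFCurve")
}

#' Write umbrella windows (metadata file plus per-window series)
#'
#' The metadata file has one line per window: center, force constant and
#' the sample-series file name (two-column colvar dialect).
#'
#' @param windows list of `UmbrellaWindow`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return path of the metadata file, invisibly.
#' @export
write_umbrella_windows <- function(windows, dir, prefix = "window") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- vapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    fn <- sprintf("%s_%02d.dat", prefix, i)
    write_colvar(colvar_series("rc_nm", w$times, w$samples),
                 file.path(dir, fn))
    sprintf("%.6f %.6f %s", w$center, w$force_constant, fn)
  }, "")
  meta_path <- file.path(dir, paste0(prefix, "s.meta"))
  writeLines(c("# center_nm k_kcal_mol_nm2 file", meta), meta_path)
  invisible(meta_path)
}

#' Read umbrella windows written by [write_umbrella_windows()]
#' @param meta_path path of the metadata file.
#' @return list of `UmbrellaWindow`.
#' @export
read_umbrella_windows <- function(meta_path) {
  lines <- readLines(meta_path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty window metadata file")
  lapply(seq_along(lines), function(i) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    fn <- file.path(dirname(meta_path), toks[3L])
    if (!file.exists(fn)) stop("missing window data file: ", fn)
    ser <- read_colvar(fn)
    umbrella_window(as.numeric(toks[1L]), as.numeric(toks[2L]),
                    ser$times, ser$values, label = sprintf("w%02d", i))
  })
}
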