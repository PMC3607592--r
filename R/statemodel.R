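#' Reference structure for a conformational state
#'
#' @param label one of `"closed"`, `"half_closed"`, `"open"`.
#' @param reference a `Structure` (typically an X-ray model).
#' @param source free-text provenance tag (e.g. a PDB identifier).
#' @return object of class `StateReference`.
#' @export
state_reference <- function(label = c("closed", "half_closed", "open"),
                            reference, source = "") {
  label <- match.arg(label)
  structure(list(label = label, reference = reference, source = source),
            class = "StateReference")
}

moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - window %/% 2L)
    hi <- min(n, i + window %/% 2L)
    mean(x[lo:hi], na.rm = TRUE)
  }, numeric(1))
}

#' Locate minima, barriers and plateaus of a PMF
#'
#' After moving-average smoothing, local minima (including boundary
#' minima) with topographic prominence at least `min_prominence` are
#' kept; barriers are the maxima between adjacent kept minima; plateaus
#' are maximal intervals where the absolute slope stays below
#' `slope_threshold`. The default prominence of 0.5 kcal/mol is about
#' kT at 300 K, so only thermally meaningful features survive.
#'
#' @param pmf a `PMFCurve` with at least 5 bins.
#' @param smoothing_window moving-average window, bins.
#' @param min_prominence minimum prominence, kcal/mol.
#' @param slope_threshold plateau slope bound, kcal/mol/nm.
#' @return object of class `PMFFeatureSet`: `minima` (data.frame
#'   position/free_energy, sorted by position, energies relative to the
#'   global minimum), `barriers` (position/height between adjacent
#'   minima), `plateaus` (lo/hi/mean_dg).
#' @export
find_pmf_features <- function(pmf, smoothing_window = 3L,
                              min_prominence = 0.5,
                              slope_threshold = 5) {
  ok <- is.finite(pmf$free_energy)
  x <- pmf$bin_centers[ok]
  g <- pmf$free_energy[ok]
  if (length(g) < 5L) stop("PMF needs at least 5 sampled bins")
  gs <- moving_average(g, smoothing_window)
  n <- length(gs)
  is_min <- vapply(seq_len(n), function(i) {
    left <- if (i > 1L) gs[i - 1L] else Inf
    right <- if (i < n) gs[i + 1L] else Inf
    gs[i] < left && gs[i] <= right
  }, logical(1))
  cand <- which(is_min)
  prominence <- vapply(cand, function(i) {
    side <- function(idx_range) {
      if (length(idx_range) == 0L) return(Inf)
      run_max <- -Inf
      for (j in idx_range) {
        if (gs[j] < gs[i]) return(run_max - gs[i])
        run_max <- max(run_max, gs[j])
      }
      run_max - gs[i]  # reached the boundary without a lower point
    }
    min(side(rev(seq_len(i - 1L))), side(seq_len(n - i) + i))
  }, numeric(1))
  keep <- cand[prominence >= min_prominence]
  if (length(keep) == 0L)
    stop("no PMF minima found; lower min_prominence")
  minima <- data.frame(position = x[keep],
                       free_energy = gs[keep] - min(gs[keep]))
  barriers <- NULL
  if (length(keep) > 1L) {
    barriers <- do.call(rbind, lapply(seq_len(length(keep) - 1L),
      function(kk) {
        seg <- keep[kk]:keep[kk + 1L]
        im <- seg[which.max(gs[seg])]
        data.frame(position = x[im],
                   height = gs[im] - min(gs[keep]))
      }))
  }
  slope <- c(NA, diff(gs) / diff(x))
  flat <- abs(slope) < slope_threshold
  flat[is.na(flat)] <- FALSE
  runs <- rle(flat)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  pl <- which(runs$values & runs$lengths >= 3L)
  plateaus <- if (length(pl) > 0L)
    do.call(rbind, lapply(pl, function(r)
      data.frame(lo = x[starts[r]], hi = x[ends[r]],
                 mean_dg = mean(gs[starts[r]:ends[r]]) - min(gs[keep]))))
  structure(list(minima = minima, barriers = barriers,
                 plateaus = plateaus),
            class = "PMFFeatureSet")
}

#' @export
print.PMFFeatureSet <- function(x, ...) {
  cat(sprintf("PMFFeatureSet: %d minima at %s nm (dG %s kcal/mol)\n",
              nrow(x$minima),
              paste(sprintf("%.3f", x$minima$position), collapse = ", "),
              paste(sprintf("%.2f", x$minima$free_energy),
                    collapse = ", ")))
  invisible(x)
}

#' State label from a table of reference RMSDs
#'
#' The argmin rule used for three-state assignment: the label of the
#' reference with the smallest RMSD wins; ties within 1e-6 nm are an
#' error (a finer selection is needed), never broken arbitrarily.
#'
#' @param rmsd_table named numeric vector of RMSDs (nm) per state label.
#' @return the winning label.
#' @export
state_from_rmsd <- function(rmsd_table) {
  if (length(rmsd_table) < 2L) stop("need at least 2 references")
  o <- order(rmsd_table)
  if (abs(rmsd_table[o[2L]] - rmsd_table[o[1L]]) < 1e-6)
    stop("RMSD tie between states '", names(rmsd_table)[o[1L]], "' and '",
         names(rmsd_table)[o[2L]], "'; use a finer selection")
  names(rmsd_table)[o[1L]]
}

#' Assign a conformation to a state by reference RMSD
#'
#' Kabsch-fit RMSD of the frame to each reference structure over the
#' common selection; the frame gets the label of the closest reference.
#'
#' @param frame a `Structure` or coordinate matrix.
#' @param references list of `StateReference` (>= 2, unique labels).
#' @param sel `Selection` mappable across the frame and all references.
#' @return list with `label` and the full `rmsd_table` (named vector,
#'   nm) for reporting.
#' @export
assign_state_by_rmsd <- function(frame, references, sel = NULL) {
  if (length(references) < 2L) stop("need at least 2 state references")
  labels <- vapply(references, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("state labels must be unique")
  tab <- vapply(references, function(ref)
    rmsd(frame, ref$reference, sel, superpose = TRUE), numeric(1))
  names(tab) <- labels
  list(label = state_from_rmsd(tab), rmsd_table = tab)
}

#' Free-energy difference between two points or plateaus of a PMF
#'
#' `dG = G(state_b) - G(state_a)`. Each state is either a position (nm;
#' the nearest sampled bin is used) or an interval `c(lo, hi)` whose
#' mean PMF is used — the reproducible version of reading a broad
#' plateau off a free-energy curve instead of a sharp minimum.
#'
#' @param pmf a `PMFCurve`.
#' @param state_a,state_b position or interval, nm.
#' @return dG in kcal/mol, with the evaluated state definitions attached
#'   as attribute `"states"`.
#' @export
endpoint_delta_g <- function(pmf, state_a, state_b) {
  eval_state <- function(st) {
    if (length(st) == 1L) {
      ok <- which(is.finite(pmf$free_energy))
      if (length(ok) == 0L) stop("PMF has no sampled bins")
      i <- ok[which.min(abs(pmf$bin_centers[ok] - st))]
      if (abs(pmf$bin_centers[i] - st) > 2 * pmf$bin_width)
        stop(sprintf("state position %.3f nm is outside the sampled PMF",
                     st))
      pmf$free_energy[i]
    } else {
      inb <- pmf$bin_centers >= st[1] & pmf$bin_centers <= st[2]
      vals <- pmf$free_energy[inb]
      if (!any(is.finite(vals)))
        stop("state interval contains no sampled bins")
      mean(vals[is.finite(vals)])
    }
  }
  ga <- eval_state(state_a); gb <- eval_state(state_b)
  structure(gb - ga, states = list(a = state_a, b = state_b))
}

#' Combine the two binding substeps into total binding free energies
#'
#' The binding (or unbinding) process is decomposed into two sequential
#' substeps: (I) opening of the initially closed receptor and (II)
#' removal of the ligand from the open binding site. Inputs are
#' positive costs of the forward (unbinding-direction) substeps in
#' kcal/mol. The umbrella-sampling total is `step I(US) + step II(US)`;
#' when a metadynamics estimate of step I is supplied, the combined
#' estimate averages the two step-I values before adding step II. The
#' binding free energies are the negations, and sign conventions are
#' explicit in the report.
#'
#' @param dg_open_us step I (receptor opening) from umbrella sampling,
#'   kcal/mol.
#' @param dg_dissociate_us step II (ligand dissociation) from umbrella
#'   sampling, kcal/mol.
#' @param dg_open_metad optional step I from metadynamics, kcal/mol.
#' @param ligand ligand label for reporting.
#' @param uncertainty optional uncertainty note echoed into the report
#'   (not re-derived).
#' @return object of class `BindingFreeEnergyReport` with fields
#'   `dg_open` (per method), `dg_dissociate`, `dg_total_us`,
#'   `dg_combined` (`NA` without metadynamics input), `dg_bind_us`,
#'   `dg_bind_combined`, plus 2- and 1-decimal display roundings.
#' @export
combine_two_step <- function(dg_open_us, dg_dissociate_us,
                             dg_open_metad = NULL, ligand = "ligand",
                             uncertainty = NULL) {
  if (missing(dg_open_us) || missing(dg_dissociate_us) ||
      is.null(dg_open_us) || is.null(dg_dissociate_us))
    stop("both umbrella-sampling substep inputs are required")
  dg_total_us <- dg_open_us + dg_dissociate_us
  dg_combined <- if (is.null(dg_open_metad)) NA_real_
                 else mean(c(dg_open_us, dg_open_metad)) + dg_dissociate_us
  rep2 <- function(v) round(v, 2)
  rep1 <- function(v) round(v, 1)
  structure(list(
    ligand = ligand,
    dg_open = c(us = dg_open_us,
                metadynamics = if (is.null(dg_open_metad)) NA_real_
                               else dg_open_metad),
    dg_dissociate = dg_dissociate_us,
    dg_total_us = dg_total_us,
    dg_combined = dg_combined,
    dg_bind_us = -dg_total_us,
    dg_bind_combined = -dg_combined,
    display = list(dg_total_us = c(rep2(dg_total_us), rep1(dg_total_us)),
                   dg_bind_us = c(rep2(-dg_total_us), rep1(-dg_total_us)),
                   dg_combined = c(rep2(dg_combined), rep1(dg_combined)),
                   dg_bind_combined = c(rep2(-dg_combined),
                                        rep1(-dg_combined))),
    uncertainty = uncertainty,
    sign_convention = paste("substep dG are positive unbinding costs;",
                            "binding free energies are their negations")
  ), class = "BindingFreeEnergyReport")
}

#' @export
print.BindingFreeEnergyReport <- function(x, ...) {
  cat(sprintf("Binding free energies for %s (kcal/mol)\n", x$ligand))
  cat(sprintf("  step I  (opening, US):      %+6.2f\n", x$dg_open[["us"]]))
  if (!is.na(x$dg_open[["metadynamics"]]))
    cat(sprintf("  step I  (opening, MetaD):   %+6.2f\n",
                x$dg_open[["metadynamics"]]))
  cat(sprintf("  step II (dissociation, US): %+6.2f\n", x$dg_dissociate))
  cat(sprintf("  US total (I + II):          %+6.2f  => dG_bind = %+.1f\n",
              x$dg_total_us, x$dg_bind_us))
  if (!is.na(x$dg_combined))
    cat(sprintf("  combined (mean I + II):     %+6.2f  => dG_bind = %+.1f\n",
                x$dg_combined, x$dg_bind_combined))
  if (!is.null(x$uncertainty))
    cat(sprintf("  uncertainty: %s\n", x$uncertainty))
  cat(sprintf("  convention: %s\n", x$sign_convention))
  invisible(x)
}

#' Format binding reports as a two-ligand summary table
#'
#' Rows: US Step1, US Step2, US Sigma, Metadynamics, Combined; one
#' column per ligand — the standard layout for reporting the two-substep
#' decomposition side by side.
#'
#' @param reports list of `BindingFreeEnergyReport`.
#' @return data.frame with one column per ligand.
#' @export
binding_report_table <- function(reports) {
  cols <- lapply(reports, function(r)
    c(`US Step1` = r$dg_open[["us"]],
      `US Step2` = r$dg_dissociate,
      `US Sigma` = r$dg_total_us,
      Metadynamics = r$dg_open[["metadynamics"]],
      Combined = r$dg_combined))
  df <- as.data.frame(cols)
  names(df) <- vapply(reports, `[[`, "", "ligand")
  df
}
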