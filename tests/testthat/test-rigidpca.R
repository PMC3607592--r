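test_that("strip_internal_motion is a fixed point on rigid input and forces rigidity", {
  p <- clamshell_toy_params(atoms_per_domain = 20L, hinge_atoms = 6L,
                            jitter = 0, seed = 3)
  traj <- generate_clamshell_trajectory(p, n_frames = 10)
  model <- attr(traj, "model")
  stripped <- strip_internal_motion(traj, model)
  expect_lt(max(abs(stripped$coords - traj$coords)), 1e-9)

  pj <- clamshell_toy_params(atoms_per_domain = 20L, hinge_atoms = 6L,
                             jitter = 0.05, seed = 3)
  tj <- generate_clamshell_trajectory(pj, n_frames = 10)
  mj <- attr(tj, "model")
  sj <- strip_internal_motion(tj, mj)
  # after substitution every frame's domain is an exact rigid copy of
  # the reference: internal RMSD to the fitted reference is 0
  ref <- mj$reference$xyz[mj$dom1$indices, ]
  for (i in seq_len(n_frames(sj))) {
    fi <- frame_coords(sj, i)[mj$dom1$indices, ]
    expect_lt(kabsch_superpose(ref, fi)$rmsd, 1e-9)
  }
})

test_that("stripping preserves the planted angle and removes internal noise", {
  p <- clamshell_toy_params(atoms_per_domain = 40L, hinge_atoms = 30L,
                            jitter = 0.015, seed = 17,
                            twist_amplitude = 0, rock_amplitude = 0)
  traj <- generate_clamshell_trajectory(p, n_frames = 40)
  model <- attr(traj, "model"); gt <- attr(traj, "ground_truth")
  spec <- colvar_spec("interdomain_angle",
                      selections = list(dom1 = model$dom1,
                                        dom2 = model$dom2,
                                        hinge = model$hinge))
  raw_err <- max(abs(colvar_timeseries(traj, spec)$values - gt$angle))
  stripped <- strip_internal_motion(traj, model)
  strip_err <- max(abs(colvar_timeseries(stripped, spec)$values -
                         gt$angle))
  # the Kabsch fit is centroid-preserving, so with equal masses the
  # domain COMs (hence the angle) are unchanged by stripping; it must
  # never get worse, and must stay within 1 degree of the plant
  expect_lte(strip_err, raw_err + 1e-9)
  expect_lt(strip_err, 1)
  # what stripping does remove is internal fluctuation: per-domain RMSF
  # of the stripped trajectory collapses relative to the raw one
  d1 <- model$dom1$indices
  aligned <- function(tr) {
    cc <- tr$coords
    for (i in seq_len(n_frames(tr)))
      cc[i, , ] <- kabsch_superpose(frame_coords(tr, i),
                                    frame_coords(tr, 1), d1)$coords
    new_trajectory(cc, tr$times, tr$topology)
  }
  expect_lt(mean(rmsf(aligned(stripped), d1)),
            0.2 * mean(rmsf(aligned(traj), d1)))
})

test_that("rigid_pca finds a planted rank-1 mode and scales eigenvalues as amplitude^2", {
  set.seed(5)
  nat <- 30L
  base <- matrix(rnorm(3 * nat), nat, 3)
  dirv <- rnorm(3 * nat); dirv <- dirv / sqrt(sum(dirv^2))
  amps <- 0.2 * sin(2 * pi * (1:80) / 16)
  frames <- lapply(seq_len(80), function(k)
    base + matrix(dirv, nat, 3) * amps[k])
  traj <- toy_trajectory(frames)
  model <- rigid_body_model(new_selection(1:10, n = nat),
                            new_selection(16:30, n = nat),
                            new_selection(11:15, n = nat),
                            reference = toy_structure(base))
  # no stripping, no alignment distortion: analyse the planted mode as-is
  pca <- rigid_pca(traj, model, align_sel = "none", strip = FALSE,
                   backbone_only = FALSE)
  expect_gt(pca$eigenvalues[1] / sum(pca$eigenvalues), 0.999)
  expect_gt(abs(sum(pca$eigenvectors[, 1] * dirv)), 0.999)
})

test_that("two orthogonal planted modes give a 4:1 eigenvalue ratio for 2:1 amplitudes", {
  set.seed(6)
  nat <- 30L
  base <- matrix(rnorm(3 * nat), nat, 3)
  v1 <- rnorm(3 * nat); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- rnorm(3 * nat); v2 <- v2 - sum(v2 * v1) * v1
  v2 <- v2 / sqrt(sum(v2^2))
  tt <- 1:200
  a1 <- 0.2 * sin(2 * pi * tt / 20)   # integer cycles: exact variance
  a2 <- 0.1 * sin(2 * pi * tt / 10)
  frames <- lapply(tt, function(k)
    base + matrix(v1, nat, 3) * a1[k] + matrix(v2, nat, 3) * a2[k])
  model <- rigid_body_model(new_selection(1:10, n = nat),
                            new_selection(16:30, n = nat),
                            new_selection(11:15, n = nat),
                            reference = toy_structure(base))
  pca <- rigid_pca(toy_trajectory(frames), model, strip = FALSE,
                   backbone_only = FALSE, align_sel = "none")
  expect_equal(pca$eigenvalues[1] / pca$eigenvalues[2], 4,
               tolerance = 0.02)
})

test_that("static trajectories have (numerically) zero eigenvalues", {
  base <- matrix(rnorm(36), 12, 3)
  traj <- toy_trajectory(rep(list(base), 5))
  model <- rigid_body_model(new_selection(1:4, n = 12),
                            new_selection(9:12, n = 12),
                            new_selection(5:8, n = 12),
                            reference = toy_structure(base))
  pca <- rigid_pca(traj, model, strip = FALSE, backbone_only = FALSE)
  expect_lt(max(pca$eigenvalues), 1e-20)
})

test_that("eigenvectors are orthonormal and total variance is conserved", {
  p <- clamshell_toy_params(atoms_per_domain = 30L, hinge_atoms = 10L,
                            seed = 23)
  traj <- generate_clamshell_trajectory(p, n_frames = 60)
  model <- attr(traj, "model")
  pca <- rigid_pca(traj, model)
  gram <- crossprod(pca$eigenvectors)
  expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-8)
  # trace of the covariance equals the eigenvalue sum
  stripped <- strip_internal_motion(traj, model)
  proj <- project_onto_modes(stripped, pca,
                             n_modes = ncol(pca$eigenvectors))
  total_proj_var <- sum(vapply(proj, function(s) var(s$values),
                               numeric(1)))
  expect_equal(sum(pca$eigenvalues), total_proj_var,
               tolerance = 1e-6)
})

test_that("rigid_pca is invariant (up to sign) under a global rigid motion", {
  p <- clamshell_toy_params(atoms_per_domain = 30L, hinge_atoms = 10L,
                            seed = 29)
  traj <- generate_clamshell_trajectory(p, n_frames = 40)
  model <- attr(traj, "model")
  pca1 <- rigid_pca(traj, model)
  set.seed(1)
  rot <- random_rotation(); shift <- c(1, -2, 0.5)
  moved <- traj$coords
  for (i in seq_len(n_frames(traj)))
    moved[i, , ] <- sweep(frame_coords(traj, i) %*% t(rot), 2, shift, "+")
  pca2 <- rigid_pca(new_trajectory(moved, traj$times, traj$topology),
                    model)
  expect_equal(pca1$eigenvalues[1:3], pca2$eigenvalues[1:3],
               tolerance = 1e-6)
  # alignment references the (rotated) first frame, so the eigenvector
  # fields come back expressed in the rotated frame: rotating them back
  # per atom must reproduce the originals up to sign
  na <- length(pca1$atom_indices)
  for (m in 1:3) {
    v2 <- matrix(pca2$eigenvectors[, m], na, 3) %*% rot
    expect_gt(abs(sum(pca1$eigenvectors[, m] * as.vector(v2))),
              1 - 1e-6)
  }
})

test_that("projections reconstruct the input and vanish at the mean", {
  p <- clamshell_toy_params(atoms_per_domain = 20L, hinge_atoms = 8L,
                            seed = 37, jitter = 0)
  traj <- generate_clamshell_trajectory(p, n_frames = 30)
  model <- attr(traj, "model")
  pca <- rigid_pca(traj, model, strip = FALSE)
  k <- ncol(pca$eigenvectors)
  proj <- project_onto_modes(traj, pca, n_modes = k)
  pm <- do.call(cbind, lapply(proj, `[[`, "values"))
  # full-basis reconstruction: per-frame residual is numerically zero
  idx <- pca$atom_indices
  ref <- pca$reference_frame
  for (i in c(1, 15, 30)) {
    al <- kabsch_superpose(frame_coords(traj, i), ref,
                           pca$align_indices)$coords
    x0 <- as.vector(al[idx, ]) - as.vector(pca$mean_coordinates)
    recon <- pca$eigenvectors %*% pm[i, ]
    expect_lt(sqrt(mean((x0 - recon)^2)), 1e-8)
  }
  expect_error(project_onto_modes(traj, pca, n_modes = k + 1),
               "exceeds")
})

test_that("mode arrows have the requested norm and survive PDB round-trip", {
  p <- clamshell_toy_params(atoms_per_domain = 20L, hinge_atoms = 8L,
                            seed = 41)
  traj <- generate_clamshell_trajectory(p, n_frames = 30)
  model <- attr(traj, "model")
  pca <- rigid_pca(traj, model)
  arrows <- export_mode_arrows(pca, traj$topology, mode = 1, scale = 0.25)
  disp <- arrows$plus$xyz - pca$mean_coordinates
  expect_equal(sum(disp^2), 0.25^2, tolerance = 1e-10)
  # mode 1 displacement lives on lobe 2 when aligned on lobe 1
  on2 <- pca$atom_indices %in% model$dom2$indices
  expect_gt(sum(disp[on2, ]^2) / sum(disp^2), 0.9)
  rt <- read_multimodel_pdb(write_multimodel_pdb(arrows$trajectory))
  expect_lt(max(abs(rt$coords[1, , ] - arrows$plus$xyz)), 1e-4)
  expect_error(export_mode_arrows(pca, traj$topology, 1, scale = 0),
               "positive")
})

test_that("PCA results serialize losslessly to plain text", {
  p <- clamshell_toy_params(atoms_per_domain = 15L, hinge_atoms = 6L,
                            seed = 43)
  traj <- generate_clamshell_trajectory(p, n_frames = 20)
  pca <- rigid_pca(traj, attr(traj, "model"))
  rt <- read_pca_result(write_pca_result(pca))
  expect_equal(rt$eigenvalues, pca$eigenvalues, tolerance = 1e-10)
  expect_equal(rt$eigenvectors, pca$eigenvectors, tolerance = 1e-10)
  expect_equal(rt$mean_coordinates, pca$mean_coordinates,
               tolerance = 1e-9)
  expect_equal(rt$mode_labels, pca$mode_labels)
  expect_equal(rt$atom_indices, pca$atom_indices)
})
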