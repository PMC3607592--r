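unit_window <- function(samples, center = 0.5, k = 100,
                        times = seq_along(samples)) {
  umbrella_window(center, k, times, samples)
}

test_that("build_histograms bins on a shared half-open grid", {
  w <- unit_window(c(0.505))
  h <- build_histograms(list(w), 0.01, c(0.5, 0.6))
  expect_equal(sum(h$counts), 1L)
  expect_equal(h$bin_centers[which(h$counts[1, ] == 1)], 0.505)

  # a sample exactly on an edge belongs to the right bin
  edge <- build_histograms(list(unit_window(0.51)), 0.01, c(0.5, 0.6))
  expect_equal(edge$bin_centers[which(edge$counts[1, ] == 1)], 0.515)

  set.seed(3)
  x <- rnorm(1e4, 0.7, 0.05)
  h2 <- build_histograms(list(unit_window(x)), 0.01, c(0.5, 0.9))
  # independent per-sample binning loop
  oracle <- integer(ncol(h2$counts))
  for (v in x) {
    j <- floor((v - 0.5) / 0.01) + 1
    if (j >= 1 && j <= length(oracle)) oracle[j] <- oracle[j] + 1L
  }
  expect_equal(as.integer(h2$counts[1, ]), oracle)
  expect_equal(h2$n_outside[1], sum(x < 0.5 | x >= 0.9))
  expect_error(build_histograms(list(unit_window(5)), 0.01, c(0, 1)),
               "outside")
})

test_that("WHAM degenerates to Boltzmann inversion for one unbiased window", {
  set.seed(8)
  x <- rnorm(2e4, 0.7, 0.06)
  w <- umbrella_window(0.7, 0, seq_along(x), x)  # k = 0: no bias
  pmf <- wham_pmf(list(w), 0.01, c(0.4, 1.0))
  hist <- attr(pmf, "histograms")
  ok <- hist$counts[1, ] > 0
  direct <- -kT_kcal(300) * log(hist$counts[1, ok])
  direct <- direct - min(direct)
  expect_equal(pmf$free_energy[ok], direct, tolerance = 1e-8)
})

test_that("identical windows get identical offsets", {
  set.seed(9)
  x <- rnorm(5000, 0.6, 0.03)
  w1 <- umbrella_window(0.6, 400, seq_along(x), x)
  w2 <- umbrella_window(0.6, 400, seq_along(x), x)
  hist <- build_histograms(list(w1, w2), 0.01)
  sol <- solve_wham(hist, list(w1, w2))
  expect_equal(sol$offsets[1], sol$offsets[2], tolerance = 1e-9)
})

test_that("WHAM recovers a harmonic PMF from seeded umbrella data", {
  pot <- harmonic_potential(20, 0.75)
  lp <- langevin_params(n_steps = 4e5, seed = 11, timestep = 2e-4,
                        save_stride = 20)
  win <- generate_umbrella_dataset(pot, seq(0.45, 1.05, 0.15), 200, lp)
  pmf <- wham_pmf(win, 0.01)
  expect_lt(pmf_deviation(pmf, pot), 0.1)
  sol <- attr(pmf, "solution")
  expect_lt(sol$residual, 1e-7)
})

test_that("flat histograms give a flat PMF", {
  counts <- matrix(100L, 1, 20)
  hist <- structure(list(bin_centers = seq(0.505, 0.695, 0.01),
                         counts = counts, n_outside = 0L,
                         edges = seq(0.5, 0.7, 0.01), bin_width = 0.01),
                    class = "WhamHistograms")
  w <- umbrella_window(0.6, 0, 1, 0.6)
  sol <- solve_wham(hist, list(w))
  pmf <- pmf_from_wham(sol, hist)
  expect_equal(max(abs(pmf$free_energy)), 0, tolerance = 1e-10)
})

test_that("double-well asymmetry and minima locations are recovered", {
  pot <- double_well_potential(barrier = 4, delta = 1.19, width = 0.1)
  lp <- langevin_params(n_steps = 6e5, seed = 5, timestep = 1e-4,
                        save_stride = 10)
  win <- generate_umbrella_dataset(pot, seq(0.40, 1.30, 0.05), 500, lp)
  pmf <- wham_pmf(win, 0.01)
  expect_equal(endpoint_delta_g(pmf, 0.53, 1.12), 1.19,
               tolerance = 0.15, ignore_attr = TRUE)
  feat <- find_pmf_features(pmf)
  expect_equal(nrow(feat$minima), 2L)
  expect_lt(max(abs(feat$minima$position - c(0.53, 1.12))), 0.011)
})

test_that("histogram overlap: identity, disjoint and Gaussian closed form", {
  set.seed(1)
  x <- rnorm(2000, 0.6, 0.02)
  wA <- unit_window(x); wB <- unit_window(x)
  hist <- build_histograms(list(wA, wB), 0.005)
  expect_equal(histogram_overlap(hist)[1, 2], 1, tolerance = 1e-12)

  w1 <- unit_window(rep(0.52, 10)); w2 <- unit_window(rep(0.58, 10))
  hd <- build_histograms(list(w1, w2), 0.005, c(0.5, 0.6))
  expect_equal(histogram_overlap(hd)[1, 2], 0)

  # two unit-variance Gaussians 2 sigma apart: overlap = 2*Phi(-1)
  grid <- seq(-6, 8, by = 0.02)
  counts <- rbind(dnorm(grid, 0, 1), dnorm(grid, 2, 1)) * 1e6
  hg <- structure(list(bin_centers = grid, counts = counts,
                       n_outside = c(0L, 0L),
                       edges = c(grid - 0.01, max(grid) + 0.01),
                       bin_width = 0.02),
                  class = "WhamHistograms")
  expect_equal(histogram_overlap(hg)[1, 2], 2 * pnorm(-1),
               tolerance = 1e-3)
})

test_that("disconnected window sets are rejected with a useful error", {
  w1 <- unit_window(rnorm(100, 0.5, 0.005), center = 0.5)
  w2 <- unit_window(rnorm(100, 0.9, 0.005), center = 0.9)
  hist <- build_histograms(list(w1, w2), 0.01, c(0.4, 1.0))
  expect_error(solve_wham(hist, list(w1, w2)), "disconnected")
})

test_that("batch convergence: duplicated data gives identical batches, drift is flagged", {
  pot <- harmonic_potential(20, 0.75)
  lp <- langevin_params(n_steps = 2e5, seed = 31, timestep = 2e-4,
                        save_stride = 20)
  win <- generate_umbrella_dataset(pot, seq(0.55, 0.95, 0.1), 300, lp)
  # duplicate every window's series in time: batches must coincide
  dup <- lapply(win, function(w)
    umbrella_window(w$center, w$force_constant,
                    c(w$times, w$times + max(w$times)),
                    c(w$samples, w$samples), w$label))
  rep2 <- batch_convergence(dup, 2, 0.01)
  expect_equal(rep2$batch_pmfs[[1]]$free_energy,
               rep2$batch_pmfs[[2]]$free_energy, tolerance = 1e-9)
  expect_lt(rep2$max_dev_last_two, 1e-9)
  expect_equal(diff(rep2$endpoint_dg), 0, tolerance = 1e-9)

  # planted drift: shift each window's samples linearly in time
  drift <- lapply(win, function(w) {
    shift <- 0.1 * (w$times / max(w$times))
    umbrella_window(w$center, w$force_constant, w$times,
                    w$samples + shift, w$label)
  })
  repd <- batch_convergence(drift, 4, 0.01, state_a = 0.75,
                            state_b = c(0.92, 1.0))
  expect_true(repd$drift)
  expect_false(rep2$drift)
})

test_that("stationary batches agree within statistical error", {
  pot <- harmonic_potential(20, 0.75)
  lp <- langevin_params(n_steps = 8e5, seed = 37, timestep = 2e-4,
                        save_stride = 20)
  win <- generate_umbrella_dataset(pot, seq(0.55, 0.95, 0.1), 300, lp)
  conv <- batch_convergence(win, 4, 0.01)
  # block-bootstrap scale of the endpoint estimate over batches
  boot_sd <- sd(conv$endpoint_dg)
  expect_lt(abs(conv$endpoint_dg[4] - conv$endpoint_dg[3]),
            pmax(2 * boot_sd, 0.05) * 2)
  expect_lt(conv$max_dev_last_two, 0.15)
})

test_that("windows and PMFs round-trip through their file dialects", {
  set.seed(13)
  win <- list(umbrella_window(0.5, 500, 1:50, rnorm(50, 0.5, 0.02)),
              umbrella_window(0.55, 500, 1:50, rnorm(50, 0.55, 0.02)))
  dir <- withr::local_tempdir()
  meta <- write_umbrella_windows(win, dir)
  back <- read_umbrella_windows(meta)
  expect_equal(back[[1]]$center, 0.5)
  expect_equal(back[[2]]$samples, win[[2]]$samples, tolerance = 1e-9)

  pmf <- wham_pmf(win, 0.01)
  rt <- read_pmf(write_pmf(pmf))
  expect_equal(rt$bin_centers, pmf$bin_centers, tolerance = 1e-6)
  expect_equal(rt$free_energy, pmf$free_energy, tolerance = 1e-7)
})

test_that("offsets are invariant under window reordering", {
  pot <- harmonic_potential(20, 0.75)
  lp <- langevin_params(n_steps = 1e5, seed = 41, timestep = 2e-4,
                        save_stride = 20)
  win <- generate_umbrella_dataset(pot, seq(0.55, 0.95, 0.1), 300, lp)
  pmf1 <- wham_pmf(win, 0.01, range = c(0.4, 1.1))
  pmf2 <- wham_pmf(rev(win), 0.01, range = c(0.4, 1.1))
  expect_equal(pmf1$free_energy, pmf2$free_energy, tolerance = 1e-6)
})
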