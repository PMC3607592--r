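two_hills <- function() {
  hill_ledger(rbind(c(1, 0.5, 0.1, 0.4),
                    c(2, 0.8, 0.2, 0.3)), 1L)
}

test_that("bias_at: empty ledger, single hill, two-hill hand formula", {
  empty <- hill_ledger(matrix(0, 0, 4), 1L)
  expect_equal(bias_at(empty, c(0, 1, 2)), c(0, 0, 0))

  one <- hill_ledger(matrix(c(5, 0.7, 0.05, 0.3), 1, 4), 1L)
  expect_equal(bias_at(one, 0.7), 0.3)
  expect_equal(bias_at(one, 0.7, t = 4), 0)  # not deposited yet

  led <- two_hills()
  x <- 0.63
  hand <- 0.4 * exp(-(x - 0.5)^2 / (2 * 0.1^2)) +
    0.3 * exp(-(x - 0.8)^2 / (2 * 0.2^2))
  expect_equal(bias_at(led, x), hand, tolerance = 1e-12)
  # 5-sigma truncation: hill 1 (sigma 0.1) is cut at 1.01, hill 2 is not
  expect_equal(bias_at(led, 1.01),
               0.3 * exp(-(1.01 - 0.8)^2 / (2 * 0.2^2)),
               tolerance = 1e-12)
})

test_that("bias is non-decreasing in time at fixed points", {
  led <- two_hills()
  pts <- seq(0.3, 1.0, by = 0.05)
  v0 <- bias_at(led, pts, t = 0)
  v1 <- bias_at(led, pts, t = 1)
  v2 <- bias_at(led, pts, t = 2)
  expect_true(all(v1 >= v0) && all(v2 >= v1))
})

test_that("hill ledgers round-trip and the authored fixture parses", {
  led <- two_hills()
  rt <- read_hills(write_hills(led))
  expect_equal(rt$hills, led$hills, tolerance = 1e-12)
  expect_equal(rt$dimension, 1L)

  fx <- read_hills(system.file("extdata", "sample_hills.dat",
                               package = "clamshellfe"))
  expect_equal(nrow(fx$hills), 3L)
  expect_equal(unname(fx$hills[, "time"]), c(10, 20, 30))
  expect_equal(unname(fx$hills[, 2]), c(0.53, 0.76, 1.12))
  expect_equal(unname(fx$hills[, "height"]), c(0.5, 0.2, 0.05))

  expect_error(read_hills(c("1 0.5 0.05 0.2", "2 0.6 0.05")), "ragged")
  expect_error(hill_ledger(rbind(c(2, 0.5, 0.1, 0.4),
                                 c(1, 0.8, 0.2, 0.3)), 1L),
               "non-decreasing")
})

test_that("a zero-duration schedule reduces to unbiased Langevin dynamics", {
  pot <- double_well_potential()
  lp <- langevin_params(n_steps = 2e4, seed = 55, timestep = 1e-4,
                        save_stride = 10)
  res <- run_metadynamics(pot, hill_schedule(0.5, 1, 0), 0.05, lp)
  expect_equal(nrow(res$ledger$hills), 0L)
  plain <- simulate_langevin(pot, lp)
  expect_identical(res$trajectory$values, plain$values)
})

test_that("hill count follows the schedule arithmetic exactly", {
  pot <- double_well_potential()
  lp <- langevin_params(n_steps = 4e5, seed = 9, timestep = 1e-4,
                        save_stride = 100)
  sch <- hill_schedule(c(0.3, 0.1), c(1, 0.5), c(20, 15))
  res <- run_metadynamics(pot, sch, 0.05, lp)
  expect_equal(nrow(res$ledger$hills), 20 / 1 + 15 / 0.5)
  # phase boundaries carry the right heights
  expect_equal(unique(res$ledger$hills[1:20, "height"]), 0.3)
  expect_equal(unique(res$ledger$hills[21:50, "height"]), 0.1)
})

test_that("filling a flat landscape yields a flat FES", {
  flat <- gaussian_wells_potential(c(0.4, 1.1), c(1e-8, 1e-8), 0.1,
                                   walls = list(lo = 0.4, hi = 1.1,
                                                k = 500))
  lp <- langevin_params(n_steps = 3e6, seed = 3, timestep = 2e-4,
                        save_stride = 100)
  res <- run_metadynamics(flat, hill_schedule(0.05, 1, 500), 0.05, lp,
                          x0 = 0.75)
  fes <- reconstruct_fes(res$ledger, list(lo = -0.4, hi = 1.9, n = 301),
                         average_from = 250)
  # plain metadynamics ripples at the sqrt(h*kT) scale; with 0.05 hills
  # the filled surface is flat to well under kT over the interior,
  # i.e. trivially flat relative to any kcal-scale landscape feature
  core <- fes$axes[[1]] > 0.55 & fes$axes[[1]] < 0.95
  expect_lt(diff(range(fes$values[core])), 0.5)
})

test_that("metadynamics multiplies basin transitions on the double well", {
  pot <- double_well_potential(barrier = 4, delta = 1.0, width = 0.1)
  lp <- langevin_params(n_steps = 4e6, seed = 13, timestep = 2e-4,
                        save_stride = 100)
  res <- run_metadynamics(pot, hill_schedule(c(0.5, 0.05), c(1, 1),
                                             c(300, 500)), 0.05, lp)
  n_meta <- count_transitions(res$trajectory$values, 0.65, 1.0)
  ub <- simulate_langevin(pot, lp, x0 = 0.53)
  n_plain <- count_transitions(ub$values, 0.65, 1.0)
  expect_gt(n_meta, 10 * max(n_plain, 1))

  fes <- reconstruct_fes(res$ledger, list(lo = -0.3, hi = 2.0, n = 461),
                         average_from = 500)
  dg <- basin_delta_g(fes, c(1.0, 1.25), c(0.4, 0.65))
  expect_equal(dg$delta_g, 1.0, tolerance = 0.3)
})

test_that("basin free energies: symmetry, identity, narrow-well limit", {
  xs <- seq(0, 2, by = 0.005)
  sym <- abs(4 - 8 * exp(-(xs - 0.5)^2 / 0.005) -
               8 * exp(-(xs - 1.5)^2 / 0.005))
  fes_sym <- structure(list(axes = list(xs),
                            values = array(sym - min(sym)),
                            dimension = 1L,
                            zero_convention = "global minimum = 0"),
                       class = "FreeEnergySurface")
  dg <- basin_delta_g(fes_sym, c(0.3, 0.7), c(1.3, 1.7))
  expect_equal(dg$delta_g, 0, tolerance = 1e-3)
  expect_equal(dg$min_to_min, 0, tolerance = 1e-9)

  # planted 2.0 kcal/mol between deep narrow wells: basin-integrated and
  # min-to-min agree within 0.1
  pot <- double_well_potential(barrier = 8, delta = 2, width = 0.03)
  vals <- potential_value(pot, xs)
  fes2 <- structure(list(axes = list(xs),
                         values = array(vals - min(vals)),
                         dimension = 1L,
                         zero_convention = "global minimum = 0"),
                    class = "FreeEnergySurface")
  dg2 <- basin_delta_g(fes2, c(1.0, 1.25), c(0.4, 0.65))
  expect_equal(dg2$min_to_min, 2, tolerance = 1e-6)
  expect_lt(abs(dg2$delta_g - dg2$min_to_min), 0.1)
  expect_error(basin_delta_g(fes2, c(0.4, 0.65), c(0.5, 0.7)),
               "disjoint")
  expect_error(basin_delta_g(fes2, c(-2, -1.9), c(0.4, 0.65)),
               "no grid points")
})

test_that("projection of a separable 2D FES matches the marginal", {
  xs <- seq(0, 1.5, by = 0.01); ys <- seq(-0.5, 0.5, by = 0.01)
  f1 <- 3 * (xs - 0.7)^2
  f2 <- 8 * ys^2
  vals <- outer(f1, f2, `+`)
  fes <- structure(list(axes = list(xs, ys), values = vals,
                        dimension = 2L,
                        zero_convention = "global minimum = 0"),
                   class = "FreeEnergySurface")
  proj <- fes_project(fes, keep = 1L)
  # separable surface: marginalising the harmonic y-part shifts by a
  # constant only
  expect_equal(proj$values, array(f1 - min(f1)), tolerance = 1e-9)
})

test_that("FES is invariant under stable reordering of equal-time hills", {
  h <- rbind(c(1, 0.5, 0.1, 0.4), c(1, 0.9, 0.1, 0.2),
             c(2, 0.7, 0.1, 0.1))
  led1 <- hill_ledger(h, 1L)
  led2 <- hill_ledger(h[c(2, 1, 3), ], 1L)
  grid <- list(lo = 0, hi = 1.4, n = 141)
  expect_equal(reconstruct_fes(led1, grid)$values,
               reconstruct_fes(led2, grid)$values, tolerance = 1e-12)
})

test_that("staged schedules ripple less than constant large hills", {
  pot <- double_well_potential(barrier = 4, delta = 1.0, width = 0.1)
  lp <- langevin_params(n_steps = 4e6, seed = 21, timestep = 2e-4,
                        save_stride = 200)
  staged <- run_metadynamics(pot, hill_schedule(c(0.5, 0.2, 0.05),
                                                c(1, 1, 1),
                                                c(200, 200, 400)),
                             0.05, lp)
  constant <- run_metadynamics(pot, hill_schedule(0.5, 1, 800), 0.05, lp)
  ripple <- function(res) {
    checks <- seq(650, 800, by = 25)
    dgs <- vapply(checks, function(tf) {
      fes <- reconstruct_fes(res$ledger,
                             list(lo = -0.3, hi = 2.0, n = 231),
                             t_final = tf)
      basin_delta_g(fes, c(1.0, 1.25), c(0.4, 0.65))$delta_g
    }, numeric(1))
    sd(dgs)
  }
  expect_lt(ripple(staged), ripple(constant))
})

test_that("suggest_hill_width is a fifth of the sampled spread", {
  pot <- harmonic_potential(50, 0.7)
  lp <- langevin_params(n_steps = 4e5, seed = 2, timestep = 2e-4,
                        save_stride = 10)
  w <- suggest_hill_width(pot, lp)
  expect_equal(w, sqrt(kT_kcal(300) / 50) / 5, tolerance = 0.1)
})
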