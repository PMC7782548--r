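# Toy-system generators: Gaussian classes, the 2-DOF landscape, Langevin
# dynamics, host-guest frames.

test_that("thermo_params satisfies beta * kB * T = 1 and validates input", {
  th <- thermo_params(287)
  expect_equal(th$beta * th$k_B * th$temperature, 1)
  expect_error(thermo_params(-1), "positive")
})

test_that("gaussian class generator is seed-deterministic and converges", {
  a <- make_gaussian_classes(50, 2, c(1, 0), c(-1, 0), seed = 9)
  b <- make_gaussian_classes(50, 2, c(1, 0), c(-1, 0), seed = 9)
  expect_identical(a, b)
  d <- make_gaussian_classes(1e4, 2, c(1, 0), c(-1, 0), seed = 10)
  mB <- colMeans(d[d$label == "B", -1])
  mU <- colMeans(d[d$label == "U", -1])
  expect_true(all(abs(mB - c(1, 0)) < 5 / sqrt(1e4)))
  expect_true(all(abs(mU - c(-1, 0)) < 5 / sqrt(1e4)))
})

test_that("non-positive-definite covariance is rejected with a clear error", {
  expect_error(
    make_gaussian_classes(10, 2, c(0, 0), c(1, 1),
                          cov = matrix(c(1, 2, 2, 1), 2)),
    "positive definite")
  expect_error(
    make_gaussian_classes(10, 2, c(0, 0), c(1, 1),
                          cov = matrix(c(1, 0.5, 0, 1), 2)),
    "symmetric")
})

test_that("identical class means give near-zero Fisher ratio downstream", {
  d <- make_gaussian_classes(2000, 2, c(0.3, -0.2), c(0.3, -0.2), seed = 3)
  st <- scatter_stats(d[d$label == "B", -1], d[d$label == "U", -1])
  expect_lt(fisher_ratio(lda_direction(st, 0), st), 0.01)
})

test_that("toy potential has the stated minima and barrier", {
  th <- th300
  ls <- toy_landscape(th)
  qb <- function(z) ls$q_B + (ls$q_U - ls$q_B) * (1 + tanh(ls$alpha * z)) / 2
  expect_equal(toy_potential(-1, qb(-1), ls), 0)
  expect_equal(toy_potential(1, qb(1), ls), 0)
  expect_equal(toy_potential(0, qb(0), ls), ls$epsilon)
  # gradient matches finite differences
  for (pt in list(c(-0.8, 0.4), c(0.2, 2.5), c(1.1, 3.9))) {
    g <- toy_potential_grad(pt[1], pt[2], ls)
    h <- 1e-6
    expect_equal(g$dz, (toy_potential(pt[1] + h, pt[2], ls) -
                          toy_potential(pt[1] - h, pt[2], ls)) / (2 * h),
                 tolerance = 1e-5)
    expect_equal(g$dq, (toy_potential(pt[1], pt[2] + h, ls) -
                          toy_potential(pt[1], pt[2] - h, ls)) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("quadrature FES matches the closed-form marginal of the landscape", {
  ls <- toy_landscape(th300)
  z <- seq(-1.6, 1.6, length.out = 81)
  fq <- landscape_fes_quadrature(ls, th300, z)
  closed <- ls$epsilon * (z^2 - 1)^2
  expect_equal(fq$fes, closed - min(closed), tolerance = 1e-7)
})

test_that("langevin trajectories are bit-identical under the same seed", {
  ls <- toy_landscape(th300)
  a <- langevin_trajectory(ls, c(-1, 0), th300, n_steps = 2000, seed = 7)
  b <- langevin_trajectory(ls, c(-1, 0), th300, n_steps = 2000, seed = 7)
  expect_identical(a$z, b$z)
  expect_identical(a$q, b$q)
  c_ <- langevin_trajectory(ls, c(-1, 0), th300, n_steps = 2000, seed = 8)
  expect_false(identical(a$z, c_$z))
})

test_that("near-zero temperature relaxes a single well to its minimum", {
  hp <- harmonic_potential(k = 5, center = 0.7)
  tr <- langevin_trajectory(hp, 2, thermo_params(1e-4), friction = 1,
                            dt = 1e-3, n_steps = 2e4, seed = 1)
  expect_equal(tail(tr$x1, 1), 0.7, tolerance = 1e-3)
})

test_that("harmonic-well sampling reproduces the equipartition variance", {
  k <- 10
  hp <- harmonic_potential(k = k)
  tr <- langevin_trajectory(hp, 0, th300, friction = 1, dt = 2e-3,
                            n_steps = 2e6, seed = 12)
  expect_equal(var(tr$x1), th300$kBT / k, tolerance = 0.03)
})

test_that("diverging trajectories abort with a diagnostic", {
  expect_error(harmonic_potential(k = 0))
  ls <- toy_landscape(th300)
  expect_error(
    langevin_trajectory(ls, c(-1, 0), th300, friction = 1e-7, dt = 10,
                        n_steps = 1000, seed = 1, bound = 50),
    "diverged")
})

test_that("unbiased sampling matches the quadrature marginal on a low-barrier landscape", {
  # the default barrier (and its strong hydration gating) is tuned to make
  # unbiased crossings rare, so global equilibration of the integrator is
  # tested on a tamer variant: low barrier and weak hydration coupling
  ls <- toy_landscape(th300, epsilon = 1 * th300$kBT, q_U = 1)
  breaks <- seq(-2.2, 2.2, length.out = 45)
  mids <- (breaks[-1] + breaks[-45]) / 2
  fq <- landscape_fes_quadrature(ls, th300, mids)
  pref <- exp(-th300$beta * fq$fes)
  pref <- pref / sum(pref)
  for (seed in 1:3) {
    tr <- langevin_trajectory(ls, c(0, qbar_mid <- 0.5), th300, friction = 1,
                              dt = 1e-3, n_steps = 2e6, seed = seed,
                              log_stride = 10)
    h <- hist(tr$z[tr$z > -2.2 & tr$z < 2.2], breaks = breaks, plot = FALSE)
    pobs <- h$counts / sum(h$counts)
    expect_lt(sum(abs(pobs - pref)) / 2, 0.05)
  }
})

test_that("within-basin conditional distribution is Boltzmann at the default barrier", {
  ls <- toy_landscape(th300)
  tr <- langevin_trajectory(ls, c(-1, ls$q_B), th300, friction = 10,
                            dt = 1e-3, n_steps = 5e5, seed = 2, log_stride = 5)
  keep <- tr$z < 0
  expect_gt(mean(keep), 0.99)  # essentially no unbiased escape
  # z-variance around the bound minimum: curvature 8 epsilon
  expect_equal(var(tr$z[keep]), th300$kBT / (8 * ls$epsilon), tolerance = 0.12)
})

test_that("toy frames have dry-cavity B states and solvated U states", {
  fb <- frames_B()
  fu <- frames_U()
  p <- switching_params()
  Vb <- colMeans(t(vapply(fb, axis_descriptors, numeric(8), p = p)))
  Vu <- colMeans(t(vapply(fu, axis_descriptors, numeric(8), p = p)))
  expect_lt(Vb[1], 0.05)   # ~2% of the bulk level: effectively dry
  expect_lt(Vb[2], 0.10)
  expect_gt(Vu[1], 10 * max(Vb[1], 0.01))
  Lb <- colMeans(t(vapply(fb, ligand_descriptors, numeric(3), p = p)))
  Lu <- colMeans(t(vapply(fu, ligand_descriptors, numeric(3), p = p)))
  expect_true(all(Lu > Lb))
  # no waters -> all descriptors vanish
  f0 <- toy_host_guest_frames(2, 0, "B", seed = 1)
  expect_equal(unname(ligand_descriptors(f0[[1]])), rep(0, 3))
  expect_equal(unname(axis_descriptors(f0[[1]])), rep(0, 8))
})
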