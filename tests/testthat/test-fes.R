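# Reweighting, FES construction, block errors, binding free energy algebra,
# replica combination, SAMPL5 metrics, cylindrical densities.

test_that("reweighting with trivial biases reduces to the plain histogram", {
  set.seed(3)
  x <- rnorm(5000)
  breaks <- seq(-4, 4, length.out = 41)
  p0 <- reweight_histogram(x, rep(1, 5000), breaks)
  h <- hist(x, breaks = breaks, plot = FALSE)
  expect_equal(as.numeric(p0), h$counts / sum(h$counts))
  expect_equal(sum(p0), 1)
  # constant bias cancels
  pc <- reweight_histogram(x, breaks = breaks, bias = rep(2.7, 5000),
                           thermo = th300)
  expect_equal(as.numeric(pc), as.numeric(p0))
  expect_error(reweight_histogram(c(9, 10), c(1, 1), breaks), "outside")
})

test_that("reweighting undoes a known harmonic bias (Gaussian moments oracle)", {
  # samples from exp(-beta(U+V)), U = k/2 x^2, V = -c x (linear bias):
  # biased law is N(c/(k), kBT/k) shifted; reweighting must recover mean 0
  th <- th300
  k <- 4; cc <- 1.5
  sd_b <- sqrt(th$kBT / k)
  set.seed(11)
  n <- 4e4
  x <- rnorm(n, mean = cc / k, sd = sd_b)
  V <- -cc * x
  w <- exp(th$beta * (V - max(V)))
  breaks <- seq(-1.5, 2.5, length.out = 101)
  p <- reweight_histogram(x, w, breaks)
  mids <- attr(p, "mids")
  m_rw <- sum(mids * p)
  se <- sqrt(sum(w^2 * (x - m_rw)^2)) / sum(w)
  expect_lt(abs(m_rw - 0), 3 * se + 1e-3)
})

test_that("FES from probabilities: uniform, two-bin gap, Gaussian curvature", {
  th <- th300
  p <- rep(1 / 7, 7); attr(p, "mids") <- 1:7
  expect_equal(fes_from_prob(p, th)$fes, rep(0, 7))
  p2 <- c(exp(-1), 1) / (exp(-1) + 1); attr(p2, "mids") <- 1:2
  expect_equal(diff(rev(fes_from_prob(p2, th)$fes)), th$kBT)
  # Gaussian probability -> quadratic FES with curvature kBT/sigma^2
  sg <- 0.4
  mids <- seq(-1, 1, length.out = 81)
  p3 <- exp(-mids^2 / (2 * sg^2)); p3 <- p3 / sum(p3)
  attr(p3, "mids") <- mids
  fes <- fes_from_prob(p3, th)
  fit <- lm(fes$fes ~ I(mids^2))
  expect_equal(unname(coef(fit)[2]), th$kBT / (2 * sg^2), tolerance = 1e-6)
  # empty bins are masked, not infinite
  p4 <- c(0.5, 0, 0.5); attr(p4, "mids") <- 1:3
  expect_true(is.na(fes_from_prob(p4, th)$fes[2]))
})

test_that("block errors behave like iid theory on white noise", {
  expect_equal(block_error(rep(3.3, 1000), mean, 10), 0)
  set.seed(21)
  errs <- replicate(30, block_error(rnorm(1e4), mean, 10))
  expect_equal(mean(errs), 0.01, tolerance = 0.15)
  expect_true(all(errs > 0.01 / 2.5 & errs < 0.01 * 2.5))
  # doubling the series with twice the blocks shrinks the error ~ sqrt(2)
  set.seed(22)
  ratio <- replicate(40, {
    x <- rnorm(4000)
    block_error(c(x, rnorm(4000)), mean, 20) / block_error(x, mean, 10)
  })
  expect_equal(mean(ratio), 1 / sqrt(2), tolerance = 0.12)
  expect_error(block_error(1:3, mean, 5), "fewer samples")
})

test_that("delta G algebra: symmetry, quadrature oracle, rigid shifts", {
  th <- th300
  z <- seq(-2, 2, length.out = 401)
  geom1 <- funnel_geometry(R_cyl = sqrt(1.660 / pi))  # C0 pi R^2 = 1
  # symmetric double well with identical basins
  fes <- hydrocv:::new_fes_curve(z, 3 * (z^2 - 1)^2, rep(0, 401))
  bw <- c(-1.5, -0.5); uw <- c(0.5, 1.5)
  dg0 <- delta_g_standard(fes, bw, uw, geom1, th)
  # with the unit standard-state factor, DG = -kBT log Int_b exp(-b(F-F_U));
  # independent quadrature oracle at 1e5 points
  zq <- seq(bw[1], bw[2], length.out = 1e5)
  Fq <- 3 * (zq^2 - 1)^2
  in_u <- z >= uw[1] & z <= uw[2]
  F_U <- mean(3 * (z[in_u]^2 - 1)^2)
  I <- sum(diff(zq) * (head(exp(-th$beta * (Fq - F_U)), -1) +
                         tail(exp(-th$beta * (Fq - F_U)), -1)) / 2)
  expect_equal(dg0$delta_g, -th$kBT * log(I), tolerance = 0.01)
  # two-Gaussian-basin FES with distinct depths
  fes2 <- hydrocv:::new_fes_curve(
    z, 2 * (1 - exp(-(z + 1)^2 / 0.05)) + 1.2 * exp(-(z - 1)^2 / 0.05), rep(0, 401))
  fes2$fes <- fes2$fes - min(fes2$fes)
  dg2 <- delta_g_standard(fes2, bw, uw, geom1, th)$delta_g
  f2 <- function(zz) 2 * (1 - exp(-(zz + 1)^2 / 0.05)) +
    1.2 * exp(-(zz - 1)^2 / 0.05) - min(fes2$fes)
  F_U2 <- mean(f2(z[in_u]))
  I2 <- integrate(function(zz) exp(-th$beta * (f2(zz) - F_U2)), bw[1], bw[2],
                  rel.tol = 1e-10)$value
  expect_equal(dg2, -th$kBT * log(I2), tolerance = 0.01)
  # deepening the bound basin by exactly 1 kBT shifts DG by -1 kBT
  fes3 <- fes
  in_b <- z >= bw[1] & z <= bw[2]
  fes3$fes[in_b] <- fes3$fes[in_b] - th$kBT
  dg3 <- delta_g_standard(fes3, bw, uw, geom1, th)
  expect_equal(dg3$delta_g - dg0$delta_g, -th$kBT, tolerance = 1e-10)
  # doubling R_cyl shifts DG by exactly -kBT ln 4
  geom2 <- funnel_geometry(R_cyl = 2 * geom1$R_cyl)
  expect_equal(delta_g_standard(fes, bw, uw, geom2, th)$delta_g -
                 dg0$delta_g, -th$kBT * log(4), tolerance = 1e-12)
  expect_error(delta_g_standard(fes, c(-1, 0.6), uw, geom1, th), "disjoint")
})

test_that("replica combination is the inverse-variance weighted mean", {
  expect_equal(combine_replicas(-5.2, 0.1), list(value = -5.2, error = 0.1))
  two <- combine_replicas(c(-5, -6), c(0.2, 0.2))
  expect_equal(two$value, -5.5)
  expect_equal(two$error, 0.2 / sqrt(2))
  v <- c(-4.8, -5.1, -5.4); e <- c(0.1, 0.2, 0.4)
  got <- combine_replicas(v, e)
  wts <- 1 / e^2
  expect_equal(got$value, sum(wts * v) / sum(wts))
  expect_equal(got$error, sqrt(1 / sum(wts)))
  expect_lte(got$error, max(e))
  expect_error(combine_replicas(c(1, 2), c(0, 0)), "degenerate")
  expect_equal(combine_replicas(c(1, 1), c(0, 0))$value, 1)
})

test_that("sampl metrics: exact cases and invariances", {
  x <- c(-6.3, -5.1, -4.2, -2.5, -3.3, -7.7)
  m <- sampl_metrics(x, x)
  expect_equal(m$rmse, 0)
  expect_equal(m$r2, 1)
  expect_equal(m$slope, 1)
  expect_equal(m$kendall_tau, 1)
  expect_equal(sampl_metrics(sort(x), rev(sort(x)))$kendall_tau, -1)
  y <- x + rnorm(6, sd = 0.5)
  m1 <- sampl_metrics(y, x)
  m2 <- sampl_metrics(y + 3.3, x + 3.3)
  expect_equal(m1$rmse, m2$rmse)
  expect_equal(m1$kendall_tau, m2$kendall_tau)
  mono <- function(v) v^3 + 2 * v   # strictly monotone
  expect_equal(sampl_metrics(mono(y), mono(x))$kendall_tau, m1$kendall_tau)
  expect_error(sampl_metrics(1:4, 1:5), "mismatch")
  expect_error(sampl_metrics(1:2, 1:2), "at least 3")
})

test_that("kendall tau and slope match explicit pair counting / hand OLS", {
  set.seed(33)
  a <- rnorm(8); b <- rnorm(8)
  m <- sampl_metrics(a, b)
  conc <- 0
  for (i in 1:7) for (j in (i + 1):8)
    conc <- conc + sign(a[i] - a[j]) * sign(b[i] - b[j])
  expect_equal(m$kendall_tau, conc / choose(8, 2))
  slope_hand <- sum((b - mean(b)) * (a - mean(a))) / sum((b - mean(b))^2)
  expect_equal(m$slope, slope_hand)
})

test_that("cylindrical density normalizes to bulk = 1 on uniform frames", {
  set.seed(9)
  frames <- lapply(1:40, function(i) {
    n <- 3000
    hydrocv:::new_frame(rep("OW", n),
                        cbind(runif(n, -1.5, 1.5), runif(n, -1.5, 1.5),
                              runif(n, -1.5, 1.5)),
                        axis = list(origin = c(0, 0, -1.2), dir = c(0, 0, 1)))
  })
  class(frames) <- "xyz_frames"
  dens <- cylindrical_density(frames, z_breaks = seq(0, 2, length.out = 6),
                              r_breaks = seq(0.15, 1.2, length.out = 5))
  expect_true(all(abs(dens - 1) < 0.2))
  # doubling identical frames leaves the map unchanged
  dens2 <- cylindrical_density(structure(c(frames, frames), class = "xyz_frames"),
                               z_breaks = seq(0, 2, length.out = 6),
                               r_breaks = seq(0.15, 1.2, length.out = 5))
  expect_equal(as.numeric(dens2), as.numeric(dens))
})

test_that("cylindrical density marks dry regions as zero and needs a bulk reference", {
  # all waters concentrated near the top-right corner
  fr <- hydrocv:::new_frame(rep("OW", 500),
                            cbind(runif(500, 0.8, 1.0), runif(500, -0.1, 0.1),
                                  runif(500, 1.6, 1.9)),
                            axis = list(origin = c(0, 0, 0), dir = c(0, 0, 1)))
  frames <- structure(list(fr), class = "xyz_frames")
  dens <- cylindrical_density(frames, z_breaks = seq(0, 2, 0.5),
                              r_breaks = seq(0, 1, 0.25))
  expect_equal(dens[1, 1], 0)
  expect_equal(dens[nrow(dens), ncol(dens)], 1)
  expect_error(
    cylindrical_density(frames, z_breaks = seq(-3, -1, 0.5),
                        r_breaks = seq(0, 1, 0.25)),
    "reference bin")
})
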