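#' Two-degree-of-freedom binding/hydration toy landscape
#'
#' A desk-scale stand-in for a host-guest system: `z` is the position of the
#' ligand along the binding axis (nm; bound minimum at z = -1, unbound at
#' z = +1) and `q` is a dimensionless pocket-hydration coordinate that tracks
#' a z-dependent equilibrium level, switching from the dry bound value `q_B`
#' to the wet unbound value `q_U` across the cavity entrance:
#'
#'   U(z, q) = epsilon (z^2 - 1)^2 + (kappa / 2) (q - qbar(z))^2,
#'   qbar(z) = q_B + (q_U - q_B) (1 + tanh(alpha z)) / 2.
#'
#' The q-restoring term is Gaussian at every z, so the marginal free energy
#' along z is exactly `epsilon (z^2 - 1)^2` up to a constant - a convenient
#' closed-form reference for the sampling machinery.
#'
#' @param thermo `thermo_params` used only to express the default energy
#'   scales in kBT.
#' @param epsilon barrier scale (kcal mol^-1); default 5 kBT.
#' @param kappa hydration stiffness (kcal mol^-1); default 10 kBT.
#' @param q_B,q_U dry/wet hydration levels (dimensionless); defaults 0 and 4.
#' @param alpha coupling steepness (nm^-1); default 3.
#' @return object of class `toy_landscape`.
#' @export
toy_landscape <- function(thermo = thermo_params(),
                          epsilon = 5 * thermo$kBT,
                          kappa = 10 * thermo$kBT,
                          q_B = 0, q_U = 4, alpha = 3) {
  thermo <- as_thermo(thermo)
  stopifnot(epsilon > 0, kappa > 0, alpha > 0)
  structure(
    list(epsilon = epsilon, kappa = kappa, q_B = q_B, q_U = q_U, alpha = alpha),
    class = "toy_landscape"
  )
}

qbar <- function(z, landscape) {
  landscape$q_B + (landscape$q_U - landscape$q_B) * (1 + tanh(landscape$alpha * z)) / 2
}

#' Toy potential energy
#'
#' @param z position along the binding axis (nm); vectorized.
#' @param q hydration coordinate (dimensionless); vectorized with `z`.
#' @param landscape a [toy_landscape()].
#' @return energy in kcal mol^-1.
#' @export
toy_potential <- function(z, q, landscape) {
  stopifnot(inherits(landscape, "toy_landscape"))
  landscape$epsilon * (z^2 - 1)^2 + landscape$kappa / 2 * (q - qbar(z, landscape))^2
}

#' Gradient of the toy potential
#'
#' @inheritParams toy_potential
#' @return list with components `dz`, `dq` (kcal mol^-1 per unit coordinate).
#' @export
toy_potential_grad <- function(z, q, landscape) {
  qb <- qbar(z, landscape)
  dqb <- (landscape$q_U - landscape$q_B) / 2 * landscape$alpha / cosh(landscape$alpha * z)^2
  list(
    dz = 4 * landscape$epsilon * z * (z^2 - 1) - landscape$kappa * (q - qb) * dqb,
    dq = landscape$kappa * (q - qb)
  )
}

#' Marginal free energy along z by quadrature
#'
#' Integrates `exp(-beta U(z, q))` over `q` on a fine trapezoid grid and
#' returns `-kBT log P(z)` shifted so its minimum is zero. This is the
#' independent reference that biased runs are compared against.
#'
#' @param landscape a [toy_landscape()].
#' @param thermo a [thermo_params()].
#' @param z vector of z values (nm) at which to evaluate the free energy.
#' @param q_range,q_n integration range and number of quadrature nodes in q.
#' @return object of class `fes_curve`: data.frame with columns `cv`, `fes`,
#'   `error` (quadrature reference, error = 0).
#' @export
landscape_fes_quadrature <- function(landscape, thermo, z,
                                     q_range = NULL, q_n = 801) {
  thermo <- as_thermo(thermo)
  if (is.null(q_range)) {
    spread <- 6 * sqrt(thermo$kBT / landscape$kappa)
    q_range <- range(landscape$q_B, landscape$q_U) + c(-spread, spread)
  }
  qs <- seq(q_range[1], q_range[2], length.out = q_n)
  dq <- qs[2] - qs[1]
  pz <- vapply(z, function(zi) {
    u <- toy_potential(zi, qs, landscape)
    w <- exp(-thermo$beta * (u - min(u)))
    # trapezoid; the min-shift cancels in the FES up to the global shift below
    (sum(w) - (w[1] + w[q_n]) / 2) * dq * exp(-thermo$beta * min(u))
  }, numeric(1))
  fes <- -thermo$kBT * log(pz)
  new_fes_curve(z, fes - min(fes), rep(0, length(z)))
}

#' Two-class Gaussian descriptor sets
#'
#' Draws `n_per_class` descriptor vectors for each of the bound ("B") and
#' unbound ("U") labels from multivariate normals sharing one covariance,
#' emulating equilibrium fluctuations recorded in short unbiased runs of the
#' two metastable states.
#'
#' @param n_per_class samples per label.
#' @param dim descriptor dimension.
#' @param mean_B,mean_U class mean vectors of length `dim`.
#' @param cov common covariance matrix (symmetric positive definite).
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return data.frame with a `label` factor column ("B"/"U") followed by
#'   descriptor columns `d1..d<dim>`.
#' @export
make_gaussian_classes <- function(n_per_class, dim, mean_B, mean_U,
                                  cov = diag(dim), seed = 1) {
  stopifnot(length(mean_B) == dim, length(mean_U) == dim,
            nrow(cov) == dim, ncol(cov) == dim)
  if (max(abs(cov - t(cov))) > 1e-10)
    stop("`cov` must be symmetric")
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("`cov` must be positive definite (smallest eigenvalue ", min(ev), ")")
  X <- with_seed(seed, {
    xb <- MASS::mvrnorm(n_per_class, mu = mean_B, Sigma = cov)
    xu <- MASS::mvrnorm(n_per_class, mu = mean_U, Sigma = cov)
    rbind(xb, xu)
  })
  colnames(X) <- paste0("d", seq_len(dim))
  out <- data.frame(label = factor(rep(c("B", "U"), each = n_per_class),
                                   levels = c("B", "U")), X)
  out
}

# -- Langevin dynamics ---------------------------------------------------------

#' Harmonic test potential
#'
#' @param k stiffness vector (kcal mol^-1 nm^-2), one entry per coordinate.
#' @param center minimum position; default origin.
#' @export
harmonic_potential <- function(k, center = rep(0, length(k))) {
  stopifnot(all(k > 0), length(center) == length(k))
  structure(list(k = as.numeric(k), center = as.numeric(center)),
            class = "harmonic_potential")
}

pot_spec <- function(potential) {
  if (inherits(potential, "toy_landscape")) {
    list(type = 0L, params = c(potential$epsilon, potential$kappa,
                               potential$q_B, potential$q_U, potential$alpha),
         dim = 2L)
  } else if (inherits(potential, "harmonic_potential")) {
    list(type = 1L, params = c(potential$k, potential$center),
         dim = length(potential$k))
  } else {
    stop("`potential` must be a toy_landscape or harmonic_potential")
  }
}

# Assemble the C++-side CV specification. cv may be:
#   NULL / "z"      : first coordinate only
#   "zq"            : identity on all coordinates
#   list(model, "z"): Deep-LDA s_w on the state vector plus first coordinate
cv_spec <- function(cv, dim) {
  if (is.null(cv) || identical(cv, "z"))
    return(list(mode = 1L, net = NULL, d = 1L,
                names = "s_z"))
  if (identical(cv, "zq"))
    return(list(mode = 2L, net = NULL, d = dim, names = paste0("x", seq_len(dim))))
  if (is.list(cv) && inherits(cv[[1]], "deeplda")) {
    stopifnot(length(cv) == 2L, identical(cv[[2]], "z"))
    return(list(mode = 3L, net = net_as_cpp(cv[[1]]), d = 2L,
                names = c("s_w", "s_z")))
  }
  stop("unsupported `cv` specification")
}

#' Overdamped Langevin trajectory
#'
#' Euler-Maruyama integration of position Langevin dynamics
#' `x <- x - dt/friction * grad(U + V_bias + wall) + sqrt(2 kBT dt / friction) * xi`
#' with iid standard normal `xi`. The stationary law is Boltzmann in the
#' total potential for `dt` small against `friction / U''` (the package
#' default `dt = 1e-3`, `friction = 10` keeps the harmonic-well variance
#' within a fraction of a percent). When a static `bias` is supplied, its
#' force enters the dynamics and the per-step bias energy is recorded, as
#' needed for reweighting.
#'
#' @param potential a [toy_landscape()] or [harmonic_potential()].
#' @param start numeric start state (length = potential dimension).
#' @param thermo a [thermo_params()].
#' @param friction friction coefficient (kcal mol^-1 time nm^-2).
#' @param dt timestep (time units).
#' @param n_steps number of steps.
#' @param seed integer seed; identical inputs give a bit-identical trajectory.
#' @param bias optional static `opes_state` evaluated on the CVs in `cv`.
#' @param cv CV specification used by `bias` (see [run_opes()]); default the
#'   first coordinate ("z").
#' @param wall optional `list(z_wall =, k_wall =)` one-sided harmonic wall on
#'   `|z|` (the outer-wall component of the funnel restraint in this
#'   axis-only toy).
#' @param log_stride record every `log_stride`-th step (default 1).
#' @param bound abort with a diagnostic if any |coordinate| exceeds this.
#' @return data.frame of class `cv_trajectory` with columns `time`, the state
#'   coordinates, and `bias` when biased; attributes `final_state`, `seed`.
#' @export
langevin_trajectory <- function(potential, start, thermo = thermo_params(),
                                friction = 10, dt = 1e-3, n_steps, seed = 1,
                                bias = NULL, cv = "z", wall = NULL,
                                log_stride = 1L, bound = 100) {
  thermo <- as_thermo(thermo)
  ps <- pot_spec(potential)
  stopifnot(length(start) == ps$dim, n_steps >= 1, dt > 0, friction > 0)
  cvs <- cv_spec(cv, ps$dim)
  if (!is.null(bias)) {
    stopifnot(inherits(bias, "opes_state"))
    if (bias$d != cvs$d) stop("bias dimension does not match CV specification")
  }
  kmat <- if (is.null(bias)) matrix(0, 0, 2 * cvs$d + 1) else opes_kernel_matrix(bias)
  bpar <- if (is.null(bias)) numeric(4) else
    c(bias$gamma, bias$dE, bias$Z, bias$sum_w)
  res <- cpp_langevin_run(
    pot_type = ps$type, pot_params = ps$params, start = as.numeric(start),
    kBT = thermo$kBT, friction = friction, dt = dt,
    n_steps = as.integer(n_steps), seed = as.integer(seed),
    log_stride = as.integer(log_stride),
    cv_mode = cvs$mode, net = cvs$net,
    bias_mode = if (is.null(bias)) 0L else 1L,
    kernels = kmat, bias_params = bpar,
    opes_params = numeric(0),
    wall = if (is.null(wall)) c(Inf, 0) else c(wall$z_wall, wall$k_wall),
    bound = bound
  )
  log <- as.data.frame(res$log)
  coords <- if (ps$dim == 2L && ps$type == 0L) c("z", "q") else
    paste0("x", seq_len(ps$dim))
  names(log) <- c("time", coords,
                  if (!is.null(bias)) c(cvs$names, "bias"))
  attr(log, "final_state") <- res$final_state
  attr(log, "seed") <- seed
  class(log) <- c("cv_trajectory", class(log))
  log
}
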