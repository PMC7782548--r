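# On-the-fly probability enhanced sampling (OPES): the bias is built from a
# compressed weighted kernel density estimate of the CV distribution,
#   V(s) = (1 - 1/gamma) kBT log( P(s)/Z + eps ),  eps = exp(-beta dE / (1 - 1/gamma)),
# with bias factor gamma and barrier parameter dE capping the deposited bias.
# Kernels carry weights e^{beta V} evaluated at deposition time, bandwidths
# shrink with the effective sample size, nearby kernels are merged, and Z is
# the mean of the probability estimate over the kernel centers.

#' Create an (empty) OPES bias state
#'
#' @param d CV dimension (1 or 2).
#' @param sigma0 initial bandwidth per CV (length d); typically the CV
#'   standard deviation in a short unbiased run.
#' @param gamma bias factor (> 1); default 10.
#' @param dE barrier parameter (kcal mol^-1); default `10 * thermo$kBT`.
#' @param thermo a [thermo_params()].
#' @param merge_threshold kernel-merge distance in bandwidth units
#'   (default 1).
#' @param stride deposition stride in integrator steps (default 500;
#'   informational at the R level, used by [run_opes()]).
#' @param shrink_bandwidth when `TRUE` (default), kernel bandwidths shrink
#'   with the effective sample size (Silverman-style); `FALSE` keeps the
#'   fixed bandwidth `sigma0`, which gives a smoother bias at the cost of
#'   some resolution.
#' @return object of class `opes_state`.
#' @export
opes_state <- function(d, sigma0, gamma = 10, thermo = thermo_params(),
                       dE = 10 * thermo$kBT, merge_threshold = 1,
                       stride = 500L, shrink_bandwidth = TRUE) {
  thermo <- as_thermo(thermo)
  stopifnot(d >= 1, length(sigma0) == d, all(sigma0 > 0), gamma > 1, dE > 0)
  eps <- exp(-thermo$beta * dE / (1 - 1 / gamma))
  structure(
    list(d = as.integer(d), centers = matrix(numeric(0), 0, d),
         sigma = matrix(numeric(0), 0, d), heights = numeric(0),
         sigma0 = as.numeric(sigma0), gamma = gamma, dE = dE,
         eps = eps, thermo = thermo, merge_threshold = merge_threshold,
         stride = as.integer(stride),
         shrink_bandwidth = isTRUE(shrink_bandwidth),
         sum_w = 0, sum_w2 = 0, n_deposit = 0L, Z = 1),
    class = "opes_state"
  )
}

#' @export
print.opes_state <- function(x, ...) {
  cat(sprintf("opes_state: %d-D, %d kernels, %d deposits, gamma=%g, dE=%g kcal/mol\n",
              x$d, nrow(x$centers), x$n_deposit, x$gamma, x$dE))
  invisible(x)
}

# weighted KDE estimate P(s) (normalized Gaussians); rows of s are points
opes_prob <- function(state, s) {
  s <- matrix(s, ncol = state$d)
  if (nrow(state$centers) == 0L) return(rep(0, nrow(s)))
  out <- numeric(nrow(s))
  norm_k <- state$heights / apply(state$sigma, 1, function(sg)
    prod(sg * sqrt(2 * pi)))
  for (i in seq_len(nrow(s))) {
    z2 <- rowSums(sweep(state$centers, 2, s[i, ], `-`)^2 / state$sigma^2)
    out[i] <- sum(norm_k * exp(-0.5 * z2))
  }
  out / state$sum_w
}

#' OPES bias energy
#'
#' `V(s) = (1 - 1/gamma) kBT log(P(s)/Z + eps)`; an empty state gives 0 by
#' convention.
#'
#' @param state an [opes_state()].
#' @param s CV point(s): vector of length d or matrix with d columns.
#' @return bias energy (kcal mol^-1), vectorized over rows.
#' @export
opes_bias <- function(state, s) {
  stopifnot(inherits(state, "opes_state"))
  s <- matrix(s, ncol = state$d)
  if (nrow(state$centers) == 0L) return(rep(0, nrow(s)))
  pref <- (1 - 1 / state$gamma) * state$thermo$kBT
  pref * log(opes_prob(state, s) / state$Z + state$eps)
}

# insert a kernel with explicit weight (merging with the nearest kernel when
# within merge_threshold bandwidths of it); exposed for unit testing
opes_deposit <- function(state, s, weight) {
  s <- as.numeric(s)
  stopifnot(length(s) == state$d, weight > 0, all(is.finite(s)))
  state$sum_w <- state$sum_w + weight
  state$sum_w2 <- state$sum_w2 + weight^2
  state$n_deposit <- state$n_deposit + 1L
  n_eff <- state$sum_w^2 / state$sum_w2
  d <- state$d
  sig <- if (state$shrink_bandwidth)
    state$sigma0 * (n_eff * (d + 2) / 4)^(-1 / (d + 4))
  else state$sigma0
  K <- nrow(state$centers)
  merged <- FALSE
  if (K > 0) {
    dist2 <- rowSums(sweep(state$centers, 2, s, `-`)^2 / state$sigma^2)
    k <- which.min(dist2)
    if (sqrt(dist2[k]) < state$merge_threshold) {
      h1 <- state$heights[k]; h2 <- weight; hs <- h1 + h2
      c1 <- state$centers[k, ]; c2 <- s
      cm <- (h1 * c1 + h2 * c2) / hs
      s2 <- (h1 * (state$sigma[k, ]^2 + c1^2) + h2 * (sig^2 + c2^2)) / hs - cm^2
      state$centers[k, ] <- cm
      state$sigma[k, ] <- sqrt(pmax(s2, 1e-300))
      state$heights[k] <- hs
      merged <- TRUE
    }
  }
  if (!merged) {
    state$centers <- unname(rbind(state$centers, s))
    state$sigma <- unname(rbind(state$sigma, sig))
    state$heights <- c(state$heights, weight)
  }
  state$Z <- mean(opes_prob(state, state$centers))
  state
}

#' One OPES update (deposition) step
#'
#' Adds a kernel at the current CV value with weight `e^{beta V(s)}` under
#' the current bias, merging with the nearest kernel when closer than the
#' merge threshold, and refreshes the normalization Z (the mean of the
#' probability estimate over kernel centers).
#'
#' @param state an [opes_state()].
#' @param s_now current CV value (length d, finite).
#' @return the updated `opes_state`.
#' @export
opes_update <- function(state, s_now) {
  stopifnot(inherits(state, "opes_state"))
  if (!all(is.finite(s_now))) stop("non-finite CV value passed to opes_update")
  w <- exp(state$thermo$beta * as.numeric(opes_bias(state, s_now)))
  opes_deposit(state, s_now, w)
}

opes_kernel_matrix <- function(state) {
  cbind(state$centers, state$sigma, state$heights)
}

opes_state_from_cpp <- function(template, res) {
  st <- template
  km <- res$kernels
  d <- st$d
  if (length(km) == 0 || nrow(km) == 0) return(st)
  st$centers <- km[, seq_len(d), drop = FALSE]
  st$sigma <- km[, d + seq_len(d), drop = FALSE]
  st$heights <- km[, 2 * d + 1]
  st$sum_w <- res$sum_w; st$sum_w2 <- res$sum_w2
  st$n_deposit <- res$n_deposit; st$Z <- res$Z
  st
}

#' Run OPES-biased Langevin dynamics on a toy landscape
#'
#' Overdamped Langevin dynamics on a [toy_landscape()] under the adaptive
#' OPES bias acting on one or two CVs, with an optional outer wall on the
#' binding coordinate. CV choices: `"z"` (the binding coordinate), `"zq"`
#' (both coordinates), or `list(model, "z")` with a trained [train_deep_lda()]
#' model evaluated on the state vector, giving the paper-style pair
#' (s_w, s_z). The time series of CV values and instantaneous bias energies
#' (the ingredients of reweighting) is logged in COLVAR layout.
#'
#' @param landscape a [toy_landscape()].
#' @param cv CV specification (see above); default `"z"`.
#' @param thermo a [thermo_params()].
#' @param n_steps,dt,friction,seed,start integrator controls (see
#'   [langevin_trajectory()]); `start` defaults to the bound minimum.
#' @param gamma,dE,stride,merge_threshold OPES parameters (defaults 10,
#'   `10 kBT`, 500 steps, 1 bandwidth).
#' @param sigma0 initial bandwidth per CV; `NULL` (default) estimates it as
#'   the CV standard deviation over a short unbiased run from `start`.
#' @param shrink_bandwidth shrink kernel bandwidths with effective sample
#'   size (default TRUE); see [opes_state()].
#' @param wall optional `list(z_wall =, k_wall =)` one-sided harmonic wall.
#' @param log_stride record every so many steps (default 10).
#' @param bound divergence guard on |coordinates|.
#' @return list of class `opes_run`: `traj` (data.frame `time`, `z`, `q`,
#'   CV columns, `opes.bias`), `state` (final `opes_state`), and the run
#'   parameters. With `gamma = 1` the bias is identically zero and the run
#'   reduces bit-for-bit to the unbiased trajectory.
#' @export
run_opes <- function(landscape, cv = "z", thermo = thermo_params(),
                     n_steps = 1e6, dt = 1e-3, friction = 10, seed = 1,
                     start = NULL, gamma = 10, dE = 10 * thermo$kBT,
                     stride = 500L, merge_threshold = 1, sigma0 = NULL,
                     shrink_bandwidth = TRUE, wall = NULL, log_stride = 10L,
                     bound = 100) {
  thermo <- as_thermo(thermo)
  stopifnot(inherits(landscape, "toy_landscape"), gamma >= 1)
  ps <- pot_spec(landscape)
  if (is.null(start)) start <- c(-1, landscape$q_B)
  cvs <- cv_spec(cv, ps$dim)

  if (gamma == 1) {  # edge case: zero bias, pure unbiased dynamics
    traj <- langevin_trajectory(landscape, start, thermo, friction, dt,
                                n_steps, seed, wall = wall,
                                log_stride = log_stride, bound = bound)
    traj$opes.bias <- 0
    return(structure(list(traj = traj, state = NULL, cv = cv, gamma = 1),
                     class = "opes_run"))
  }

  if (is.null(sigma0)) {
    pre <- langevin_trajectory(landscape, start, thermo, friction, dt,
                               n_steps = 5000, seed = seed + 1000003L,
                               log_stride = 1L, bound = bound)
    smat <- cv_values(cvs, as.matrix(pre[, c("z", "q")]))
    sigma0 <- pmax(apply(smat, 2, stats::sd), 1e-3)
  }
  stopifnot(length(sigma0) == cvs$d)

  res <- cpp_langevin_run(
    pot_type = ps$type, pot_params = ps$params, start = as.numeric(start),
    kBT = thermo$kBT, friction = friction, dt = dt,
    n_steps = as.integer(n_steps), seed = as.integer(seed),
    log_stride = as.integer(log_stride),
    cv_mode = cvs$mode, net = cvs$net,
    bias_mode = 2L, kernels = matrix(0, 0, 2 * cvs$d + 1),
    bias_params = numeric(4),
    opes_params = c(gamma, dE, stride, merge_threshold,
                    as.numeric(shrink_bandwidth), sigma0),
    wall = if (is.null(wall)) c(Inf, 0) else c(wall$z_wall, wall$k_wall),
    bound = bound
  )
  traj <- as.data.frame(res$log)
  names(traj) <- c("time", "z", "q", cvs$names, "opes.bias")
  template <- opes_state(cvs$d, sigma0, gamma, thermo, dE, merge_threshold,
                         stride, shrink_bandwidth)
  state <- opes_state_from_cpp(template, res)
  structure(list(traj = traj, state = state, cv = cv, gamma = gamma,
                 dE = dE, stride = stride, sigma0 = sigma0, seed = seed,
                 dt = dt, friction = friction, thermo = thermo),
            class = "opes_run")
}

# evaluate the CV map on state rows (R-side mirror of the C++ CV modes)
cv_values <- function(cvs, states) {
  states <- matrix(states, ncol = ncol(states))
  if (cvs$mode == 1L) return(states[, 1, drop = FALSE])
  if (cvs$mode == 2L) return(states)
  if (cvs$mode == 3L) {
    sw <- cpp_net_sw(cvs$net, states)
    return(cbind(sw, states[, 1]))
  }
  stop("bad cv mode")
}

#' Count barrier crossings of the binding coordinate
#'
#' With `hysteresis = 0` (default), the number of sign changes of `z - z0`
#' along the trajectory. A subsampled trajectory dithering on the dividing
#' surface registers many sign changes per passage, so for counting genuine
#' binding/unbinding events a `hysteresis` deadband is preferable: a
#' crossing is then counted only when the trajectory moves from below
#' `z0 - hysteresis` to above `z0 + hysteresis` or vice versa.
#'
#' @param z numeric vector of binding-coordinate values.
#' @param z0 dividing surface (default 0).
#' @param hysteresis half-width of the deadband (default 0: plain sign
#'   changes).
#' @return integer crossing count.
#' @export
count_crossings <- function(z, z0 = 0, hysteresis = 0) {
  if (hysteresis <= 0) {
    s <- sign(z - z0)
    s <- s[s != 0]
    return(sum(diff(s) != 0))
  }
  s <- ifelse(z < z0 - hysteresis, -1L, ifelse(z > z0 + hysteresis, 1L, 0L))
  s <- s[s != 0L]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0L)
}
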