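# Reweighting, free energy surfaces, block errors, binding free energies,
# replica combination, SAMPL5-style metrics, cylindrical water densities.

new_fes_curve <- function(cv, fes, error) {
  out <- data.frame(cv = cv, fes = fes, error = error)
  class(out) <- c("fes_curve", class(out))
  out
}

#' Umbrella-sampling-like reweighting to an unbiased histogram
#'
#' Each biased sample carries a statistical weight proportional to
#' `e^{beta V}` with `V` the bias acting when it was recorded; the unbiased
#' probability of a bin is the weight it holds over the total weight.
#'
#' @param samples CV values (numeric vector).
#' @param weights statistical weights (positive, finite); either raw weights
#'   or bias energies via `bias` + `thermo`.
#' @param breaks bin edges (increasing numeric vector).
#' @param bias,thermo alternative to `weights`: bias energies (kcal mol^-1)
#'   and a [thermo_params()], giving `weights = exp(beta * bias)`.
#' @return vector of bin probabilities (sums to 1); attribute `mids` holds
#'   the bin midpoints.
#' @export
reweight_histogram <- function(samples, weights = NULL, breaks,
                               bias = NULL, thermo = NULL) {
  if (is.null(weights)) {
    if (is.null(bias) || is.null(thermo))
      stop("supply `weights`, or `bias` together with `thermo`")
    thermo <- as_thermo(thermo)
    weights <- exp(thermo$beta * (bias - max(bias)))
  }
  stopifnot(length(weights) == length(samples), all(is.finite(weights)),
            all(weights > 0))
  keep <- samples >= breaks[1] & samples <= breaks[length(breaks)]
  if (!any(keep)) stop("all samples fall outside the histogram range")
  idx <- findInterval(samples[keep], breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  p <- vapply(seq_len(length(breaks) - 1L),
              function(b) sum(weights[keep][idx == b]), numeric(1))
  p <- p / sum(p)
  attr(p, "mids") <- (breaks[-1] + breaks[-length(breaks)]) / 2
  p
}

#' Free energy surface from a probability histogram
#'
#' `FES(s) = -kBT log P(s)`, shifted so the minimum over non-empty bins is
#' zero; empty bins are masked (NA), never written as infinities.
#'
#' @param p bin probabilities (should sum to 1); attribute `mids` or the
#'   `mids` argument supplies the CV grid.
#' @param thermo a [thermo_params()].
#' @param mids bin midpoints (defaults to `attr(p, "mids")`).
#' @param error optional per-bin error (energy), e.g. from [fes_reweight()].
#' @return `fes_curve` data.frame: `cv`, `fes` (min 0), `error`.
#' @export
fes_from_prob <- function(p, thermo, mids = attr(p, "mids"), error = NULL) {
  thermo <- as_thermo(thermo)
  if (is.null(mids)) stop("bin midpoints required")
  fes <- ifelse(p > 0, -thermo$kBT * log(p), NA_real_)
  fes <- fes - min(fes, na.rm = TRUE)
  new_fes_curve(mids, fes, if (is.null(error)) rep(0, length(p)) else error)
}

#' Reweighted FES with block errors
#'
#' Convenience pipeline: reweights biased samples onto a grid, computes the
#' FES, and estimates per-bin errors by a block average over `n_blocks`
#' contiguous blocks of the time series.
#'
#' @inheritParams reweight_histogram
#' @param n_blocks number of contiguous blocks (default 5).
#' @return `fes_curve` with per-bin block errors.
#' @export
fes_reweight <- function(samples, weights = NULL, breaks, thermo,
                         bias = NULL, n_blocks = 5L) {
  thermo <- as_thermo(thermo)
  if (is.null(weights)) {
    stopifnot(!is.null(bias))
    weights <- exp(thermo$beta * (bias - max(bias)))
  }
  p <- reweight_histogram(samples, weights, breaks)
  n <- length(samples)
  bl <- block_indices(n, n_blocks)
  fes_b <- matrix(NA_real_, n_blocks, length(p))
  for (b in seq_len(n_blocks)) {
    pb <- tryCatch(reweight_histogram(samples[bl[[b]]], weights[bl[[b]]], breaks),
                   error = function(e) NULL)
    if (!is.null(pb)) fes_b[b, ] <- ifelse(pb > 0, -thermo$kBT * log(pb), NA)
  }
  # per-bin spread of block FES estimates (relative FES: centre each block)
  fes_b <- fes_b - rowMeans(fes_b, na.rm = TRUE)
  err <- apply(fes_b, 2, function(col) {
    col <- col[is.finite(col)]
    if (length(col) < 2) return(NA_real_)
    stats::sd(col) / sqrt(length(col))
  })
  fes_from_prob(p, thermo, error = err)
}

block_indices <- function(n, n_blocks) {
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 2L) stop("`n_blocks` must be >= 2")
  size <- n %/% n_blocks
  if (size < 1L) stop("fewer samples (", n, ") than blocks (", n_blocks, ")")
  lapply(seq_len(n_blocks), function(b) (b - 1L) * size + seq_len(size))
}

#' Block-average error of a (weighted) statistic
#'
#' Splits the series into `n_blocks` contiguous blocks (trailing remainder
#' dropped), evaluates the statistic on each block, and returns the standard
#' error over blocks - the standard correlated-time-series error estimate.
#'
#' @param samples numeric vector (time ordered).
#' @param statistic function of `(samples)` or `(samples, weights)`.
#' @param n_blocks number of blocks (>= 2).
#' @param weights optional weights passed through to the statistic.
#' @return standard error of the statistic.
#' @export
block_error <- function(samples, statistic = mean, n_blocks = 5L,
                        weights = NULL) {
  bl <- block_indices(length(samples), n_blocks)
  est <- vapply(bl, function(ix) {
    if (is.null(weights)) statistic(samples[ix])
    else statistic(samples[ix], weights[ix])
  }, numeric(1))
  stats::sd(est) / sqrt(length(est))
}

#' Standard-state binding free energy from an axial FES
#'
#' Implements the funnel-restraint binding formula
#' `DeltaG = -kBT log( C0 pi R_cyl^2 * Int_bound exp(-beta (F(z) - F_U)) dz )`
#' with `F_U` the mean FES over the unbound window (which must lie in the
#' funnel's cylinder region) and the integral taken over the bound window by
#' the trapezoid rule on the FES grid. The entropic funnel correction is the
#' `C0 pi R_cyl^2` factor (see [funnel_correction()]).
#'
#' @param fes an `fes_curve` along the binding coordinate z (nm).
#' @param bound_window,unbound_window length-2 z intervals (disjoint, each
#'   covering >= 3 grid bins with finite FES).
#' @param geom a [funnel_geometry()] (supplies `R_cyl`).
#' @param thermo a [thermo_params()].
#' @param standard_conc standard concentration (molecules nm^-3).
#' @return list with `delta_g` (kcal mol^-1), `f_u`, `correction` and the
#'   windows used.
#' @export
delta_g_standard <- function(fes, bound_window, unbound_window, geom,
                             thermo = thermo_params(),
                             standard_conc = 1 / 1.660) {
  thermo <- as_thermo(thermo)
  stopifnot(inherits(geom, "funnel_geometry"))
  if (max(bound_window) > min(unbound_window) &&
      max(unbound_window) > min(bound_window))
    stop("bound and unbound windows must be disjoint")
  in_b <- fes$cv >= bound_window[1] & fes$cv <= bound_window[2]
  in_u <- fes$cv >= unbound_window[1] & fes$cv <= unbound_window[2]
  fb <- fes$fes[in_b]; zu <- fes$fes[in_u]
  if (sum(is.finite(fb)) < 3L || sum(is.finite(zu)) < 3L)
    stop("each window needs >= 3 bins with finite FES values")
  if (anyNA(fb) || anyNA(zu))
    stop("empty (masked) bins inside a window; refine sampling or windows")
  f_u <- mean(zu)
  zb <- fes$cv[in_b]
  integrand <- exp(-thermo$beta * (fb - f_u))
  integral <- sum(diff(zb) * (head(integrand, -1) + tail(integrand, -1)) / 2)
  dg <- -thermo$kBT * log(standard_conc * pi * geom$R_cyl^2 * integral)
  list(delta_g = dg, f_u = f_u,
       correction = funnel_correction(geom$R_cyl, thermo, standard_conc),
       bound_window = bound_window, unbound_window = unbound_window)
}

#' Binding free energy with block error from biased samples
#'
#' Computes the reweighted FES(z) and the standard-state binding free energy
#' on the full series, plus a block-average error from `n_blocks` contiguous
#' sub-series.
#'
#' @param z binding-coordinate samples (time ordered).
#' @param bias bias energies at the samples (kcal mol^-1).
#' @param breaks FES grid edges.
#' @param bound_window,unbound_window,geom,thermo,standard_conc see
#'   [delta_g_standard()].
#' @param n_blocks number of blocks for the error (default 5).
#' @return list with `delta_g`, `error`, `fes`, `blocks` (per-block
#'   estimates).
#' @export
binding_delta_g <- function(z, bias, breaks, bound_window, unbound_window,
                            geom, thermo = thermo_params(),
                            standard_conc = 1 / 1.660, n_blocks = 5L) {
  thermo <- as_thermo(thermo)
  w <- exp(thermo$beta * (bias - max(bias)))
  est_one <- function(zs, ws) {
    p <- reweight_histogram(zs, ws, breaks)
    fes <- fes_from_prob(p, thermo)
    delta_g_standard(fes, bound_window, unbound_window, geom, thermo,
                     standard_conc)$delta_g
  }
  dg <- est_one(z, w)
  bl <- block_indices(length(z), n_blocks)
  dgb <- vapply(bl, function(ix)
    tryCatch(est_one(z[ix], w[ix]), error = function(e) NA_real_),
    numeric(1))
  nfin <- sum(is.finite(dgb))
  if (nfin < n_blocks)
    warning(n_blocks - nfin, " block(s) lack window coverage; ",
            "error estimated from ", nfin, " blocks")
  err <- if (nfin >= 2) stats::sd(dgb, na.rm = TRUE) / sqrt(nfin) else NA_real_
  list(delta_g = dg, error = err, blocks = dgb,
       fes = fes_reweight(z, w, breaks, thermo, n_blocks = n_blocks))
}

#' Inverse-variance weighted combination of replica estimates
#'
#' The weighted block average used to pool the binding free energies from
#' runs biased with independently trained CVs.
#'
#' @param values replica estimates.
#' @param errors replica standard errors (same length; positive unless all
#'   values agree).
#' @return list with `value` and `error` (standard error of the weighted
#'   mean).
#' @export
combine_replicas <- function(values, errors) {
  stopifnot(length(values) == length(errors), length(values) >= 1)
  if (any(!is.finite(errors))) {
    keep <- is.finite(errors)
    if (!any(keep)) {
      warning("no finite replica errors; returning the plain mean")
      return(list(value = mean(values), error = NA_real_))
    }
    warning(sum(!keep), " replica(s) without finite errors dropped")
    values <- values[keep]; errors <- errors[keep]
  }
  if (any(errors == 0)) {
    if (max(values) - min(values) > 1e-12)
      stop("zero errors with disagreeing values: weights are degenerate")
    return(list(value = values[1], error = 0))
  }
  wts <- 1 / errors^2
  list(value = sum(wts * values) / sum(wts), error = sqrt(1 / sum(wts)))
}

#' SAMPL5-style accuracy metrics
#'
#' The four scalar metrics used to benchmark host-guest binding predictions
#' against experiment: root-mean-squared error, Pearson coefficient of
#' determination, ordinary-least-squares slope of calculated on experimental,
#' and the Kendall rank correlation (tau-a; ties are not expected).
#'
#' @param calc calculated binding free energies (kcal mol^-1).
#' @param exp experimental values (same length, >= 3).
#' @return list `rmse`, `r2`, `slope`, `kendall_tau`.
#' @export
sampl_metrics <- function(calc, exp) {
  if (length(calc) != length(exp)) stop("`calc` and `exp` length mismatch")
  if (length(calc) < 3L) stop("need at least 3 pairs")
  list(rmse = sqrt(mean((calc - exp)^2)),
       r2 = stats::cor(calc, exp)^2,
       slope = unname(stats::coef(stats::lm(calc ~ exp))[2]),
       kendall_tau = stats::cor(calc, exp, method = "kendall"))
}

#' Cylindrical water-density histogram
#'
#' Histograms the water oxygens of a frame set in cylindrical coordinates
#' (z along the binding axis, r radial), divides each bin by its shell
#' volume `2 pi r_mid dr dz` and by the frame count, and normalizes the
#' whole map by the value of its top-right (largest z, largest r) bin - so
#' bulk water reads 1 and a dry pocket reads 0.
#'
#' @param frames an `xyz_frames` list sharing one axis definition.
#' @param axis axis override (defaults to the first frame's).
#' @param z_breaks,r_breaks bin edges (>= 3 values each).
#' @param water_labels element labels counted as water oxygens.
#' @return matrix (rows = z bins, cols = r bins) with attributes `z_mids`,
#'   `r_mids`.
#' @export
cylindrical_density <- function(frames, axis = frames[[1]]$axis,
                                z_breaks, r_breaks,
                                water_labels = c("OW", "W")) {
  stopifnot(length(z_breaks) >= 3, length(r_breaks) >= 3)
  dir <- axis$dir / sqrt(sum(axis$dir^2))
  counts <- matrix(0, length(z_breaks) - 1L, length(r_breaks) - 1L)
  for (fr in frames) {
    wat <- frame_waters(fr, water_labels)
    if (nrow(wat) == 0) next
    rel <- sweep(wat, 2, axis$origin)
    z <- drop(rel %*% dir)
    r <- sqrt(rowSums((rel - tcrossprod(z, dir))^2))
    keep <- z >= z_breaks[1] & z <= z_breaks[length(z_breaks)] &
      r >= r_breaks[1] & r <= r_breaks[length(r_breaks)]
    iz <- findInterval(z[keep], z_breaks, rightmost.closed = TRUE, all.inside = TRUE)
    ir <- findInterval(r[keep], r_breaks, rightmost.closed = TRUE, all.inside = TRUE)
    for (k in seq_along(iz)) counts[iz[k], ir[k]] <- counts[iz[k], ir[k]] + 1
  }
  r_mids <- (r_breaks[-1] + r_breaks[-length(r_breaks)]) / 2
  z_mids <- (z_breaks[-1] + z_breaks[-length(z_breaks)]) / 2
  vol <- outer(diff(z_breaks), 2 * pi * r_mids * diff(r_breaks))
  dens <- counts / vol / length(frames)
  ref <- dens[nrow(dens), ncol(dens)]
  if (ref <= 0) stop("top-right reference bin is empty; normalization undefined")
  out <- dens / ref
  attr(out, "z_mids") <- z_mids
  attr(out, "r_mids") <- r_mids
  out
}

#' @export
plot.fes_curve <- function(x, ..., ylab = "FES (kcal/mol)", xlab = "CV") {
  ok <- is.finite(x$fes)
  graphics::plot(x$cv[ok], x$fes[ok], type = "l", xlab = xlab, ylab = ylab, ...)
  if (any(x$error[ok] > 0)) {
    graphics::arrows(x$cv[ok], x$fes[ok] - x$error[ok],
                     x$cv[ok], x$fes[ok] + x$error[ok],
                     angle = 90, code = 3, length = 0.02, col = "grey50")
  }
  invisible(x)
}
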