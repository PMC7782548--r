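#' Class scatter statistics for linear discriminant analysis
#'
#' Computes the class means `mu_B`, `mu_U`, the per-class scatter matrices
#' `S_B`, `S_U` (sample covariances, divided by n - 1; the Fisher ratio is
#' invariant to this overall scale, only the convention must be fixed), the
#' within-class scatter `S_w = S_B + S_U` and the rank-one between-class
#' scatter `S_b = (mu_B - mu_U)(mu_B - mu_U)^T`.
#'
#' @param data_B,data_U numeric matrices / data.frames (rows = samples,
#'   columns = descriptors), at least 2 rows each, equal column counts.
#' @return object of class `scatter_stats` with fields `mu_B`, `mu_U`, `S_B`,
#'   `S_U`, `S_w`, `S_b`, `n_B`, `n_U`.
#' @export
scatter_stats <- function(data_B, data_U) {
  B <- as.matrix(data_B); U <- as.matrix(data_U)
  if (ncol(B) != ncol(U))
    stop("descriptor dimension mismatch: ", ncol(B), " vs ", ncol(U))
  if (nrow(B) < 2L || nrow(U) < 2L)
    stop("each class needs at least 2 samples")
  mu_B <- colMeans(B); mu_U <- colMeans(U)
  S_B <- stats::cov(B); S_U <- stats::cov(U)
  d <- mu_B - mu_U
  structure(
    list(mu_B = mu_B, mu_U = mu_U, S_B = S_B, S_U = S_U,
         S_w = S_B + S_U, S_b = tcrossprod(d), n_B = nrow(B), n_U = nrow(U)),
    class = "scatter_stats"
  )
}

#' Fisher's discriminant ratio
#'
#' `J(w) = (w' S_b w) / (w' (S_w + lambda I) w)`: between-class over
#' (regularized) within-class scatter of the projection on `w`. Invariant
#' under rescaling of `w`.
#'
#' @param w nonzero direction vector.
#' @param stats a [scatter_stats()].
#' @param lambda ridge regularizer added to `S_w` (default 0).
#' @return dimensionless ratio.
#' @export
fisher_ratio <- function(w, stats, lambda = 0) {
  stopifnot(inherits(stats, "scatter_stats"))
  w <- as.numeric(w)
  if (sqrt(sum(w^2)) < 1e-300) stop("`w` must be nonzero")
  num <- drop(crossprod(w, stats$S_b %*% w))
  den <- drop(crossprod(w, stats$S_w %*% w)) + lambda * sum(w^2)
  num / den
}

#' Optimal LDA direction
#'
#' Closed form for the maximizer of the Fisher ratio with a rank-one
#' between-class scatter: `w` proportional to
#' `(S_w + lambda I)^{-1} (mu_B - mu_U)`, returned unit-norm with the sign
#' fixed so the bound class projects higher than the unbound class.
#'
#' @param stats a [scatter_stats()].
#' @param lambda ridge regularizer (default 0.05; the within scatter of a
#'   wide feature layer is otherwise often rank-deficient).
#' @return unit-norm direction vector.
#' @export
lda_direction <- function(stats, lambda = 0.05) {
  stopifnot(inherits(stats, "scatter_stats"))
  A <- stats$S_w + lambda * diag(nrow(stats$S_w))
  w <- tryCatch(solve(A, stats$mu_B - stats$mu_U),
                error = function(e) stop("regularized S_w is singular: ",
                                         conditionMessage(e)))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-300) return(w)  # zero mean gap: any direction has J = 0
  w <- w / nw
  if (sum(w * (stats$mu_B - stats$mu_U)) < 0) w <- -w
  w
}
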