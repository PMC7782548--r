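#' Derivative-based descriptor relevance
#'
#' Relative weight of each input descriptor in the action of the CV: the mean
#' over samples of the absolute partial derivative `|d s_w / d d_i|`
#' (gradients through the full network, rescale and cubic transform),
#' normalized to sum to one. Large weight marks a descriptor whose
#' fluctuations the biased CV amplifies around those samples.
#'
#' @param model a trained [train_deep_lda()] model.
#' @param state_samples descriptor matrix/data.frame of samples from one
#'   metastable state (>= 1 row).
#' @param of "s_w" (default; the biased CV) or "s" (raw projection).
#' @param normalize "sum" (weights sum to 1, default) or "max" (largest
#'   weight is 1).
#' @return named weight vector, one entry per descriptor in model order.
#' @export
descriptor_relevance <- function(model, state_samples, of = c("s_w", "s"),
                                 normalize = c("sum", "max")) {
  of <- match.arg(of); normalize <- match.arg(normalize)
  X <- as_X(state_samples)
  if (nrow(X) < 1L) stop("need at least one sample")
  g <- abs(deeplda_gradient(model, X, of = of))
  wts <- colMeans(g)
  tot <- switch(normalize, sum = sum(wts), max = max(wts))
  if (tot <= 0) return(setNames(rep(0, length(wts)), names(wts)))
  wts / tot
}

#' Per-state descriptor ranking report
#'
#' Computes [descriptor_relevance()] for each labelled state (and, when a
#' list of independently trained models is given, averages the weights over
#' models), yielding the tidy table behind per-state descriptor-importance
#' bar plots.
#'
#' @param model a `deeplda` model or a list of them (replicas).
#' @param samples_by_state named list of descriptor matrices, one entry per
#'   state label (>= 2 states).
#' @param of,normalize see [descriptor_relevance()].
#' @return data.frame with columns `state`, `descriptor`, `weight`.
#' @export
state_ranking_report <- function(model, samples_by_state,
                                 of = c("s_w", "s"),
                                 normalize = c("sum", "max")) {
  of <- match.arg(of); normalize <- match.arg(normalize)
  models <- if (inherits(model, "deeplda")) list(model) else model
  stopifnot(length(models) >= 1, all(vapply(models, inherits, logical(1), "deeplda")))
  if (is.null(names(samples_by_state)) || any(!nzchar(names(samples_by_state))))
    stop("`samples_by_state` must be a named list of state labels")
  if (length(samples_by_state) < 2L) stop("need >= 2 labelled states")
  rows <- lapply(names(samples_by_state), function(st) {
    per_model <- vapply(models, function(m)
      descriptor_relevance(m, samples_by_state[[st]], of, normalize),
      numeric(models[[1]]$n_d))
    w <- rowMeans(matrix(per_model, nrow = models[[1]]$n_d))
    nm <- models[[1]]$descriptor_names
    if (is.null(nm)) nm <- paste0("d", seq_along(w))
    data.frame(state = st, descriptor = nm, weight = w, row.names = NULL)
  })
  do.call(rbind, rows)
}
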