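# Deep-LDA: a small feed-forward network mapping the descriptor vector d to
# features h (the last hidden layer), trained by maximizing the Fisher ratio
# of the h-features; the CV is s = w' h with w the LDA direction on h, then
# smoothed by the cubic transform s_w = s + s^3 after an affine rescale of the
# training projections into [-1, 1].

act_fun <- function(z, act) {
  switch(act, linear = z, relu = pmax(z, 0), tanh = tanh(z),
         elu = ifelse(z > 0, z, expm1(z)),
         stop("unknown activation ", act))
}
act_grad <- function(z, act) {
  switch(act, linear = array(1, dim(z)), relu = (z > 0) * 1, tanh = 1 - tanh(z)^2,
         elu = ifelse(z > 0, 1, exp(z)),
         stop("unknown activation ", act))
}
act_code <- function(act) match(act, c("linear", "relu", "tanh", "elu")) - 1L

init_layers <- function(n_in, hidden, activation) {
  sizes <- c(n_in, hidden)
  lapply(seq_along(hidden), function(l) {
    fan_in <- sizes[l]
    sdv <- if (activation %in% c("relu", "elu")) sqrt(2 / fan_in)
           else sqrt(1 / fan_in)
    list(W = matrix(stats::rnorm(sizes[l + 1] * fan_in, 0, sdv),
                    sizes[l + 1], fan_in),
         b = numeric(sizes[l + 1]))
  })
}

# forward pass on standardized inputs; returns activations and pre-activations
net_forward <- function(layers, activation, X) {
  a <- list(X); z <- list()
  for (l in seq_along(layers)) {
    z[[l]] <- sweep(a[[l]] %*% t(layers[[l]]$W), 2, layers[[l]]$b, `+`)
    a[[l + 1]] <- act_fun(z[[l]], activation)
  }
  list(a = a, z = z)
}

# J and its gradient with respect to the feature rows H (n x N_h)
fisher_loss_grad <- function(H, isB, lambda) {
  HB <- H[isB, , drop = FALSE]; HU <- H[!isB, , drop = FALSE]
  nB <- nrow(HB); nU <- nrow(HU)
  muB <- colMeans(HB); muU <- colMeans(HU)
  delta <- muB - muU
  Sw <- stats::cov(HB) + stats::cov(HU)
  A <- Sw + lambda * diag(ncol(H))
  v <- solve(A, delta)           # v = (Sw + lambda I)^{-1} delta
  J <- sum(delta * v)
  G <- matrix(0, nrow(H), ncol(H))
  cB <- drop(sweep(HB, 2, muB) %*% v)
  cU <- drop(sweep(HU, 2, muU) %*% v)
  G[isB, ]  <- matrix(2 / nB * v, nB, ncol(H), byrow = TRUE) -
    (2 / (nB - 1)) * tcrossprod(cB, v)
  G[!isB, ] <- matrix(-2 / nU * v, nU, ncol(H), byrow = TRUE) -
    (2 / (nU - 1)) * tcrossprod(cU, v)
  list(J = J, grad_H = G, v = v)
}

# backpropagate dL/dH through the layers, returning parameter gradients
net_backprop <- function(layers, activation, fw, dH) {
  L <- length(layers)
  grads <- vector("list", L)
  delta <- dH * act_grad(fw$z[[L]], activation)
  for (l in L:1) {
    grads[[l]] <- list(W = crossprod(delta, fw$a[[l]]),
                       b = colSums(delta))
    if (l > 1) delta <- (delta %*% layers[[l]]$W) * act_grad(fw$z[[l - 1]], activation)
  }
  grads
}

#' Train a Deep-LDA collective variable
#'
#' Feeds labelled descriptor vectors through a small feed-forward network and
#' maximizes the Fisher ratio of the last-hidden-layer features, with the LDA
#' direction recomputed in closed form at every step; the negative ratio is
#' the training loss. Weights with the best validation ratio are kept
#' (early stopping when the validation ratio stagnates).
#'
#' @param x matrix/data.frame of descriptors (rows = samples), or a
#'   data.frame whose first column is `label` as produced by
#'   [make_gaussian_classes()] / [descriptor_table()] plus a label argument.
#' @param labels vector of class labels with exactly two levels; the first
#'   level (or "B") is the bound class and projects positive.
#' @param hidden integer vector of hidden-layer widths; the last entry is the
#'   feature width N_h. Default `c(32, 16, 8)`.
#' @param activation "elu" (default; continuously differentiable, so the CV
#'   gradient that enters biasing forces and derivative rankings is
#'   continuous), "relu", "tanh" or "linear".
#' @param lambda ridge regularizer on the feature within-scatter
#'   (default 0.05).
#' @param epochs maximum full-batch Adam epochs (default 400).
#' @param lr Adam learning rate (default 2e-3).
#' @param val_frac validation fraction (default 0.2, stratified).
#' @param patience early-stopping patience in epochs (default 50).
#' @param seed seed for the split and the weight initialization.
#' @return object of class `deeplda` with the network weights, the LDA vector
#'   `w` (unit norm, bound class positive), the input standardization, the
#'   affine rescale onto \[-1, 1\], and the training history.
#' @export
train_deep_lda <- function(x, labels, hidden = c(32, 16, 8),
                           activation = c("elu", "relu", "tanh", "linear"),
                           lambda = 0.05, epochs = 400, lr = 2e-3,
                           val_frac = 0.2, patience = 50, seed = 1) {
  activation <- match.arg(activation)
  if (is.data.frame(x) && "label" %in% names(x) && missing(labels)) {
    labels <- x$label
    x <- x[, setdiff(names(x), "label"), drop = FALSE]
  }
  X <- as.matrix(x); storage.mode(X) <- "double"
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L)
    stop("need exactly two classes, got ", length(lv))
  bound <- if ("B" %in% lv) "B" else lv[1]
  isB <- labels == bound
  if (min(hidden) < 1L) stop("hidden widths must be >= 1")

  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, `/`)

  with_seed(seed, {
    idx_val <- c(sample(which(isB), max(1, round(val_frac * sum(isB)))),
                 sample(which(!isB), max(1, round(val_frac * sum(!isB)))))
    layers <- init_layers(ncol(X), hidden, activation)
  })
  idx_tr <- setdiff(seq_len(nrow(X)), idx_val)
  Xtr <- Xs[idx_tr, , drop = FALSE]; Btr <- isB[idx_tr]
  Xva <- Xs[idx_val, , drop = FALSE]; Bva <- isB[idx_val]

  # Adam state
  m <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  v2 <- m
  beta1 <- 0.9; beta2 <- 0.999; eps_adam <- 1e-8
  best <- list(J = -Inf, layers = layers, epoch = 0L)
  hist_tr <- hist_va <- numeric(0)
  stall <- 0L

  val_J <- function(layers) {
    H <- net_forward(layers, activation, Xva)$a[[length(layers) + 1]]
    st <- scatter_stats(H[Bva, , drop = FALSE], H[!Bva, , drop = FALSE])
    fisher_ratio(lda_direction(st, lambda), st, lambda)
  }

  for (ep in seq_len(epochs)) {
    fw <- net_forward(layers, activation, Xtr)
    H <- fw$a[[length(layers) + 1]]
    lg <- fisher_loss_grad(H, Btr, lambda)
    if (!is.finite(lg$J)) stop("non-finite Fisher ratio at epoch ", ep,
                               " - training aborted")
    grads <- net_backprop(layers, activation, fw, -lg$grad_H)  # minimize -J
    for (l in seq_along(layers)) {
      for (p in c("W", "b")) {
        g <- grads[[l]][[p]]
        gn <- sqrt(sum(g^2))
        if (is.finite(gn) && gn > 100) g <- g * (100 / gn)
        m[[l]][[p]] <- beta1 * m[[l]][[p]] + (1 - beta1) * g
        v2[[l]][[p]] <- beta2 * v2[[l]][[p]] + (1 - beta2) * g^2
        mhat <- m[[l]][[p]] / (1 - beta1^ep)
        vhat <- v2[[l]][[p]] / (1 - beta2^ep)
        layers[[l]][[p]] <- layers[[l]][[p]] - lr * mhat / (sqrt(vhat) + eps_adam)
      }
    }
    Jva <- val_J(layers)
    hist_tr <- c(hist_tr, lg$J); hist_va <- c(hist_va, Jva)
    if (is.finite(Jva) && Jva > best$J * (1 + 1e-6) + 1e-12) {
      best <- list(J = Jva, layers = layers, epoch = ep)
      stall <- 0L
    } else stall <- stall + 1L
    if (stall >= patience) break
  }
  layers <- best$layers

  # final LDA vector on the training-split features, then rescale on all data
  Htr <- net_forward(layers, activation, Xtr)$a[[length(layers) + 1]]
  st <- scatter_stats(Htr[Btr, , drop = FALSE], Htr[!Btr, , drop = FALSE])
  w <- lda_direction(st, lambda)
  Hall <- net_forward(layers, activation, Xs)$a[[length(layers) + 1]]
  s_all <- drop(Hall %*% w)
  if (mean(s_all[isB]) < mean(s_all[!isB])) w <- -w  # bound class positive
  s_all <- drop(Hall %*% w)
  rng <- range(s_all)
  if (diff(rng) < 1e-12) rng <- rng + c(-0.5, 0.5)
  a_res <- 2 / diff(rng)
  b_res <- -(rng[1] + rng[2]) / diff(rng)

  structure(
    list(layers = layers, activation = activation, w = w,
         center = center, scale = scale, rescale = c(a = a_res, b = b_res),
         lambda = lambda, seed = seed, hidden = hidden,
         n_d = ncol(X), n_h = hidden[length(hidden)],
         descriptor_names = colnames(X), bound_label = bound,
         history = data.frame(epoch = seq_along(hist_tr),
                              J_train = hist_tr, J_val = hist_va),
         J_val_best = best$J, best_epoch = best$epoch),
    class = "deeplda"
  )
}

#' @export
print.deeplda <- function(x, ...) {
  cat(sprintf("deeplda CV: %d descriptors -> [%s] -> s (act %s, lambda %g)\n",
              x$n_d, paste(x$hidden, collapse = ", "), x$activation, x$lambda))
  cat(sprintf("  best validation J = %.4g at epoch %d\n", x$J_val_best, x$best_epoch))
  invisible(x)
}

check_dim <- function(model, X) {
  if (ncol(X) != model$n_d)
    stop("descriptor size mismatch: model expects ", model$n_d,
         ", got ", ncol(X))
}

as_X <- function(d) {
  if (is.null(dim(d))) matrix(d, nrow = 1) else as.matrix(d)
}

#' Deep-LDA projection s = w' h(d)
#'
#' @param model a trained [train_deep_lda()] model.
#' @param d descriptor vector or matrix (rows = samples).
#' @return projection value(s) `s` (before the cubic transform).
#' @export
project <- function(model, d) {
  stopifnot(inherits(model, "deeplda"))
  X <- as_X(d); check_dim(model, X)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, `/`)
  H <- net_forward(model$layers, model$activation, Xs)$a[[length(model$layers) + 1]]
  unname(drop(H %*% model$w))
}

#' Cubic smoothing transform s_w = s + s^3
#'
#' Applies the model's affine rescale (fitted so the training projections lie
#' in \[-1, 1\]) and then the strictly increasing cubic `s + s^3` that widens
#' the sharply bimodal classifier output into a CV suitable for biasing.
#'
#' @param model a trained `deeplda` model (provides the rescale).
#' @param s raw projection value(s) from [project()].
#' @return smoothed CV value(s) `s_w`.
#' @export
stretch <- function(model, s) {
  stopifnot(inherits(model, "deeplda"))
  sp <- model$rescale["a"] * s + model$rescale["b"]
  unname(sp + sp^3)
}

#' Deep-LDA CV value s_w(d)
#'
#' Convenience composition of [project()] and [stretch()].
#' @inheritParams project
#' @export
deeplda_sw <- function(model, d) stretch(model, project(model, d))

#' Gradient of the CV with respect to the raw descriptors
#'
#' Backpropagates through the network (and through the standardization,
#' rescale and cubic transform for `of = "s_w"`).
#'
#' @param model a trained `deeplda` model.
#' @param d descriptor vector or matrix.
#' @param of "s_w" (default; the biased CV) or "s" (raw projection).
#' @return n x N_d matrix of partial derivatives.
#' @export
deeplda_gradient <- function(model, d, of = c("s_w", "s")) {
  of <- match.arg(of)
  stopifnot(inherits(model, "deeplda"))
  X <- as_X(d); check_dim(model, X)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, `/`)
  fw <- net_forward(model$layers, model$activation, Xs)
  L <- length(model$layers)
  delta <- matrix(model$w, nrow(Xs), length(model$w), byrow = TRUE) *
    act_grad(fw$z[[L]], model$activation)
  if (L >= 2)
    for (l in L:2)
      delta <- (delta %*% model$layers[[l]]$W) * act_grad(fw$z[[l - 1]], model$activation)
  g <- delta %*% model$layers[[1]]$W           # ds/d(standardized input)
  g <- sweep(g, 2, model$scale, `/`)           # ds/d(raw input)
  if (of == "s_w") {
    s <- drop(fw$a[[L + 1]] %*% model$w)
    sp <- model$rescale["a"] * s + model$rescale["b"]
    g <- g * (model$rescale["a"] * (1 + 3 * sp^2))
  }
  colnames(g) <- model$descriptor_names
  g
}

# model in the layout the C++ integrator consumes
net_as_cpp <- function(model) {
  list(W = lapply(model$layers, `[[`, "W"),
       b = lapply(model$layers, `[[`, "b"),
       act = act_code(model$activation),
       w = as.numeric(model$w),
       a = unname(model$rescale["a"]), b2 = unname(model$rescale["b"]),
       center = as.numeric(model$center), scale = as.numeric(model$scale))
}

#' Serialize a Deep-LDA model to a JSON archive
#'
#' Plain-text, full-precision archive (weights, LDA vector, rescale,
#' descriptor specification); the same inputs always produce byte-identical
#' archives, and [read_deeplda()] restores an exactly equivalent model.
#'
#' @param model a `deeplda` model.
#' @param path output path (.json).
#' @export
write_deeplda <- function(model, path) {
  stopifnot(inherits(model, "deeplda"))
  obj <- list(
    format = "hydrocv-deeplda-1",
    hidden = model$hidden, activation = model$activation,
    lambda = model$lambda, seed = model$seed,
    n_d = model$n_d, n_h = model$n_h,
    bound_label = model$bound_label,
    descriptor_names = model$descriptor_names,
    center = model$center, scale = model$scale,
    rescale = as.list(model$rescale), w = model$w,
    layers = lapply(model$layers, function(l)
      list(W = as.vector(l$W), dim = dim(l$W), b = l$b)),
    J_val_best = model$J_val_best, best_epoch = model$best_epoch
  )
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' Restore a Deep-LDA model from a JSON archive
#'
#' @param path archive written by [write_deeplda()].
#' @return a `deeplda` model.
#' @export
read_deeplda <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "hydrocv-deeplda-1"))
    stop("not a hydrocv Deep-LDA archive: ", path)
  layers <- lapply(seq_len(nrow_list(obj$layers)), function(i) {
    li <- layer_i(obj$layers, i)
    list(W = matrix(li$W, li$dim[1], li$dim[2]), b = as.numeric(li$b))
  })
  structure(
    list(layers = layers, activation = obj$activation,
         w = as.numeric(obj$w), center = as.numeric(obj$center),
         scale = as.numeric(obj$scale),
         rescale = c(a = obj$rescale$a, b = obj$rescale$b),
         lambda = obj$lambda, seed = obj$seed, hidden = as.integer(obj$hidden),
         n_d = obj$n_d, n_h = obj$n_h,
         descriptor_names = obj$descriptor_names,
         bound_label = obj$bound_label,
         history = NULL, J_val_best = obj$J_val_best,
         best_epoch = obj$best_epoch),
    class = "deeplda"
  )
}

# jsonlite may return the layer list either as a list or a data.frame
nrow_list <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
layer_i <- function(x, i) {
  if (is.data.frame(x))
    list(W = x$W[[i]], dim = x$dim[[i]], b = x$b[[i]])
  else x[[i]]
}
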