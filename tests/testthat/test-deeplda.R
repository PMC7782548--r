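# Deep-LDA: training by Fisher-ratio maximization, projection, cubic
# transform, serialization, and C++/R forward-pass agreement.

test_that("training validates its inputs", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(train_deep_lda(X, rep("B", 20), epochs = 2), "two classes")
  expect_error(train_deep_lda(X, rep(c("B", "U"), 10), hidden = c(4, 0),
                              epochs = 2), ">= 1")
})

test_that("analytic Fisher-loss gradient matches finite differences", {
  set.seed(1)
  H <- matrix(rnorm(60), 20, 3)
  isB <- rep(c(TRUE, FALSE), each = 10)
  lg <- hydrocv:::fisher_loss_grad(H, isB, lambda = 0.05)
  h <- 1e-6
  for (idx in list(c(1, 1), c(3, 2), c(15, 3), c(20, 1))) {
    Hp <- H; Hp[idx[1], idx[2]] <- Hp[idx[1], idx[2]] + h
    Hm <- H; Hm[idx[1], idx[2]] <- Hm[idx[1], idx[2]] - h
    fd <- (hydrocv:::fisher_loss_grad(Hp, isB, 0.05)$J -
             hydrocv:::fisher_loss_grad(Hm, isB, 0.05)$J) / (2 * h)
    expect_equal(lg$grad_H[idx[1], idx[2]], fd, tolerance = 1e-4)
  }
})

test_that("a single linear layer reproduces the plain-LDA validation ratio", {
  d <- gauss4()
  X <- as.matrix(d[, -1]); lab <- as.character(d$label)
  m <- train_deep_lda(X, lab, hidden = 4, activation = "linear",
                      lambda = 1e-8, epochs = 60, seed = 3)
  # held-out samples (generated fresh) as the validation comparison
  d2 <- make_gaussian_classes(500, 4, c(1, 0.5, 0, 0), c(-1, -0.5, 0, 0),
                              cov = diag(4) + 0.3, seed = 202)
  X2 <- as.matrix(d2[, -1]); isB2 <- d2$label == "B"
  # plain LDA ratio on raw descriptors
  st_d <- scatter_stats(X2[isB2, ], X2[!isB2, ])
  J_plain <- fisher_ratio(lda_direction(st_d, 0), st_d, 0)
  # deep model ratio on its features
  Xs <- sweep(sweep(X2, 2, m$center), 2, m$scale, `/`)
  H <- hydrocv:::net_forward(m$layers, m$activation, Xs)$a[[2]]
  st_h <- scatter_stats(H[isB2, ], H[!isB2, ])
  J_deep <- fisher_ratio(lda_direction(st_h, 0), st_h, 0)
  expect_equal(J_deep, J_plain, tolerance = 1e-3)
})

test_that("learned projection tracks the analytic LDA direction on held-out data", {
  m <- model4()
  d2 <- make_gaussian_classes(1000, 4, c(1, 0.5, 0, 0), c(-1, -0.5, 0, 0),
                              cov = diag(4) + 0.3, seed = 303)
  X2 <- as.matrix(d2[, -1])
  d <- gauss4()
  st <- scatter_stats(d[d$label == "B", -1], d[d$label == "U", -1])
  w_an <- lda_direction(st, 0)
  s_deep <- project(m, X2)
  s_lin <- drop(X2 %*% w_an)
  expect_gte(abs(cor(s_deep, s_lin)), 0.95)
  # sign convention: bound class projects positive
  expect_gt(mean(project(m, as.matrix(d[d$label == "B", -1]))),
            mean(project(m, as.matrix(d[d$label == "U", -1]))))
})

test_that("three seeds give consistent CVs (pairwise held-out correlation)", {
  d <- gauss4()
  ms <- lapply(c(5, 6, 7), function(s)
    train_deep_lda(d[, -1], d$label, hidden = c(16, 8), epochs = 200, seed = s))
  d2 <- make_gaussian_classes(400, 4, c(1, 0.5, 0, 0), c(-1, -0.5, 0, 0),
                              cov = diag(4) + 0.3, seed = 404)
  S <- vapply(ms, function(m) deeplda_sw(m, as.matrix(d2[, -1])), numeric(800))
  for (i in 1:2) for (j in (i + 1):3)
    expect_gte(abs(cor(S[, i], S[, j])), 0.9)
})

test_that("projection matches an independent scalar-loop forward pass", {
  m <- model4()
  X <- as.matrix(gauss4()[1:7, -1])
  s_ref <- vapply(seq_len(nrow(X)), function(i) {
    a <- (X[i, ] - m$center) / m$scale
    for (l in seq_along(m$layers)) {
      z <- numeric(nrow(m$layers[[l]]$W))
      for (r in seq_along(z))
        z[r] <- sum(m$layers[[l]]$W[r, ] * a) + m$layers[[l]]$b[r]
      a <- ifelse(z > 0, z, exp(z) - 1)   # ELU, written independently
    }
    sum(m$w * a)
  }, numeric(1))
  expect_equal(project(m, X), s_ref, tolerance = 1e-10)
  # batch of identical descriptors project identically
  Xr <- X[rep(2, 5), ]
  expect_equal(project(m, Xr), rep(project(m, X[2, , drop = FALSE]), 5))
  expect_error(project(m, X[, 1:3]), "size mismatch")
})

test_that("C++ CV evaluation and gradient mirror the R implementation", {
  m <- landscape_model(101)
  X <- cbind(seq(-1.4, 1.4, length.out = 31),
             seq(0, 4, length.out = 31) + 0.1 * sin(1:31))
  net <- hydrocv:::net_as_cpp(m)
  sw_cpp <- hydrocv:::cpp_net_sw(net, X)
  expect_equal(sw_cpp, deeplda_sw(m, X), tolerance = 1e-12)
  eg <- hydrocv:::cpp_net_sw_grad(net, X)
  expect_equal(unname(eg$grad), unname(deeplda_gradient(m, X)),
               tolerance = 1e-10)
})

test_that("cubic stretch maps the rescaled projection as s + s^3", {
  m <- model4()
  # invert the rescale so the rescaled values are exactly 0, 1, -1
  a <- m$rescale["a"]; b <- m$rescale["b"]
  s_for <- function(sp) (sp - b) / a
  expect_equal(stretch(m, s_for(0)), 0)
  expect_equal(stretch(m, s_for(1)), 2)
  expect_equal(stretch(m, s_for(-1)), -2)
  # strictly increasing over a dense scan
  s <- seq(s_for(-1.5), s_for(1.5), length.out = 1000)
  expect_true(all(diff(stretch(m, s)) > 0))
})

test_that("stretch widens the training projection distribution", {
  m <- model4()
  s <- project(m, as.matrix(gauss4()[, -1]))
  sp <- m$rescale["a"] * s + m$rescale["b"]
  expect_gte(var(stretch(m, s)), var(sp))
})

test_that("deep CV separates classes at least as well as the best descriptor", {
  m <- model4()
  d2 <- make_gaussian_classes(1000, 4, c(1, 0.5, 0, 0), c(-1, -0.5, 0, 0),
                              cov = diag(4) + 0.3, seed = 505)
  X2 <- as.matrix(d2[, -1]); isB <- d2$label == "B"
  sep <- function(v) abs(mean(v[isB]) - mean(v[!isB])) / sd(v)
  sep_deep <- sep(deeplda_sw(m, X2))
  sep_best <- max(apply(X2, 2, sep))
  expect_gte(sep_deep, sep_best)
})

test_that("model archives round-trip and are byte-identical for equal seeds", {
  d <- gauss4()[seq(1, 4000, 8), ]
  m1 <- train_deep_lda(d[, -1], d$label, hidden = c(8, 4), epochs = 40, seed = 9)
  m2 <- train_deep_lda(d[, -1], d$label, hidden = c(8, 4), epochs = 40, seed = 9)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_deeplda(m1, f1); write_deeplda(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  m3 <- read_deeplda(f1)
  X <- as.matrix(d[1:20, -1])
  expect_equal(deeplda_sw(m3, X), deeplda_sw(m1, X), tolerance = 1e-12)
  expect_equal(deeplda_gradient(m3, X), deeplda_gradient(m1, X),
               tolerance = 1e-12)
})
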