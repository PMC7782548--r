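# Shared fixtures, built lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

th300 <- thermo_params(300)

# well-separated two-class Gaussian descriptor set (4-D)
gauss4 <- function() fixture("gauss4", function() {
  make_gaussian_classes(2000, 4, mean_B = c(1, 0.5, 0, 0),
                        mean_U = c(-1, -0.5, 0, 0),
                        cov = diag(4) + 0.3, seed = 71)
})

# small trained model on the 4-D Gaussian data
model4 <- function() fixture("model4", function() {
  d <- gauss4()
  train_deep_lda(d[, -1], d$label, hidden = c(16, 8), epochs = 200, seed = 5)
})

# toy host-guest frame sets (small but informative)
frames_B <- function() fixture("frames_B", function()
  toy_host_guest_frames(60, 200, "B", seed = 21))
frames_U <- function() fixture("frames_U", function()
  toy_host_guest_frames(60, 200, "U", seed = 22))

# two-class descriptor data from the toy landscape basins: short unbiased
# runs in each basin, descriptors d = (z, q)
basin_descriptors <- function() fixture("basin_descriptors", function() {
  ls <- toy_landscape(th300)
  tb <- langevin_trajectory(ls, c(-1, ls$q_B), th300, n_steps = 4e4,
                            seed = 31, log_stride = 4)
  tu <- langevin_trajectory(ls, c(1, ls$q_U), th300, n_steps = 4e4,
                            seed = 32, log_stride = 4)
  list(X = rbind(as.matrix(tb[, c("z", "q")]), as.matrix(tu[, c("z", "q")])),
       labels = rep(c("B", "U"), each = nrow(tb)))
})

landscape_model <- function(seed = 101) {
  key <- paste0("landscape_model_", seed)
  fixture(key, function() {
    bd <- basin_descriptors()
    train_deep_lda(bd$X, bd$labels, hidden = c(8, 4), epochs = 250,
                   seed = seed)
  })
}
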