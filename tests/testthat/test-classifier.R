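test_that("initialization is seeded, sized and fan-in scaled", {
  net1 <- init_network(c(12, 64, 64, 64, 3), seed = 31)
  net2 <- init_network(c(12, 64, 64, 64, 3), seed = 31)
  expect_identical(net1, net2)
  expect_equal(sapply(net1$w, dim), matrix(c(12, 64, 64, 64, 64, 64, 64, 3), 2))
  expect_true(all(sapply(net1$b, function(b) all(b == 0))))
  # U(-sqrt(6/fan_in), +) has SD lim/sqrt(3); check over ~1e4 draws
  big <- init_network(c(100, 100, 3), seed = 32)
  lim <- sqrt(6 / 100)
  expect_lt(max(abs(big$w[[1]])), lim)
  expect_equal(stats::sd(big$w[[1]]), lim / sqrt(3), tolerance = 0.03)
  expect_error(init_network(c(12), seed = 1), "layer_sizes")
})

test_that("forward pass reproduces the per-node affine + activation rule", {
  # all-zero weights: symmetric softmax
  net <- init_network(c(12, 4, 3), seed = 33)
  net$w <- lapply(net$w, function(w) w * 0)
  p <- forward(net, runif(12))
  expect_equal(unname(p[1, ]), rep(1 / 3, 3), tolerance = 1e-12)

  # single hidden node computed by hand: y = relu(b + sum x_n w_n)
  net1 <- init_network(c(3, 1, 3), seed = 34)
  x <- c(0.2, 0.5, 0.9)
  h <- max(0, net1$b[[1]] + sum(x * net1$w[[1]]))
  z <- net1$b[[2]] + h * as.vector(net1$w[[2]])
  expect_equal(unname(forward(net1, x)[1, ]), exp(z) / sum(exp(z)),
               tolerance = 1e-12)

  expect_error(forward(net1, runif(5)), "does not match")
})

test_that("forward agrees with an independently coded matrix oracle", {
  net <- init_network(c(12, 7, 5, 3), seed = 35)
  set.seed(36)
  x <- matrix(runif(10 * 12), 10)
  # plain loop-based oracle, no shared code path
  oracle <- t(apply(x, 1, function(xi) {
    a <- xi
    for (l in seq_along(net$w)) {
      z <- drop(t(net$w[[l]]) %*% a) + net$b[[l]]
      a <- if (l < length(net$w)) pmax(z, 0) else exp(z) / sum(exp(z))
    }
    a
  }))
  expect_lt(max(abs(forward(net, x) - oracle)), 1e-12)
  expect_true(all(abs(rowSums(forward(net, x)) - 1) < 1e-9))
})

test_that("cross-entropy matches closed forms and hand computation", {
  y <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(cross_entropy(y, y), 0, tolerance = 1e-9)
  expect_equal(cross_entropy(matrix(1 / 3, 2, 3), y), log(3))
  p <- rbind(c(0.7, 0.2, 0.1), c(0.25, 0.6, 0.15))
  expect_equal(cross_entropy(p, y), mean(-log(c(0.7, 0.6))))
})

test_that("backpropagated gradients match finite differences", {
  net <- init_network(c(4, 5, 3), seed = 37)
  set.seed(38)
  x <- matrix(runif(6 * 4), 6)
  y <- pkprescreen:::one_hot(sample(c("first_order", "erlang", "split_peak"), 6,
                      replace = TRUE))
  g <- pkprescreen:::mlp_gradients(net, x, y)
  eps <- 1e-6
  for (l in seq_along(net$w)) {
    for (idx in sample(length(net$w[[l]]), 5)) {
      up <- net; up$w[[l]][idx] <- up$w[[l]][idx] + eps
      dn <- net; dn$w[[l]][idx] <- dn$w[[l]][idx] - eps
      fd <- (cross_entropy(forward(up, x), y) -
               cross_entropy(forward(dn, x), y)) / (2 * eps)
      expect_equal(g$w[[l]][idx], fd, tolerance = 1e-5)
    }
    up <- net; up$b[[l]][1] <- up$b[[l]][1] + eps
    dn <- net; dn$b[[l]][1] <- dn$b[[l]][1] - eps
    fd <- (cross_entropy(forward(up, x), y) -
             cross_entropy(forward(dn, x), y)) / (2 * eps)
    expect_equal(unname(g$b[[l]][1]), fd, tolerance = 1e-5)
  }
})

test_that("training solves a linearly separable toy problem", {
  set.seed(39)
  n <- 200
  cls <- sample(shape_levels(), n, replace = TRUE)
  centers <- list(first_order = c(0, 0), erlang = c(3, 0), split_peak = c(0, 3))
  x <- t(vapply(cls, function(cc) centers[[cc]] + rnorm(2, 0, 0.3),
                numeric(2)))
  y <- pkprescreen:::one_hot(cls)
  net <- init_network(c(2, 8, 3), seed = 40)
  out <- train_network(net, x, y, cfg = training_config(epochs = 100,
                                                        seed = 41))
  expect_equal(out$history$train_acc[100], 1)
})

test_that("training learns noiseless profiles almost perfectly", {
  # even without residual error the shape classes overlap slightly (a
  # first-order subject with a very low ka draw resembles a mixed
  # profile), so validation accuracy saturates just below 1
  ds <- simulate_dataset(n_per_shape = 200, seed = 42, ruv = FALSE)
  sp <- stratified_split(ds, 0.3, seed = 43)
  ftr <- assemble_features(sp$train)
  fva <- assemble_features(sp$validation)
  net <- init_network(c(12, 32, 32, 32, 3), seed = 44)
  out <- train_network(net, ftr$x, ftr$y, fva$x, fva$y,
                       training_config(epochs = 100, seed = 45))
  expect_equal(out$history$train_acc[100], 1)
  expect_gte(out$history$val_acc[100], 0.98)
})

test_that("training histories are reproducible from the seed", {
  ds <- simulate_dataset(n_per_shape = 30, seed = 46)
  f <- assemble_features(ds)
  run <- function() {
    net <- init_network(c(12, 16, 3), seed = 47)
    train_network(net, f$x, f$y, cfg = training_config(epochs = 5, seed = 48))
  }
  expect_identical(run(), run())
})

test_that("classification argmax and tie handling are deterministic", {
  net <- init_network(c(12, 3), seed = 49)
  net$w[[1]] <- net$w[[1]] * 0
  net$b[[1]] <- c(1, 1, 0)     # exact tie between the first two classes
  out <- classify(net, matrix(runif(12), 1))
  expect_equal(as.character(out$assigned), "first_order")
  expect_true(out$tie)
  net$b[[1]] <- c(0, 2, 0)
  out2 <- classify(net, matrix(runif(12), 1))
  expect_equal(as.character(out2$assigned), "erlang")
  expect_false(out2$tie)
})

test_that("model artifacts round-trip bit-exactly and validate on load", {
  net <- init_network(c(12, 8, 5, 3), seed = 50)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(net, path)
  back <- load_model(path)
  set.seed(51)
  x <- matrix(runif(3 * 12), 3)
  expect_identical(forward(back, x), forward(net, x))

  art <- jsonlite::read_json(path)
  art$w[[1]]$dim <- list(12L, 9L)
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(art, bad, auto_unbox = TRUE)
  expect_error(load_model(bad), "inconsistent")

  art2 <- jsonlite::read_json(path)
  art2$version <- 99L
  bad2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(art2, bad2, auto_unbox = TRUE)
  expect_error(load_model(bad2), "unsupported")
})
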