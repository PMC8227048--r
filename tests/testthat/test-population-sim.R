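test_that("zero variability returns the weight-scaled typical values", {
  pop <- population_parameters(cv_cl = 0, cv_v = 0, cv_ka = 0, cv_ktr = 0,
                               sd_fraction_logit = 0)
  des <- study_design()
  set.seed(1)
  p <- sample_individual(pop, des, "split_peak")
  expect_identical(p$cl, allometric_scale(22.6, 20, 0.75))
  expect_identical(p$v, allometric_scale(38.9, 20, 1))
  expect_identical(p$ka, 7.6)
  expect_identical(p$ktr, 5.2)
  expect_equal(p$fraction, 0.78, tolerance = 1e-12)
})

test_that("typical values equal the population estimates at 70 kg", {
  pop <- population_parameters(cv_cl = 0, cv_v = 0, cv_ka = 0, cv_ktr = 0)
  des <- study_design(weight = 70)
  set.seed(1)
  p <- sample_individual(pop, des, "first_order")
  expect_equal(p$cl, 22.6)
  expect_equal(p$v, 38.9)
  expect_equal(p$ka, 3.3)
})

test_that("realized between-subject CV matches the population CV", {
  pop <- population_parameters()
  des <- study_design()
  set.seed(2)
  cl <- replicate(1e5, sample_individual(pop, des, "erlang")$cl)
  emp_cv <- stats::sd(cl) / mean(cl)
  expect_gt(emp_cv, 0.28)
  expect_lt(emp_cv, 0.30)
})

test_that("proportional residual error has the right magnitude", {
  set.seed(3)
  reps <- apply_ruv(rep(100, 1e5), 0.165)
  expect_gt(stats::sd(reps) / mean(reps), 0.16)
  expect_lt(stats::sd(reps) / mean(reps), 0.17)
  # identity at sigma 0 and zero-preserving
  expect_identical(apply_ruv(c(0, 1, 2), 0), c(0, 1, 2))
  set.seed(4)
  expect_identical(apply_ruv(c(0, 0), 0.5), c(0, 0))
  expect_error(apply_ruv(1, -0.1), "sigma_prop")
})

test_that("simulate_dataset is balanced, finite and non-negative", {
  ds <- simulate_dataset(n_per_shape = 50, seed = 5)
  expect_equal(as.integer(table(ds$shape)), rep(50L, 3))
  expect_equal(dim(ds$conc), c(150, 12))
  expect_true(all(is.finite(ds$conc)))
  expect_true(all(ds$conc >= 0))
  expect_true(all(ds$conc[, 1] == 0))   # predose sample is structurally 0
  one <- simulate_dataset(n_per_shape = 1, seed = 5)
  expect_equal(nrow(one$conc), 3)
})

test_that("identical seed gives a bit-identical dataset", {
  a <- simulate_dataset(n_per_shape = 20, seed = 6)
  b <- simulate_dataset(n_per_shape = 20, seed = 6)
  expect_identical(a, b)
})

test_that("residual-error settings do not perturb sampled parameters", {
  a <- simulate_dataset(pop = population_parameters(ruv_prop = 0.165),
                        n_per_shape = 20, seed = 7)
  b <- simulate_dataset(pop = population_parameters(ruv_prop = 0.5),
                        n_per_shape = 20, seed = 7)
  expect_identical(a$params, b$params)
})

test_that("noiseless mean profile reflects the log-normal mean shift", {
  # E[1/CL-like terms]: at a single late time point the concentration is
  # dominated by exp(-k t) variation; verify the simulated mean against a
  # direct large-sample Monte-Carlo of the same log-normal model
  pop <- population_parameters(cv_ka = 0)
  des <- study_design()
  set.seed(8)
  ds <- simulate_dataset(pop, des, n_per_shape = 5000, seed = 8, ruv = FALSE)
  sim_mean <- mean(ds$conc[ds$shape == "first_order", 12])
  set.seed(9)
  omega_cl <- sqrt(log(1 + 0.29^2)); omega_v <- sqrt(log(1 + 0.21^2))
  cl0 <- allometric_scale(22.6, 20, 0.75) * exp(rnorm(2e5, 0, omega_cl))
  v0 <- allometric_scale(38.9, 20, 1) * exp(rnorm(2e5, 0, omega_v))
  k0 <- cl0 / v0
  mc_mean <- mean(10 * 3.3 / (v0 * (3.3 - k0)) * (exp(-k0 * 6) - exp(-3.3 * 6)))
  expect_equal(sim_mean, mc_mean, tolerance = 0.05)
})

test_that("stratified split partitions each class at the stated fraction", {
  ds <- simulate_dataset(n_per_shape = 100, seed = 10)
  sp <- stratified_split(ds, 0.3, seed = 11)
  expect_equal(as.integer(table(sp$validation$shape)), rep(30L, 3))
  expect_equal(as.integer(table(sp$train$shape)), rep(70L, 3))
  expect_identical(sort(c(sp$train$id, sp$validation$id)), sort(ds$id))
  expect_length(intersect(sp$train$id, sp$validation$id), 0)
})

test_that("split rounding holds out 3 of 10 per class at 30%", {
  ds <- simulate_dataset(n_per_shape = 10, seed = 12)
  sp <- stratified_split(ds, 0.3, seed = 13)
  expect_equal(as.integer(table(sp$validation$shape)), rep(3L, 3))
})

test_that("degenerate holdouts are rejected", {
  ds <- simulate_dataset(n_per_shape = 2, seed = 14)
  expect_error(stratified_split(ds, 0.95, seed = 1), "empty class")
  expect_error(stratified_split(ds, 1.2, seed = 1), "holdout_fraction")
})
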