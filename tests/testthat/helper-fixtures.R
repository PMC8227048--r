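# shared fixtures for the suite

typical_individual <- function(shape = "split_peak", weight = 20, dose = 10) {
  pop <- population_parameters()
  cl <- allometric_scale(pop$cl_typical, weight, 0.75)
  v <- allometric_scale(pop$v_typical, weight, 1)
  switch(shape,
         first_order = individual_parameters(cl, v, ka = pop$ka_typical,
                                             dose = dose, weight = weight),
         erlang = individual_parameters(cl, v, ktr = pop$ktr_erlang,
                                        dose = dose, weight = weight),
         split_peak = individual_parameters(cl, v, ka = pop$ka_split,
                                            ktr = pop$ktr_split,
                                            fraction = pop$fraction_typical,
                                            dose = dose, weight = weight))
}

design_times <- function() study_design()$sample_times

# draw a random positive parameter set spanning a wide plausible range
random_individual <- function(shape) {
  individual_parameters(
    cl = exp(stats::runif(1, log(1), log(50))),
    v = exp(stats::runif(1, log(5), log(100))),
    ka = exp(stats::runif(1, log(0.3), log(20))),
    ktr = exp(stats::runif(1, log(0.3), log(20))),
    fraction = stats::runif(1, 0.05, 0.95),
    dose = stats::runif(1, 1, 100),
    weight = 20)
}

# labeled prediction/reference pair reproducing the published external
# confusion counts: rows predicted, cols reference
external_confusion_fixture <- function() {
  counts <- matrix(c(18, 1, 1,
                     0, 21, 1,
                     0, 0, 6), nrow = 3, byrow = TRUE)
  lv <- c("first_order", "erlang", "split_peak")
  predicted <- character(0); reference <- character(0)
  for (i in 1:3) for (j in 1:3) {
    predicted <- c(predicted, rep(lv[i], counts[i, j]))
    reference <- c(reference, rep(lv[j], counts[i, j]))
  }
  list(predicted = predicted, reference = reference)
}

# small trained classifier shared across io tests (built once per run)
small_trained_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- simulate_dataset(n_per_shape = 300, seed = 77)
      f <- assemble_features(ds)
      net <- init_network(c(12, 32, 32, 3), seed = 78)
      cache <<- train_network(net, f$x, f$y,
                              cfg = training_config(epochs = 40,
                                                    seed = 79))$net
    }
    cache
  }
})
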