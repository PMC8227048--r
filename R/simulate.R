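#' Derive per-purpose sub-seeds from one master seed
#'
#' A single master seed deterministically spawns independent sub-seeds for
#' each randomness consumer (parameter sampling, residual error, data
#' splitting, network initialization, batch shuffling), so that e.g.
#' changing the residual-error magnitude never perturbs the sampled
#' individual parameters.
#'
#' @param seed Master seed (integer).
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of `n` sub-seeds.
#' @export
spawn_seeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Sample one subject's parameters from the population model
#'
#' Clearance and volume are weight-scaled allometrically (exponents 0.75
#' and 1) and drawn log-normally around their typicals with variance
#' \eqn{\omega^2 = \ln(1 + CV^2)}, so the realized coefficient of
#' variation equals the stated CV.  The absorption parameters drawn depend
#' on `shape`: `ka` for first-order, `ktr` for Erlang, and `ka`, `ktr` and
#' the logit-normally distributed absorbed `fraction` for split-peak.
#' The clearance/volume population distribution is identical across
#' shapes.  Uses the current R RNG state; seed before calling for
#' reproducibility.
#'
#' @param pop A [population_parameters()] object.
#' @param design A [study_design()] object (supplies dose and weight).
#' @param shape One of `"first_order"`, `"erlang"`, `"split_peak"`.
#' @return An [individual_parameters()] object.
#' @examples
#' set.seed(1)
#' sample_individual(population_parameters(), study_design(), "erlang")
#' @export
sample_individual <- function(pop, design, shape) {
  shape <- match.arg(shape, shape_levels())
  lnorm_draw <- function(typical, cv) {
    omega <- sqrt(log(1 + cv^2))
    typical * exp(stats::rnorm(1L, 0, omega))
  }
  cl <- lnorm_draw(allometric_scale(pop$cl_typical, design$weight, 0.75),
                   pop$cv_cl)
  v <- lnorm_draw(allometric_scale(pop$v_typical, design$weight, 1),
                  pop$cv_v)
  ka <- NA_real_
  ktr <- NA_real_
  fraction <- NA_real_
  if (shape == "first_order") {
    ka <- lnorm_draw(pop$ka_typical, pop$cv_ka)
  } else if (shape == "erlang") {
    ktr <- lnorm_draw(pop$ktr_erlang, pop$cv_ktr)
  } else {
    ka <- lnorm_draw(pop$ka_split, pop$cv_ka)
    ktr <- lnorm_draw(pop$ktr_split, pop$cv_ktr)
    mu <- stats::qlogis(pop$fraction_typical)
    fraction <- stats::plogis(mu + stats::rnorm(1L, 0, pop$sd_fraction_logit))
  }
  individual_parameters(cl = cl, v = v, ka = ka, ktr = ktr,
                        fraction = fraction, dose = design$dose,
                        weight = design$weight)
}

#' Apply proportional residual error to true concentrations
#'
#' Each concentration is multiplied by `1 + eps` with
#' `eps ~ Normal(0, sigma_prop^2)`; results are clipped at zero (an event
#' requiring `eps < -1`, probability ~1e-9 at sigma 0.165).  A true
#' concentration of zero stays zero.  Uses the current RNG state.
#'
#' @param true_conc Numeric vector or matrix of model-predicted
#'   concentrations.
#' @param sigma_prop Proportional error SD (fraction, >= 0).
#' @return Perturbed concentrations, same shape as the input.
#' @export
apply_ruv <- function(true_conc, sigma_prop) {
  if (!is.finite(sigma_prop) || sigma_prop < 0) {
    stop("sigma_prop must be non-negative")
  }
  eps <- stats::rnorm(length(true_conc), 0, sigma_prop)
  out <- true_conc * (1 + eps)
  out[out < 0] <- 0
  out
}

#' Simulate a labeled dataset of concentration-time profiles
#'
#' Generates `n_per_shape` profiles for each of the three absorption
#' shapes: individual parameters are drawn by [sample_individual()], the
#' matching closed-form model is evaluated at the design's sample times,
#' and proportional residual error is added by [apply_ruv()].  Parameter
#' sampling and residual error consume two independent sub-streams spawned
#' from `seed` (see [spawn_seeds()]), making the dataset bit-reproducible.
#'
#' @param pop A [population_parameters()] object.
#' @param design A [study_design()] object.
#' @param n_per_shape Number of profiles per shape (>= 1).
#' @param seed Master seed.
#' @param ruv Set `FALSE` to simulate noiseless profiles.
#' @return A `pk_dataset`: list with elements `id`, `shape` (factor),
#'   `conc` (profiles x times matrix), `times`, `dose`, `weight`, and
#'   `params` (data frame of realized individual parameters).
#' @examples
#' ds <- simulate_dataset(n_per_shape = 5, seed = 42)
#' table(ds$shape)
#' @export
simulate_dataset <- function(pop = population_parameters(),
                             design = study_design(),
                             n_per_shape = 10000L,
                             seed = 2021L,
                             ruv = TRUE) {
  n_per_shape <- as.integer(n_per_shape)
  if (is.na(n_per_shape) || n_per_shape < 1L) stop("n_per_shape must be >= 1")
  seeds <- spawn_seeds(seed, 2L)
  shapes <- rep(shape_levels(), each = n_per_shape)
  n <- length(shapes)
  nt <- length(design$sample_times)

  set.seed(seeds[1])
  params <- vector("list", n)
  for (i in seq_len(n)) params[[i]] <- sample_individual(pop, design, shapes[i])

  conc <- matrix(0, nrow = n, ncol = nt)
  for (i in seq_len(n)) {
    conc[i, ] <- conc_profile(shapes[i], params[[i]], design$sample_times,
                              n_transit = pop$n_transit)
  }

  if (ruv) {
    set.seed(seeds[2])
    conc <- apply_ruv(conc, pop$ruv_prop)
  }

  pd <- data.frame(
    cl = vapply(params, `[[`, numeric(1), "cl"),
    v = vapply(params, `[[`, numeric(1), "v"),
    ka = vapply(params, `[[`, numeric(1), "ka"),
    ktr = vapply(params, `[[`, numeric(1), "ktr"),
    fraction = vapply(params, `[[`, numeric(1), "fraction"))

  structure(
    list(id = sprintf("%s_%05d", shapes, sequence(rep(n_per_shape, 3))),
         shape = factor(shapes, levels = shape_levels()),
         conc = conc,
         times = design$sample_times,
         dose = design$dose,
         weight = design$weight,
         params = pd,
         n_transit = pop$n_transit,
         seed = seed),
    class = "pk_dataset")
}

#' @export
print.pk_dataset <- function(x, ...) {
  cat(sprintf("pk_dataset: %d profiles x %d times\n",
              nrow(x$conc), ncol(x$conc)))
  print(table(x$shape))
  invisible(x)
}

#' Subset a pk_dataset by profile index
#'
#' @param ds A `pk_dataset`.
#' @param idx Integer indices of the profiles to keep.
#' @return A `pk_dataset` with the selected profiles.
#' @export
subset_dataset <- function(ds, idx) {
  ds$id <- ds$id[idx]
  ds$shape <- ds$shape[idx]
  ds$conc <- ds$conc[idx, , drop = FALSE]
  ds$params <- ds$params[idx, , drop = FALSE]
  ds
}

# round half away from zero (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

#' Stratified train/validation split
#'
#' Holds out `holdout_fraction` of each shape's profiles (rounded half
#' away from zero per class, with the last class adjusted if the total
#' drifts from the overall target), sampled without replacement from a
#' sub-stream of `seed`.  No profile appears in both parts.
#'
#' @param ds A `pk_dataset` (all profiles labeled).
#' @param holdout_fraction Fraction held out for validation, in (0, 1).
#' @param seed Seed for the split.
#' @return List with elements `train` and `validation`, both `pk_dataset`s.
#' @examples
#' ds <- simulate_dataset(n_per_shape = 10, seed = 1)
#' sp <- stratified_split(ds, 0.3, seed = 2)
#' nrow(sp$train$conc); nrow(sp$validation$conc)
#' @export
stratified_split <- function(ds, holdout_fraction, seed = 1L) {
  if (!is.finite(holdout_fraction) ||
      holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop("holdout_fraction must lie strictly inside (0, 1)")
  }
  labels <- levels(ds$shape)
  n_by <- table(ds$shape)[labels]
  n_hold <- round_half_up(holdout_fraction * as.numeric(n_by))
  target_total <- round_half_up(holdout_fraction * sum(n_by))
  drift <- target_total - sum(n_hold)
  if (drift != 0) n_hold[length(n_hold)] <- n_hold[length(n_hold)] + drift
  if (any(n_hold < 1) || any(n_hold >= as.numeric(n_by))) {
    stop("holdout_fraction would leave an empty class in train or validation")
  }
  set.seed(spawn_seeds(seed, 1L))
  val_idx <- integer(0)
  for (j in seq_along(labels)) {
    cls <- which(ds$shape == labels[j])
    val_idx <- c(val_idx, sort(sample(cls, n_hold[j])))
  }
  list(train = subset_dataset(ds, setdiff(seq_along(ds$id), val_idx)),
       validation = subset_dataset(ds, val_idx))
}

#' Convert a pk_dataset to a long-format data frame
#'
#' One row per observation with NONMEM-flavored companions (dose, weight),
#' the format written by [write_dataset()].
#'
#' @param x A `pk_dataset`.
#' @param ... Unused.
#' @return data.frame with columns `id`, `shape`, `time`, `conc`, `dose`,
#'   `weight`.
#' @export
as.data.frame.pk_dataset <- function(x, ...) {
  nt <- length(x$times)
  data.frame(
    id = rep(x$id, each = nt),
    shape = rep(as.character(x$shape), each = nt),
    time = rep(x$times, times = length(x$id)),
    conc = as.vector(t(x$conc)),
    dose = x$dose,
    weight = x$weight,
    stringsAsFactors = FALSE)
}

#' Write a simulated dataset and its metadata sidecar
#'
#' Writes the long-format table as CSV and a YAML sidecar recording the
#' seed, design and label counts next to it (same path with `.yaml`
#' appended).
#'
#' @param ds A `pk_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE)
  meta <- list(seed = ds$seed,
               n_profiles = length(ds$id),
               counts = as.list(table(ds$shape)),
               sample_times = ds$times,
               dose = ds$dose,
               weight = ds$weight,
               n_transit = ds$n_transit)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}
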