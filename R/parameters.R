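#' Population pharmacokinetic parameters
#'
#' Bundles the typical values and between-subject variability (BSV)
#' magnitudes of the one-compartment oral model with its three alternative
#' absorption sub-models: first-order (rate constant `ka`), an Erlang
#' transit chain (`n_transit` sequential compartments, each emptying at
#' rate `ktr`), and a mixed "split-peak" process in which a fraction of the
#' dose is absorbed first-order and the remainder through the transit
#' chain.  Clearance and volume are shared across the three sub-models and
#' are expressed per 70 kg; BSV magnitudes are coefficients of variation
#' (fractions, log-normal scale), and `ruv_prop` is the proportional
#' residual-error SD.
#'
#' The defaults are the population estimates from a pediatric cortisol
#' study: CL 22.6 L/h/70 kg (29% CV), V 38.9 L/70 kg (21% CV),
#' first-order KA 3.3 1/h (48% CV), Erlang KTR 8.2 1/h (23% CV),
#' split-peak KTR 5.2 1/h (23% CV), split-peak KA 7.6 1/h (48% CV),
#' absorbed fraction 0.78 (0.80 variability on the logit scale), and a
#' 16.5% proportional residual error.
#'
#' @param cl_typical Clearance, L/h per 70 kg.
#' @param v_typical Volume of distribution, L per 70 kg.
#' @param ka_typical First-order absorption rate constant, 1/h
#'   (first-order model).
#' @param ka_split First-order rate constant of the split-peak model, 1/h.
#' @param ktr_erlang Transit rate constant of the Erlang model, 1/h.
#' @param ktr_split Transit rate constant of the split-peak model, 1/h.
#' @param fraction_typical Fraction of the dose absorbed through the
#'   delayed Erlang path in the split-peak model, in (0, 1); the
#'   remainder takes the fast first-order path.
#' @param cv_cl,cv_v,cv_ka,cv_ktr Between-subject CVs (fractions).
#' @param sd_fraction_logit Between-subject SD of the absorbed fraction on
#'   the logit scale.
#' @param ruv_prop Proportional residual error SD (fraction).
#' @param n_transit Number of Erlang transit compartments (integer >= 1).
#' @return An object of class `population_parameters`.
#' @examples
#' pop <- population_parameters()
#' pop$cl_typical
#' @export
population_parameters <- function(cl_typical = 22.6,
                                  v_typical = 38.9,
                                  ka_typical = 3.3,
                                  ka_split = 7.6,
                                  ktr_erlang = 8.2,
                                  ktr_split = 5.2,
                                  fraction_typical = 0.78,
                                  cv_cl = 0.29,
                                  cv_v = 0.21,
                                  cv_ka = 0.48,
                                  cv_ktr = 0.23,
                                  sd_fraction_logit = 0.80,
                                  ruv_prop = 0.165,
                                  n_transit = 8L) {
  pos <- c(cl_typical = cl_typical, v_typical = v_typical,
           ka_typical = ka_typical, ka_split = ka_split,
           ktr_erlang = ktr_erlang, ktr_split = ktr_split)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("clearance, volume and all rate constants must be strictly positive")
  }
  if (!is.finite(fraction_typical) ||
      fraction_typical <= 0 || fraction_typical >= 1) {
    stop("fraction_typical must lie strictly inside (0, 1)")
  }
  cvs <- c(cv_cl, cv_v, cv_ka, cv_ktr, sd_fraction_logit, ruv_prop)
  if (any(!is.finite(cvs)) || any(cvs < 0)) {
    stop("variability magnitudes must be non-negative")
  }
  n_transit <- as.integer(n_transit)
  if (is.na(n_transit) || n_transit < 1L) {
    stop("n_transit must be an integer >= 1")
  }
  structure(
    list(cl_typical = cl_typical, v_typical = v_typical,
         ka_typical = ka_typical, ka_split = ka_split,
         ktr_erlang = ktr_erlang, ktr_split = ktr_split,
         fraction_typical = fraction_typical,
         cv_cl = cv_cl, cv_v = cv_v, cv_ka = cv_ka, cv_ktr = cv_ktr,
         sd_fraction_logit = sd_fraction_logit,
         ruv_prop = ruv_prop, n_transit = n_transit),
    class = "population_parameters")
}

#' Sampling design of a single-dose concentration-time study
#'
#' The default reproduces the rich early-absorption design of the source
#' study: 12 samples at 0 (predose), 0.25, 0.5, 0.75, 1, 1.25, 1.5, 2,
#' 2.5, 3, 4 and 6 h after a 10-mg oral dose in a standard 20-kg subject.
#'
#' @param sample_times Strictly increasing sample times in hours; the
#'   first element must be 0 (predose).
#' @param dose Dose in mg.
#' @param weight Body weight in kg.
#' @return An object of class `study_design`.
#' @examples
#' study_design()$sample_times
#' @export
study_design <- function(sample_times = c(0, 0.25, 0.5, 0.75, 1, 1.25,
                                          1.5, 2, 2.5, 3, 4, 6),
                         dose = 10, weight = 20) {
  if (length(sample_times) < 2 || any(!is.finite(sample_times))) {
    stop("sample_times must contain at least two finite values")
  }
  if (sample_times[1] != 0) stop("the first sample time must be 0 (predose)")
  if (any(diff(sample_times) <= 0)) {
    stop("sample_times must be strictly increasing")
  }
  if (!is.finite(dose) || dose <= 0) stop("dose must be positive")
  if (!is.finite(weight) || weight <= 0) stop("weight must be positive")
  structure(list(sample_times = as.numeric(sample_times),
                 dose = dose, weight = weight),
            class = "study_design")
}

#' Individual realized pharmacokinetic parameters
#'
#' One subject's parameter set after weight scaling and (optionally)
#' between-subject variability.  `ka` is the first-order absorption rate,
#' `ktr` the transit rate of the Erlang chain, and `fraction` the share of
#' the dose taking the delayed Erlang path in the split-peak model; sub-models
#' that do not use a parameter may leave it `NA`.
#'
#' @param cl Clearance, L/h.
#' @param v Volume of distribution, L.
#' @param ka First-order absorption rate constant, 1/h (or `NA`).
#' @param ktr Transit rate constant, 1/h (or `NA`).
#' @param fraction Share of the dose absorbed via the Erlang path in
#'   (0, 1) (or `NA`).
#' @param dose Dose, mg.
#' @param weight Body weight, kg.
#' @return An object of class `individual_parameters`.
#' @export
individual_parameters <- function(cl, v, ka = NA_real_, ktr = NA_real_,
                                  fraction = NA_real_, dose = 10,
                                  weight = 20) {
  chk <- c(cl = cl, v = v, dose = dose, weight = weight)
  if (any(!is.finite(chk)) || any(chk <= 0)) {
    stop("cl, v, dose and weight must be strictly positive")
  }
  for (nm in c("ka", "ktr")) {
    val <- get(nm)
    if (!is.na(val) && (!is.finite(val) || val <= 0)) {
      stop(sprintf("%s must be strictly positive when supplied", nm))
    }
  }
  if (!is.na(fraction) && (fraction <= 0 || fraction >= 1)) {
    stop("fraction must lie strictly inside (0, 1)")
  }
  structure(list(cl = cl, v = v, ka = ka, ktr = ktr, fraction = fraction,
                 dose = dose, weight = weight),
            class = "individual_parameters")
}

#' Allometric weight scaling of a typical parameter
#'
#' Scales a per-70-kg typical value to a subject's body weight with a
#' power law, `typical * (weight / 70)^exponent`.  The conventional
#' exponents are 0.75 for clearance-like and 1 for volume-like parameters.
#'
#' @param typical_value Typical value referenced to 70 kg.
#' @param weight Body weight in kg (> 0).
#' @param exponent Allometric exponent.
#' @return The weight-scaled parameter value.
#' @examples
#' allometric_scale(22.6, 20, 0.75)
#' @export
allometric_scale <- function(typical_value, weight, exponent) {
  if (!is.finite(weight) || weight <= 0) stop("weight must be positive")
  typical_value * (weight / 70)^exponent
}

#' Canonical absorption-shape labels
#'
#' The fixed label order used throughout: confusion-matrix rows/columns,
#' one-hot label columns, class-probability columns and argmax
#' tie-breaking.
#'
#' @return `c("first_order", "erlang", "split_peak")`.
#' @export
shape_levels <- function() c("first_order", "erlang", "split_peak")
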