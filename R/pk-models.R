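#' Closed-form concentration for first-order absorption
#'
#' One-compartment disposition with first-order input from a depot
#' compartment (bioavailable fraction fixed at 1):
#' \deqn{C(t) = \frac{D\,k_a}{V (k_a - k)} (e^{-kt} - e^{-k_a t}),
#'       \quad k = CL/V.}
#' When `ka` and `k` coincide the expression is replaced by its analytic
#' limit \eqn{(D/V)\, k\, t\, e^{-kt}}; the switch happens for
#' `|ka - k| < 1e-9 * k` to avoid catastrophic cancellation.
#'
#' @param p An [individual_parameters()] object with `cl`, `v`, `ka`.
#' @param t Time(s) after the dose, hours (>= 0); vectorized.
#' @return Concentration(s) in dose-amount units per litre.
#' @examples
#' p <- individual_parameters(cl = 8.84, v = 11.1, ka = 3.3)
#' conc_first_order(p, c(0, 0.5, 1, 6))
#' @export
conc_first_order <- function(p, t) {
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  if (is.na(p$ka)) stop("individual parameters lack ka")
  k <- p$cl / p$v
  ka <- p$ka
  if (abs(ka - k) < 1e-9 * k) {
    (p$dose / p$v) * k * t * exp(-k * t)
  } else {
    (p$dose * ka) / (p$v * (ka - k)) * (exp(-k * t) - exp(-ka * t))
  }
}

# Regularized lower incomplete gamma P(n, x) divided by x^n, i.e.
# P(n, x) / x^n, valid for any real x including x <= 0 where pgamma() is
# not defined.  Computed from the power series
#   gamma(n, x) = x^n * sum_j (-x)^j / ((n + j) j!),
# whose terms are all positive for x < 0 (no cancellation); for x >= 1 the
# standard pgamma() is accurate, so the series is only used for x < 1.
reg_inc_gamma_over_xn <- function(n, x) {
  out <- numeric(length(x))
  big <- x >= 1
  out[big] <- stats::pgamma(x[big], shape = n) / x[big]^n
  if (any(!big)) {
    xs <- x[!big]
    term <- rep(1, length(xs))          # (-x)^j / j!  at j = 0
    s <- term / n
    for (j in 1:60) {
      term <- term * (-xs) / j
      s <- s + term / (n + j)
      if (all(abs(term) < 1e-18 * abs(s) * (n + j))) break
    }
    out[!big] <- s / gamma(n)
  }
  out
}

#' Closed-form concentration for Erlang transit-chain absorption
#'
#' The dose traverses `n_transit` sequential compartments, each emptying
#' at first-order rate `ktr`, before reaching the central compartment with
#' elimination rate \eqn{k = CL/V}.  Arrival times therefore follow an
#' Erlang(`n_transit`, `ktr`) distribution and the central concentration
#' is the convolution of that density with a mono-exponential decay:
#' \deqn{C(t) = \frac{D\,k_{tr}^n\, t^n\, e^{-kt}}{V\,(n-1)!}
#'       \cdot \frac{\gamma(n, (k_{tr}-k)t)}{((k_{tr}-k)t)^n},}
#' evaluated through `pgamma()` for well-separated rates and through a
#' cancellation-safe power series of the lower incomplete gamma near (and
#' below) `ktr = k`.
#'
#' @param p An [individual_parameters()] object with `cl`, `v`, `ktr`.
#' @param t Time(s) after the dose, hours (>= 0); vectorized.
#' @param n_transit Number of transit compartments (integer >= 1).
#' @return Concentration(s).
#' @examples
#' p <- individual_parameters(cl = 8.84, v = 11.1, ktr = 8.2)
#' conc_erlang(p, c(0, 0.5, 1, 6), n_transit = 8)
#' @export
conc_erlang <- function(p, t, n_transit = 8L) {
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  n_transit <- as.integer(n_transit)
  if (is.na(n_transit) || n_transit < 1L) stop("n_transit must be >= 1")
  if (is.na(p$ktr)) stop("individual parameters lack ktr")
  k <- p$cl / p$v
  ktr <- p$ktr
  n <- n_transit
  x <- (ktr - k) * t
  # C = (D/V) ktr^n t^n e^{-kt} / (n-1)! * [P(n,x) Gamma(n) / x^n]
  (p$dose / p$v) * ktr^n * t^n * exp(-k * t) *
    reg_inc_gamma_over_xn(n, x)
}

#' Closed-form concentration for mixed (split-peak) absorption
#'
#' A fraction `f` of the dose is absorbed through the delayed Erlang
#' transit chain (rate `ktr`) and the remainder `1 - f` through the fast
#' first-order path (rate `ka`), both feeding the same one-compartment
#' disposition:
#' \deqn{C(t) = (1 - f)\, C_{fo}(t) + f\, C_{Erlang}(t).}
#' The fast path produces an early rise or first peak and the transit
#' chain the delayed main peak, giving the characteristic shoulder or
#' double-peak ("split-peak") profile.
#'
#' @param p An [individual_parameters()] object with `cl`, `v`, `ka`,
#'   `ktr` and `fraction`.
#' @param t Time(s) after the dose, hours (>= 0); vectorized.
#' @param n_transit Number of transit compartments for the Erlang path.
#' @return Concentration(s).
#' @examples
#' p <- individual_parameters(cl = 8.84, v = 11.1, ka = 7.6, ktr = 5.2,
#'                            fraction = 0.78)
#' conc_split_peak(p, c(0, 0.5, 1, 6))
#' @export
conc_split_peak <- function(p, t, n_transit = 8L) {
  if (is.na(p$fraction) || p$fraction <= 0 || p$fraction >= 1) {
    stop("fraction must lie strictly inside (0, 1)")
  }
  f <- p$fraction
  p_fo <- p
  p_fo$dose <- p$dose * (1 - f)
  p_er <- p
  p_er$dose <- p$dose * f
  conc_first_order(p_fo, t) + conc_erlang(p_er, t, n_transit)
}

#' Evaluate an absorption model by its shape label
#'
#' Dispatches to [conc_first_order()], [conc_erlang()] or
#' [conc_split_peak()].
#'
#' @param shape One of `"first_order"`, `"erlang"`, `"split_peak"`.
#' @param p An [individual_parameters()] object.
#' @param t Time(s), hours.
#' @param n_transit Transit compartments for the Erlang path.
#' @return Concentration(s).
#' @export
conc_profile <- function(shape, p, t, n_transit = 8L) {
  switch(match.arg(shape, shape_levels()),
         first_order = conc_first_order(p, t),
         erlang = conc_erlang(p, t, n_transit),
         split_peak = conc_split_peak(p, t, n_transit))
}

#' Numerical-integration oracle for the absorption models
#'
#' Integrates the linear compartmental ODE system corresponding to each
#' absorption shape (depot and/or transit chain plus central compartment)
#' from a bolus in the absorption site at `t = 0`, with tight tolerances
#' (`rtol = 1e-10`).  Serves as an independent reference for the closed
#' forms; it is deliberately structured as a generic ODE solve rather than
#' reusing any analytic shortcut.
#'
#' @param shape One of `"first_order"`, `"erlang"`, `"split_peak"`.
#' @param p An [individual_parameters()] object.
#' @param times Sorted non-negative output times, hours.
#' @param n_transit Transit compartments for the Erlang path.
#' @return Numeric vector of central-compartment concentrations at `times`.
#' @export
ode_oracle <- function(shape, p, times, n_transit = 8L) {
  shape <- match.arg(shape, shape_levels())
  if (is.unsorted(times) || any(times < 0)) {
    stop("times must be sorted and non-negative")
  }
  n_transit <- as.integer(n_transit)
  if (is.na(n_transit) || n_transit < 1L) stop("n_transit must be >= 1")
  k <- p$cl / p$v
  tout <- sort(unique(c(0, times)))
  state_and_deriv <- switch(
    shape,
    first_order = list(
      y0 = c(depot = p$dose, central = 0),
      deriv = function(t, y, parms) {
        list(c(-p$ka * y[1], p$ka * y[1] - k * y[2]))
      },
      central = 2L),
    erlang = list(
      y0 = c(p$dose, rep(0, n_transit)),
      deriv = function(t, y, parms) {
        nt <- n_transit
        d <- numeric(nt + 1)
        d[1] <- -p$ktr * y[1]
        if (nt > 1) {
          d[2:nt] <- p$ktr * (y[1:(nt - 1)] - y[2:nt])
        }
        d[nt + 1] <- p$ktr * y[nt] - k * y[nt + 1]
        list(d)
      },
      central = n_transit + 1L),
    split_peak = list(
      y0 = c((1 - p$fraction) * p$dose, p$fraction * p$dose,
             rep(0, n_transit - 1), 0),
      deriv = function(t, y, parms) {
        nt <- n_transit
        d <- numeric(nt + 2)
        d[1] <- -p$ka * y[1]
        d[2] <- -p$ktr * y[2]
        if (nt > 1) {
          d[3:(nt + 1)] <- p$ktr * (y[2:nt] - y[3:(nt + 1)])
        }
        d[nt + 2] <- p$ka * y[1] + p$ktr * y[nt + 1] - k * y[nt + 2]
        list(d)
      },
      central = n_transit + 2L))
  sol <- deSolve::lsoda(y = state_and_deriv$y0,
                        times = tout,
                        func = state_and_deriv$deriv,
                        parms = NULL,
                        rtol = 1e-10, atol = 1e-14)
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0) {
    stop("ODE oracle integration failed")
  }
  central <- sol[match(times, sol[, 1]), 1L + state_and_deriv$central]
  unname(central) / p$v
}
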