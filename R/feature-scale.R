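#' Min-max feature scaling of one concentration profile
#'
#' Standardizes a subject's concentrations onto \[0, 1\] while preserving
#' the shape of the profile:
#' \deqn{CS_i = \frac{C_i - C_{min}}{C_{max} - C_{min}}.}
#' Scaling is strictly per subject — no training-set statistics are ever
#' reused — so observed profiles are transformed identically to simulated
#' ones.  The transform is invariant to positive affine changes of the
#' concentration scale and preserves the rank order of the samples.
#'
#' @param conc Numeric vector of concentrations (one profile, >= 2
#'   values, no missing entries).
#' @return Numeric vector of the same length with min 0 and max 1.
#' @examples
#' feature_scale(c(0, 2, 4))
#' @export
feature_scale <- function(conc) {
  if (length(conc) < 2) stop("a profile needs at least two observations")
  if (any(!is.finite(conc))) {
    stop("incomplete profile: missing or non-finite concentrations")
  }
  rng <- range(conc)
  if (rng[1] == rng[2]) {
    stop("degenerate profile: all concentrations are equal, cannot scale")
  }
  (conc - rng[1]) / (rng[2] - rng[1])
}

#' Assemble the feature matrix and one-hot labels of a dataset
#'
#' Row `i` is [feature_scale()] applied to profile `i`, columns in time
#' order; labels are encoded as one-of-three indicator columns in the
#' canonical order (first_order, erlang, split_peak).
#'
#' @param ds A `pk_dataset`.
#' @return List with `x` (profiles x times feature matrix), `y` (one-hot
#'   label matrix, or `NULL` if the dataset is unlabeled) and `labels`
#'   (factor of shape labels).
#' @examples
#' ds <- simulate_dataset(n_per_shape = 3, seed = 7)
#' dim(assemble_features(ds)$x)
#' @export
assemble_features <- function(ds) {
  n <- nrow(ds$conc)
  x <- matrix(0, nrow = n, ncol = ncol(ds$conc))
  for (i in seq_len(n)) {
    xi <- tryCatch(feature_scale(ds$conc[i, ]),
                   error = function(e) {
                     stop(sprintf("profile '%s': %s",
                                  ds$id[i], conditionMessage(e)),
                          call. = FALSE)
                   })
    x[i, ] <- xi
  }
  y <- NULL
  if (!is.null(ds$shape) && !anyNA(ds$shape)) {
    y <- one_hot(ds$shape)
  }
  list(x = x, y = y, labels = ds$shape)
}

# one-of-three indicator matrix in canonical label order
one_hot <- function(labels) {
  labels <- factor(as.character(labels), levels = shape_levels())
  y <- matrix(0, nrow = length(labels), ncol = length(shape_levels()),
              dimnames = list(NULL, shape_levels()))
  y[cbind(seq_along(labels), as.integer(labels))] <- 1
  y
}
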