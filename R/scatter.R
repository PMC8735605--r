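#' Square-field collimator scatter factor model
#'
#' A two-coefficient power law for the in-air output ratio of square fields,
#' `Sc(FS) = n_E * FS^(k * mu_E)`, where `FS` is the square field side in cm
#' and `k` is a fixed exponent multiplier (default 0.63). When
#' `constrained = TRUE` the coefficient `n_E` is tied to
#' `10^(-k * mu_E)` so the model passes exactly through `Sc(10) = 1`, the
#' reference-field normalization.
#'
#' @param n_E Multiplicative coefficient, > 0. Ignored (recomputed) when
#'   `constrained = TRUE`.
#' @param mu_E Exponent-scale coefficient (pairs with `k` in the exponent).
#' @param k Fixed exponent multiplier, default 0.63.
#' @param constrained Force `Sc(10) = 1` exactly.
#' @return An object of class `sc_square_model`.
#' @examples
#' m <- sc_square_model(mu_E = 0.0515, constrained = TRUE)
#' sc_square_eval(m, 10)  # exactly 1
#' @export
sc_square_model <- function(n_E = NULL, mu_E, k = 0.63, constrained = FALSE) {
  stopifnot(is.numeric(mu_E), length(mu_E) == 1L, is.finite(mu_E),
            is.numeric(k), length(k) == 1L, is.finite(k))
  if (constrained) {
    n_E <- 10^(-k * mu_E)
  } else {
    if (is.null(n_E)) stop("'n_E' is required for an unconstrained model")
    stopifnot(is.numeric(n_E), length(n_E) == 1L, is.finite(n_E))
    if (n_E <= 0) stop("'n_E' must be > 0")
  }
  structure(list(n_E = as.numeric(n_E), mu_E = as.numeric(mu_E),
                 k = as.numeric(k), constrained = isTRUE(constrained)),
            class = "sc_square_model")
}

#' @export
print.sc_square_model <- function(x, ...) {
  cat(sprintf("Sc square-field power law: n_E = %.6g, mu_E = %.6g, k = %g%s\n",
              x$n_E, x$mu_E, x$k,
              if (x$constrained) " [constrained: Sc(10) = 1]" else ""))
  invisible(x)
}

#' Evaluate the square-field Sc power law
#'
#' @param model An [sc_square_model()].
#' @param FS Square field side(s) in cm, > 0. Vectorized.
#' @return Predicted Sc value(s).
#' @export
sc_square_eval <- function(model, FS) {
  stopifnot(inherits(model, "sc_square_model"), is.numeric(FS))
  if (any(FS <= 0)) stop("field size must be > 0")
  model$n_E * FS^(model$k * model$mu_E)
}

#' Measured square-field Sc table
#'
#' @param field_size Strictly increasing positive square field sides, cm.
#' @param sc Positive measured Sc values, same length.
#' @param energy,machine Optional labels.
#' @return An object of class `sc_table`.
#' @export
sc_table <- function(field_size, sc, energy = NA_character_,
                     machine = NA_character_) {
  field_size <- as.numeric(field_size)
  sc <- as.numeric(sc)
  if (length(field_size) != length(sc))
    stop("'field_size' and 'sc' must have the same length")
  if (any(field_size <= 0)) stop("field sizes must be > 0")
  if (any(diff(field_size) <= 0)) stop("field sizes must be strictly increasing")
  if (any(sc <= 0)) stop("Sc values must be > 0")
  structure(list(field_size = field_size, sc = sc,
                 metadata = list(energy = energy, machine = machine)),
            class = "sc_table")
}

#' @export
as.data.frame.sc_table <- function(x, ...) {
  data.frame(field_size_cm = x$field_size, sc = x$sc)
}

#' @export
print.sc_table <- function(x, ...) {
  cat(sprintf("Sc table (%s): %d field sizes, %g-%g cm\n",
              if (is.na(x$metadata$energy)) "unlabelled" else x$metadata$energy,
              length(x$field_size), min(x$field_size), max(x$field_size)))
  invisible(x)
}

#' Calibrate the square-field Sc power law to a measured table
#'
#' Least squares on relative deviations `(model - measured) / measured`.
#' The closed-form log-log regression `ln Sc ~ ln FS` supplies the starting
#' point; a deterministic quasi-Newton refinement follows. With
#' `constrained = TRUE` the substitution `n_E = 10^(-k mu_E)` reduces the
#' problem to a one-dimensional search over `mu_E`, and the fitted model
#' passes exactly through `Sc(10) = 1`.
#'
#' @param table An [sc_table()] with at least 3 rows (2 when constrained).
#' @param constrained Tie `n_E` to `mu_E` so that `Sc(10) = 1`.
#' @param k Fixed exponent multiplier, default 0.63.
#' @return A list with `model` (the fitted [sc_square_model()]),
#'   `deviations_pct` (per-row percent deviations) and `max_abs_dev_pct`.
#' @export
sc_square_fit <- function(table, constrained = FALSE, k = 0.63) {
  stopifnot(inherits(table, "sc_table"))
  fs <- table$field_size
  sc <- table$sc
  if (length(fs) < (if (constrained) 2L else 3L))
    stop("too few rows to calibrate the power law")
  # log-log initializer (exact for noiseless power-law data)
  co <- stats::coef(stats::lm(log(sc) ~ log(fs)))
  mu0 <- co[[2]] / k
  ctl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)
  if (constrained) {
    rf <- function(p) ((fs / 10)^(k * p[1]) - sc) / sc
    opt <- minpack.lm::nls.lm(par = mu0, fn = rf, control = ctl)
    model <- sc_square_model(mu_E = opt$par[1], k = k, constrained = TRUE)
  } else {
    rf <- function(p) (exp(p[1]) * fs^(k * p[2]) - sc) / sc
    opt <- minpack.lm::nls.lm(par = c(co[[1]], mu0), fn = rf, control = ctl)
    model <- sc_square_model(n_E = exp(opt$par[1]), mu_E = opt$par[2], k = k)
  }
  pred <- sc_square_eval(model, fs)
  dev <- 100 * (pred - sc) / sc
  list(model = model, deviations_pct = dev, max_abs_dev_pct = max(abs(dev)))
}

#' Asymmetric-jaw collimator scatter factor model
#'
#' A weighted geometric-mean power law for the in-air output ratio at an
#' asymmetric collimator setting:
#' `Sc = A * (upper^w_upper * lower^w_lower)^p`. The defaults
#' `A = 0.88, w_upper = 0.65, w_lower = 0.35, p = 0.06` weight the upper
#' jaw more heavily, reproducing the collimator exchange effect (swapping
#' the jaw settings changes Sc). Without the `w_upper + w_lower = 1`
#' constraint only the products `p * w_upper`, `p * w_lower` and `A` are
#' identifiable.
#'
#' @param A Positive scale factor, default 0.88.
#' @param w_upper,w_lower Jaw weights, defaults 0.65 / 0.35.
#' @param p Positive outer exponent, default 0.06.
#' @return An object of class `sc_jaw_model`.
#' @examples
#' sc_jaw_eval(sc_jaw_model(), 15, 10)  # larger than with jaws swapped
#' @export
sc_jaw_model <- function(A = 0.88, w_upper = 0.65, w_lower = 0.35, p = 0.06) {
  stopifnot(is.numeric(A), is.numeric(w_upper), is.numeric(w_lower),
            is.numeric(p), length(A) == 1L, length(w_upper) == 1L,
            length(w_lower) == 1L, length(p) == 1L)
  if (A <= 0) stop("'A' must be > 0")
  if (p <= 0) stop("'p' must be > 0")
  structure(list(A = as.numeric(A), w_upper = as.numeric(w_upper),
                 w_lower = as.numeric(w_lower), p = as.numeric(p)),
            class = "sc_jaw_model")
}

#' @export
print.sc_jaw_model <- function(x, ...) {
  cat(sprintf("Sc jaw model: A = %.6g, w_upper = %.6g, w_lower = %.6g, p = %.6g\n",
              x$A, x$w_upper, x$w_lower, x$p))
  invisible(x)
}

#' Evaluate the asymmetric-jaw Sc model
#'
#' @param model An [sc_jaw_model()].
#' @param upper,lower Jaw settings in cm, > 0. Vectorized (recycled).
#' @return Predicted Sc value(s).
#' @export
sc_jaw_eval <- function(model, upper, lower) {
  stopifnot(inherits(model, "sc_jaw_model"), is.numeric(upper), is.numeric(lower))
  if (any(upper <= 0) || any(lower <= 0)) stop("jaw settings must be > 0")
  model$A * (upper^model$w_upper * lower^model$w_lower)^model$p
}

#' Measured Sc matrix over upper/lower jaw settings
#'
#' @param upper,lower Strictly increasing positive jaw settings in cm
#'   (rows = upper jaw, columns = lower jaw).
#' @param values Matrix of positive Sc values, `length(upper)` rows by
#'   `length(lower)` columns.
#' @param energy,machine Optional labels.
#' @return An object of class `jaw_sc_matrix`.
#' @export
jaw_sc_matrix <- function(upper, lower, values, energy = NA_character_,
                          machine = NA_character_) {
  upper <- as.numeric(upper)
  lower <- as.numeric(lower)
  values <- as.matrix(values)
  if (any(upper <= 0) || any(lower <= 0)) stop("jaw settings must be > 0")
  if (any(diff(upper) <= 0) || any(diff(lower) <= 0))
    stop("jaw settings must be strictly increasing")
  if (nrow(values) != length(upper) || ncol(values) != length(lower))
    stop("matrix dimensions must match the jaw setting lists")
  if (any(values <= 0)) stop("Sc values must be > 0")
  dimnames(values) <- list(upper = format(upper), lower = format(lower))
  structure(list(upper = upper, lower = lower, values = values,
                 metadata = list(energy = energy, machine = machine)),
            class = "jaw_sc_matrix")
}

#' @export
print.jaw_sc_matrix <- function(x, ...) {
  cat(sprintf("Jaw Sc matrix (%s): %d upper x %d lower settings\n",
              if (is.na(x$metadata$energy)) "unlabelled" else x$metadata$energy,
              length(x$upper), length(x$lower)))
  print(x$values)
  invisible(x)
}

#' Calibrate the asymmetric-jaw Sc model to a measured matrix
#'
#' Least squares on relative deviations over all cells. The log-linear
#' reformulation `ln Sc = ln A + b_u ln U + b_l ln L` (with
#' `b_u = p w_upper`, `b_l = p w_lower`) supplies exact starting values;
#' a deterministic quasi-Newton refinement on the relative scale follows.
#' With `constrain_weights = TRUE` the weights are normalized to sum to 1,
#' which makes `p = b_u + b_l`; otherwise `p` is held at `p_fixed` and the
#' weights absorb the exponents (predictions are identical either way —
#' only the factorization differs).
#'
#' @param matrix A [jaw_sc_matrix()], at least 2 x 2 with variation in both
#'   jaw directions.
#' @param constrain_weights Normalize `w_upper + w_lower = 1` (default).
#' @param p_fixed Outer exponent used when `constrain_weights = FALSE`.
#' @return A list with `model` (fitted [sc_jaw_model()]), `residuals_pct`
#'   (per-cell percent deviations, same shape as the input) and
#'   `max_abs_residual_pct`.
#' @export
sc_jaw_fit <- function(matrix, constrain_weights = TRUE, p_fixed = 0.06) {
  stopifnot(inherits(matrix, "jaw_sc_matrix"))
  if (length(matrix$upper) < 2L || length(matrix$lower) < 2L)
    stop("identifiability error: need at least 2 distinct settings per jaw")
  U <- rep(matrix$upper, times = length(matrix$lower))
  L <- rep(matrix$lower, each = length(matrix$upper))
  y <- as.vector(matrix$values)
  # exact log-linear initializer
  co <- stats::coef(stats::lm(log(y) ~ log(U) + log(L)))
  rf <- function(pp) (exp(pp[1]) * U^pp[2] * L^pp[3] - y) / y
  opt <- minpack.lm::nls.lm(par = c(co[[1]], co[[2]], co[[3]]), fn = rf,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  lnA <- opt$par[1]; bu <- opt$par[2]; bl <- opt$par[3]
  if (constrain_weights) {
    p <- bu + bl
    if (p <= 0) stop("fitted exponents imply a non-positive outer exponent")
    model <- sc_jaw_model(A = exp(lnA), w_upper = bu / p, w_lower = bl / p, p = p)
  } else {
    model <- sc_jaw_model(A = exp(lnA), w_upper = bu / p_fixed,
                          w_lower = bl / p_fixed, p = p_fixed)
  }
  pred <- matrix$values
  for (i in seq_along(matrix$upper))
    pred[i, ] <- sc_jaw_eval(model, matrix$upper[i], matrix$lower)
  res <- 100 * (pred - matrix$values) / matrix$values
  list(model = model, residuals_pct = res, max_abs_residual_pct = max(abs(res)))
}

#' Collimator exchange effect
#'
#' The change in Sc when the upper and lower jaw settings are swapped:
#' `Sc(upper, lower) - Sc(lower, upper)`. Antisymmetric under the swap and
#' zero for square settings. For a measured [jaw_sc_matrix()] both cells
#' must exist exactly (no interpolation); for an [sc_jaw_model()] the model
#' is evaluated at both orderings.
#'
#' @param source A [jaw_sc_matrix()] or [sc_jaw_model()].
#' @param upper,lower Jaw settings in cm.
#' @return The signed Sc difference.
#' @examples
#' exchange_effect(sc_jaw_model(), 15, 10)  # > 0: upper jaw dominates
#' @export
exchange_effect <- function(source, upper, lower) {
  UseMethod("exchange_effect")
}

#' @export
exchange_effect.sc_jaw_model <- function(source, upper, lower) {
  sc_jaw_eval(source, upper, lower) - sc_jaw_eval(source, lower, upper)
}

#' @export
exchange_effect.jaw_sc_matrix <- function(source, upper, lower) {
  cell <- function(u, l) {
    i <- which(abs(source$upper - u) < 1e-9)
    j <- which(abs(source$lower - l) < 1e-9)
    if (length(i) != 1L || length(j) != 1L)
      stop(sprintf("no exact matrix cell for upper = %g, lower = %g (no interpolation)",
                   u, l))
    source$values[i, j]
  }
  cell(upper, lower) - cell(lower, upper)
}
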