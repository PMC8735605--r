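#' Configuration for buildup-tail curve fitting
#'
#' @param depth_window Length-2 numeric `[d_lo, d_hi]` in cm bounding the
#'   depths used by the objective, or `NULL` (default) for
#'   `[depth of the measured maximum, last depth]` — i.e. the buildup region
#'   is excluded by default, since the two-parameter model cannot follow it
#'   closely and would otherwise dominate the objective.
#' @param residual_scale `"relative"` (default; residuals divided by the
#'   measured value, appropriate when scan noise is roughly proportional to
#'   dose) or `"absolute"` (appropriate for additive noise on the percent
#'   scale).
#' @param init_grid_n Coarse grid of candidate `n` values scanned by the
#'   initializer in lieu of random restarts; keeps the fit deterministic.
#' @param bounds_n,bounds_mu,bounds_amplitude Box constraints for the
#'   optimizer.
#' @param max_iterations,tol Levenberg-Marquardt iteration cap and
#'   convergence tolerance.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(depth_window = NULL,
                       residual_scale = c("relative", "absolute"),
                       init_grid_n = c(0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10, 50),
                       bounds_n = c(1e-6, 1e4),
                       bounds_mu = c(0, 5),
                       bounds_amplitude = c(1e-12, Inf),
                       max_iterations = 200L,
                       tol = 1e-12) {
  residual_scale <- match.arg(residual_scale)
  if (!is.null(depth_window)) {
    stopifnot(is.numeric(depth_window), length(depth_window) == 2L)
    if (depth_window[1] >= depth_window[2])
      stop("depth_window must satisfy d_lo < d_hi")
  }
  if (length(init_grid_n) == 0L || any(init_grid_n <= 0))
    stop("init_grid_n must be a non-empty grid of positive values")
  structure(list(depth_window = depth_window, residual_scale = residual_scale,
                 init_grid_n = as.numeric(init_grid_n),
                 bounds_n = bounds_n, bounds_mu = bounds_mu,
                 bounds_amplitude = bounds_amplitude,
                 max_iterations = as.integer(max_iterations), tol = tol),
            class = "fit_config")
}

# Resolve the fitting window for a curve (default: from the measured maximum
# to the deepest point) and return the indices inside it.
window_indices <- function(curve, config) {
  win <- config$depth_window
  if (is.null(win)) {
    win <- c(curve$depths[which.max(curve$values)],
             curve$depths[length(curve$depths)])
  }
  which(curve$depths >= win[1] & curve$depths <= win[2])
}

residual_fun <- function(d, y, scale) {
  if (scale == "relative") {
    function(par) (par[3] * buildup(d, par[1]) * tail_factor(d, par[2]) - y) / y
  } else {
    function(par) par[3] * buildup(d, par[1]) * tail_factor(d, par[2]) - y
  }
}

#' Deterministic starting values for a buildup-tail fit
#'
#' A two-stage initializer: `mu0` is the negative log-slope of a
#' least-squares line through `(d, ln value)` over the deepest third of the
#' fitting window (floored at 1e-4/cm); then, for each candidate `n` on the
#' configured grid, the optimal amplitude has the closed form
#' `A = sum(y f) / sum(f^2)` with `f = buildup * tail`, and the grid point
#' with the smallest residual sum of squares wins.
#'
#' @param curve A [depth_dose_curve()].
#' @param config A [fit_config()].
#' @return A [beam_params()] object.
#' @export
init_params <- function(curve, config = fit_config()) {
  stopifnot(inherits(curve, "depth_dose_curve"), inherits(config, "fit_config"))
  idx <- window_indices(curve, config)
  if (length(idx) < 4L)
    stop("insufficient data: need at least 4 points inside the depth window")
  d <- curve$depths[idx]
  y <- curve$values[idx]
  # deepest third of the window for the tail slope
  lo <- d[1] + 2 / 3 * (d[length(d)] - d[1])
  tail_sel <- d >= lo
  if (sum(tail_sel) >= 2L && all(y[tail_sel] > 0)) {
    slope <- stats::coef(stats::lm(log(y[tail_sel]) ~ d[tail_sel]))[[2]]
    mu0 <- max(-slope, 1e-4)
  } else {
    mu0 <- 1e-4
  }
  mu0 <- min(mu0, config$bounds_mu[2])
  best <- NULL
  rf <- residual_fun(d, y, config$residual_scale)
  for (n0 in config$init_grid_n) {
    f <- buildup(d, n0) * tail_factor(d, mu0)
    A <- sum(y * f) / sum(f^2)
    if (!is.finite(A) || A <= 0) next
    rss <- sum(rf(c(n0, mu0, A))^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = c(n0, mu0, A), rss = rss)
  }
  if (is.null(best)) stop("initializer failed to find finite starting values")
  beam_params(best$par[1], best$par[2], best$par[3])
}

#' Fit the buildup-tail model to a measured depth-dose curve
#'
#' Minimizes the sum of squared residuals (relative or absolute, see
#' [fit_config()]) over `(n, mu, amplitude)` within box bounds by
#' Levenberg-Marquardt, starting from [init_params()]. The fit is
#' deterministic: no random restarts; a coarse grid over `n` in the
#' initializer stands in for global search. The returned comparison covers
#' every depth of the input curve — including depths outside the fitting
#' window — so buildup-region misfit remains visible in reports.
#'
#' Non-convergence is reported through `converged = FALSE` together with
#' the best parameters found; it never raises an error.
#'
#' @param curve A measured [depth_dose_curve()].
#' @param config A [fit_config()].
#' @return An object of class `pdd_fit`: a list with `params`
#'   ([beam_params()]), `comparison` (a [make_comparison()] table over all
#'   input depths), `max_abs_pct_error`, `rmse`, `converged`,
#'   `n_points_used`, and the initial/final objective values.
#' @examples
#' p <- beam_params(0.208, 0.0515, 1000)
#' curve <- evaluate_pdd(p, seq(0.5, 23, 0.5), normalization = "raw")
#' fit <- fit_pdd(curve, fit_config(depth_window = c(0.5, 23)))
#' fit$params
#' @export
fit_pdd <- function(curve, config = fit_config()) {
  stopifnot(inherits(curve, "depth_dose_curve"), inherits(config, "fit_config"))
  idx <- window_indices(curve, config)
  if (length(idx) == 0L)
    stop("insufficient data: the depth window excludes every point")
  start <- init_params(curve, config)
  d <- curve$depths[idx]
  y <- curve$values[idx]
  rf <- residual_fun(d, y, config$residual_scale)
  obj0 <- sum(rf(c(start$n, start$mu, start$amplitude))^2)
  lower <- c(config$bounds_n[1], config$bounds_mu[1], config$bounds_amplitude[1])
  upper <- c(config$bounds_n[2], config$bounds_mu[2], config$bounds_amplitude[2])
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(start$n, start$mu, start$amplitude),
                       lower = lower, upper = upper, fn = rf,
                       control = minpack.lm::nls.lm.control(
                         maxiter = config$max_iterations,
                         ftol = config$tol, ptol = config$tol)),
    error = function(e) NULL)
  if (is.null(fit)) {
    par <- c(start$n, start$mu, start$amplitude)
    converged <- FALSE
    obj1 <- obj0
  } else {
    par <- fit$par
    converged <- fit$info %in% 1:4
    obj1 <- sum(rf(par)^2)
    if (obj1 > obj0) {  # never return worse than the initializer
      par <- c(start$n, start$mu, start$amplitude)
      obj1 <- obj0
      converged <- FALSE
    }
  }
  params <- beam_params(par[1], par[2], par[3])
  modeled <- depth_dose_curve(curve$depths, pdd_raw(curve$depths, params),
                              energy = curve$metadata$energy,
                              field_size = curve$metadata$field_size,
                              source = "modeled")
  comparison <- make_comparison(curve, modeled)
  summ <- summarize_errors(comparison, depth_min = min(curve$depths))
  structure(list(params = params, comparison = comparison,
                 max_abs_pct_error = summ$max_abs_pct_error,
                 rmse = summ$rmse, converged = converged,
                 n_points_used = length(idx),
                 objective_initial = obj0, objective_final = obj1),
            class = "pdd_fit")
}

#' @export
print.pdd_fit <- function(x, ...) {
  cat(sprintf("Buildup-tail fit (%s, %d points): n = %.6g, mu = %.6g /cm, amplitude = %.6g\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_points_used, x$params$n, x$params$mu, x$params$amplitude))
  cat(sprintf("  max |error| = %.2f %%, RMSE = %.4g %% over all %d depths\n",
              x$max_abs_pct_error, x$rmse, nrow(x$comparison)))
  invisible(x)
}

# Round half away from zero, the convention used for displayed percent errors.
round_half_away <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Depth-wise measured/modeled comparison table
#'
#' Builds the standard commissioning comparison: one row per depth with the
#' measured and modeled dose and the percent error
#' `100 * (modeled - measured) / measured`. Errors are kept unrounded in the
#' `pct_error` column; display and report writers round half-away-from-zero
#' to 2 decimals.
#'
#' @param measured,modeled Two [depth_dose_curve()] objects on identical
#'   depth grids (no implicit interpolation; a grid mismatch is an error).
#' @return A `comparison_table`: a data frame with columns `depth_cm`,
#'   `measured`, `modeled`, `pct_error`.
#' @examples
#' m <- depth_dose_curve(c(1, 10), c(98.09, 65.94))
#' f <- depth_dose_curve(c(1, 10), c(97.12, 65.22), source = "modeled")
#' make_comparison(m, f)
#' @export
make_comparison <- function(measured, modeled) {
  stopifnot(inherits(measured, "depth_dose_curve"),
            inherits(modeled, "depth_dose_curve"))
  if (length(measured$depths) != length(modeled$depths) ||
      any(abs(measured$depths - modeled$depths) > 1e-9))
    stop("depth grids differ; comparison requires identical grids (no interpolation)")
  if (any(measured$values == 0))
    stop("measured values must be nonzero to form percent errors")
  tab <- data.frame(depth_cm = measured$depths,
                    measured = measured$values,
                    modeled = modeled$values,
                    pct_error = 100 * (modeled$values - measured$values) /
                      measured$values)
  class(tab) <- c("comparison_table", "data.frame")
  tab
}

#' @export
print.comparison_table <- function(x, ...) {
  out <- as.data.frame(x)
  out$pct_error <- sprintf("%.2f", round_half_away(out$pct_error, 2L))
  print(out, row.names = FALSE, ...)
  invisible(x)
}

#' Summary error statistics of a comparison table
#'
#' @param table A [make_comparison()] result.
#' @param depth_min Only rows with `depth_cm >= depth_min` enter the
#'   summary; use it to exclude the buildup region, where the model's
#'   errors are large by construction.
#' @return A list with `max_abs_pct_error` (maximum absolute percent error,
#'   computed from unrounded errors then rounded to 2 decimals), `rmse`
#'   (unrounded root-mean-square percent error) and `n` (rows used).
#' @export
summarize_errors <- function(table, depth_min = 0) {
  stopifnot(inherits(table, "comparison_table"))
  sel <- table$depth_cm >= depth_min
  if (!any(sel))
    stop("insufficient data: no rows at or beyond 'depth_min'")
  e <- table$pct_error[sel]
  list(max_abs_pct_error = round_half_away(max(abs(e)), 2L),
       rmse = sqrt(mean(e^2)),
       n = sum(sel))
}
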