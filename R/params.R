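#' Buildup-tail beam model parameters
#'
#' Bundle the parameter triple defining one buildup-tail depth-dose curve:
#' the beam-hardening parameter `n`, the effective linear attenuation
#' coefficient `mu`, and a positive `amplitude` that maps the raw model onto
#' the percent scale. Physically, larger `n` means a harder beam (less
#' surface dose, deeper dose maximum); larger `mu` means stronger
#' attenuation (a steeper tail).
#'
#' @param n Beam-hardening parameter; must be strictly positive (it guards
#'   the `d/(d^2 + n)` buildup term against a pole at the surface).
#' @param mu Attenuation parameter in 1/cm; must be non-negative. `mu = 0`
#'   is admitted as the no-attenuation limit.
#' @param amplitude Positive scale factor applied to the raw model; defaults
#'   to 1. Fits on percent-scale curves typically return amplitudes near
#'   `100 / pdd_raw(d_max)`.
#'
#' @return An object of class `beam_params`.
#'
#' @examples
#' p6 <- beam_params(n = 0.208, mu = 0.0515)
#' pdd_raw(10, p6)
#' d_max(p6)
#' @export
beam_params <- function(n, mu, amplitude = 1) {
  stopifnot(is.numeric(n), length(n) == 1L, is.finite(n),
            is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(amplitude), length(amplitude) == 1L, is.finite(amplitude))
  if (n <= 0) stop("'n' must be > 0 (n <= 0 allows a pole in the buildup term)")
  if (mu < 0) stop("'mu' must be >= 0")
  if (amplitude <= 0) stop("'amplitude' must be > 0")
  structure(list(n = as.numeric(n), mu = as.numeric(mu),
                 amplitude = as.numeric(amplitude)),
            class = "beam_params")
}

#' @export
print.beam_params <- function(x, ...) {
  cat(sprintf("Buildup-tail beam parameters: n = %g, mu = %g /cm, amplitude = %g\n",
              x$n, x$mu, x$amplitude))
  invisible(x)
}

#' Central-axis depth-dose curve
#'
#' A measured, modeled or synthetic central-axis depth-dose scan: a strictly
#' increasing depth grid (cm) with the dose at each depth on the percent
#' scale, plus beam metadata.
#'
#' @param depths Numeric vector of depths in cm, non-negative and strictly
#'   increasing, length at least 2.
#' @param values Numeric vector of dose values (percent) of the same length;
#'   strictly positive except possibly at depth 0.
#' @param energy Energy label, e.g. `"6 MV"`.
#' @param field_size Side of the square field in cm (optional).
#' @param ssd Source-to-surface distance in cm; default 100.
#' @param source One of `"measured"`, `"modeled"`, `"synthetic"`.
#'
#' @return An object of class `depth_dose_curve`.
#' @examples
#' depth_dose_curve(c(1.5, 10), c(100.08, 65.94), energy = "6 MV")
#' @export
depth_dose_curve <- function(depths, values, energy = NA_character_,
                             field_size = NA_real_, ssd = 100,
                             source = c("measured", "modeled", "synthetic")) {
  source <- match.arg(source)
  depths <- as.numeric(depths)
  values <- as.numeric(values)
  if (length(depths) < 2L) stop("a depth-dose curve needs at least 2 points")
  if (length(depths) != length(values))
    stop("'depths' and 'values' must have the same length")
  if (anyNA(depths) || anyNA(values)) stop("depths/values must not contain NA")
  if (any(depths < 0)) stop("depths must be >= 0")
  if (any(diff(depths) <= 0)) stop("depths must be strictly increasing")
  if (any(values[depths > 0] <= 0))
    stop("dose values must be > 0 (except possibly at depth 0)")
  structure(list(depths = depths, values = values,
                 metadata = list(energy = energy,
                                 field_size = as.numeric(field_size),
                                 ssd = as.numeric(ssd), source = source)),
            class = "depth_dose_curve")
}

#' @export
print.depth_dose_curve <- function(x, ...) {
  m <- x$metadata
  cat(sprintf("Depth-dose curve (%s%s): %d points, depth %.4g-%.4g cm, dose %.4g-%.4g %%\n",
              if (is.na(m$energy)) "unlabelled" else m$energy,
              sprintf(", %s", m$source), length(x$depths),
              min(x$depths), max(x$depths), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.depth_dose_curve <- function(x, ...) {
  data.frame(depth_cm = x$depths, pdd_percent = x$values)
}
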