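#' Configuration for synthetic scan generation
#'
#' Describes a ground-truth scan: true buildup-tail parameters, a regular
#' depth grid (default 0.1-23 cm in 0.1 cm steps, the grid of a typical
#' water-phantom scan), additive Gaussian noise on the percent scale
#' (default sd 0.2 %, the order of chamber-scan repeatability) and a
#' normalization mode.
#'
#' @param true_params A [beam_params()] object, the ground truth.
#' @param depth_start,depth_stop,depth_step Depth grid in cm; `depth_step`
#'   must be > 0.
#' @param noise_sd Standard deviation of additive Gaussian noise, in
#'   percentage points; 0 gives a noiseless curve.
#' @param seed Integer RNG seed; mandatory when `noise_sd > 0` so every
#'   synthetic curve is reproducible.
#' @param normalization Passed to [evaluate_pdd()]; default `"max100"`.
#' @return An object of class `synthetic_scan_config`.
#' @export
synthetic_scan_config <- function(true_params, depth_start = 0.1,
                                  depth_stop = 23, depth_step = 0.1,
                                  noise_sd = 0.2, seed = NULL,
                                  normalization = "max100") {
  stopifnot(inherits(true_params, "beam_params"))
  if (depth_step <= 0) stop("'depth_step' must be > 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (noise_sd > 0 && is.null(seed))
    stop("'seed' is mandatory when noise_sd > 0")
  structure(list(true_params = true_params, depth_start = depth_start,
                 depth_stop = depth_stop, depth_step = depth_step,
                 noise_sd = noise_sd, seed = seed,
                 normalization = normalization),
            class = "synthetic_scan_config")
}

#' Generate a synthetic depth-dose scan with known ground truth
#'
#' Evaluates the buildup-tail model on the configured grid and adds iid
#' Gaussian noise. With `noise_sd = 0` the output equals [evaluate_pdd()]
#' exactly; with a seed the output is fully reproducible.
#'
#' @param config A [synthetic_scan_config()].
#' @return A [depth_dose_curve()] tagged `source = "synthetic"`.
#' @examples
#' cfg <- synthetic_scan_config(beam_params(0.208, 0.0515), seed = 7)
#' scan <- gen_scan(cfg)
#' @export
gen_scan <- function(config) {
  stopifnot(inherits(config, "synthetic_scan_config"))
  depths <- seq(config$depth_start, config$depth_stop, by = config$depth_step)
  clean <- evaluate_pdd(config$true_params, depths,
                        normalization = config$normalization)
  values <- clean$values
  if (config$noise_sd > 0) {
    set.seed(config$seed)
    values <- values + stats::rnorm(length(values), 0, config$noise_sd)
  }
  depth_dose_curve(depths, values, source = "synthetic")
}

#' Generate a synthetic Sc table or jaw matrix with known ground truth
#'
#' Evaluates an Sc model at the requested settings and adds iid Gaussian
#' noise (on the Sc scale).
#'
#' @param model An [sc_square_model()] (for `gen_sc_table`) or an
#'   [sc_jaw_model()] (for `gen_jaw_matrix`).
#' @param sizes Positive square field sizes, strictly increasing.
#' @param noise_sd Gaussian noise sd on the Sc scale (default 0).
#' @param seed RNG seed, mandatory when `noise_sd > 0`.
#' @return An [sc_table()] / [jaw_sc_matrix()].
#' @export
gen_sc_table <- function(model, sizes, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(model, "sc_square_model"))
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (noise_sd > 0 && is.null(seed)) stop("'seed' is mandatory when noise_sd > 0")
  sc <- sc_square_eval(model, sizes)
  if (noise_sd > 0) {
    set.seed(seed)
    sc <- sc + stats::rnorm(length(sc), 0, noise_sd)
  }
  sc_table(sizes, sc)
}

#' @rdname gen_sc_table
#' @param upper,lower Jaw setting lists in cm for the matrix rows/columns.
#' @export
gen_jaw_matrix <- function(model, upper, lower, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(model, "sc_jaw_model"))
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (noise_sd > 0 && is.null(seed)) stop("'seed' is mandatory when noise_sd > 0")
  vals <- outer(upper, lower, function(u, l) sc_jaw_eval(model, u, l))
  if (noise_sd > 0) {
    set.seed(seed)
    vals <- vals + matrix(stats::rnorm(length(vals), 0, noise_sd),
                          nrow = length(upper))
  }
  jaw_sc_matrix(upper, lower, vals)
}
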