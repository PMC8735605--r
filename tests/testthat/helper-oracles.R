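# Independent oracles used across the suite. They recompute quantities by
# brute force (dense grids, direct arithmetic) and never call the code paths
# they check.

# Raw buildup-tail product, written out directly.
oracle_pdd <- function(d, n, mu) d / (d^2 + n) * exp(-mu * d)

# Depth of maximum by arg-max on a dense grid (default 1e-4 cm).
oracle_dmax <- function(n, mu, step = 1e-4) {
  g <- seq(step, 1.2 * sqrt(n) + step, by = step)
  g[which.max(oracle_pdd(g, n, mu))]
}

# Published per-energy (n, mu) parameter pairs.
table2_params <- list(
  "4MV"  = c(n = 0.17,  mu = 0.0605),
  "6MV"  = c(n = 0.208, mu = 0.0515),
  "10MV" = c(n = 0.495, mu = 0.0458),
  "18MV" = c(n = 1.2,   mu = 0.0422)
)

# Least-squares power-law fit on relative residuals by coarse-to-fine grid
# search over (log a, b) in sc = a * FS^b; independent of sc_square_fit's
# optimizer and parameterization.
oracle_power_fit <- function(fs, sc) {
  obj <- function(lna, b) sum(((exp(lna) * fs^b - sc) / sc)^2)
  co <- coef(lm(log(sc) ~ log(fs)))
  center <- c(co[[1]], co[[2]])
  width <- c(0.02, 0.02)
  for (level in 1:12) {
    grid <- expand.grid(
      lna = seq(center[1] - width[1], center[1] + width[1], length.out = 21),
      b = seq(center[2] - width[2], center[2] + width[2], length.out = 21))
    vals <- mapply(obj, grid$lna, grid$b)
    center <- as.numeric(grid[which.min(vals), ])
    width <- width / 3
  }
  pred <- exp(center[1]) * fs^center[2]
  list(a = exp(center[1]), b = center[2],
       dev_pct = 100 * (pred - sc) / sc)
}

# Coarse-to-fine grid search for the jaw model's identifiable parameters
# (ln A, p*w_upper, p*w_lower), minimizing relative residuals over all cells.
oracle_jaw_grid_fit <- function(upper, lower, values) {
  U <- rep(upper, times = length(lower))
  L <- rep(lower, each = length(upper))
  y <- as.vector(values)
  obj <- function(lnA, bu, bl) sum(((exp(lnA) * U^bu * L^bl - y) / y)^2)
  co <- coef(lm(log(y) ~ log(U) + log(L)))
  center <- c(co[[1]], co[[2]], co[[3]])
  width <- c(0.05, 0.05, 0.05)
  for (level in 1:16) {
    grid <- expand.grid(
      lnA = seq(center[1] - width[1], center[1] + width[1], length.out = 11),
      bu = seq(center[2] - width[2], center[2] + width[2], length.out = 11),
      bl = seq(center[3] - width[3], center[3] + width[3], length.out = 11))
    vals <- mapply(obj, grid$lnA, grid$bu, grid$bl)
    center <- as.numeric(grid[which.min(vals), ])
    width <- width / 3
  }
  pred <- matrix(exp(center[1]) * U^center[2] * L^center[3],
                 nrow = length(upper))
  list(lnA = center[1], bu = center[2], bl = center[3],
       residuals_pct = 100 * (pred - values) / values)
}

# Read the Table 1 fixture file directly (all printed columns, including the
# printed error columns, which load_fixture does not expose).
read_table1_printed <- function() {
  path <- system.file("extdata", "table1_pdd.csv", package = "buildtail")
  read.csv(path, comment.char = "#")
}
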