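#' @title Scan and scatter-factor file formats
#' @description
#' All files are plain CSV. Lines starting with `#` before the header are
#' metadata in `# key: value` form (keys: `energy`, `field_size_cm`,
#' `ssd_cm`, `source`, `machine`, `dialect`). Scan files carry the columns
#' `depth_cm,pdd_percent`; Sc tables carry `field_size_cm,sc`; jaw matrices
#' carry a header row of lower-jaw settings and a first column of upper-jaw
#' settings. The dialect is versioned via the `dialect` metadata key
#' (currently `scan-csv/1`, `sc-csv/1`, `jaw-csv/1`).
#' @name io_formats
NULL

parse_metadata <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  meta
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Read a depth-dose scan from CSV
#'
#' @param path Path to a scan file (see [io_formats]).
#' @return A [depth_dose_curve()] with metadata populated from the file.
#' @export
read_scan <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta <- parse_metadata(lines)
  body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(body_idx) < 2L) stop("parse error: empty data section in ", path)
  header <- strsplit(lines[body_idx[1]], ",")[[1]]
  di <- match("depth_cm", trimws(header))
  vi <- match("pdd_percent", trimws(header))
  if (is.na(di) || is.na(vi))
    stop("parse error: required columns depth_cm, pdd_percent missing in ", path)
  rows <- body_idx[-1]
  depths <- values <- numeric(length(rows))
  for (k in seq_along(rows)) {
    cells <- strsplit(lines[rows[k]], ",")[[1]]
    d <- num_or_na(cells[di]); v <- num_or_na(cells[vi])
    if (is.na(d) || is.na(v))
      stop(sprintf("parse error at line %d of %s: non-numeric cell", rows[k], path))
    if (v <= 0 && d > 0)
      stop(sprintf("parse error at line %d of %s: non-positive dose value", rows[k], path))
    depths[k] <- d; values[k] <- v
  }
  if (anyDuplicated(depths))
    stop(sprintf("parse error at line %d of %s: duplicate depth",
                 rows[which(duplicated(depths))[1]], path))
  if (any(diff(depths) < 0))
    stop(sprintf("parse error at line %d of %s: decreasing depth",
                 rows[which(diff(depths) < 0)[1] + 1L], path))
  src <- meta$source %||% "measured"
  depth_dose_curve(depths, values,
                   energy = meta$energy %||% NA_character_,
                   field_size = num_or_na(meta$field_size_cm %||% NA),
                   ssd = num_or_na(meta$ssd_cm %||% 100),
                   source = match.arg(src, c("measured", "modeled", "synthetic")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a depth-dose scan to CSV
#'
#' Values are written with 17 significant digits so a write/read round trip
#' is lossless at double precision.
#'
#' @param curve A [depth_dose_curve()].
#' @param path Output path.
#' @export
write_scan <- function(curve, path) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  m <- curve$metadata
  lines <- c("# dialect: scan-csv/1")
  if (!is.na(m$energy)) lines <- c(lines, paste0("# energy: ", m$energy))
  if (!is.na(m$field_size)) lines <- c(lines, sprintf("# field_size_cm: %g", m$field_size))
  if (!is.na(m$ssd)) lines <- c(lines, sprintf("# ssd_cm: %g", m$ssd))
  lines <- c(lines, paste0("# source: ", m$source), "depth_cm,pdd_percent",
             sprintf("%.17g,%.17g", curve$depths, curve$values))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a square-field Sc table (CSV)
#'
#' @param path File path.
#' @return `read_sc_table()` returns an [sc_table()].
#' @export
read_sc_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta <- parse_metadata(lines)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  tab <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (!all(c("field_size_cm", "sc") %in% names(tab)))
    stop("parse error: required columns field_size_cm, sc missing in ", path)
  sc_table(tab$field_size_cm, tab$sc,
           energy = meta$energy %||% NA_character_,
           machine = meta$machine %||% NA_character_)
}

#' @rdname read_sc_table
#' @param table An [sc_table()].
#' @export
write_sc_table <- function(table, path) {
  stopifnot(inherits(table, "sc_table"))
  m <- table$metadata
  lines <- "# dialect: sc-csv/1"
  if (!is.na(m$energy)) lines <- c(lines, paste0("# energy: ", m$energy))
  if (!is.na(m$machine)) lines <- c(lines, paste0("# machine: ", m$machine))
  lines <- c(lines, "field_size_cm,sc",
             sprintf("%.17g,%.17g", table$field_size, table$sc))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a jaw Sc matrix (CSV)
#'
#' The matrix layout mirrors the measured-table orientation: the header row
#' holds the lower-jaw settings (X, cm), the first column the upper-jaw
#' settings (Y, cm).
#'
#' @param path File path.
#' @return `read_jaw_matrix()` returns a [jaw_sc_matrix()].
#' @export
read_jaw_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta <- parse_metadata(lines)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) < 3L) stop("parse error: jaw matrix needs a header and >= 2 rows")
  header <- strsplit(body[1], ",")[[1]]
  lower <- num_or_na(header[-1])
  if (anyNA(lower)) stop("parse error: non-numeric lower-jaw setting in header of ", path)
  rows <- lapply(body[-1], function(ln) num_or_na(strsplit(ln, ",")[[1]]))
  if (any(vapply(rows, anyNA, logical(1))))
    stop("parse error: non-numeric cell in jaw matrix ", path)
  upper <- vapply(rows, `[`, numeric(1), 1L)
  vals <- do.call(rbind, lapply(rows, `[`, -1L))
  jaw_sc_matrix(upper, lower, vals,
                energy = meta$energy %||% NA_character_,
                machine = meta$machine %||% NA_character_)
}

#' @rdname read_jaw_matrix
#' @param matrix A [jaw_sc_matrix()].
#' @export
write_jaw_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "jaw_sc_matrix"))
  m <- matrix$metadata
  lines <- "# dialect: jaw-csv/1"
  if (!is.na(m$energy)) lines <- c(lines, paste0("# energy: ", m$energy))
  if (!is.na(m$machine)) lines <- c(lines, paste0("# machine: ", m$machine))
  lines <- c(lines,
             paste(c("upper_cm", sprintf("%g", matrix$lower)), collapse = ","))
  for (i in seq_along(matrix$upper)) {
    lines <- c(lines, paste(c(sprintf("%g", matrix$upper[i]),
                              sprintf("%.17g", matrix$values[i, ])),
                            collapse = ","))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a measured/modeled comparison report (TSV)
#'
#' One row per depth with the error printed to 2 decimals
#' (half-away-from-zero), followed by a footer line with the maximum
#' absolute error and the RMSE.
#'
#' @param table A [make_comparison()] result.
#' @param path Output path.
#' @export
write_report <- function(table, path) {
  stopifnot(inherits(table, "comparison_table"))
  summ <- summarize_errors(table, depth_min = min(table$depth_cm))
  lines <- c("depth_cm\tmeasured\tmodeled\terror_pct",
             sprintf("%g\t%g\t%g\t%.2f", table$depth_cm, table$measured,
                     table$modeled, round_half_away(table$pct_error, 2L)),
             sprintf("# max_abs_error_pct: %.2f\trmse_pct: %.4f",
                     summ$max_abs_pct_error, summ$rmse))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize fitted model coefficients to JSON
#'
#' @param x A [beam_params()], [sc_square_model()], [sc_jaw_model()] or
#'   `pdd_fit` object.
#' @param path Output path.
#' @export
write_model_json <- function(x, path) {
  obj <- if (inherits(x, "pdd_fit")) {
    list(schema = "buildtail-fit/1",
         params = list(n = x$params$n, mu = x$params$mu,
                       amplitude = x$params$amplitude),
         max_abs_pct_error = x$max_abs_pct_error, rmse = x$rmse,
         converged = x$converged, n_points_used = x$n_points_used)
  } else if (inherits(x, "beam_params")) {
    list(schema = "buildtail-params/1", n = x$n, mu = x$mu,
         amplitude = x$amplitude)
  } else if (inherits(x, "sc_square_model")) {
    list(schema = "buildtail-sc-square/1", n_E = x$n_E, mu_E = x$mu_E,
         k = x$k, constrained = x$constrained)
  } else if (inherits(x, "sc_jaw_model")) {
    list(schema = "buildtail-sc-jaw/1", A = x$A, w_upper = x$w_upper,
         w_lower = x$w_lower, p = x$p)
  } else stop("unsupported object for JSON serialization")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "buildtail", mustWork = TRUE)
}

fixture_names <- function() {
  energies <- c("4MV", "6MV", "10MV", "18MV")
  c(paste0("table1_", rep(energies, each = 2), "_",
           c("measured", "modeled")),
    "table2", "table3_6MV", "table3_10MV", "table4")
}

#' Load a packaged reference fixture
#'
#' The package ships the published commissioning tables it models against:
#' `table1_<energy>_<measured|modeled>` — the depth-dose comparison scans
#' (46 depths, 0.1-23 cm, energies 4/6/10/18 MV, 10 x 10 cm field);
#' `table2` — the fitted `(n, mu)` pairs per energy, returned as a named
#' list of [beam_params()]; `table3_<energy>` — measured square-field Sc
#' tables (19 field sizes, 4-40 cm, 6 and 10 MV); `table4` — the measured
#' 8 x 8 Sc matrix over upper/lower jaw settings (6 MV).
#'
#' @param name One of the names above.
#' @return A [depth_dose_curve()], named list of [beam_params()],
#'   [sc_table()] or [jaw_sc_matrix()].
#' @examples
#' load_fixture("table2")$`6MV`
#' load_fixture("table3_10MV")
#' @export
load_fixture <- function(name) {
  valid <- fixture_names()
  if (!name %in% valid)
    stop("unknown fixture '", name, "'; valid names: ",
         paste(valid, collapse = ", "))
  if (grepl("^table1_", name)) {
    parts <- strsplit(name, "_")[[1]]
    energy <- parts[2]; which_col <- parts[3]
    tab <- utils::read.csv(fixture_path("table1_pdd.csv"), comment.char = "#")
    col <- paste0(if (which_col == "measured") "meas_" else "model_", energy)
    return(depth_dose_curve(tab$depth_cm, tab[[col]],
                            energy = sub("MV", " MV", energy),
                            field_size = 10,
                            source = if (which_col == "measured") "measured" else "modeled"))
  }
  if (name == "table2") {
    tab <- utils::read.csv(fixture_path("table2_params.csv"), comment.char = "#")
    out <- lapply(seq_len(nrow(tab)),
                  function(i) beam_params(tab$n[i], tab$mu[i]))
    names(out) <- tab$energy
    return(out)
  }
  if (grepl("^table3_", name)) {
    energy <- sub("table3_", "", name)
    tab <- utils::read.csv(fixture_path("table3_sc_square.csv"), comment.char = "#")
    return(sc_table(tab$field_size_cm, tab[[paste0("sc_meas_", energy)]],
                    energy = sub("MV", " MV", energy), machine = "Varian"))
  }
  # table4
  mtx <- read_jaw_matrix(fixture_path("table4_jaw_sc.csv"))
  mtx
}
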