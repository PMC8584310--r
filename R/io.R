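#' Read a release curve from CSV
#'
#' Expects a header with columns `time_min` and `release`. Metadata may be
#' supplied in comment lines of the form `# value_kind: fraction` and
#' `# c_inf: 1.0` before the header.
#'
#' @param path CSV file path.
#' @return A [release_curve()].
#' @export
read_release_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(\\S+)", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  df <- utils::read.csv(text = paste(grep("^#", lines, invert = TRUE,
                                          value = TRUE), collapse = "\n"))
  if (!all(c("time_min", "release") %in% names(df))) {
    stop("CSV must have columns time_min and release", call. = FALSE)
  }
  value_kind <- if (!is.null(meta$value_kind)) meta$value_kind else "fraction"
  c_inf <- if (!is.null(meta$c_inf)) as.numeric(meta$c_inf) else NULL
  release_curve(df$time_min, df$release, value_kind = value_kind, c_inf = c_inf)
}

#' Write a release curve to CSV
#'
#' @param curve A [release_curve()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_release_csv <- function(curve, path) {
  stopifnot(inherits(curve, "release_curve"))
  header <- c(sprintf("# value_kind: %s", curve$value_kind),
              if (!is.null(curve$c_inf)) sprintf("# c_inf: %.10g", curve$c_inf))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(data.frame(time_min = curve$times, release = curve$values),
                   con, row.names = FALSE)
  invisible(path)
}

#' Fit all kinetic models to a CSV curve and write a JSON report
#'
#' The full kinetics pipeline: read the curve, fit the requested models,
#' rank them by R^2, classify the mechanism from the best power-law and
#' Weibull fits, and write a machine-readable JSON report.
#'
#' @param input_csv Release-curve CSV (see [read_release_csv()]).
#' @param output_json Report path; `NULL` to skip writing.
#' @param models Model subset (default all seven).
#' @param scale `"natural"` or `"linearized"`.
#' @return Invisibly, the report list (`fits`, `ranking`, `mechanism`).
#' @export
run_fit_kinetics <- function(input_csv, output_json = NULL,
                             models = kinetic_model_names(),
                             scale = "natural") {
  curve <- read_release_csv(input_csv)
  fits <- fit_all(curve, models = models, scale = scale)
  if (!any(vapply(fits, `[[`, logical(1), "converged"))) {
    stop("all model fits failed", call. = FALSE)
  }
  mech <- mechanism_calls(fits)
  report <- list(
    input = basename(input_csv),
    n_points = length(curve$times),
    value_kind = curve$value_kind,
    fit_scale = scale,
    fits = lapply(fits, function(f) list(
      model = f$model,
      parameters = as.list(f$estimates),
      r_squared = f$r_squared,
      converged = f$converged,
      fit_scale = f$fit_scale
    )),
    ranking = vapply(fits, `[[`, character(1), "model"),
    mechanism = list(
      power_law = if (!is.null(mech$power_law)) list(
        n = mech$power_law$statistic_value, label = mech$power_law$label),
      weibull = if (!is.null(mech$weibull)) list(
        b = mech$weibull$statistic_value, label = mech$weibull$label)
    )
  )
  if (!is.null(output_json)) {
    jsonlite::write_json(report, output_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(report)
}

#' Analyse configuration snapshot(s) and write a per-frame CSV
#'
#' Reads one or more coordinate files (frames), computes the adsorption
#' summary of each, and writes a CSV time series with columns `frame`,
#' `n_aggregates`, `mean_size`, `pct_adsorbed`, `pct_inside`. Analysis
#' parameters are echoed as `#` comment lines so every run is
#' self-describing.
#'
#' @param paths Coordinate file paths, one frame each.
#' @param output_csv Output path; `NULL` to skip writing.
#' @param format,... Passed to [read_configuration()].
#' @param cutoff Contact cutoff (nm).
#' @param tube A [nanotube_model()] for the ring-method count, or `NULL`.
#' @param sphere_radius_mode `"half_diameter"` uses half the innermost tube
#'   diameter (so "inside" means the lumen); `"printed"` uses the full
#'   diameter, which also captures molecules on the outer wall.
#' @return Invisibly, the per-frame data.frame.
#' @export
run_analyze_config <- function(paths, output_csv = NULL,
                               format = "auto", cutoff = 0.35, tube = NULL,
                               sphere_radius_mode = c("half_diameter",
                                                      "printed"), ...) {
  sphere_radius_mode <- match.arg(sphere_radius_mode)
  rows <- lapply(seq_along(paths), function(i) {
    config <- read_configuration(paths[i], format = format, ...)
    sr <- if (is.null(tube)) NULL
          else if (sphere_radius_mode == "half_diameter") min(tube$diameter) / 2
          else min(tube$diameter)
    s <- summarize_adsorption(config, cutoff = cutoff, tube = tube,
                              sphere_radius = sr)
    data.frame(frame = i, n_aggregates = s$n_aggregates,
               mean_size = s$mean_aggregate_size,
               pct_adsorbed = s$pct_adsorbed, pct_inside = s$pct_inside)
  })
  out <- do.call(rbind, rows)
  if (!is.null(output_csv)) {
    con <- file(output_csv, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# cutoff_nm: %g", cutoff),
                 sprintf("# sphere_radius_mode: %s", sphere_radius_mode),
                 sprintf("# frames: %d", length(paths))), con)
    utils::write.csv(out, con, row.names = FALSE)
  }
  invisible(out)
}

#' Simulate a release curve and write it to CSV
#'
#' Thin wrapper around [generate_release_curve()] plus [write_release_csv()].
#'
#' @inheritParams generate_release_curve
#' @param output_csv Output path; `NULL` to skip writing.
#' @return Invisibly, the generator result.
#' @export
simulate_release <- function(model, params, output_csv = NULL,
                             times = c(1, 3, 5, 10, 20, 30), noise_sd = 0,
                             seed = NULL) {
  gen <- generate_release_curve(model, params, times = times,
                                noise_sd = noise_sd, seed = seed)
  if (!is.null(output_csv)) write_release_csv(gen$curve, output_csv)
  invisible(gen)
}

#' Simulate a boxed configuration and write coordinates plus truth
#'
#' Wrapper around [generate_configuration()] writing the configuration
#' (XYZ or GRO) and the ground-truth record as JSON.
#'
#' @inheritParams generate_configuration
#' @param output Coordinate file path; `NULL` to skip writing. Format from
#'   the extension (`.gro` or `.xyz`).
#' @param truth_json Truth-record path (default `<output>.truth.json`).
#' @param ... Passed to [generate_configuration()].
#' @return Invisibly, the generator result.
#' @export
simulate_config <- function(output = NULL,
                            truth_json = if (is.null(output)) NULL
                                         else paste0(output, ".truth.json"),
                            ...) {
  gen <- generate_configuration(...)
  if (!is.null(output)) {
    if (grepl("\\.gro$", output, ignore.case = TRUE)) {
      write_gro(gen$config, output)
    } else {
      write_xyz(gen$config, output)
    }
  }
  if (!is.null(truth_json)) {
    jsonlite::write_json(gen$truth[c("labels", "n_aggregates", "mean_size",
                                     "pct_adsorbed", "pct_inside")],
                         truth_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(gen)
}
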