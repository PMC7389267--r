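#' Run one pipeline subcommand
#'
#' Programmatic entry point wiring the analysis modules end to end.  Each
#' subcommand reads plain-text inputs, runs the corresponding module and
#' writes its artifacts; every JSON report echoes the full configuration and
#' seed for provenance (no timestamps, so identical configuration and seed
#' give byte-identical reports).  A thin command-line wrapper around this
#' function ships in `inst/cli/afmdfs-cli.R`.
#'
#' Subcommands and their configuration entries:
#' \describe{
#'   \item{simulate}{`what` in `"dfs"`, `"curve"`, `"map"`, `"contact"`;
#'     `seed` (mandatory); `params` passed to the matching generator;
#'     `out` output path (TSV; `"map"` treats `out` as a directory).}
#'   \item{detect-events}{`curves`: character vector of curve files (or
#'     `index` CSV + `dir`); optional `events` config list for
#'     [event_config()]; `out`: events TSV.}
#'   \item{fit-gauss}{`events`: events TSV; optional `bin_width`; `out`:
#'     JSON report.}
#'   \item{fit-kinetics}{`input`: TSV with `contact_time_s`, `n_curves`,
#'     `n_adhesive`; optional `method`; `out`: JSON report.}
#'   \item{fit-dfs}{`events`: events TSV (or bare TSV with
#'     `loading_rate_pN_per_s`, `rupture_force_pN`); optional `binned`,
#'     `n_bins`, `k_c`, `temperature`; `out`: JSON report.}
#'   \item{render-map}{`events`: events TSV; `index`: grid index CSV;
#'     `out`: basename for `<out>.csv` / `<out>.pgm`.}
#' }
#'
#' @param name Subcommand name.
#' @param config Named list (or path to a JSON file) with the entries above.
#' @return Invisibly, a list of output paths and key results.
#' @export
run_subcommand <- function(name = c("simulate", "detect-events", "fit-gauss",
                                    "fit-kinetics", "fit-dfs", "render-map"),
                           config) {
  name <- match.arg(name)
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  switch(name,
         "simulate" = cmd_simulate(config),
         "detect-events" = cmd_detect_events(config),
         "fit-gauss" = cmd_fit_gauss(config),
         "fit-kinetics" = cmd_fit_kinetics(config),
         "fit-dfs" = cmd_fit_dfs(config),
         "render-map" = cmd_render_map(config))
}

report_header <- function(config) {
  list(package = "afmdfs",
       version = as.character(utils::packageVersion("afmdfs")),
       config = config)
}

write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

cmd_simulate <- function(config) {
  what <- config$what %||% "dfs"
  if (is.null(config$seed)) stop("--seed is mandatory for simulate")
  params <- config$params %||% list()
  out <- config$out %||% stop("simulate requires an output path 'out'")
  if (what == "dfs") {
    d <- do.call(sample_rupture_forces, c(params, list(seed = config$seed)))
    readr::write_tsv(d, out, progress = FALSE)
    jsonlite::write_json(attr(d, "ground_truth"), paste0(out, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (what == "curve") {
    do.call(synthesize_curve,
            c(params, list(seed = config$seed, path = out)))
  } else if (what == "map") {
    do.call(synthesize_map, c(params, list(seed = config$seed, dir = out)))
  } else if (what == "contact") {
    d <- do.call(synthesize_contact_series, c(params, list(seed = config$seed)))
    readr::write_tsv(d, out, progress = FALSE)
    jsonlite::write_json(attr(d, "ground_truth"), paste0(out, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    stop("unknown simulate target '", what, "'")
  }
  invisible(list(out = out))
}

cmd_detect_events <- function(config) {
  paths <- config$curves
  if (is.null(paths) && !is.null(config$index)) {
    idx <- read_grid_index(config$index)
    paths <- file.path(config$dir %||% dirname(config$index), idx$curve_path)
  }
  if (is.null(paths) || length(paths) == 0) stop("no input curves")
  cfg <- do.call(event_config, config$events %||% list())
  events <- purrr::map(paths, function(p) {
    detect_events(correct_baseline(read_curve(p)), config = cfg)
  })
  combined <- bind_rows(events)
  out <- config$out %||% stop("detect-events requires an output path 'out'")
  readr::write_tsv(combined, out, progress = FALSE)
  freq <- adhesion_frequency(events)
  invisible(list(out = out, n_curves = length(paths), frequency = freq))
}

cmd_fit_gauss <- function(config) {
  events <- readr::read_tsv(config$events, show_col_types = FALSE, progress = FALSE)
  fit <- fit_gaussian_histogram(events$rupture_force_pN,
                                bin_width = config$bin_width %||% 10)
  report <- c(report_header(config),
              list(n_events = fit$n_events, fit_ok = fit$fit_ok,
                   mu_pN = fit$mu, sigma_pN = fit$sigma,
                   histogram = fit$histogram))
  out <- config$out %||% stop("fit-gauss requires an output path 'out'")
  write_report(report, out)
  invisible(list(out = out, fit = fit))
}

cmd_fit_kinetics <- function(config) {
  d <- readr::read_tsv(config$input, show_col_types = FALSE, progress = FALSE)
  fit <- fit_hyperbolic(d$contact_time_s, d$n_adhesive / d$n_curves,
                        method = config$method %||% "double_reciprocal")
  report <- c(report_header(config),
              list(f_max = fit$f_max, k_half_s = fit$k_half,
                   method = fit$method, valid = fit$valid,
                   cross_check = fit$fits))
  out <- config$out %||% stop("fit-kinetics requires an output path 'out'")
  write_report(report, out)
  invisible(list(out = out, fit = fit))
}

cmd_fit_dfs <- function(config) {
  d <- readr::read_tsv(config$events, show_col_types = FALSE, progress = FALSE)
  if (!is.null(d$is_specific)) d <- d[d$is_specific, , drop = FALSE]
  if (length(unique(d$loading_rate_pN_per_s)) < 2) {
    stop("cannot fit a force spectrum with fewer than 2 distinct loading rates")
  }
  fit <- fit_fndy(d, binned = isTRUE(config$binned),
                  n_bins = config$n_bins %||% 8,
                  k_c = config$k_c, temperature = config$temperature %||% 293.15)
  const <- afm_constants()
  report <- c(report_header(config), list(
    model = "F(r) = f_eq + f_beta * ln(1 + exp(-gamma) * r / (k_off * f_beta))",
    derived_equations = c("x_t = k_B*T / f_beta", "|delta_G| = f_eq^2 / (2*k_c)",
                          "tau0 = 1 / k_off"),
    parameters = tidy(fit),
    parameters_si = list(f_eq_N = fit$estimates[["f_eq"]] * 1e-12,
                         f_beta_N = fit$estimates[["f_beta"]] * 1e-12,
                         k_off_per_s = fit$estimates[["k_off"]]),
    derived = fit$derived,
    derived_si = list(x_t_m = fit$derived$x_t_A * 1e-10,
                      delta_G_J = fit$derived$delta_G_pN_nm * 1e-21,
                      tau0_s = fit$derived$tau0_ms / 1000),
    diagnostics = glance(fit),
    temperature_K = fit$temperature,
    k_c_pN_per_nm = fit$k_c,
    constants = const))
  out <- config$out %||% stop("fit-dfs requires an output path 'out'")
  write_report(report, out)
  invisible(list(out = out, fit = fit))
}

cmd_render_map <- function(config) {
  events <- readr::read_tsv(config$events, show_col_types = FALSE, progress = FALSE)
  grid <- read_grid_index(config$index)
  map <- render_adhesion_map(events, grid)
  out <- config$out %||% stop("render-map requires an output path 'out'")
  write_map_csv(map, paste0(out, ".csv"))
  write_map_pgm(map, paste0(out, ".pgm"))
  invisible(list(out = out, map = map,
                 frequency = attr(map, "frequency")))
}
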