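# Default loading-rate ladder: 12 log-spaced rates spanning the
# experimentally accessible window 100-20,000 pN/s.
default_loading_rates <- function(n = 12, range = c(100, 20000)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' Simulate rupture forces under a linear force ramp
#'
#' Draws rupture forces from the first-passage law of a bond whose escape
#' rate grows exponentially above the equilibrium force (Bell-type kinetics
#' referenced to \eqn{f_{eq}}), with the near-equilibrium regime represented
#' as a hard floor at \eqn{f_{eq}} (rebinding below it treated as
#' instantaneous).  Under a force ramp at loading rate `r` the survival
#' probability is
#' \deqn{S(F) = \exp\!\big(-(f_\beta k_{off}/r)\,(e^{(F-f_{eq})/f_\beta} - 1)\big),
#'   \quad F \ge f_{eq},}
#' sampled exactly by inversion:
#' \eqn{F = f_{eq} + f_\beta \ln(1 + r E / (f_\beta k_{off}))} with
#' \eqn{E \sim} Exp(1).  The exact mean of this law is
#' \eqn{f_{eq} + f_\beta e^{b} E_1(b)} with \eqn{b = f_\beta k_{off}/r}
#' (exponential integral \eqn{E_1}), which the interpolation formula of
#' [fndy_mean_force()] approaches in both the near-equilibrium and the deep
#' kinetic limit.
#'
#' @param f_eq Equilibrium force, pN.
#' @param f_beta Thermal force, pN.
#' @param k_off Dissociation rate at \eqn{f_{eq}}, 1/s.
#' @param loading_rates Loading rates, pN/s.  Default 12 log-spaced values in
#'   \[100, 20000\].
#' @param n_per_rate Ruptures drawn per loading rate.
#' @param seed Mandatory RNG seed (the generators never touch global RNG
#'   state).
#' @return Tibble with columns `loading_rate_pN_per_s`, `rupture_force_pN`
#'   and a `ground_truth` attribute recording the generating parameters.
#' @examples
#' d <- sample_rupture_forces(36.2, 67.46, 732.4, n_per_rate = 50, seed = 1)
#' @export
sample_rupture_forces <- function(f_eq, f_beta, k_off,
                                  loading_rates = default_loading_rates(),
                                  n_per_rate = 167, seed) {
  if (missing(seed)) stop("seed is mandatory for stochastic generators")
  if (any(c(f_eq, f_beta, k_off) <= 0)) {
    stop("f_eq, f_beta and k_off must be positive")
  }
  if (any(loading_rates <= 0)) stop("loading rates must be positive")
  out <- withr::with_seed(seed, {
    purrr::map_dfr(loading_rates, function(r) {
      e <- stats::rexp(n_per_rate)
      tibble(loading_rate_pN_per_s = r,
             rupture_force_pN = f_eq + f_beta * log1p(r * e / (f_beta * k_off)))
    })
  })
  attr(out, "ground_truth") <- list(f_eq = f_eq, f_beta = f_beta, k_off = k_off,
                                    n_per_rate = n_per_rate, seed = seed)
  out
}

#' Synthesize a force-distance curve with known embedded events
#'
#' Builds an idealised approach/retract cycle: the approach runs from far
#' field down to the force setpoint through a linear contact ramp at the
#' cantilever spring constant; the retract runs back out and, for every
#' embedded event, a linear tether-loading dip (constant effective tether
#' stiffness) pulls the force down to \eqn{-f} at the stated rupture
#' distance, followed by instantaneous release.  Seeded Gaussian noise is
#' added to the force channel.  The requested events are attached as a
#' ground-truth attribute (and written as a JSON sidecar when the curve is
#' saved to `path`).
#'
#' @param events Tibble/data.frame with columns `distance_nm`, `force_pN`
#'   (event magnitudes, pN > 0), or `NULL` for an event-free curve.
#' @param noise_sigma Gaussian force noise SD, pN.  Default 5.
#' @param sampling_rate Samples per second.  Default 2048.
#' @param retract_speed Retraction speed, um/s (typical instruments: 1-6).
#' @param setpoint Contact force setpoint, pN.  Default 500.
#' @param spring_constant Cantilever spring constant, pN/nm.  Default 10.
#' @param tether_stiffness Effective tether loading stiffness, pN/nm.
#'   Default 2.
#' @param z_range Retract travel, nm.  Default 600.
#' @param curve_id Curve identifier.
#' @param seed Mandatory RNG seed.
#' @param path Optional file path: the curve is written with [write_curve()]
#'   and the ground truth as `<path>.truth.json`.
#' @return A [force_curve()] with attribute `ground_truth`.
#' @export
synthesize_curve <- function(events = NULL, noise_sigma = 5,
                             sampling_rate = 2048, retract_speed = 1,
                             setpoint = 500, spring_constant = 10,
                             tether_stiffness = 2, z_range = 600,
                             curve_id = "sim", seed, path = NULL) {
  if (missing(seed)) stop("seed is mandatory for stochastic generators")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (is.null(events)) {
    events <- tibble(distance_nm = double(), force_pN = double())
  }
  events <- as_tibble(events)
  if (nrow(events) > 0) {
    stopifnot(all(c("distance_nm", "force_pN") %in% names(events)))
    if (any(events$force_pN > 10 * setpoint)) {
      stop("embedded event force exceeds 10x the setpoint")
    }
    if (any(events$force_pN <= 0)) stop("event forces must be positive")
    if (any(events$distance_nm <= 0 | events$distance_nm >= z_range)) {
      stop("event distances must lie inside (0, z_range)")
    }
  }

  v <- retract_speed * 1000            # nm/s
  dt <- 1 / sampling_rate
  dz <- v * dt
  h_min <- -setpoint / spring_constant # indentation depth reaching setpoint
  heights_ret <- seq(h_min, z_range, by = dz)
  n_ret <- length(heights_ret)
  heights_app <- rev(heights_ret)

  clean_app <- ifelse(heights_app < 0, -spring_constant * heights_app, 0)
  clean_ret <- ifelse(heights_ret < 0, -spring_constant * heights_ret, 0)
  for (i in seq_len(nrow(events))) {
    d <- events$distance_nm[i]; f <- events$force_pN[i]
    d0 <- d - f / tether_stiffness
    in_ramp <- heights_ret > d0 & heights_ret <= d
    clean_ret[in_ramp] <- clean_ret[in_ramp] -
      tether_stiffness * (heights_ret[in_ramp] - d0)
  }

  noise <- withr::with_seed(seed, rnorm(2 * n_ret, sd = noise_sigma))
  samples <- tibble(
    segment = rep(c("approach", "retract"), each = n_ret),
    time_s = c(seq_len(n_ret), seq_len(n_ret)) * dt,
    height_nm = c(heights_app, heights_ret),
    force_pN = c(clean_app, clean_ret) + noise)

  curve <- force_curve(samples, spring_constant = spring_constant,
                       retract_speed = retract_speed, setpoint = setpoint,
                       curve_id = curve_id)
  truth <- list(events = events, noise_sigma = noise_sigma,
                tether_stiffness = tether_stiffness, seed = seed,
                loading_rate_nominal_pN_per_s = tether_stiffness * v)
  attr(curve, "ground_truth") <- truth
  if (!is.null(path)) {
    write_curve(curve, path)
    jsonlite::write_json(
      list(events = events, noise_sigma = noise_sigma,
           tether_stiffness = tether_stiffness, seed = seed),
      paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA)
  }
  curve
}

#' Synthesize a force-volume map with patterned adhesion
#'
#' Generates an N x N force-volume grid in which each pixel shows an adhesion
#' event with probability `background_p`, raised to a patch-specific
#' probability inside circular patches (emulating, e.g., chitin-rich bud
#' scars on a yeast cell).  Event forces are drawn from a Gaussian and event
#' distances uniformly within `distance_range`; full synthetic curves are
#' generated per pixel when `materialize = TRUE` (or when writing to `dir`).
#'
#' @param n_rows,n_cols Grid dimensions.  Default 32 x 32 (1024 curves).
#' @param background_p Background per-pixel event probability.
#' @param patches List of patches, each a list with `center` (row, col),
#'   `radius` (pixels) and `p` (event probability inside).  Probabilities
#'   above 1 are clipped with a warning.
#' @param force_mean,force_sd Gaussian event-force parameters, pN.
#' @param distance_range Event rupture-distance range, nm.
#' @param seed Mandatory RNG seed.
#' @param materialize Generate full synthetic curves per pixel (needed to run
#'   event detection downstream).  Default FALSE: grid + truth only.
#' @param dir Optional output directory: curves, `index.csv` and
#'   `truth.json` are written there (implies `materialize`).
#' @param ... Further arguments passed to [synthesize_curve()].
#' @return List with `grid` (a [force_volume_grid()]), `truth` (per-pixel
#'   tibble: `row`, `col`, `curve_id`, `has_event`, `force_pN`,
#'   `distance_nm`), and `curves` (named list of curves, when materialised).
#' @export
synthesize_map <- function(n_rows = 32, n_cols = 32, background_p = 0.05,
                           patches = list(), force_mean = 80, force_sd = 20,
                           distance_range = c(30, 150), seed,
                           materialize = FALSE, dir = NULL, ...) {
  if (missing(seed)) stop("seed is mandatory for stochastic generators")
  stopifnot(background_p >= 0, background_p <= 1)
  pixels <- tidyr::expand_grid(row = seq_len(n_rows) - 1L,
                               col = seq_len(n_cols) - 1L)
  p <- rep(background_p, nrow(pixels))
  for (patch in patches) {
    inside <- (pixels$row - patch$center[1])^2 +
      (pixels$col - patch$center[2])^2 <= patch$radius^2
    pp <- patch$p
    if (pp > 1) {
      warning("patch probability ", pp, " clipped to 1")
      pp <- 1
    }
    p[inside] <- pp
  }

  truth <- withr::with_seed(seed, {
    has_event <- runif(nrow(pixels)) < p
    force <- ifelse(has_event,
                    pmax(abs(rnorm(nrow(pixels), force_mean, force_sd)), 10), NA)
    dist <- ifelse(has_event,
                   runif(nrow(pixels), distance_range[1], distance_range[2]), NA)
    mutate(pixels,
           curve_id = sprintf("px_%03d_%03d", .data$row, .data$col),
           has_event = has_event, force_pN = force, distance_nm = dist)
  })

  grid <- force_volume_grid(truth[c("row", "col", "curve_id")],
                            n_rows = n_rows, n_cols = n_cols)
  out <- list(grid = grid, truth = truth, curves = NULL)

  if (materialize || !is.null(dir)) {
    curves <- purrr::pmap(
      list(truth$curve_id, truth$has_event, truth$force_pN, truth$distance_nm,
           seq_len(nrow(truth))),
      function(id, has, f, d, i) {
        ev <- if (isTRUE(has)) tibble(distance_nm = d, force_pN = f) else NULL
        synthesize_curve(events = ev, curve_id = id, seed = seed + i, ...)
      })
    names(curves) <- truth$curve_id
    out$curves <- curves
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, paste0(truth$curve_id, ".tsv"))
    purrr::walk2(out$curves, paths, write_curve)
    idx <- mutate(as_tibble(as.data.frame(grid)), curve_path = basename(paths))
    readr::write_csv(idx, file.path(dir, "index.csv"), progress = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    out$dir <- dir
  }
  out
}

#' Synthesize a contact-time interaction-frequency series
#'
#' For each contact time `t`, draws the number of adhesive curves out of
#' `n_per_time` as Binomial with success probability
#' \eqn{f_{max} t / (k_{0.5} + t)} — the hyperbolic contact-time law fitted
#' by [fit_hyperbolic()].
#'
#' @param f_max Maximal interaction frequency (0, 1\].
#' @param k_half Contact time at half-maximal frequency, s.
#' @param times Contact times, s.
#' @param n_per_time Curves probed per contact time.  Default 64.
#' @param seed Mandatory RNG seed.
#' @return Tibble with `contact_time_s`, `n_curves`, `n_adhesive`,
#'   `frequency` and a `ground_truth` attribute.
#' @export
synthesize_contact_series <- function(f_max, k_half,
                                      times = c(0.05, 0.1, 0.25, 0.5, 1, 2, 4),
                                      n_per_time = 64, seed) {
  if (missing(seed)) stop("seed is mandatory for stochastic generators")
  stopifnot(f_max > 0, f_max <= 1, k_half > 0, all(times >= 0))
  p <- f_max * times / (k_half + times)
  n_adh <- withr::with_seed(seed, rbinom(length(times), n_per_time, p))
  out <- tibble(contact_time_s = times, n_curves = as.integer(n_per_time),
                n_adhesive = n_adh, frequency = n_adh / n_per_time)
  attr(out, "ground_truth") <- list(f_max = f_max, k_half = k_half,
                                    n_per_time = n_per_time, seed = seed)
  out
}
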