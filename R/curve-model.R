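#' Construct a force-distance curve
#'
#' A force curve is stored as a tibble with one row per sample and columns
#' `segment` (`"approach"` or `"retract"`), `time_s`, `height_nm` and
#' `force_pN`, carrying the acquisition metadata as attributes.  Piezo height
#' increases away from the surface; attractive (adhesive) forces are negative
#' in the raw force channel, and rupture forces are reported as magnitudes
#' downstream.
#'
#' @param samples Data frame with columns `segment`, `time_s`, `height_nm`,
#'   `force_pN`.  Time must be strictly increasing within each segment.
#' @param spring_constant Cantilever spring constant \eqn{k_c}, pN/nm.
#'   Values outside \[1, 1000\] trigger a warning (typical functionalised
#'   levers sit around 10-20 pN/nm).
#' @param retract_speed Retraction speed, um/s.
#' @param temperature Temperature, K.  Default 293.15 K (20 degC).
#' @param setpoint Applied force setpoint during contact, pN.
#' @param curve_id Unique curve identifier (character).
#' @param probe_label Free-text description of the probe molecule.
#' @param distance_mode Either `"height"` (raw piezo height, default) or
#'   `"separation"` (tip-sample separation); recorded for provenance only.
#' @return A `force_curve` tibble.
#' @examples
#' s <- tibble::tibble(
#'   segment = rep(c("approach", "retract"), each = 32),
#'   time_s = c(seq_len(32), seq_len(32)) * 1e-3,
#'   height_nm = c(seq(310, 0, length.out = 32), seq(0, 310, length.out = 32)),
#'   force_pN = 0
#' )
#' fc <- force_curve(s, spring_constant = 10, retract_speed = 1, curve_id = "demo")
#' @export
force_curve <- function(samples, spring_constant, retract_speed,
                        temperature = 293.15, setpoint = 500,
                        curve_id = "curve", probe_label = "",
                        distance_mode = c("height", "separation")) {
  distance_mode <- match.arg(distance_mode)
  required <- c("segment", "time_s", "height_nm", "force_pN")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    stop("samples is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  samples <- as_tibble(samples)[required]
  if (!all(samples$segment %in% c("approach", "retract"))) {
    stop("segment must be 'approach' or 'retract'")
  }
  if (!is.numeric(spring_constant) || length(spring_constant) != 1 ||
      is.na(spring_constant) || spring_constant <= 0) {
    stop("spring_constant must be a single positive number (pN/nm)")
  }
  if (spring_constant < 1 || spring_constant > 1000) {
    warning("spring_constant ", spring_constant,
            " pN/nm is outside the expected range [1, 1000]")
  }
  if (!is.numeric(retract_speed) || retract_speed <= 0) {
    stop("retract_speed must be positive (um/s)")
  }
  if (!is.numeric(temperature) || temperature <= 0) {
    stop("temperature must be positive (K)")
  }
  for (seg in unique(samples$segment)) {
    t_seg <- samples$time_s[samples$segment == seg]
    if (any(diff(t_seg) <= 0)) {
      stop("time_s must be strictly increasing within the ", seg, " segment")
    }
  }
  structure(
    samples,
    class = c("force_curve", class(samples)),
    curve_id = as.character(curve_id),
    spring_constant_pN_per_nm = spring_constant,
    retract_speed_um_per_s = retract_speed,
    temperature_K = temperature,
    setpoint_pN = setpoint,
    probe_label = probe_label,
    distance_mode = distance_mode,
    baseline_corrected = FALSE,
    contact_height_nm = NA_real_
  )
}

#' Acquisition metadata of a force curve
#'
#' @param curve A [force_curve()].
#' @return Named list of metadata fields.
#' @export
curve_meta <- function(curve) {
  stopifnot(inherits(curve, "force_curve"))
  fields <- c("curve_id", "spring_constant_pN_per_nm", "retract_speed_um_per_s",
              "temperature_K", "setpoint_pN", "probe_label", "distance_mode",
              "baseline_corrected", "contact_height_nm")
  setNames(lapply(fields, function(f) attr(curve, f)), fields)
}

# Extract one segment, ordered by time, as a plain tibble.
curve_segment <- function(curve, segment, min_samples = 16) {
  seg <- curve[curve$segment == segment, , drop = FALSE]
  seg <- as_tibble(as.data.frame(seg))
  if (nrow(seg) < min_samples) {
    stop("curve '", attr(curve, "curve_id"), "' has ", nrow(seg), " ", segment,
         " samples; at least ", min_samples, " are required")
  }
  seg[order(seg$time_s), ]
}

# Rebuild a force_curve with a new force channel (and/or updated attributes),
# keeping metadata intact.
curve_update <- function(curve, force_pN = NULL, ...) {
  out <- curve
  if (!is.null(force_pN)) out$force_pN <- force_pN
  dots <- list(...)
  for (nm in names(dots)) attr(out, nm) <- dots[[nm]]
  out
}

#' @export
print.force_curve <- function(x, ...) {
  m <- curve_meta(x)
  cat(sprintf(
    "<force_curve '%s'>  k_c = %g pN/nm, v = %g um/s, T = %g K, setpoint = %g pN\n",
    m$curve_id, m$spring_constant_pN_per_nm, m$retract_speed_um_per_s,
    m$temperature_K, m$setpoint_pN))
  cat(sprintf("  %d samples (%d approach, %d retract); baseline corrected: %s\n",
              nrow(x), sum(x$segment == "approach"), sum(x$segment == "retract"),
              m$baseline_corrected))
  NextMethod()
}

#' Construct a force-volume grid
#'
#' A force-volume grid maps pixel coordinates of an N x N (or N x M) scan to
#' curve identifiers, row-major with 0-based indices.  A complete 32 x 32 map
#' holds 1024 curves.
#'
#' @param pixels Data frame with columns `row`, `col`, `curve_id` and
#'   optionally `curve_path`.
#' @param n_rows,n_cols Grid dimensions.
#' @param scan_extent_nm Physical scan extent per axis, nm (optional).
#' @return A `force_volume_grid` tibble.
#' @export
force_volume_grid <- function(pixels, n_rows, n_cols, scan_extent_nm = NA_real_) {
  pixels <- as_tibble(pixels)
  stopifnot(all(c("row", "col", "curve_id") %in% names(pixels)))
  if (any(pixels$row < 0 | pixels$row >= n_rows |
          pixels$col < 0 | pixels$col >= n_cols)) {
    stop("pixel coordinates outside the ", n_rows, " x ", n_cols, " grid")
  }
  if (anyDuplicated(pixels[c("row", "col")]) > 0) {
    stop("each (row, col) pixel may map to at most one curve")
  }
  structure(pixels, class = c("force_volume_grid", class(pixels)),
            n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
            scan_extent_nm = scan_extent_nm)
}

#' @export
print.force_volume_grid <- function(x, ...) {
  cat(sprintf("<force_volume_grid %d x %d> %d of %d pixels mapped\n",
              attr(x, "n_rows"), attr(x, "n_cols"), nrow(x),
              attr(x, "n_rows") * attr(x, "n_cols")))
  NextMethod()
}
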