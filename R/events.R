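#' Event detection configuration
#'
#' @param smoothing_window Centred running-median window (samples, odd) used
#'   for event localisation only; rupture forces are read from the unsmoothed
#'   channel.  Default 7.
#' @param threshold_sigma Detection threshold in units of the baseline noise
#'   SD (must be >= 2).  Default 3.
#' @param min_separation Minimum distance between events, nm; of two
#'   candidate minima closer than this, the deeper one is kept, and the force
#'   must jump back toward baseline within this distance after each rupture.
#'   Default 10 nm.
#' @param distance_window Numeric length-2: rupture-distance window, nm,
#'   inside which events are flagged specific.  Default c(20, 500), the union
#'   of the ranges seen for antibody- and lectin-functionalised probes.
#' @param slope_window Number of samples immediately preceding a rupture used
#'   to estimate the instantaneous loading rate (|dF/dt|).  Default 20.
#' @param tail_fraction Retract tail fraction used for noise estimation.
#' @return A list of class `event_config`.
#' @export
event_config <- function(smoothing_window = 7, threshold_sigma = 3,
                         min_separation = 10, distance_window = c(20, 500),
                         slope_window = 20, tail_fraction = 0.3) {
  if (threshold_sigma < 2) stop("threshold_sigma must be >= 2")
  if (length(distance_window) != 2 || distance_window[1] >= distance_window[2]) {
    stop("distance_window must be (min, max) with min < max")
  }
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window %% 2 == 0) smoothing_window <- smoothing_window + 1L
  structure(list(smoothing_window = smoothing_window,
                 threshold_sigma = threshold_sigma,
                 min_separation = min_separation,
                 distance_window = distance_window,
                 slope_window = as.integer(slope_window),
                 tail_fraction = tail_fraction),
            class = "event_config")
}

empty_events <- function() {
  tibble(curve_id = character(), rupture_force_pN = double(),
         rupture_distance_nm = double(), loading_rate_pN_per_s = double(),
         is_specific = logical())
}

#' Detect adhesion (rupture) events on the retract segment
#'
#' An adhesion event is a local minimum of the (median-smoothed) retract
#' force deeper than `threshold_sigma` noise SD below baseline, followed by a
#' jump back toward baseline of comparable magnitude within `min_separation`
#' nm (the signature of bond rupture).  For each event the rupture force is
#' the magnitude of the unsmoothed force minimum, the rupture distance is
#' measured from the contact point, and the loading rate is the magnitude of
#' the slope of force versus time over `slope_window` samples immediately
#' before the rupture ("critical loading rate").  Events whose distance falls
#' inside `distance_window` are flagged specific.  Events are returned sorted
#' by rupture distance.
#'
#' @param curve A baseline-corrected [force_curve()].
#' @param config An [event_config()].
#' @param contact_height Contact piezo height, nm.  Defaults to
#'   [find_contact_point()] when an approach segment is present, else 0.
#' @return Tibble with columns `curve_id`, `rupture_force_pN`,
#'   `rupture_distance_nm`, `loading_rate_pN_per_s`, `is_specific`.
#' @export
detect_events <- function(curve, config = event_config(), contact_height = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  retract <- curve_segment(curve, "retract")
  tail_win <- retract_tail(retract, config$tail_fraction)
  sigma <- noise_sd(tail_win$force_pN - median(tail_win$force_pN))
  if (sigma == 0 || !is.finite(sigma)) sigma <- max(noise_sd(retract$force_pN), 1e-9)
  if (abs(mean(tail_win$force_pN)) > 3 * sigma) {
    stop("curve '", attr(curve, "curve_id"),
         "' does not look baseline-corrected (far-field mean force ",
         signif(mean(tail_win$force_pN), 3), " pN exceeds 3 noise SD); ",
         "run correct_baseline() first")
  }
  if (is.null(contact_height)) {
    contact_height <- if (any(curve$segment == "approach") &&
                          isTRUE(attr(curve, "baseline_corrected"))) {
      tryCatch(find_contact_point(curve), error = function(e) 0)
    } else {
      attr(curve, "contact_height_nm")
    }
    if (is.null(contact_height) || is.na(contact_height)) contact_height <- 0
  }

  n <- nrow(retract)
  k <- min(config$smoothing_window, if (n %% 2 == 1) n else n - 1L)
  sm <- stats::runmed(retract$force_pN, k = k, endrule = "median")
  dist <- retract$height_nm - contact_height
  dz <- median(abs(diff(retract$height_nm)))
  sep_samples <- max(1L, ceiling(config$min_separation / dz))

  deep <- which(sm < -config$threshold_sigma * sigma)
  # local minima of the smoothed channel among deep samples
  cand <- deep[vapply(deep, function(i) {
    lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
    sm[i] <= min(sm[lo:hi])
  }, logical(1))]

  # require a rupture jump: smoothed force returns near baseline within
  # min_separation after the minimum
  cand <- cand[vapply(cand, function(i) {
    after <- sm[seq.int(min(n, i + 1L), min(n, i + sep_samples))]
    (max(after) - sm[i]) >= 0.8 * abs(sm[i])
  }, logical(1))]

  # merge candidates closer than min_separation, keeping the deeper minimum
  if (length(cand) > 1) {
    cand <- cand[order(dist[cand])]
    kept <- cand[1]
    for (i in cand[-1]) {
      last <- kept[length(kept)]
      if (dist[i] - dist[last] < config$min_separation) {
        if (sm[i] < sm[last]) kept[length(kept)] <- i
      } else {
        kept <- c(kept, i)
      }
    }
    cand <- kept
  }
  if (length(cand) == 0) return(empty_events())

  half <- (config$smoothing_window - 1L) %/% 2L
  events <- purrr::map_dfr(cand, function(i) {
    win <- seq.int(max(1L, i - half), min(n, i + half))
    i_raw <- win[which.min(retract$force_pN[win])]
    pre <- seq.int(max(1L, i_raw - config$slope_window + 1L), i_raw)
    rate <- if (length(pre) >= 3) {
      abs(unname(coef(lm(retract$force_pN[pre] ~ retract$time_s[pre]))[2]))
    } else NA_real_
    tibble(
      curve_id = attr(curve, "curve_id"),
      rupture_force_pN = abs(retract$force_pN[i_raw]),
      rupture_distance_nm = dist[i_raw],
      loading_rate_pN_per_s = rate
    )
  })
  events$is_specific <- events$rupture_distance_nm >= config$distance_window[1] &
    events$rupture_distance_nm <= config$distance_window[2]
  arrange(events, .data$rupture_distance_nm)
}

#' Adhesion frequency of a set of curves
#'
#' Fraction of curves showing at least one (specific) adhesion event.
#'
#' @param events Either a list of per-curve event tibbles (as returned by
#'   [detect_events()]), or a single combined events tibble, in which case
#'   `n_curves` must give the total number of curves probed (curves without
#'   events do not appear in an events table).
#' @param n_curves Total number of curves; required when `events` is a single
#'   tibble, inferred as `length(events)` for a list.
#' @param specific_only Count only events flagged specific.  Default TRUE.
#' @return One-row tibble with `n_adhesive`, `n_total`, `frequency`.
#' @examples
#' ev <- tibble::tibble(curve_id = as.character(1:307), is_specific = TRUE)
#' adhesion_frequency(ev, n_curves = 1024)
#' @export
adhesion_frequency <- function(events, n_curves = NULL, specific_only = TRUE) {
  if (is.list(events) && !is.data.frame(events)) {
    if (length(events) == 0) stop("empty input: no curves")
    n_curves <- n_curves %||% length(events)
    events <- bind_rows(events)
  }
  if (is.null(n_curves) || n_curves < 1) {
    stop("n_curves must be supplied (>= 1) with a combined events table")
  }
  if (nrow(events) > 0 && specific_only) {
    events <- events[events$is_specific, , drop = FALSE]
  }
  n_adh <- length(unique(events$curve_id))
  if (n_adh > n_curves) {
    stop("number of adhesive curves (", n_adh, ") exceeds n_curves (",
         n_curves, ")")
  }
  tibble(n_adhesive = n_adh, n_total = as.integer(n_curves),
         frequency = n_adh / n_curves)
}

#' Compare adhesion frequencies before and after a blocking control
#'
#' Quantifies the effect of adding free competitor sugar (e.g. 200 mM
#' mannose) on the adhesion frequency: the absolute drop, the after/before
#' ratio, and a blocked flag when the ratio falls below `blocked_cutoff`.
#'
#' @param freq_before,freq_after Adhesion frequencies in \[0, 1\].
#' @param blocked_cutoff Ratio below which the interaction is called blocked.
#'   Default 0.5.
#' @return One-row tibble with `freq_before`, `freq_after`, `drop`, `ratio`,
#'   `blocked`.  `ratio` is `NA` (undefined) when `freq_before` is 0.
#' @export
blocking_comparison <- function(freq_before, freq_after, blocked_cutoff = 0.5) {
  stopifnot(freq_before >= 0, freq_before <= 1, freq_after >= 0, freq_after <= 1)
  ratio <- if (freq_before == 0) NA_real_ else freq_after / freq_before
  tibble(freq_before = freq_before, freq_after = freq_after,
         drop = freq_before - freq_after, ratio = ratio,
         blocked = !is.na(ratio) && ratio < blocked_cutoff)
}
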