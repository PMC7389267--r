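# Robust noise estimate: scaled median absolute deviation of a detrended
# force window (MAD x 1.4826 matches the SD of Gaussian noise while ignoring
# sparse rupture events).
noise_sd <- function(force) {
  if (length(force) < 4) return(NA_real_)
  mad(force, constant = 1.4826)
}

# Far-from-surface tail of the retract segment (largest heights, i.e. the
# final tail_fraction of samples in time order).
retract_tail <- function(retract, tail_fraction) {
  n <- nrow(retract)
  n_tail <- max(16L, floor(n * tail_fraction))
  retract[seq.int(n - min(n_tail, n) + 1L, n), ]
}

#' Baseline-correct a force curve
#'
#' Fits a straight line (force versus piezo height) to the far-from-surface
#' tail of the retract segment and subtracts it from the force channel of the
#' whole curve, removing offset and tilt so that the far-field force averages
#' to zero.  Samples in the tail window whose residual exceeds 5 noise SD
#' (events, spikes) are flagged; if any are found the window is shrunk to the
#' clean samples with a warning, and an error is raised when fewer than 16
#' clean samples remain.
#'
#' The correction is idempotent: applying it twice changes forces by less
#' than 1e-6 pN.
#'
#' @param curve A [force_curve()] with a retract segment of >= 16 samples.
#' @param tail_fraction Fraction (0, 0.5\] of the retract segment, counted
#'   from its far end, used as the baseline window.  Default 0.3.
#' @return The corrected `force_curve` (attribute `baseline_corrected` set).
#' @export
correct_baseline <- function(curve, tail_fraction = 0.3) {
  stopifnot(inherits(curve, "force_curve"))
  if (!is.numeric(tail_fraction) || tail_fraction <= 0 || tail_fraction > 0.5) {
    stop("tail_fraction must be in (0, 0.5]")
  }
  retract <- curve_segment(curve, "retract")
  tail_win <- retract_tail(retract, tail_fraction)

  fit <- lm(force_pN ~ height_nm, data = tail_win)
  resid <- stats::residuals(fit)
  sigma <- noise_sd(resid)
  clean <- abs(resid) <= 5 * sigma
  if (!all(clean)) {
    warning("baseline window contains ", sum(!clean),
            " event-like excursion(s); window auto-shrunk")
    if (sum(clean) < 16) {
      stop("cannot find a clean baseline window on curve '",
           attr(curve, "curve_id"), "'")
    }
    fit <- lm(force_pN ~ height_nm, data = tail_win[clean, ])
  }
  beta <- coef(fit)
  corrected <- curve$force_pN - (beta[1] + beta[2] * curve$height_nm)
  curve_update(curve, force_pN = unname(corrected), baseline_corrected = TRUE)
}

#' Locate the tip-surface contact point on the approach segment
#'
#' Scans the baseline-corrected approach segment in time order (tip moving
#' toward the surface) for the first point where the repulsive force exceeds
#' `noise_sigma_mult` times the baseline noise SD and stays above it for
#' `persistence` consecutive samples, then extrapolates the local contact
#' ramp back to zero force.  The returned piezo height defines the origin for
#' rupture distances; it is equivariant under rigid height translations.
#'
#' @param curve A baseline-corrected [force_curve()] with an approach segment.
#' @param noise_sigma_mult Detection threshold in units of the baseline noise
#'   SD.  Default 5.
#' @param persistence Number of consecutive above-threshold samples required.
#' @return Contact piezo height, nm.
#' @export
find_contact_point <- function(curve, noise_sigma_mult = 5, persistence = 5) {
  stopifnot(inherits(curve, "force_curve"))
  if (!isTRUE(attr(curve, "baseline_corrected"))) {
    stop("curve must be baseline-corrected before contact-point detection")
  }
  approach <- curve_segment(curve, "approach")
  n <- nrow(approach)
  # Far field = first third of the approach (tip still away from the surface).
  far <- approach[seq_len(max(16L, floor(n / 3))), ]
  sigma <- noise_sd(far$force_pN - median(far$force_pN))
  threshold <- noise_sigma_mult * sigma
  above <- approach$force_pN > threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- which(runs$values & runs$lengths >= persistence)
  if (length(hit) == 0) stop("no contact found on curve '",
                             attr(curve, "curve_id"), "'")
  i0 <- starts[hit[1]]
  # Extrapolate the contact ramp back to zero force for a sharper estimate.
  ramp <- approach[seq.int(i0, min(n, i0 + 19L)), ]
  slope <- coef(lm(force_pN ~ height_nm, data = ramp))[2]
  h0 <- approach$height_nm[i0]
  if (is.finite(slope) && slope < 0) {
    h0 <- h0 + approach$force_pN[i0] / (-slope)
  }
  unname(h0)
}
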