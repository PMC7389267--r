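#' Fit a Gaussian to an adhesion-force histogram
#'
#' Bins the rupture-force magnitudes (default 10 pN bins over at least
#' 0-300 pN, extended to cover the data) and least-squares fits a Gaussian
#' `A * exp(-(x - mu)^2 / (2 sigma^2))` to the bin counts, mirroring how
#' adhesion-force histograms are summarised as "mu +/- sigma pN".  A
#' maximum-likelihood alternative (`method = "mle"`: sample mean and SD of
#' the raw forces) is also available.
#'
#' The fit is only attempted with at least `min_events` forces; below that
#' (or for degenerate all-identical input) the histogram alone is returned
#' with `fit_ok = FALSE`.
#'
#' @param forces Numeric vector of rupture forces, pN (magnitudes, > 0).
#' @param bin_width Histogram bin width, pN.  Default 10.
#' @param force_range Minimum histogram span, pN.  Default c(0, 300).
#' @param method `"binned"` (least squares on bin counts, default) or
#'   `"mle"` (moments of the raw forces).
#' @param min_events Minimum number of events for a fit.  Default 30.
#' @return An `adhesion_force_fit` object: list with `histogram` (tibble
#'   `bin_left_pN`, `bin_right_pN`, `count`), `mu`, `sigma`, `amplitude`,
#'   `n_events`, `fit_ok`, `method`.
#' @examples
#' f <- withr::with_seed(1, rnorm(500, 36, 19))
#' fit <- fit_gaussian_histogram(f[f > 0])
#' c(fit$mu, fit$sigma)
#' @export
fit_gaussian_histogram <- function(forces, bin_width = 10,
                                   force_range = c(0, 300),
                                   method = c("binned", "mle"),
                                   min_events = 30) {
  method <- match.arg(method)
  if (length(forces) == 0) stop("no forces supplied")
  if (any(!is.finite(forces))) stop("forces must be finite")
  if (bin_width <= 0) stop("bin_width must be positive")

  lo <- min(force_range[1], floor(min(forces) / bin_width) * bin_width)
  hi <- max(force_range[2], ceiling(max(forces) / bin_width) * bin_width)
  breaks <- seq(lo, hi, by = bin_width)
  if (max(forces) >= breaks[length(breaks)]) breaks <- c(breaks, hi + bin_width)
  h <- graphics::hist(forces, breaks = breaks, plot = FALSE, right = FALSE)
  histogram <- tibble(bin_left_pN = head(h$breaks, -1),
                      bin_right_pN = tail(h$breaks, -1),
                      count = h$counts)

  out <- list(histogram = histogram, mu = NA_real_, sigma = NA_real_,
              amplitude = NA_real_, n_events = length(forces),
              fit_ok = FALSE, method = method)
  class(out) <- "adhesion_force_fit"

  degenerate <- sd(forces) == 0
  if (length(forces) < min_events || degenerate) return(out)

  if (method == "mle") {
    out$mu <- mean(forces)
    out$sigma <- sd(forces)
    out$amplitude <- length(forces) * bin_width /
      (out$sigma * sqrt(2 * pi))
    out$fit_ok <- TRUE
    return(out)
  }

  centers <- (histogram$bin_left_pN + histogram$bin_right_pN) / 2
  counts <- histogram$count
  start <- list(A = max(counts), mu = mean(forces), sigma = sd(forces))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      counts ~ A * exp(-(centers - mu)^2 / (2 * sigma^2)),
      start = start, control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    p <- coef(fit)
    if (is.finite(p[["sigma"]]) && p[["sigma"]] != 0) {
      out$mu <- unname(p[["mu"]])
      out$sigma <- abs(unname(p[["sigma"]]))
      out$amplitude <- unname(p[["A"]])
      out$fit_ok <- TRUE
    }
  }
  out
}

#' @export
print.adhesion_force_fit <- function(x, ...) {
  cat("<adhesion_force_fit>", x$n_events, "events,", x$method, "fit\n")
  if (x$fit_ok) {
    cat(sprintf("  adhesion force: %.1f +/- %.1f pN\n", x$mu, x$sigma))
  } else {
    cat("  no valid Gaussian fit (histogram only)\n")
  }
  invisible(x)
}

#' @method tidy adhesion_force_fit
#' @export
tidy.adhesion_force_fit <- function(x, ...) {
  tibble(term = c("mu_pN", "sigma_pN", "amplitude"),
         estimate = c(x$mu, x$sigma, x$amplitude))
}

#' @method glance adhesion_force_fit
#' @export
glance.adhesion_force_fit <- function(x, ...) {
  tibble(n_events = x$n_events, fit_ok = x$fit_ok, method = x$method)
}

#' @method autoplot adhesion_force_fit
#' @export
autoplot.adhesion_force_fit <- function(object, ...) {
  h <- object$histogram
  p <- ggplot2::ggplot(h) +
    ggplot2::geom_col(
      ggplot2::aes(x = (.data$bin_left_pN + .data$bin_right_pN) / 2,
                   y = .data$count),
      width = h$bin_right_pN[1] - h$bin_left_pN[1],
      fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = "Adhesion force (pN)", y = "Count")
  if (object$fit_ok) {
    xs <- seq(min(h$bin_left_pN), max(h$bin_right_pN), length.out = 200)
    fit_df <- tibble(x = xs, y = object$amplitude *
                       exp(-(xs - object$mu)^2 / (2 * object$sigma^2)))
    p <- p + ggplot2::geom_line(data = fit_df,
                                ggplot2::aes(x = .data$x, y = .data$y),
                                colour = "red")
  }
  p
}

#' Render a force-volume adhesion map
#'
#' Summarises detected events per pixel of a force-volume grid: a binary
#' adhesion map (white pixel = at least one specific event, black = none)
#' plus a quantitative per-pixel summary of the specific rupture forces.
#' Pixels present in the grid but without events get `has_event = FALSE` and
#' an `NA` force; pixels absent from the grid are marked unobserved.
#'
#' @param events Combined events tibble (see [detect_events()]).
#' @param grid A [force_volume_grid()].  Every `curve_id` in `events` must
#'   appear in the grid.
#' @param summary Per-pixel force summary: `"max"` (default), `"first"`
#'   (smallest rupture distance) or `"sum"`.
#' @param specific_only Use only specific events.  Default TRUE.
#' @return An `adhesion_map` tibble with one row per grid pixel (columns
#'   `row`, `col`, `curve_id`, `observed`, `has_event`, `force_pN`) and
#'   attributes `n_rows`, `n_cols`, `frequency`.
#' @export
render_adhesion_map <- function(events, grid, summary = c("max", "first", "sum"),
                                specific_only = TRUE) {
  summary <- match.arg(summary)
  stopifnot(inherits(grid, "force_volume_grid"))
  if (nrow(events) > 0) {
    unknown <- setdiff(unique(events$curve_id), grid$curve_id)
    if (length(unknown) > 0) {
      stop("events reference curve_id(s) absent from the grid: ",
           paste(head(unknown, 5), collapse = ", "))
    }
    if (specific_only) events <- events[events$is_specific, , drop = FALSE]
  }
  n_rows <- attr(grid, "n_rows"); n_cols <- attr(grid, "n_cols")
  pixels <- tidyr::expand_grid(row = seq_len(n_rows) - 1L,
                               col = seq_len(n_cols) - 1L)
  pixels <- dplyr::left_join(pixels, as_tibble(as.data.frame(grid)),
                             by = c("row", "col"))
  pixels$observed <- !is.na(pixels$curve_id)

  per_curve <- if (nrow(events) > 0) {
    events |>
      group_by(.data$curve_id) |>
      summarise(force_pN = switch(summary,
                                  max = max(.data$rupture_force_pN),
                                  first = .data$rupture_force_pN[
                                    which.min(.data$rupture_distance_nm)],
                                  sum = sum(.data$rupture_force_pN)),
                .groups = "drop")
  } else {
    tibble(curve_id = character(), force_pN = double())
  }
  pixels <- dplyr::left_join(pixels, per_curve, by = "curve_id")
  pixels$has_event <- ifelse(pixels$observed, !is.na(pixels$force_pN), NA)
  freq <- mean(pixels$has_event[pixels$observed])

  structure(pixels[c("row", "col", "curve_id", "observed", "has_event", "force_pN")],
            class = c("adhesion_map", class(pixels)),
            n_rows = n_rows, n_cols = n_cols, frequency = freq)
}

#' @export
print.adhesion_map <- function(x, ...) {
  cat(sprintf("<adhesion_map %d x %d> adhesion frequency %.3f\n",
              attr(x, "n_rows"), attr(x, "n_cols"), attr(x, "frequency")))
  NextMethod()
}

#' @method autoplot adhesion_map
#' @export
autoplot.adhesion_map <- function(object, fill = c("binary", "force"), ...) {
  fill <- match.arg(fill)
  df <- as_tibble(as.data.frame(object))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row")
  if (fill == "binary") {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$has_event)) +
      ggplot2::scale_fill_manual(values = c(`TRUE` = "white", `FALSE` = "black"),
                                 na.value = "grey50", name = "adhesion")
  } else {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$force_pN)) +
      ggplot2::scale_fill_viridis_c(na.value = "black", name = "force (pN)")
  }
}

#' Write an adhesion map to disk
#'
#' `write_map_csv()` writes the quantitative per-pixel force grid as a CSV
#' matrix (`NA` for event-free or unobserved pixels); `write_map_pgm()`
#' writes the binary map as a plain-text (P2) PGM image, white (255) for
#' adhesion, black (0) for none.
#'
#' @param map An `adhesion_map` from [render_adhesion_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "adhesion_map"))
  n_rows <- attr(map, "n_rows"); n_cols <- attr(map, "n_cols")
  m <- matrix(NA_real_, n_rows, n_cols)
  m[cbind(map$row + 1L, map$col + 1L)] <- map$force_pN
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_map_csv
#' @export
write_map_pgm <- function(map, path) {
  stopifnot(inherits(map, "adhesion_map"))
  n_rows <- attr(map, "n_rows"); n_cols <- attr(map, "n_cols")
  m <- matrix(0L, n_rows, n_cols)
  m[cbind(map$row + 1L, map$col + 1L)] <-
    ifelse(!is.na(map$has_event) & map$has_event, 255L, 0L)
  lines <- c("P2", paste(n_cols, n_rows), "255",
             apply(m, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
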