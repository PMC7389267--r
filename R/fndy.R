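#' Friddle-Noy-de Yoreo mean rupture force
#'
#' Mean rupture force of a single bond loaded at constant rate `r` under the
#' two-regime (near-equilibrium + kinetic) model:
#' \deqn{F(r) = f_{eq} + f_\beta \ln\!\big(1 + e^{-\gamma}\, r /(k_{off} f_\beta)\big)}
#' with \eqn{\gamma = 0.577} (Euler's constant).  \eqn{F} is strictly
#' increasing in `r`, tends to the equilibrium force \eqn{f_{eq}} as
#' \eqn{r \to 0}, and grows as \eqn{f_\beta \ln r} in the kinetic regime.
#'
#' @param loading_rate Loading rate(s) `r`, pN/s (>= 0).
#' @param f_eq Equilibrium force, pN (> 0).
#' @param f_beta Thermal force \eqn{f_\beta = k_B T / x_t}, pN (> 0).
#' @param k_off Dissociation rate at \eqn{f_{eq}}, 1/s (> 0).
#' @return Mean rupture force(s), pN.
#' @examples
#' fndy_mean_force(0, f_eq = 36.2, f_beta = 67.46, k_off = 732.4)  # = f_eq
#' @export
fndy_mean_force <- function(loading_rate, f_eq, f_beta, k_off) {
  if (any(!is.finite(c(f_eq, f_beta, k_off))) ||
      f_eq <= 0 || f_beta <= 0 || k_off <= 0) {
    stop("f_eq, f_beta and k_off must all be positive and finite")
  }
  if (any(loading_rate < 0)) stop("loading_rate must be >= 0")
  gam <- afm_constants()$gamma_euler
  f_eq + f_beta * log1p(exp(-gam) * loading_rate / (k_off * f_beta))
}

#' Derive energy-landscape quantities from fitted bond parameters
#'
#' Converts the three fitted bond parameters into the derived landscape
#' quantities:
#' \itemize{
#'   \item barrier width \eqn{x_t = k_B T / f_\beta}, reported in Angstrom;
#'   \item binding free energy \eqn{|\Delta G| = f_{eq}^2 / (2 k_c)} in pN nm,
#'     reported negative (favourable binding) in kcal/mol;
#'   \item bond lifetime \eqn{\tau_0 = 1 / k_{off}}, reported in ms.
#' }
#' \eqn{\Delta G} requires the cantilever spring constant \eqn{k_c}; when it
#' is not supplied, \eqn{\Delta G} is returned as `NA` with a warning rather
#' than guessed.
#'
#' @param f_eq Equilibrium force, pN.
#' @param f_beta Thermal force, pN.
#' @param k_off Dissociation rate, 1/s.
#' @param k_c Cantilever spring constant, pN/nm (optional).
#' @param temperature Temperature, K.  Default 293.15.
#' @return One-row tibble with `x_t_A`, `delta_G_pN_nm`, `delta_G_kcal_mol`,
#'   `tau0_ms`.
#' @examples
#' derive_landscape(f_eq = 88.1, f_beta = 404.7, k_off = 113.6, k_c = 10)
#' @export
derive_landscape <- function(f_eq, f_beta, k_off, k_c = NULL,
                             temperature = 293.15) {
  if (any(c(f_eq, f_beta, k_off, temperature) <= 0)) {
    stop("f_eq, f_beta, k_off and temperature must be positive")
  }
  const <- afm_constants()
  x_t_A <- 10 * kBT(temperature) / f_beta  # nm -> Angstrom
  tau0_ms <- 1000 / k_off
  if (is.null(k_c) || is.na(k_c)) {
    warning("k_c not supplied; delta_G omitted (spring constant is required ",
            "to convert f_eq into a binding free energy)")
    dg_pn_nm <- NA_real_
  } else {
    if (k_c <= 0) stop("k_c must be positive")
    dg_pn_nm <- f_eq^2 / (2 * k_c)
  }
  tibble(x_t_A = x_t_A,
         delta_G_pN_nm = -dg_pn_nm,
         delta_G_kcal_mol = -dg_pn_nm / const$kcal_per_mol_to_pN_nm,
         tau0_ms = tau0_ms)
}

#' Bin a dynamic force spectrum by loading rate
#'
#' Partitions (loading rate, rupture force) points into log-spaced
#' loading-rate bins.  Each bin is summarised by the geometric mean loading
#' rate and a representative force: the mode of a Gaussian fit to the binned
#' force histogram when the bin holds at least `min_events_for_mode` events
#' (mirroring how force spectra are usually reduced to one dot per rate),
#' otherwise the mean.  Empty bins are dropped; fewer bins than requested
#' triggers a warning.
#'
#' @param data Tibble with columns `loading_rate_pN_per_s`,
#'   `rupture_force_pN`.
#' @param n_bins Number of log-spaced bins (>= 3).  Default 8.
#' @param min_events_for_mode Minimum bin size for the Gaussian-mode summary.
#' @return Tibble with columns `loading_rate_pN_per_s` (geometric mean),
#'   `rupture_force_pN` (representative force), `n`; attribute
#'   `binned = TRUE`.
#' @export
bin_dfs <- function(data, n_bins = 8, min_events_for_mode = 30) {
  if (n_bins < 3) stop("n_bins must be >= 3")
  stopifnot(all(c("loading_rate_pN_per_s", "rupture_force_pN") %in% names(data)))
  r <- data$loading_rate_pN_per_s
  if (any(r <= 0)) stop("loading rates must be positive")
  if (length(unique(r)) < n_bins) {
    stop("need at least n_bins (", n_bins, ") distinct loading rates")
  }
  breaks <- exp(seq(log(min(r)), log(max(r)), length.out = n_bins + 1))
  breaks[1] <- breaks[1] * (1 - 1e-12)
  breaks[length(breaks)] <- breaks[length(breaks)] * (1 + 1e-12)
  bin <- cut(r, breaks = breaks, labels = FALSE)
  out <- data |>
    mutate(.bin = bin) |>
    group_by(.data$.bin) |>
    summarise(
      loading_rate_pN_per_s = exp(mean(log(.data$loading_rate_pN_per_s))),
      rupture_force_pN = {
        f <- .data$rupture_force_pN
        if (length(f) >= min_events_for_mode) {
          g <- fit_gaussian_histogram(f, min_events = min_events_for_mode)
          if (g$fit_ok) g$mu else mean(f)
        } else mean(f)
      },
      n = dplyr::n(), .groups = "drop") |>
    dplyr::select(-".bin") |>
    arrange(.data$loading_rate_pN_per_s)
  if (nrow(out) < n_bins) {
    warning("only ", nrow(out), " non-empty bins returned (", n_bins,
            " requested)")
  }
  attr(out, "binned") <- TRUE
  out
}

# Analytic gradient of fndy_mean_force with respect to (f_eq, f_beta, k_off),
# n x 3 matrix. u = e^-gamma * r / (k_off * f_beta).
fndy_gradient <- function(r, f_eq, f_beta, k_off) {
  gam <- afm_constants()$gamma_euler
  u <- exp(-gam) * r / (k_off * f_beta)
  cbind(f_eq = rep(1, length(r)),
        f_beta = log1p(u) - u / (1 + u),
        k_off = -f_beta * u / ((1 + u) * k_off))
}

#' Fit the Friddle-Noy-de Yoreo model to a dynamic force spectrum
#'
#' Three-parameter nonlinear least squares of [fndy_mean_force()] on
#' (loading rate, rupture force) pairs using the Levenberg-Marquardt
#' algorithm (iteration cap 500, chi-square change tolerance 1e-15).  The
#' parameters are log-transformed internally so that every iterate stays
#' positive; confidence intervals are computed on the log scale from the
#' linearised covariance with t quantiles (df = n - 3) and transformed back.
#' 99% confidence and prediction bands over the fitted loading-rate range are
#' available through [predict.fndy_fit()].
#'
#' Initial values (when `init` is not given) are data driven: `f_eq` starts
#' at the smallest binned force, `f_beta` at the slope of force versus
#' log loading rate over the top decade, and `k_off` is solved from the model
#' at the median point.
#'
#' @param data Tibble with columns `loading_rate_pN_per_s`,
#'   `rupture_force_pN` — per-event points (default) or bin summaries.
#' @param init Optional named vector/list with starting values `f_eq`,
#'   `f_beta`, `k_off`.
#' @param binned If `TRUE`, the data are first reduced with [bin_dfs()] and
#'   the fit runs on the bin summaries.
#' @param n_bins Bins used when `binned = TRUE`.
#' @param k_c Cantilever spring constant, pN/nm, used for the derived
#'   \eqn{\Delta G} (omitted with a warning when `NULL`).
#' @param temperature Temperature, K.  Default 293.15.
#' @param max_iter Levenberg-Marquardt iteration cap.  Default 500.
#' @param chisq_tol Relative chi-square change tolerance.  Default 1e-15.
#' @param conf_level Confidence level for intervals.  Default 0.99.
#' @return An `fndy_fit` object; see [tidy.fndy_fit()], [glance.fndy_fit()],
#'   [predict.fndy_fit()], [autoplot.fndy_fit()] and the `derived` element
#'   (from [derive_landscape()]).
#' @export
fit_fndy <- function(data, init = NULL, binned = FALSE, n_bins = 8,
                     k_c = NULL, temperature = 293.15,
                     max_iter = 500, chisq_tol = 1e-15, conf_level = 0.99) {
  stopifnot(all(c("loading_rate_pN_per_s", "rupture_force_pN") %in% names(data)))
  if (any(data$loading_rate_pN_per_s <= 0) || any(data$rupture_force_pN <= 0)) {
    stop("loading rates and rupture forces must be positive")
  }
  if (binned) data <- bin_dfs(data, n_bins = n_bins)
  r <- data$loading_rate_pN_per_s
  F <- data$rupture_force_pN

  r_distinct <- unique(r)
  if (length(r_distinct) < 5 ||
      max(r_distinct) / min(r_distinct) < 10) {
    warning("loading rates are poorly conditioned for a three-parameter fit ",
            "(need >= 5 distinct rates spanning >= 1 decade)")
  }

  if (is.null(init)) {
    init <- fndy_init(r, F)
  } else {
    init <- unlist(init)[c("f_eq", "f_beta", "k_off")]
  }
  if (any(!is.finite(init)) || any(init <= 0)) {
    stop("initial parameter values must be positive and finite")
  }

  # Raw model evaluation without domain checks: LM trial steps may momentarily
  # overflow on the log scale, which must yield a large residual, not an error.
  gam <- afm_constants()$gamma_euler
  resid_fn <- function(theta) {
    p <- exp(theta)
    res <- F - (p[1] + p[2] * log1p(exp(-gam) * r / (p[3] * p[2])))
    res[!is.finite(res)] <- 1e6
    res
  }
  lm_out <- minpack.lm::nls.lm(
    par = log(init), fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = chisq_tol, ptol = 1e-12, gtol = 0))
  theta <- lm_out$par
  est <- setNames(exp(theta), c("f_eq", "f_beta", "k_off"))
  converged <- lm_out$info %in% 1:4 && lm_out$niter <= max_iter

  n <- length(F)
  df_resid <- n - 3L
  fitted <- fndy_mean_force(r, est[1], est[2], est[3])
  deviance <- sum((F - fitted)^2)
  sigma2 <- if (df_resid > 0) deviance / df_resid else NA_real_

  # Linearised covariance on the log scale: J_log = J_nat %*% diag(params)
  J <- fndy_gradient(r, est[1], est[2], est[3]) %*% diag(est)
  cov_log <- tryCatch(sigma2 * solve(crossprod(J)),
                      error = function(e) matrix(NA_real_, 3, 3))
  se_log <- sqrt(diag(cov_log))
  tq <- qt(1 - (1 - conf_level) / 2, df = max(df_resid, 1))
  ci <- cbind(low = est * exp(-tq * se_log), high = est * exp(tq * se_log))
  rownames(ci) <- names(est)
  se_nat <- est * se_log

  derived <- withCallingHandlers(
    derive_landscape(est[["f_eq"]], est[["f_beta"]], est[["k_off"]],
                     k_c = k_c, temperature = temperature),
    warning = function(w) {
      if (grepl("k_c not supplied", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })

  structure(list(
    estimates = est, se = se_nat, ci = ci, cov_log = cov_log,
    data = tibble(loading_rate_pN_per_s = r, rupture_force_pN = F),
    fitted = fitted, residuals = F - fitted,
    deviance = deviance, sigma = sqrt(sigma2), df_residual = df_resid,
    iterations = lm_out$niter, converged = converged,
    message = lm_out$message, init = init, binned = isTRUE(binned),
    k_c = k_c, temperature = temperature, conf_level = conf_level,
    derived = derived), class = "fndy_fit")
}

# Data-driven starting values for the three bond parameters.
fndy_init <- function(r, F) {
  gam <- afm_constants()$gamma_euler
  binned <- tryCatch(
    bin_dfs(tibble(loading_rate_pN_per_s = r, rupture_force_pN = F),
            n_bins = min(8, max(3, length(unique(r))))),
    error = function(e) tibble(loading_rate_pN_per_s = r, rupture_force_pN = F))
  f_eq0 <- max(min(binned$rupture_force_pN), 1e-3)
  top <- r >= max(r) / 10
  f_beta0 <- if (sum(top) >= 3 && length(unique(r[top])) >= 2) {
    unname(coef(lm(F[top] ~ log(r[top])))[2])
  } else NA_real_
  if (!is.finite(f_beta0) || f_beta0 <= 0) f_beta0 <- max(sd(F), 1)
  i_med <- which.min(abs(r - median(r)))
  dF <- F[i_med] - f_eq0
  k_off0 <- if (dF > 0) {
    exp(-gam) * r[i_med] / (f_beta0 * expm1(dF / f_beta0))
  } else {
    median(r) / f_beta0
  }
  if (!is.finite(k_off0) || k_off0 <= 0) k_off0 <- median(r) / f_beta0
  c(f_eq = f_eq0, f_beta = f_beta0, k_off = k_off0)
}

#' @export
print.fndy_fit <- function(x, ...) {
  cat("<fndy_fit>", nrow(x$data), "points,",
      if (x$binned) "binned," else "per-event,",
      x$iterations, "LM iterations,",
      if (x$converged) "converged" else "NOT CONVERGED", "\n")
  lab <- c("f_eq (pN)", "f_beta (pN)", "k_off (1/s)")
  for (i in 1:3) {
    cat(sprintf("  %-12s %10.4g +/- %.3g   %g%% CI [%.4g, %.4g]\n",
                lab[i], x$estimates[i], x$se[i], 100 * x$conf_level,
                x$ci[i, 1], x$ci[i, 2]))
  }
  d <- x$derived
  cat(sprintf("  x_t = %.3g A, tau0 = %.3g ms, delta_G = %s kcal/mol\n",
              d$x_t_A, d$tau0_ms,
              if (is.na(d$delta_G_kcal_mol)) "NA (k_c not supplied)"
              else sprintf("%.3g", d$delta_G_kcal_mol)))
  invisible(x)
}

#' Tidy method for FNdY fits
#'
#' @param x An `fndy_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @method tidy fndy_fit
#' @export
tidy.fndy_fit <- function(x, ...) {
  tibble(term = c("f_eq_pN", "f_beta_pN", "k_off_per_s"),
         estimate = unname(x$estimates),
         std.error = unname(x$se),
         conf.low = unname(x$ci[, "low"]),
         conf.high = unname(x$ci[, "high"]))
}

#' Glance method for FNdY fits
#'
#' @param x An `fndy_fit`.
#' @param ... Unused.
#' @return One-row tibble of fit diagnostics.
#' @method glance fndy_fit
#' @export
glance.fndy_fit <- function(x, ...) {
  tibble(n = nrow(x$data), df.residual = x$df_residual,
         deviance = x$deviance, sigma = x$sigma,
         iterations = x$iterations, converged = x$converged,
         binned = x$binned)
}

#' Predict mean rupture force with confidence / prediction bands
#'
#' @param object An `fndy_fit`.
#' @param newdata Optional tibble with column `loading_rate_pN_per_s`.
#' @param interval `"none"`, `"confidence"` or `"prediction"` (bands at the
#'   fit's `conf_level`, default 99%).
#' @param ... Unused.
#' @return Tibble with `loading_rate_pN_per_s`, `fit` and, for bands, `lwr`
#'   and `upr`.
#' @export
predict.fndy_fit <- function(object, newdata = NULL,
                             interval = c("none", "confidence", "prediction"),
                             ...) {
  interval <- match.arg(interval)
  r <- if (is.null(newdata)) object$data$loading_rate_pN_per_s
       else newdata$loading_rate_pN_per_s
  est <- object$estimates
  fit <- fndy_mean_force(r, est[1], est[2], est[3])
  out <- tibble(loading_rate_pN_per_s = r, fit = fit)
  if (interval != "none") {
    Jlog <- fndy_gradient(r, est[1], est[2], est[3]) %*% diag(est)
    var_fit <- rowSums((Jlog %*% object$cov_log) * Jlog)
    if (interval == "prediction") var_fit <- var_fit + object$sigma^2
    tq <- qt(1 - (1 - object$conf_level) / 2, df = max(object$df_residual, 1))
    out$lwr <- fit - tq * sqrt(var_fit)
    out$upr <- fit + tq * sqrt(var_fit)
  }
  out
}

#' Plot a dynamic force spectrum with its FNdY fit
#'
#' @param object An `fndy_fit`.
#' @param ... Unused.
#' @return A ggplot: rupture force vs log10 loading rate, fitted curve, and
#'   confidence (dashed) and prediction (shaded) bands.
#' @method autoplot fndy_fit
#' @export
autoplot.fndy_fit <- function(object, ...) {
  rr <- range(object$data$loading_rate_pN_per_s)
  grid <- tibble(loading_rate_pN_per_s =
                   exp(seq(log(rr[1]), log(rr[2]), length.out = 200)))
  cb <- predict(object, grid, interval = "confidence")
  pb <- predict(object, grid, interval = "prediction")
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$loading_rate_pN_per_s,
                               y = .data$rupture_force_pN)) +
    ggplot2::geom_ribbon(data = pb,
                         ggplot2::aes(x = .data$loading_rate_pN_per_s,
                                      ymin = .data$lwr, ymax = .data$upr),
                         inherit.aes = FALSE, alpha = 0.15) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(data = cb,
                       ggplot2::aes(x = .data$loading_rate_pN_per_s, y = .data$fit),
                       colour = "red", inherit.aes = FALSE) +
    ggplot2::geom_line(data = cb,
                       ggplot2::aes(x = .data$loading_rate_pN_per_s, y = .data$lwr),
                       linetype = "dashed", colour = "red", inherit.aes = FALSE) +
    ggplot2::geom_line(data = cb,
                       ggplot2::aes(x = .data$loading_rate_pN_per_s, y = .data$upr),
                       linetype = "dashed", colour = "red", inherit.aes = FALSE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Loading rate (pN/s)", y = "Rupture force (pN)")
}
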