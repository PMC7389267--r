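test_that("mean rupture force has the right limits and analytic values", {
  f_eq <- 36.2; f_beta <- 67.46; k_off <- 732.4
  gam <- afm_constants()$gamma_euler

  expect_equal(fndy_mean_force(0, f_eq, f_beta, k_off), f_eq)
  r_half <- exp(gam) * k_off * f_beta
  expect_equal(fndy_mean_force(r_half, f_eq, f_beta, k_off),
               f_eq + f_beta * log(2), tolerance = 1e-12)

  rs <- exp(seq(log(1), log(1e6), length.out = 100))
  F <- fndy_mean_force(rs, f_eq, f_beta, k_off)
  expect_true(all(diff(F) > 0))
  # concave in r, and the slope vs ln r saturates at f_beta from below
  rs_lin <- seq(100, 1e5, length.out = 200)
  expect_true(all(diff(fndy_mean_force(rs_lin, f_eq, f_beta, k_off),
                       differences = 2) < 0))
  slopes <- diff(F) / diff(log(rs))
  expect_true(all(diff(slopes) > 0))
  expect_lt(max(slopes), f_beta)

  expect_error(fndy_mean_force(100, -1, f_beta, k_off), "positive")
  expect_error(fndy_mean_force(-5, f_eq, f_beta, k_off), ">= 0")
})

test_that("derived landscape quantities match the published bond lifetimes", {
  p <- table2_params()
  for (i in seq_len(nrow(p))) {
    d <- derive_landscape(p$f_eq[i], p$f_beta[i], p$k_off[i], k_c = 10)
    expect_equal(d$tau0_ms, p$tau0_ms_printed[i], tolerance = 0.011,
                 label = paste("tau0", p$pair[i]))
    expect_equal(d$x_t_A, p$x_t_A[i], tolerance = 1e-6)
  }
})

test_that("derived quantities follow their defining identities exactly", {
  # x_t inverts the thermal-force definition
  d <- derive_landscape(50, 67.42, 500, k_c = 10)
  expect_equal(d$x_t_A, 10 * 0.0138065 * 293.15 / 67.42, tolerance = 1e-12)
  expect_equal(round(d$x_t_A, 3), 0.600)
  # |delta_G| = f_eq^2 / (2 k_c): 88.1 pN at 10 pN/nm -> 388.1 pN nm
  d2 <- derive_landscape(88.1, 404.74, 113.6, k_c = 10)
  expect_equal(d2$delta_G_pN_nm, -88.1^2 / 20, tolerance = 1e-12)
  expect_equal(d2$delta_G_kcal_mol, -55.86, tolerance = 1e-3)
  # tau0 = 1000 / k_off ms
  expect_equal(d2$tau0_ms, 1000 / 113.6, tolerance = 1e-12)
  # missing k_c: delta_G omitted with warning, never guessed
  expect_warning(d3 <- derive_landscape(50, 100, 500), "k_c")
  expect_true(is.na(d3$delta_G_kcal_mol))
  expect_false(is.na(d3$tau0_ms))
})

test_that("sampler is deterministic under a fixed seed and needs one", {
  a <- sample_rupture_forces(36.2, 67.46, 732.4, n_per_rate = 50, seed = 71)
  b <- sample_rupture_forces(36.2, 67.46, 732.4, n_per_rate = 50, seed = 71)
  expect_identical(a$rupture_force_pN, b$rupture_force_pN)
  expect_error(sample_rupture_forces(36.2, 67.46, 732.4), "seed")
})

test_that("sampler collapses to f_eq in the ramp-independent limit", {
  d <- sample_rupture_forces(50, 0.1, 500, n_per_rate = 100, seed = 72)
  expect_lt(max(abs(d$rupture_force_pN - 50)), 2)
})

test_that("sampler mean matches the exact first-passage mean", {
  # oracle: numeric quadrature of the survival function (helper)
  p <- table2_params()
  for (i in c(1, 4)) {
    rs <- c(100, 2000, 20000)
    d <- sample_rupture_forces(p$f_eq[i], p$f_beta[i], p$k_off[i],
                               loading_rates = rs, n_per_rate = 4000,
                               seed = 700 + i)
    emp <- tapply(d$rupture_force_pN, d$loading_rate_pN_per_s, mean)
    se <- tapply(d$rupture_force_pN, d$loading_rate_pN_per_s, sd) / sqrt(4000)
    exact <- exact_mean_rupture(as.numeric(names(emp)),
                                p$f_eq[i], p$f_beta[i], p$k_off[i])
    expect_true(all(abs(emp - exact) < 4 * se + 0.002 * exact),
                label = paste("sampler mean vs quadrature,", p$pair[i]))
  }
})

test_that("fit recovers exact-model parameters to < 0.5% (self-consistency)", {
  p <- table2_params()[1, ]
  rs <- exp(seq(log(100), log(20000), length.out = 12))
  d <- tibble::tibble(
    loading_rate_pN_per_s = rs,
    rupture_force_pN = fndy_mean_force(rs, p$f_eq, p$f_beta, p$k_off))
  fit <- fit_fndy(d)
  expect_true(fit$converged)
  expect_equal(fit$estimates[["f_eq"]], p$f_eq, tolerance = 5e-3)
  expect_equal(fit$estimates[["f_beta"]], p$f_beta, tolerance = 5e-3)
  expect_equal(fit$estimates[["k_off"]], p$k_off, tolerance = 5e-3)
})

test_that("binned and unbinned fits agree on noiseless model data", {
  p <- table2_params()[1, ]
  # replicated rates: each log-spaced bin then summarises exactly one rate
  rs <- rep(exp(seq(log(100), log(20000), length.out = 12)), each = 4)
  d <- tibble::tibble(
    loading_rate_pN_per_s = rs,
    rupture_force_pN = fndy_mean_force(rs, p$f_eq, p$f_beta, p$k_off))
  f1 <- fit_fndy(d)
  f2 <- fit_fndy(d, binned = TRUE, n_bins = 12)
  for (nm in c("f_eq", "f_beta", "k_off")) {
    expect_equal(f2$estimates[[nm]], f1$estimates[[nm]], tolerance = 5e-3,
                 label = nm)
  }
})

test_that("derived identities hold for every fit result", {
  d <- sample_rupture_forces(52.7, 134.9, 1046.7, n_per_rate = 100, seed = 73)
  fit <- fit_fndy(d, k_c = 15)
  est <- fit$estimates
  expect_equal(fit$derived$tau0_ms, 1000 / est[["k_off"]], tolerance = 1e-12)
  expect_equal(fit$derived$x_t_A, 10 * 0.0138065 * 293.15 / est[["f_beta"]],
               tolerance = 1e-12)
  expect_equal(fit$derived$delta_G_pN_nm, -est[["f_eq"]]^2 / (2 * 15),
               tolerance = 1e-12)
})

test_that("poorly conditioned spectra trigger a warning", {
  d <- tibble::tibble(loading_rate_pN_per_s = rep(1000, 30),
                      rupture_force_pN = withr::with_seed(74, rnorm(30, 60, 5)))
  expect_warning(try(fit_fndy(d), silent = TRUE), "poorly conditioned")
})

test_that("tidy, glance and predict expose the fit", {
  d <- sample_rupture_forces(36.2, 67.46, 732.4, n_per_rate = 80, seed = 75)
  fit <- fit_fndy(d)
  td <- tidy(fit)
  expect_identical(td$term, c("f_eq_pN", "f_beta_pN", "k_off_per_s"))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_lte(gl$iterations, 500)

  pr <- predict(fit, tibble::tibble(loading_rate_pN_per_s = c(100, 1000)),
                interval = "prediction")
  cf <- predict(fit, tibble::tibble(loading_rate_pN_per_s = c(100, 1000)),
                interval = "confidence")
  expect_true(all(pr$lwr < cf$lwr & cf$upr < pr$upr))
  expect_true(all(cf$lwr < cf$fit & cf$fit < cf$upr))
})

test_that("binning validates input and reduces points", {
  d <- sample_rupture_forces(36.2, 67.46, 732.4, n_per_rate = 100, seed = 76)
  b <- bin_dfs(d, n_bins = 8)
  expect_lte(nrow(b), 8)
  expect_true(all(b$n >= 1))
  expect_equal(sum(b$n), nrow(d))
  expect_true(all(diff(b$loading_rate_pN_per_s) > 0))
  expect_error(bin_dfs(d, n_bins = 2), ">= 3")
  # rates clustered at the range ends leave middle bins empty
  r_clust <- c(seq(100, 150, length.out = 10), seq(900, 1000, length.out = 10))
  d1 <- tibble::tibble(loading_rate_pN_per_s = r_clust,
                       rupture_force_pN = fndy_mean_force(r_clust, 36, 67, 700))
  expect_warning(b1 <- bin_dfs(d1, n_bins = 8), "non-empty bins")
  expect_lt(nrow(b1), 8)
})
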