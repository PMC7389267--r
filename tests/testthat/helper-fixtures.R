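# Energy-landscape parameter sets of the four probe/substrate pairs
# (lectins and antibodies vs their cognate cell-wall polysaccharides),
# with the thermal force reconstructed from the barrier width at 293.15 K.
table2_params <- function() {
  p <- tibble::tibble(
    pair = c("anti_b13_laminarin", "anti_b16_gentiobiose",
             "conA_mannan", "WGA_chitopentaose"),
    x_t_A = c(0.6, 0.3, 0.2, 0.1),
    f_eq = c(36.2, 52.7, 35.3, 88.1),
    k_off = c(732.4, 1046.7, 569.9, 113.6),
    tau0_ms_printed = c(1.37, 0.96, 1.75, 8.81))
  p$f_beta <- 10 * 0.0138065 * 293.15 / p$x_t_A   # kBT / x_t, A -> pN
  p
}

# Independent oracle for the mean rupture force of the first-passage law:
# E[F] = f_eq + integral_0^inf S(f) df with
# S(f) = exp(-(f_beta*k_off/r) * (exp(f/f_beta) - 1)), by numeric quadrature.
exact_mean_rupture <- function(r, f_eq, f_beta, k_off) {
  vapply(r, function(ri) {
    b <- f_beta * k_off / ri
    f_eq + stats::integrate(function(f) exp(-b * expm1(f / f_beta)),
                            0, Inf, rel.tol = 1e-10)$value
  }, numeric(1))
}

# Flat synthetic retract-only curve builder for low-level detection tests.
flat_curve <- function(n = 1024, noise_sigma = 0, seed = 1, z_range = 600,
                       tilt = 0, offset = 0, events = NULL, ...) {
  cv <- synthesize_curve(events = events, noise_sigma = noise_sigma,
                         z_range = z_range, seed = seed, ...)
  if (tilt != 0 || offset != 0) {
    cv$force_pN <- cv$force_pN + offset + tilt * cv$height_nm
  }
  cv
}
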