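# Shared fixtures built in code.

# noise-free homogeneous sphere dataset (R in A) with a realistic sigma model
sphere_dataset <- function(radius = 243, q = exp(seq(log(0.004), log(0.25),
                                                     length.out = 150)),
                           contrast = 4, phi = 0.01, noise_pct = 0,
                           seed = 1) {
  p <- core_shell_params(radius, 0, contrast, contrast, 0, phi)
  iv <- core_shell_intensity(q, p)
  sigma <- noise_pct / 100 * iv + 1e-4 * iv[1]
  if (noise_pct > 0) {
    set.seed(seed)
    iv <- iv + sigma * rnorm(length(iv))
  }
  sas_dataset(q, iv, sigma)
}

rg_sphere <- function(radius) sqrt(3 / 5) * radius

# contrast-weighted analytic Rg of a radial SLD profile, by direct quadrature
rg_profile_oracle <- function(rc, rt, drho_core, drho_shell) {
  r <- seq(0, rt, length.out = 20001)
  drho <- ifelse(r <= rc, drho_core, drho_shell)
  sqrt(pracma::trapz(r, r^4 * drho) / pracma::trapz(r, r^2 * drho))
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
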