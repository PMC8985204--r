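# Core-shell sphere forward model.

test_that("sphere kernel limits, root and continuity", {
  expect_identical(sphere_kernel(0), 1)
  # first root of tan x = x, located independently by bisection
  f <- function(x) tan(x) - x
  lo <- 4.4; hi <- 4.6
  for (k in 1:60) { mid <- (lo + hi) / 2; if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid }
  expect_lt(abs(sphere_kernel((lo + hi) / 2)), 1e-10)
  expect_lt(abs(sphere_kernel(4.4934)), 1e-4)
  expect_equal(sphere_kernel(pi), 3 / pi^2, tolerance = 1e-12)
  # series/direct branches join smoothly
  expect_equal(sphere_kernel(1e-3 - 1e-9), sphere_kernel(1e-3 + 1e-9),
               tolerance = 1e-9)
  expect_error(sphere_kernel(-0.1), ">= 0")
})

test_that("degenerate contrasts collapse to the homogeneous sphere", {
  q <- exp(seq(log(0.002), log(0.4), length.out = 80))
  sphere <- core_shell_params(220, 0, 2, 5, 6.35, 0.01)
  # equal core/shell SLD: homogeneous sphere of the total radius
  shell_eq <- core_shell_params(200, 20, 2, 2, 6.35, 0.01)
  ref_t <- core_shell_params(220, 0, 2, 9, 6.35, 0.01)
  expect_equal(core_shell_intensity(q, shell_eq), core_shell_intensity(q, ref_t),
               tolerance = 1e-14)
  # zero thickness: homogeneous sphere of the core radius
  thick0 <- core_shell_params(220, 0, 2, 9.9, 6.35, 0.01)
  expect_equal(core_shell_intensity(q, thick0), core_shell_intensity(q, sphere),
               tolerance = 1e-14)
})

test_that("forward limit matches the closed-form volume-weighted contrast", {
  rc <- 200; th <- 20; rt <- rc + th; phi <- 0.01; bkg <- 0.05
  vc <- 4 / 3 * pi * rc^3; vt <- 4 / 3 * pi * rt^3
  drho_eff <- (3.0 - 6.35) + vc / vt * (1.0 - 3.0)
  p <- core_shell_params(rc, th, 1.0, 3.0, 6.35, phi, background = bkg)
  expect_rel(core_shell_intensity(1e-6, p) - bkg, 1e-4 * phi * vt * drho_eff^2,
             1e-8)
})

test_that("intensity obeys scale linearity, contrast square law and zero-contrast null", {
  q <- exp(seq(log(0.003), log(0.3), length.out = 60))
  base <- core_shell_params(200, 15, 0.15, 3.3, 6.35, 0.01, 0.2, background = 0.1)
  i1 <- polydisperse_intensity(q, base)
  # doubling phi doubles I - background
  p2 <- base; p2$volume_fraction <- 0.02
  expect_equal(polydisperse_intensity(q, p2) - 0.1, 2 * (i1 - 0.1),
               tolerance = 1e-12)
  # scaling all SLD differences by c scales I - background by c^2
  c_ <- 2.5
  p3 <- core_shell_params(200, 15, 6.35 + c_ * (0.15 - 6.35),
                          6.35 + c_ * (3.3 - 6.35), 6.35, 0.01, 0.2,
                          background = 0.1)
  expect_equal(polydisperse_intensity(q, p3) - 0.1, c_^2 * (i1 - 0.1),
               tolerance = 1e-10)
  # equal SLDs everywhere: pure background
  p0 <- core_shell_params(200, 15, 2.2, 2.2, 2.2, 0.01, 0.2, background = 0.07)
  expect_equal(polydisperse_intensity(q, p0), rep(0.07, length(q)),
               tolerance = 1e-14)
  expect_true(all(polydisperse_intensity(q, base) >= 0))
})

test_that("polydisperse quadrature reduces to monodisperse and matches Monte Carlo", {
  q <- exp(seq(log(0.003), log(0.2), length.out = 60))
  p0 <- core_shell_params(200, 15, 0.15, 3.3, 6.35, 0.009, 0)
  expect_equal(polydisperse_intensity(q, p0), core_shell_intensity(q, p0),
               tolerance = 1e-12)
  expect_error(polydisperse_intensity(q, p0, n_points = 10), ">= 15")
  # brute-force Monte-Carlo oracle over the same truncated Gaussian
  p <- core_shell_params(200, 15, 0.15, 3.3, 6.35, 0.009, 0.2)
  set.seed(99)
  r <- rnorm(1.6e6, 200, 40)
  r <- r[r >= 200 - 120 & r <= 200 + 120][1:4e5]
  vc <- 4 / 3 * pi * r^3; vt <- 4 / 3 * pi * (r + 15)^3
  imc <- vapply(q, function(qi) {
    f <- vt * (3.3 - 6.35) * sphere_kernel(qi * (r + 15)) +
      vc * (0.15 - 3.3) * sphere_kernel(qi * r)
    mean(f^2)
  }, numeric(1)) * 1e-4 * 0.009 / mean(vt)
  expect_lt(max(abs(polydisperse_intensity(q, p) / imc - 1)), 0.005)
})

test_that("polydispersity smears the first form-factor minimum monotonically", {
  q <- seq(0.01, 0.05, length.out = 400)
  ratios <- vapply(c(0, 0.05, 0.1, 0.2, 0.3), function(pd) {
    p <- core_shell_params(220, 0, 2, 2, 6.35, 0.01, pd)
    iv <- polydisperse_intensity(q, p)
    k <- which.min(iv)
    min(iv) / max(iv[seq_len(k)])
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("Percus-Yevick structure factor limits and dilute bound", {
  q <- exp(seq(log(1e-4), log(0.5), length.out = 100))
  expect_equal(hs_structure_factor(q, 243, 0), rep(1, length(q)))
  # compressibility limit, exact
  phi <- 0.092
  expect_equal(hs_structure_factor(0, 243, phi),
               (1 - phi)^4 / (1 + 2 * phi)^2, tolerance = 1e-12)
  expect_equal(hs_structure_factor(0, 243, 0.092), 0.485, tolerance = 1e-3)
  # SANS dilution regime: the largest deviation from 1 is the q = 0 limit,
  # 1 - (1-phi)^4/(1+2phi)^2 = 6.9% at phi = 0.009, and decays with q
  s_dil <- hs_structure_factor(q, 215, 0.009)
  bound <- 1 - (1 - 0.009)^4 / (1 + 2 * 0.009)^2
  expect_lt(max(abs(s_dil - 1)), bound + 1e-12)
  expect_lt(max(abs(s_dil[q > 0.05] - 1)), 0.01)
  expect_error(hs_structure_factor(q, 243, 0.5), "0.5")
  # series and direct branches agree around the threshold
  a_thr <- 0.05 / (2 * 243)
  expect_equal(hs_structure_factor(a_thr * 0.999, 243, 0.2),
               hs_structure_factor(a_thr * 1.001, 243, 0.2), tolerance = 1e-6)
})

test_that("Guinier analysis recovers sphere and core-shell radii of gyration", {
  q <- exp(seq(log(0.001), log(0.05), length.out = 150))
  iv <- core_shell_intensity(q, core_shell_params(243, 0, 2, 2, 6.35, 0.01))
  g <- guinier_fit(q, iv)
  expect_rel(g$rg, rg_sphere(243), 0.01)
  expect_rel(g$i0, core_shell_intensity(1e-8, core_shell_params(243, 0, 2, 2, 6.35, 0.01)), 0.01)
  # contrast-weighted core-shell Rg against the direct integral oracle
  p <- core_shell_params(200, 20, 0.15, 3.3, 6.35, 0.01)
  rg_ref <- rg_profile_oracle(200, 220, 0.15 - 6.35, 3.3 - 6.35)
  g2 <- guinier_fit(q, core_shell_intensity(q, p))
  expect_rel(g2$rg, rg_ref, 0.01)
  # flat curve has no defined radius
  expect_error(guinier_fit(q, rep(3, length(q))), "Rg")
  expect_error(guinier_fit(q[1:4], iv[1:4]), "few")
})

test_that("parameter validation rejects unphysical core-shell settings", {
  expect_error(core_shell_params(-1, 0, 1, 1, 1, 0.1), "core_radius")
  expect_error(core_shell_params(100, -2, 1, 1, 1, 0.1), "shell_thickness")
  expect_error(core_shell_params(100, 0, 1, 1, 1, 0.9), "volume_fraction")
  expect_error(core_shell_params(100, 0, 1, 1, 1, 0.1, polydispersity = 1.2),
               "polydispersity")
  p <- core_shell_params(100, 0, 1, 2, 3, 0.1)
  expect_error(core_shell_intensity(c(-0.1, 0.1), p), "positive")
})
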