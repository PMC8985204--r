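# Core-shell sphere forward model on absolute scale.
#
# I(Q) = 1e-4 * (phi / <V_t>) * <F^2(Q)> * S(Q) + background   [cm^-1]
# F(Q) = V_t (rho_shell - rho_solv) Phi(Q R_t) + V_c (rho_core - rho_shell) Phi(Q R_c)
# with SLDs numerically on the 10^-6 A^-2 scale, lengths in A, and
# Phi(x) = 3 (sin x - x cos x) / x^3 the homogeneous-sphere amplitude kernel.
# The 1e-4 prefactor is the A -> cm unit conversion under this SLD scaling.
# Polydispersity is a Gaussian number distribution of the core radius at fixed
# shell thickness, averaged as <F^2>/<V_t> so the fitted volume fraction keeps
# its dilute-suspension meaning; the number density n = phi/<V_t> is always
# derived, never a free parameter.

.I_PREFACTOR <- 1e-4

#' Homogeneous sphere amplitude kernel
#'
#' \code{Phi(x) = 3 (sin x - x cos x) / x^3}, with a series expansion below
#' \code{x = 1e-3} so \code{Phi(0) = 1} exactly and the function is smooth.
#'
#' @param x numeric vector, \code{>= 0} (typically \code{q * R}).
#' @return Kernel values; \code{Phi(0) = 1}, first zero at \code{x = 4.4934}.
#' @export
sphere_kernel <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) stop("x must be finite numeric")
  if (any(x < 0)) stop("x must be >= 0")
  out <- x
  small <- x < 1e-3
  xs <- x[small]
  out[small] <- 1 - xs^2 / 10 + xs^4 / 280
  xl <- x[!small]
  out[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

#' Core-shell sphere model parameters
#'
#' @param core_radius core radius, A, > 0.
#' @param shell_thickness shell thickness, A, >= 0.
#' @param sld_core,sld_shell,sld_solvent SLDs on the 10^-6 A^-2 scale.
#' @param volume_fraction particle volume fraction, in (0, 0.74).
#' @param polydispersity relative width (sigma/mean) of the Gaussian core
#'   radius distribution, >= 0 and < 1.
#' @param background flat incoherent background, cm^-1, >= 0.
#' @return An object of class \code{core_shell_params}.
#' @export
core_shell_params <- function(core_radius, shell_thickness,
                              sld_core, sld_shell, sld_solvent,
                              volume_fraction, polydispersity = 0,
                              background = 0) {
  stopifnot(is.numeric(core_radius), is.numeric(shell_thickness),
            is.numeric(sld_core), is.numeric(sld_shell), is.numeric(sld_solvent),
            is.numeric(volume_fraction), is.numeric(polydispersity),
            is.numeric(background))
  if (core_radius <= 0) stop("core_radius must be > 0")
  if (shell_thickness < 0) stop("shell_thickness must be >= 0")
  if (volume_fraction <= 0 || volume_fraction >= 0.74)
    stop("volume_fraction must lie in (0, 0.74)")
  if (polydispersity < 0 || polydispersity >= 1)
    stop("polydispersity must lie in [0, 1)")
  if (background < 0) stop("background must be >= 0")
  structure(list(core_radius = core_radius, shell_thickness = shell_thickness,
                 sld_core = sld_core, sld_shell = sld_shell,
                 sld_solvent = sld_solvent, volume_fraction = volume_fraction,
                 polydispersity = polydispersity, background = background),
            class = "core_shell_params")
}

#' @export
print.core_shell_params <- function(x, ...) {
  cat(sprintf(paste0("<core-shell sphere> Rc = %.1f A, t = %.1f A, pd = %.3f, ",
                     "phi = %.4g\n  SLD core/shell/solvent = %.3f / %.3f / %.3f ",
                     "(1e-6 A^-2), bkg = %.3g cm^-1\n"),
              x$core_radius, x$shell_thickness, x$polydispersity,
              x$volume_fraction, x$sld_core, x$sld_shell, x$sld_solvent,
              x$background))
  invisible(x)
}

# F(q; r_core) for a vector of radii; returns |F| matrix [length(q) x length(rc)]
# and total-particle volumes. SLDs on the 1e-6 scale.
.cs_amplitude <- function(q, rc, thickness, sld_core, sld_shell, sld_solvent) {
  rt <- rc + thickness
  vc <- (4 / 3) * pi * rc^3
  vt <- (4 / 3) * pi * rt^3
  # outer(q, r) kernels
  phi_t <- sphere_kernel(outer(q, rt))
  phi_c <- sphere_kernel(outer(q, rc))
  f <- sweep(phi_t, 2, vt * (sld_shell - sld_solvent), `*`) +
       sweep(phi_c, 2, vc * (sld_core - sld_shell), `*`)
  list(f = f, vt = vt)
}

#' Monodisperse core-shell sphere intensity
#'
#' Absolute-scale scattering intensity of identical core-shell spheres.
#' With \code{sld_shell == sld_core} or \code{shell_thickness == 0} this
#' collapses to the homogeneous sphere of the total or core radius.
#'
#' @param q scattering vector magnitudes, A^-1, > 0.
#' @param p \code{\link{core_shell_params}}.
#' @param s_q optional structure factor values at \code{q} (defaults to 1,
#'   the dilute limit); see \code{\link{hs_structure_factor}}.
#' @return Intensity in cm^-1.
#' @export
core_shell_intensity <- function(q, p, s_q = NULL) {
  stopifnot(inherits(p, "core_shell_params"))
  if (!is.numeric(q) || any(!is.finite(q)) || any(q <= 0))
    stop("q must be positive and finite (A^-1)")
  if (is.null(s_q)) s_q <- 1
  a <- .cs_amplitude(q, p$core_radius, p$shell_thickness,
                     p$sld_core, p$sld_shell, p$sld_solvent)
  drop(.I_PREFACTOR * p$volume_fraction * a$f[, 1]^2 / a$vt * s_q + p$background)
}

# Gaussian quadrature nodes/weights over the truncated radius distribution
.pd_nodes <- function(mean_r, pd, n_points) {
  s <- pd * mean_r
  lo <- max(mean_r - 3 * s, .Machine$double.eps)
  hi <- mean_r + 3 * s
  gl <- pracma::gaussLegendre(n_points, lo, hi)
  w <- gl$w * stats::dnorm(gl$x, mean_r, s)
  list(r = gl$x, w = w / sum(w))
}

#' Polydisperse core-shell sphere intensity
#'
#' Number-averages the core-shell intensity over a Gaussian distribution of
#' the core radius (mean \code{core_radius}, relative width
#' \code{polydispersity}), truncated at \code{max(0, mu - 3 sigma) .. mu + 3
#' sigma}, with fixed shell thickness, using Gauss-Legendre quadrature. The
#' average is \code{<F^2>/<V_t>}, so the fitted volume fraction stays
#' comparable between mono- and polydisperse fits. Reduces exactly to
#' \code{\link{core_shell_intensity}} at zero polydispersity.
#'
#' @inheritParams core_shell_intensity
#' @param n_points number of quadrature nodes, >= 15 (default 35).
#' @return Intensity in cm^-1.
#' @export
polydisperse_intensity <- function(q, p, n_points = 35, s_q = NULL) {
  stopifnot(inherits(p, "core_shell_params"))
  if (n_points < 15) stop("n_points must be >= 15 for quadrature accuracy")
  if (p$polydispersity == 0) return(core_shell_intensity(q, p, s_q = s_q))
  if (!is.numeric(q) || any(!is.finite(q)) || any(q <= 0))
    stop("q must be positive and finite (A^-1)")
  if (is.null(s_q)) s_q <- 1
  nd <- .pd_nodes(p$core_radius, p$polydispersity, n_points)
  a <- .cs_amplitude(q, nd$r, p$shell_thickness,
                     p$sld_core, p$sld_shell, p$sld_solvent)
  mean_f2 <- drop(a$f^2 %*% nd$w)
  mean_vt <- sum(a$vt * nd$w)
  .I_PREFACTOR * p$volume_fraction * mean_f2 / mean_vt * s_q + p$background
}

#' Percus-Yevick hard-sphere structure factor
#'
#' Analytic S(Q) for hard spheres of effective radius \code{r_eff} at volume
#' fraction \code{phi}. \code{S(0) = (1 - phi)^4 / (1 + 2 phi)^2} (the
#' compressibility limit) is reproduced exactly; a series expansion is used at
#' small \code{Q r_eff} to avoid catastrophic cancellation.
#'
#' @param q scattering vector magnitudes, A^-1, >= 0.
#' @param r_eff effective hard-sphere radius, A, > 0.
#' @param phi hard-sphere volume fraction, in [0, 0.5).
#' @return S(Q) values; identically 1 at \code{phi = 0}.
#' @export
hs_structure_factor <- function(q, r_eff, phi) {
  if (!is.numeric(q) || any(!is.finite(q)) || any(q < 0))
    stop("q must be >= 0 and finite")
  if (!is.numeric(r_eff) || r_eff <= 0) stop("r_eff must be > 0")
  if (!is.numeric(phi) || phi < 0 || phi >= 0.5)
    stop("phi must lie in [0, 0.5)")
  if (phi == 0) return(rep(1, length(q)))
  u <- (1 - phi)^4
  alpha <- (1 + 2 * phi)^2 / u
  beta <- -6 * phi * (1 + phi / 2)^2 / u
  gam <- phi * alpha / 2
  a <- 2 * q * r_eff
  g_over_a <- numeric(length(a))
  small <- a < 0.05
  as <- a[small]
  # G(A)/A -> alpha/3 + beta/4 + gamma/6 as A -> 0
  g_over_a[small] <- alpha * (1 / 3 - as^2 / 30) +
                     beta  * (1 / 4 - as^2 / 36) +
                     gam   * (1 / 6 - as^2 / 48)
  al <- a[!small]
  sa <- sin(al); ca <- cos(al)
  g <- alpha * (sa - al * ca) / al^2 +
       beta * (2 * al * sa + (2 - al^2) * ca - 2) / al^3 +
       gam * (-al^4 * ca + 4 * ((3 * al^2 - 6) * ca + (al^3 - 6 * al) * sa + 6)) / al^5
  g_over_a[!small] <- g / al
  1 / (1 + 24 * phi * g_over_a)
}

#' Guinier fit for the radius of gyration
#'
#' Weighted linear fit of \code{ln I} versus \code{q^2} over the low-Q
#' window, iterating the point selection until \code{q_max * Rg <= qrg_max}
#' stabilizes. By default a \code{q^4} curvature term is included in the
#' regression (Rg is still taken from the \code{q^2} coefficient); this
#' removes the leading-order window bias of the pure two-term Guinier fit,
#' which for a sphere at \code{qrg_max = 1.3} is about +1.6\%. Intensities
#' must be background-subtracted and positive over the window.
#'
#' @param q scattering vector, A^-1, increasing.
#' @param i intensities.
#' @param sigma optional uncertainties; when given, points are weighted by
#'   \code{(i/sigma)^2} (error propagation of \code{ln I}).
#' @param qrg_max Guinier validity cutoff (default 1.3).
#' @param correct_curvature include the \code{q^4} term (default TRUE).
#' @return List with \code{rg} (A), \code{i0} (extrapolated zero-angle
#'   intensity), \code{n_used}, and \code{qrg} actually reached.
#' @export
guinier_fit <- function(q, i, sigma = NULL, qrg_max = 1.3,
                        correct_curvature = TRUE) {
  stopifnot(is.numeric(q), is.numeric(i), length(q) == length(i))
  ord <- order(q)
  q <- q[ord]; i <- i[ord]
  if (!is.null(sigma)) sigma <- sigma[ord]
  gfit <- function(keep) {
    qs <- q[keep]; is_ <- i[keep]
    if (any(is_ <= 0)) stop("non-positive intensities in the Guinier window")
    w <- if (is.null(sigma)) rep(1, length(qs)) else (is_ / sigma[keep])^2
    X <- if (correct_curvature) cbind(1, qs^2, qs^4) else cbind(1, qs^2)
    stats::lm.wfit(X, log(is_), w)$coefficients
  }
  keep <- seq_len(min(length(q), max(5L, 10L)))
  rg <- NA_real_
  for (iter in 1:40) {
    if (length(keep) < 5) stop("too few low-q points for a Guinier fit")
    cf <- gfit(keep)
    slope <- cf[2]
    if (!is.finite(slope) || slope >= 0)
      stop("non-negative Guinier slope: Rg^2 < 0, radius of gyration undefined")
    rg_new <- sqrt(-3 * slope)
    if (rg_new * q[1] > qrg_max)
      stop("no data below q*Rg = ", qrg_max, "; curve starts beyond the Guinier regime")
    keep_new <- which(q * rg_new <= qrg_max)
    if (length(keep_new) < 5) keep_new <- seq_len(5L)
    if (identical(keep_new, keep)) { rg <- rg_new; break }
    keep <- keep_new
    rg <- rg_new
  }
  if (!is.finite(rg) || rg <= 0)
    stop("Guinier fit did not converge to a positive Rg")
  if (rg * max(q[keep]) < 0.1)
    stop("non-negative Guinier slope: Rg^2 indistinguishable from zero ",
         "(flat curve over the accessible window)")
  cf <- gfit(keep)
  list(rg = sqrt(-3 * cf[[2]]), i0 = exp(cf[[1]]),
       n_used = length(keep), qrg = max(q[keep]) * rg)
}
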