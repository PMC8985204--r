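# Synthetic contrast-series generator.
#
# Emulates the measurement design the analysis is built for: four SANS
# solvent/core contrasts (h/d core in H2O/D2O) of polydisperse core-shell
# spheres with TOF-pinhole Gaussian Q resolution, and point-collimation SAXS
# of the same particles. Noise is multiplicative Gaussian (a counting-
# statistics proxy appropriate to reduced data with Gaussian error bars) with
# a small floor, and the recorded sigma column is the true noise scale.

#' Instrument description with its Q grid
#'
#' \code{"saxs"}: 200 log-spaced points, 0.0076-3 A^-1 (the SAXS collection
#' starts at 0.076 nm^-1), point collimation so no Q smearing.
#' \code{"sans"}: 120 log-spaced points, 0.003-0.7 A^-1 with a constant
#' fractional resolution delta-Q/Q = 0.08.
#'
#' @param kind \code{"saxs"} or \code{"sans"}.
#' @return Object of class \code{sas_instrument}: radiation, wavelength (A),
#'   \code{q} grid (A^-1) and per-point \code{dq} (Gaussian sigma_Q, A^-1).
#' @export
make_q_grid <- function(kind = c("saxs", "sans")) {
  kind <- match.arg(kind)
  if (kind == "saxs") {
    q <- exp(seq(log(0.0076), log(3), length.out = 200))
    structure(list(radiation = "xray", wavelength = 1.541, q = q,
                   dq = rep(0, length(q)), kind = kind),
              class = "sas_instrument")
  } else {
    q <- exp(seq(log(0.003), log(0.7), length.out = 120))
    structure(list(radiation = "neutron", wavelength = NA_real_, q = q,
                   dq = 0.08 * q, kind = kind),
              class = "sas_instrument")
  }
}

#' Define a synthetic measurement scenario
#'
#' @param name scenario name.
#' @param truth named list of true structural parameters: core_radius (A),
#'   shell_thickness (A), polydispersity, hydration, volume_fraction.
#' @param contrasts data.frame with columns \code{core_kind} ("h"/"d"),
#'   \code{f_d2o} (D2O volume fraction) and \code{background} (cm^-1).
#' @param instrument a \code{\link{make_q_grid}} instrument.
#' @param noise_pct relative Gaussian noise, percent of intensity, >= 0.
#' @param concentration_mg_ml particle mass concentration.
#' @param temperature_c sample temperature tag.
#' @param seed integer seed; a fixed seed makes the output byte-identical.
#' @return Object of class \code{sas_scenario}.
#' @export
sas_scenario <- function(name, truth, contrasts, instrument,
                         noise_pct = 3, concentration_mg_ml = NA_real_,
                         temperature_c = 25, seed = 101L) {
  stopifnot(is.list(truth), is.data.frame(contrasts), nrow(contrasts) >= 1,
            inherits(instrument, "sas_instrument"))
  need <- c("core_radius", "shell_thickness", "polydispersity", "hydration",
            "volume_fraction")
  if (!all(need %in% names(truth)))
    stop("truth must name: ", paste(need, collapse = ", "))
  if (noise_pct < 0) stop("noise_pct must be >= 0")
  structure(list(name = name, truth = truth, contrasts = contrasts,
                 instrument = instrument, noise_pct = noise_pct,
                 concentration_mg_ml = concentration_mg_ml,
                 temperature_c = temperature_c, seed = as.integer(seed)),
            class = "sas_scenario")
}

.contrast_label <- function(core_kind, f_d2o) {
  solv <- if (f_d2o == 0) "H2O" else if (f_d2o == 1) "D2O"
          else sprintf("fd2o=%.4g", f_d2o)
  paste0(core_kind, "-core/", solv)
}

#' Simulate one contrast dataset of a scenario
#'
#' Evaluates the smeared polydisperse core-shell model at the scenario truth
#' with per-contrast SLDs from the composition module, then adds seeded
#' Gaussian noise with sigma = noise_pct/100 * I plus a floor of 1e-4 times
#' the lowest-Q intensity. The sigma column records the true noise scale.
#'
#' @param scenario a \code{\link{sas_scenario}}.
#' @param contrast_index row of the scenario's contrast table.
#' @param materials component set for the SLDs.
#' @return A \code{\link{sas_dataset}}.
#' @export
simulate_dataset <- function(scenario, contrast_index = 1L,
                             materials = lnc_materials()) {
  stopifnot(inherits(scenario, "sas_scenario"))
  ct <- scenario$contrasts[contrast_index, ]
  ins <- scenario$instrument
  tr <- scenario$truth
  if (ins$radiation == "neutron") {
    sld_core <- lnc_core_sld(ct$core_kind, "neutron", materials)
    sld_solv <- solvent_sld(ct$f_d2o)
    dry <- dry_shell_sld("neutron")
  } else {
    sld_core <- sld(materials$labrafac, "xray")
    sld_solv <- sld(materials$water, "xray")
    dry <- dry_shell_sld("xray")
  }
  sld_shell <- (1 - tr$hydration) * dry + tr$hydration * sld_solv
  p <- core_shell_params(tr$core_radius, tr$shell_thickness, sld_core,
                         sld_shell, sld_solv, tr$volume_fraction,
                         tr$polydispersity, background = 0)
  kernel <- if (all(ins$dq == 0)) resolution_kernel("none")
            else resolution_kernel("gaussian_pointwise", ins$dq)
  i_true <- smear(ins$q, function(qv) polydisperse_intensity(qv, p), kernel) +
    ct$background
  sigma <- scenario$noise_pct / 100 * i_true + 1e-4 * i_true[1]
  if (scenario$noise_pct > 0) {
    set.seed((scenario$seed * 97L + as.integer(contrast_index)) %% .Machine$integer.max)
    i_obs <- i_true + stats::rnorm(length(i_true)) * sigma
  } else {
    # zero noise: the dataset is exactly the smeared model; sigma keeps the
    # floor so weighted fits remain well defined
    i_obs <- i_true
  }
  sas_dataset(ins$q, i_obs, sigma, resolution = kernel,
              contrast_label = .contrast_label(ct$core_kind, ct$f_d2o),
              sld_solvent = sld_solv, sld_core = sld_core,
              radiation = ins$radiation,
              temperature_c = scenario$temperature_c,
              concentration_mg_ml = scenario$concentration_mg_ml)
}

#' Simulate every contrast of a scenario
#'
#' @inheritParams simulate_dataset
#' @return List of \code{\link{sas_dataset}}, one per contrast row.
#' @export
simulate_scenario <- function(scenario, materials = lnc_materials()) {
  lapply(seq_len(nrow(scenario$contrasts)), function(j)
    simulate_dataset(scenario, j, materials))
}

.sans_contrasts_4 <- function() {
  data.frame(core_kind = c("h", "h", "d", "d"),
             f_d2o = c(0, 1, 0, 1),
             background = c(0.8, 0.06, 0.8, 0.06))
}

#' Bundled measurement scenarios
#'
#' Ready-made scenario definitions for the LNC study conditions:
#' \describe{
#'   \item{unloaded}{4-contrast SANS series; core radius 200 A, shell 15 A,
#'     polydispersity 0.20, hydration 0.50, volume fraction 0.009.}
#'   \item{loaded}{drug-loaded counterpart: 202 A / 20 A / 0.25 / 0.70 /
#'     0.009.}
#'   \item{saxs_unloaded, saxs_loaded}{single-contrast X-ray sets at 62
#'     mg/mL, volume fraction 0.092; 217 A / 26 A / 0.20 and 185 A / 36 A /
#'     0.35.}
#'   \item{matched_core}{h-core SANS with the solvent at the core's contrast
#'     match point, so only the shell scatters.}
#'   \item{dilution}{list of three single-contrast (h-core/D2O) scenarios at
#'     1.24 / 3.1 / 6.2 mg/mL with volume fraction scaling accordingly.}
#' }
#'
#' @param noise_pct relative noise level, percent (default 3).
#' @param seed base seed.
#' @return Named list; \code{dilution} is itself a list of three scenarios.
#' @export
lnc_scenarios <- function(noise_pct = 3, seed = 101L) {
  sans <- make_q_grid("sans")
  saxs <- make_q_grid("saxs")
  tr_unl <- list(core_radius = 200, shell_thickness = 15,
                 polydispersity = 0.20, hydration = 0.50,
                 volume_fraction = 0.009)
  tr_load <- list(core_radius = 202, shell_thickness = 20,
                  polydispersity = 0.25, hydration = 0.70,
                  volume_fraction = 0.009)
  match_f <- match_point(lnc_core_sld("h"))
  dil_conc <- c(1.24, 3.1, 6.2)
  dilution <- lapply(seq_along(dil_conc), function(k) {
    tr <- tr_unl
    tr$volume_fraction <- 0.009 * dil_conc[k] / 6.2
    sas_scenario(paste0("dilution_", dil_conc[k]), tr,
                 data.frame(core_kind = "h", f_d2o = 1, background = 0.06),
                 sans, noise_pct, concentration_mg_ml = dil_conc[k],
                 seed = seed + 10L * k)
  })
  list(
    unloaded = sas_scenario("unloaded", tr_unl, .sans_contrasts_4(), sans,
                            noise_pct, 6.2, seed = seed),
    loaded = sas_scenario("loaded", tr_load, .sans_contrasts_4(), sans,
                          noise_pct, 6.2, seed = seed + 1L),
    saxs_unloaded = sas_scenario(
      "saxs_unloaded",
      list(core_radius = 217, shell_thickness = 26, polydispersity = 0.20,
           hydration = 0.50, volume_fraction = 0.092),
      data.frame(core_kind = "h", f_d2o = 0, background = 0.02),
      saxs, noise_pct, 62, seed = seed + 2L),
    saxs_loaded = sas_scenario(
      "saxs_loaded",
      list(core_radius = 185, shell_thickness = 36, polydispersity = 0.35,
           hydration = 0.50, volume_fraction = 0.092),
      data.frame(core_kind = "h", f_d2o = 0, background = 0.02),
      saxs, noise_pct, 62, seed = seed + 3L),
    matched_core = sas_scenario(
      "matched_core", tr_unl,
      data.frame(core_kind = "h", f_d2o = match_f, background = 0.1),
      sans, noise_pct, 6.2, seed = seed + 4L),
    dilution = dilution
  )
}
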