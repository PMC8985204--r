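# Bundled lipid-nanocapsule (LNC) materials.
#
# The formulation: a caprylic/capric triglyceride oil core (Labrafac),
# optionally blended with 5% deuterated octanoic/decanoic acids to raise the
# core's neutron SLD, surrounded by a PEG-15-hydroxystearate (Kolliphor HS 15)
# shell, dispersed in H2O/D2O. Kolliphor is represented by its ethylene-glycol
# repeat C20H40O4, the convention used by formulation SLD tables.

#' Bundled LNC formulation components
#'
#' Component definitions (formula + mass density) for the LNC system:
#' Labrafac oil, the deuterated octanoic-d15/decanoic-d19 acids, Kolliphor
#' HS 15 (as its C20H40O4 ethylene-glycol-repeat), and light/heavy water.
#' Densities are configurable defaults; the deuterated acid densities are the
#' protiated values scaled by the isotopic mass ratio.
#'
#' @param labrafac_density Labrafac mass density, g/cm^3 (default 0.94).
#' @param kolliphor_density Kolliphor HS 15 mass density, g/cm^3 (default 1.0).
#' @return Named list of \code{\link{component}} objects.
#' @export
lnc_materials <- function(labrafac_density = 0.94, kolliphor_density = 1.0) {
  list(
    labrafac    = component("Labrafac", "C8H16O2 + C10H20O2", labrafac_density),
    dc8         = component("octanoic-d15 acid", "C8D15O2H", 1.005),
    dc10        = component("decanoic-d19 acid", "C10D19O2H", 0.992),
    kolliphor   = component("Kolliphor HS 15", "C20H40O4", kolliphor_density),
    water       = component("light water", "H2O", 0.997),
    heavy_water = component("heavy water", "D2O", 1.107)
  )
}

#' Core SLD for the hydrogenous or deuterated oil core
#'
#' \code{"h"} is pure Labrafac; \code{"d"} is the 95:5 (w/w) blend of Labrafac
#' with the deuterated octanoic/decanoic acid mixture (5.89 : 0.17 : 0.14 mass
#' parts), combined by mass-to-volume-fraction conversion at the component
#' densities.
#'
#' @param kind \code{"h"} or \code{"d"}.
#' @param radiation \code{"neutron"} or \code{"xray"}.
#' @param materials component set, see \code{\link{lnc_materials}}.
#' @return Core SLD on the 10^-6 A^-2 scale.
#' @export
lnc_core_sld <- function(kind = c("h", "d"), radiation = c("neutron", "xray"),
                         materials = lnc_materials()) {
  kind <- match.arg(kind)
  radiation <- match.arg(radiation)
  if (kind == "h") return(sld(materials$labrafac, radiation))
  parts <- list(materials$labrafac, materials$dc8, materials$dc10)
  mass <- c(5.89, 0.17, 0.14)
  vf <- mass_to_volume_fractions(mass, vapply(parts, `[[`, numeric(1), "density"))
  mix_sld(vapply(parts, sld, numeric(1), radiation = radiation), vf)
}

#' Read a formulation composition document
#'
#' Parses a declarative YAML document describing a formulation: a list of
#' \code{components} (name, formula, density, optional mass_fraction), a
#' solvent \code{f_d2o} and an optional \code{temperature_c} tag.
#'
#' @param path YAML file path.
#' @return List with \code{components} (named list of
#'   \code{\link{component}}), \code{mass_fractions}, \code{f_d2o} and
#'   \code{temperature_c}.
#' @export
read_composition <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read composition documents")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$components) || !length(cfg$components))
    stop("composition document must list at least one component")
  comps <- list()
  mf <- numeric(0)
  for (cc in cfg$components) {
    if (is.null(cc$name) || is.null(cc$formula) || is.null(cc$density))
      stop("each component needs name, formula and density")
    comps[[cc$name]] <- component(cc$name, cc$formula, cc$density)
    mf[cc$name] <- if (is.null(cc$mass_fraction)) NA_real_ else cc$mass_fraction
  }
  f_d2o <- cfg$f_d2o %||% 0
  if (f_d2o < 0 || f_d2o > 1) stop("f_d2o must lie in [0, 1]")
  list(components = comps, mass_fractions = mf, f_d2o = f_d2o,
       temperature_c = cfg$temperature_c %||% NA_real_)
}

#' Dry shell SLD reference values
#'
#' Reference SLDs for the dry Kolliphor HS 15 shell material as tabulated by
#' standard SLD calculators for formulation work (neutron 0.13, X-ray 9.92,
#' both 10^-6 A^-2). These are the defaults used when converting a fitted
#' shell SLD to a hydration fraction; \code{\link{sld}} on the
#' \code{\link{lnc_materials}} component is available when a purely computed
#' value is preferred.
#'
#' @param radiation \code{"neutron"} or \code{"xray"}.
#' @return SLD on the 10^-6 A^-2 scale.
#' @export
dry_shell_sld <- function(radiation = c("neutron", "xray")) {
  radiation <- match.arg(radiation)
  c(neutron = 0.13, xray = 9.92)[[radiation]]
}
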