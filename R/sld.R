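# Composition -> scattering length density (SLD) arithmetic.
#
# Neutron SLDs use bound coherent scattering lengths (Sears-style tabulation,
# bundled below so results do not drift with external databases); X-ray SLDs
# use electron counts and the classical electron radius. All SLDs in this
# package are reported numerically on the 10^-6 A^-2 scale, the convention of
# small-angle scattering software and of published material tables.

# bound coherent scattering length, fm (1 fm = 1e-5 A)
.neutron_b <- c(
  H = -3.7390, D = 6.6710, C = 6.6460, N = 9.3600, O = 5.8030,
  F = 5.6540, Na = 3.6300, Mg = 5.3750, P = 5.1300, S = 2.8470,
  Cl = 9.5770, K = 3.6700, Ca = 4.7000, Br = 6.7950, I = 5.2800
)

# standard atomic weight, g/mol (D is the isotope mass)
.atomic_mass <- c(
  H = 1.00794, D = 2.01410, C = 12.0107, N = 14.0067, O = 15.9994,
  F = 18.99840, Na = 22.98977, Mg = 24.3050, P = 30.97376, S = 32.0650,
  Cl = 35.4530, K = 39.0983, Ca = 40.0780, Br = 79.9040, I = 126.90447
)

.atomic_number <- c(
  H = 1, D = 1, C = 6, N = 7, O = 8,
  F = 9, Na = 11, Mg = 12, P = 15, S = 16,
  Cl = 17, K = 19, Ca = 20, Br = 35, I = 53
)

.r_electron_A <- 2.818e-5     # classical electron radius, A
.avogadro_per_A3 <- 0.6022141 # N_A * 1e-24: converts g/mol / (g/cm3) to A^3

#' Parse a Hill-style chemical formula
#'
#' Accepts a single Hill-style formula (e.g. \code{"C20H40O4"}) or a
#' \code{"+"}-joined list of such formulas whose element counts are summed
#' (e.g. \code{"C8H16O2 + C10H20O2"}). Deuterium is written \code{"D"} or
#' \code{"d"} and is kept distinct from hydrogen. Underscores and whitespace
#' are ignored, so table-style spellings like \code{"C_8_d_15_O_2_H"} parse.
#'
#' @param text formula string.
#' @return An object of class \code{sas_formula}: a list with an integer
#'   vector \code{counts} named by element symbol.
#' @examples
#' parse_formula("H2O")
#' parse_formula("C8H16O2 + C10H20O2")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("formula must be a non-empty string")
  terms <- strsplit(text, "+", fixed = TRUE)[[1]]
  counts <- integer(0)
  for (term in terms) {
    s <- gsub("[_[:space:]]", "", term)
    if (!nzchar(s)) stop("empty term in formula: ", sQuote(text))
    pos <- 1L
    while (pos <= nchar(s)) {
      rest <- substr(s, pos, nchar(s))
      m <- regmatches(rest, regexpr("^([A-Z][a-z]?|d)([0-9]*)", rest))
      frag <- if (length(m)) m else ""
      if (!nzchar(frag))
        stop("cannot parse formula at ", sQuote(substr(s, pos, nchar(s))))
      sym <- sub("[0-9]*$", "", frag)
      if (sym == "d") sym <- "D"
      if (!sym %in% names(.neutron_b))
        stop("unknown element symbol ", sQuote(sym), " in formula ", sQuote(text))
      num <- sub("^[A-Za-z]+", "", frag)
      n <- if (nzchar(num)) as.integer(num) else 1L
      if (n < 1L) stop("element count must be >= 1 for ", sQuote(sym))
      counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + n else n
      pos <- pos + nchar(frag)
    }
  }
  structure(list(counts = counts), class = "sas_formula")
}

#' @export
print.sas_formula <- function(x, ...) {
  cat("<formula> ", paste0(names(x$counts), x$counts, collapse = " "), "\n", sep = "")
  invisible(x)
}

.as_formula <- function(x) {
  if (inherits(x, "sas_formula")) x else parse_formula(x)
}

#' Define a material component
#'
#' Bundles a chemical formula with a mass density so scattering length
#' densities can be computed for either radiation.
#'
#' @param name component name.
#' @param formula formula string or \code{\link{parse_formula}} result.
#' @param density mass density in g/cm^3, > 0.
#' @return An object of class \code{sas_component}.
#' @examples
#' component("light water", "H2O", 0.997)
#' @export
component <- function(name, formula, density) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) || density <= 0)
    stop("density must be a positive number (g/cm^3)")
  structure(list(name = name, formula = .as_formula(formula), density = density),
            class = "sas_component")
}

#' @export
print.sas_component <- function(x, ...) {
  cat("<component> ", x$name, ": ",
      paste0(names(x$formula$counts), x$formula$counts, collapse = ""),
      " @ ", x$density, " g/cm^3\n", sep = "")
  invisible(x)
}

.formula_mass <- function(f) sum(.atomic_mass[names(f$counts)] * f$counts)

# molecular volume in A^3
.molecular_volume <- function(f, density) .formula_mass(f) / (density * .avogadro_per_A3)

#' Scattering length density of a component
#'
#' Neutron SLD is the sum of bound coherent scattering lengths divided by the
#' molecular volume; X-ray SLD is the electron count times the classical
#' electron radius divided by the molecular volume. The molecular volume comes
#' from the molar mass and the mass density.
#'
#' @param x a \code{\link{component}}, a formula, or a formula string.
#' @param radiation \code{"neutron"} or \code{"xray"}.
#' @param density mass density in g/cm^3; required unless \code{x} is a
#'   component (which carries its own).
#' @return SLD as a number on the 10^-6 A^-2 scale (neutron SLDs may be
#'   negative; X-ray SLDs of ordinary matter are non-negative).
#' @examples
#' sld(component("light water", "H2O", 0.997), "neutron")   # about -0.56
#' sld("D2O", "neutron", density = 1.107)                    # about 6.37
#' @export
sld <- function(x, radiation = c("neutron", "xray"), density = NULL) {
  radiation <- match.arg(radiation)
  if (inherits(x, "sas_component")) {
    f <- x$formula
    density <- x$density
  } else {
    if (is.null(density)) stop("density (g/cm^3) is required when x is not a component")
    if (!is.numeric(density) || density <= 0 || !is.finite(density))
      stop("density must be a positive number (g/cm^3)")
    f <- .as_formula(x)
  }
  v <- .molecular_volume(f, density)
  if (radiation == "neutron") {
    b <- sum(.neutron_b[names(f$counts)] * f$counts) * 1e-5 # fm -> A
    b / v * 1e6
  } else {
    z <- sum(.atomic_number[names(f$counts)] * f$counts)
    z * .r_electron_A / v * 1e6
  }
}

#' Volume-fraction-weighted SLD of a mixture
#'
#' @param slds numeric vector of SLDs (10^-6 A^-2).
#' @param fractions volume fractions, non-negative, summing to 1 (within 1e-9).
#' @return The weighted mean SLD.
#' @examples
#' mix_sld(c(0.13, 6.35), c(0.5, 0.5))  # 3.24
#' @export
mix_sld <- function(slds, fractions) {
  stopifnot(is.numeric(slds), is.numeric(fractions))
  if (length(slds) != length(fractions) || length(slds) < 1L)
    stop("slds and fractions must be equal-length, non-empty vectors")
  if (any(fractions < 0)) stop("volume fractions must be >= 0")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("volume fractions must sum to 1 (got ", format(sum(fractions)), ")")
  sum(slds * fractions)
}

#' Convert mass fractions to volume fractions
#'
#' @param mass mass fractions or masses (any common scale).
#' @param density per-part mass densities, g/cm^3.
#' @return Normalized volume fractions.
#' @export
mass_to_volume_fractions <- function(mass, density) {
  stopifnot(is.numeric(mass), is.numeric(density), length(mass) == length(density))
  if (any(mass < 0) || any(density <= 0)) stop("masses must be >= 0 and densities > 0")
  v <- mass / density
  v / sum(v)
}

# water endpoints of the H2O/D2O contrast series, computed once from the
# bundled tables at the default densities (0.997 / 1.107 g/cm^3)
.water_sld <- function(radiation = "neutron") {
  if (radiation == "neutron")
    c(h2o = sld("H2O", "neutron", density = 0.997),
      d2o = sld("D2O", "neutron", density = 1.107))
  else
    c(h2o = sld("H2O", "xray", density = 0.997),
      d2o = sld("D2O", "xray", density = 1.107))
}

#' Neutron SLD of an H2O/D2O solvent mixture
#'
#' @param f_d2o D2O volume fraction in [0, 1].
#' @return Solvent SLD on the 10^-6 A^-2 scale.
#' @examples
#' solvent_sld(0)    # light water, about -0.56
#' solvent_sld(1)    # heavy water, about 6.37
#' @export
solvent_sld <- function(f_d2o) {
  if (!is.numeric(f_d2o) || any(!is.finite(f_d2o)) || any(f_d2o < 0) || any(f_d2o > 1))
    stop("f_d2o must lie in [0, 1]")
  w <- .water_sld("neutron")
  vapply(f_d2o, function(f) mix_sld(unname(w), c(1 - f, f)), numeric(1))
}

#' D2O fraction that contrast-matches a target SLD
#'
#' Inverse of \code{\link{solvent_sld}}: the D2O volume fraction at which the
#' solvent SLD equals the target, so the matched region contributes no
#' coherent signal.
#'
#' @param target_sld target SLD (10^-6 A^-2), between the H2O and D2O values.
#' @return D2O volume fraction in [0, 1].
#' @examples
#' match_point(0.45)  # about 0.146
#' @export
match_point <- function(target_sld) {
  w <- .water_sld("neutron")
  lo <- min(w); hi <- max(w)
  if (!is.numeric(target_sld) || length(target_sld) != 1L || !is.finite(target_sld))
    stop("target_sld must be a finite number")
  if (target_sld < lo || target_sld > hi)
    stop(sprintf("target SLD %.3f is outside the achievable range [%.3f, %.3f]",
                 target_sld, lo, hi))
  (target_sld - w[["h2o"]]) / (w[["d2o"]] - w[["h2o"]])
}

#' Shell hydration from a fitted shell SLD
#'
#' Inverts the linear volume-fraction mixing rule: a shell that is a mixture
#' of dry material and solvent at hydration h has
#' SLD = (1 - h) * dry + h * solvent.
#'
#' @param fitted_shell fitted shell SLD (10^-6 A^-2).
#' @param dry_shell dry shell material SLD.
#' @param solvent solvent SLD; must differ from \code{dry_shell}.
#' @return Hydration as a fraction in [0, 1]. Values straying outside
#'   [-0.05, 1.05] signal inconsistent SLDs and raise an error; small
#'   excursions within that tolerance are clipped.
#' @examples
#' hydration_from_sld(3.3, 0.13, 6.35)  # about 0.51
#' @export
hydration_from_sld <- function(fitted_shell, dry_shell, solvent) {
  stopifnot(is.numeric(fitted_shell), is.numeric(dry_shell), is.numeric(solvent))
  if (abs(solvent - dry_shell) < 1e-12)
    stop("solvent and dry-shell SLDs are equal; hydration is unidentifiable")
  h <- (fitted_shell - dry_shell) / (solvent - dry_shell)
  if (h < -0.05 || h > 1.05)
    stop(sprintf(paste0("implied hydration %.3f lies outside [0, 1]; ",
                        "fitted/dry/solvent SLDs are inconsistent"), h))
  min(max(h, 0), 1)
}
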