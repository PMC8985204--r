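# Reduced 1-D scattering datasets and their on-disk ASCII form.
#
# Canonical units are A^-1 for Q and cm^-1 for I; nm^-1 input is accepted
# with an explicit unit declaration (header or argument) and divided by 10 on
# read. Files are whitespace-delimited 3- or 4-column ASCII (Q, I, sigma[,
# dQ]) with "# key: value" header lines carrying metadata.

#' Construct a reduced scattering dataset
#'
#' @param q scattering vector, A^-1, strictly increasing.
#' @param i intensities, cm^-1.
#' @param sigma intensity uncertainties, cm^-1, > 0.
#' @param resolution a \code{\link{resolution_kernel}}.
#' @param contrast_label contrast tag, e.g. \code{"h-core/D2O"}.
#' @param sld_solvent,sld_core fixed SLDs for this contrast (10^-6 A^-2);
#'   may be NA when they are to be filled in by \code{\link{build_problem}}.
#' @param radiation \code{"neutron"} or \code{"xray"}.
#' @param temperature_c,concentration_mg_ml sample metadata.
#' @return Object of class \code{sas_dataset}.
#' @export
sas_dataset <- function(q, i, sigma, resolution = resolution_kernel("none"),
                        contrast_label = "", sld_solvent = NA_real_,
                        sld_core = NA_real_, radiation = "neutron",
                        temperature_c = NA_real_,
                        concentration_mg_ml = NA_real_) {
  stopifnot(is.numeric(q), is.numeric(i), is.numeric(sigma))
  n <- length(q)
  if (n < 1L || length(i) != n || length(sigma) != n)
    stop("q, i, sigma must be equal-length, non-empty")
  dq <- diff(q)
  if (any(dq <= 0))
    stop("q must be strictly increasing; first violation at row ",
         which(dq <= 0)[1] + 1L)
  if (any(sigma <= 0)) stop("sigma must be > 0 everywhere")
  if (!radiation %in% c("neutron", "xray"))
    stop("radiation must be 'neutron' or 'xray'")
  stopifnot(inherits(resolution, "resolution_kernel"))
  if (resolution$kind == "gaussian_pointwise" &&
      length(resolution$value) != n)
    stop("pointwise resolution array must match the dataset length")
  structure(list(q = q, i = i, sigma = sigma, resolution = resolution,
                 contrast_label = contrast_label, sld_solvent = sld_solvent,
                 sld_core = sld_core, radiation = radiation,
                 temperature_c = temperature_c,
                 concentration_mg_ml = concentration_mg_ml),
            class = "sas_dataset")
}

#' @export
print.sas_dataset <- function(x, ...) {
  cat(sprintf("<sas_dataset> %s: %d points, q = %.4g..%.4g A^-1 (%s)\n",
              if (nzchar(x$contrast_label)) x$contrast_label else "(unlabeled)",
              length(x$q), min(x$q), max(x$q), x$radiation))
  invisible(x)
}

.q_unit_factor <- function(q_unit) {
  switch(q_unit,
         "1/A" = , "inverse_angstrom" = 1,
         "1/nm" = , "inverse_nanometer" = 0.1,
         stop("unknown q unit ", sQuote(q_unit),
              "; use '1/A' or '1/nm'"))
}

#' Read a reduced scattering data file
#'
#' Whitespace-delimited ASCII with 3 columns (Q, I, sigma) or 4 (plus
#' per-point sigma_Q). Header lines of the form \code{# key: value} supply
#' metadata (\code{q_unit}, \code{contrast_label}, \code{radiation},
#' \code{temperature_c}, \code{concentration_mg_ml}, \code{sld_solvent},
#' \code{sld_core}). A file whose sigma column is absent gets sigma imputed
#' as 2\% of I with a warning.
#'
#' @param path file path.
#' @param q_unit \code{"1/A"} or \code{"1/nm"}; a header declaration takes
#'   precedence, and with neither present A^-1 is assumed.
#' @return A \code{\link{sas_dataset}} in canonical units.
#' @export
read_dat <- function(path, q_unit = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*\\S)\\s*$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) < 10) stop("data file must contain at least 10 rows")
  rows <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1) stop("ragged data file: rows have differing column counts")
  if (ncols < 2 || ncols > 4)
    stop("expected 2-4 numeric columns, found ", ncols)
  mat <- do.call(rbind, rows)
  if (anyNA(mat)) stop("non-numeric values in data block")
  unit <- meta$q_unit %||% q_unit %||% "1/A"
  fac <- .q_unit_factor(unit)
  q <- mat[, 1] * fac
  i <- mat[, 2]
  if (ncols == 2) {
    warning("no sigma column; imputing sigma = 2% of I")
    sigma <- pmax(0.02 * abs(i), 1e-12)
  } else sigma <- mat[, 3]
  res <- if (ncols == 4) resolution_kernel("gaussian_pointwise", mat[, 4] * fac)
         else resolution_kernel("none")
  num <- function(key) if (is.null(meta[[key]])) NA_real_ else as.numeric(meta[[key]])
  sas_dataset(q, i, sigma, resolution = res,
              contrast_label = meta$contrast_label %||% "",
              sld_solvent = num("sld_solvent"), sld_core = num("sld_core"),
              radiation = meta$radiation %||% "neutron",
              temperature_c = num("temperature_c"),
              concentration_mg_ml = num("concentration_mg_ml"))
}

#' Write a reduced scattering data file
#'
#' Deterministic fixed-precision ASCII output with a metadata header; the
#' inverse of \code{\link{read_dat}}.
#'
#' @param dataset a \code{\link{sas_dataset}}.
#' @param path output path.
#' @param seed optional integer recorded in the header for provenance.
#' @return The path, invisibly.
#' @export
write_dat <- function(dataset, path, seed = NULL) {
  stopifnot(inherits(dataset, "sas_dataset"))
  if (length(dataset$q) == 0) stop("refusing to write an empty dataset")
  hdr <- c(
    paste0("# sascontrast: ", as.character(utils::packageVersion("sascontrast"))),
    "# q_unit: 1/A",
    paste0("# radiation: ", dataset$radiation),
    if (nzchar(dataset$contrast_label))
      paste0("# contrast_label: ", dataset$contrast_label),
    if (!is.na(dataset$sld_solvent))
      sprintf("# sld_solvent: %.10g", dataset$sld_solvent),
    if (!is.na(dataset$sld_core))
      sprintf("# sld_core: %.10g", dataset$sld_core),
    if (!is.na(dataset$temperature_c))
      sprintf("# temperature_c: %.10g", dataset$temperature_c),
    if (!is.na(dataset$concentration_mg_ml))
      sprintf("# concentration_mg_ml: %.10g", dataset$concentration_mg_ml),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)),
    "# columns: q i sigma"
  )
  sig <- .kernel_sigma(dataset$q, dataset$resolution)
  if (!is.null(sig)) {
    hdr[length(hdr)] <- "# columns: q i sigma dq"
    body <- sprintf("%.8e %.8e %.8e %.8e", dataset$q, dataset$i,
                    dataset$sigma, sig)
  } else {
    body <- sprintf("%.8e %.8e %.8e", dataset$q, dataset$i, dataset$sigma)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
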