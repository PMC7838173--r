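# Energy-dependent attenuation of elements, alloys and tissue surrogates.
# Elemental mass attenuation coefficients are packaged as plain-text tables
# (30-200 keV, no K-edges above 30 keV for any packaged element) and combined
# by the weight-fraction mixture rule.

.dectlab_cache <- new.env(parent = emptyenv())

element_data_dir <- function() {
  system.file("extdata", "elements", package = "dectlab", mustWork = TRUE)
}

#' Packaged element symbols
#'
#' @return Data frame with columns `symbol` and `Z` (atomic number) for every
#'   element whose mass attenuation table ships with the package.
#' @export
element_symbols <- function() {
  if (is.null(.dectlab_cache$elements)) {
    .dectlab_cache$elements <- utils::read.delim(
      file.path(element_data_dir(), "elements.tsv"),
      stringsAsFactors = FALSE
    )
  }
  .dectlab_cache$elements
}

element_table <- function(symbol) {
  key <- paste0("tab_", symbol)
  tab <- .dectlab_cache[[key]]
  if (is.null(tab)) {
    idx <- element_symbols()
    if (!symbol %in% idx$symbol) {
      stop("unknown element: ", symbol, call. = FALSE)
    }
    tab <- utils::read.table(
      file.path(element_data_dir(), paste0(symbol, ".txt")),
      col.names = c("energy_kev", "mu_over_rho"), comment.char = "#"
    )
    if (is.unsorted(tab$energy_kev, strictly = TRUE) || any(tab$mu_over_rho <= 0)) {
      stop("malformed element table for ", symbol, call. = FALSE)
    }
    .dectlab_cache[[key]] <- tab
  }
  tab
}

#' Elemental mass attenuation coefficient
#'
#' Looks up the packaged table for one element and evaluates it at the
#' requested photon energies. Between tabulated grid points the value is
#' interpolated log-log (attenuation is close to a power law between
#' absorption edges, and no packaged element has an edge above 30 keV);
#' on a grid point the tabulated value is returned exactly.
#'
#' @param element Element symbol, e.g. `"Fe"`.
#' @param energy_kev Photon energies in keV; must lie within the table span
#'   (30-200 keV for all packaged elements).
#' @return Mass attenuation coefficients in cm^2/g, one per energy.
#' @export
mass_attenuation <- function(element, energy_kev) {
  tab <- element_table(element)
  energy_kev <- as.numeric(energy_kev)
  if (any(!is.finite(energy_kev))) stop("non-finite energy", call. = FALSE)
  if (any(energy_kev < min(tab$energy_kev) | energy_kev > max(tab$energy_kev))) {
    stop(sprintf("energy outside table span [%g, %g] keV for %s",
                 min(tab$energy_kev), max(tab$energy_kev), element),
         call. = FALSE)
  }
  out <- exp(stats::approx(log(tab$energy_kev), log(tab$mu_over_rho),
                           xout = log(energy_kev), rule = 1)$y)
  # exact passthrough on grid points (protect against log/exp round-off)
  hit <- match(energy_kev, tab$energy_kev)
  on_grid <- !is.na(hit)
  out[on_grid] <- tab$mu_over_rho[hit[on_grid]]
  out
}

#' Define a material from density and elemental weight fractions
#'
#' @param name Material name.
#' @param density_g_cm3 Mass density in g/cm^3, > 0.
#' @param composition Named numeric vector of elemental weight fractions;
#'   each in (0, 1], summing to 1 within 1e-6, with every element packaged.
#' @return A `material_spec` object.
#' @export
material_spec <- function(name, density_g_cm3, composition) {
  composition <- unlist(composition)
  if (!is.character(name) || length(name) != 1L) stop("bad name", call. = FALSE)
  if (!is.numeric(density_g_cm3) || length(density_g_cm3) != 1L ||
      !is.finite(density_g_cm3) || density_g_cm3 <= 0) {
    stop("density must be a single positive number", call. = FALSE)
  }
  if (is.null(names(composition)) || any(names(composition) == "")) {
    stop("composition must be a named vector of weight fractions", call. = FALSE)
  }
  if (any(composition <= 0) || any(composition > 1)) {
    stop("weight fractions must lie in (0, 1]", call. = FALSE)
  }
  if (abs(sum(composition) - 1) > 1e-6) {
    stop("weight fractions must sum to 1 (got ", sum(composition), ")",
         call. = FALSE)
  }
  known <- element_symbols()$symbol
  bad <- setdiff(names(composition), known)
  if (length(bad)) stop("unknown element(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(
    list(name = name, density_g_cm3 = density_g_cm3,
         composition = composition),
    class = "material_spec"
  )
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material_spec> %s (rho = %.3g g/cm^3)\n", x$name,
              x$density_g_cm3))
  comp <- paste(sprintf("%s %.4f", names(x$composition), x$composition),
                collapse = ", ")
  cat("  weight fractions:", comp, "\n")
  invisible(x)
}

#' Read a material specification from a YAML or JSON file
#'
#' Expected layout: `{name, density_g_cm3, composition: {element: fraction}}`.
#'
#' @param path File path; `.json` is parsed as JSON, anything else as YAML.
#' @export
read_material <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  material_spec(spec$name, spec$density_g_cm3, unlist(spec$composition))
}

#' Packaged default materials
#'
#' Water (the gel surrogate), the 200 mg/cm^3 hydroxyapatite calibration
#' pellet, and the three hip-stem alloys (Ti-6Al-7Nb, CoCrMo, CrNi steel).
#' The definitions live as editable YAML under `inst/extdata/materials`.
#'
#' @return Named list of `material_spec` objects.
#' @export
default_materials <- function() {
  dir <- system.file("extdata", "materials", package = "dectlab",
                     mustWork = TRUE)
  files <- list.files(dir, pattern = "\\.ya?ml$", full.names = TRUE)
  mats <- lapply(files, read_material)
  names(mats) <- vapply(mats, `[[`, "", "name")
  mats
}

#' Mixture-rule mass attenuation of a material
#'
#' Weight-fraction-weighted sum of the elemental mass attenuation
#' coefficients: sum_i w_i (mu/rho)_i(E).
#'
#' @inheritParams linear_attenuation
#' @return cm^2/g, one value per energy.
#' @export
mixture_mass_attenuation <- function(spec, energy_kev) {
  stopifnot(inherits(spec, "material_spec"))
  vals <- vapply(names(spec$composition),
                 function(el) mass_attenuation(el, energy_kev),
                 numeric(length(energy_kev)))
  if (length(energy_kev) == 1L) vals <- matrix(vals, nrow = 1L)
  as.numeric(vals %*% spec$composition)
}

#' Linear attenuation coefficient of a material
#'
#' LAC = density x mixture mass attenuation, in 1/cm.
#'
#' @param spec A `material_spec`.
#' @param energy_kev Photon energies in keV.
#' @export
linear_attenuation <- function(spec, energy_kev) {
  stopifnot(inherits(spec, "material_spec"))
  if (spec$density_g_cm3 <= 0) stop("non-positive density", call. = FALSE)
  spec$density_g_cm3 * mixture_mass_attenuation(spec, energy_kev)
}

#' Linear attenuation curve over an energy list
#'
#' @param spec A `material_spec`.
#' @param energies_kev Non-empty vector of energies (order preserved,
#'   duplicates allowed).
#' @return Data frame of class `attenuation_curve` with columns
#'   `energy_kev`, `lac_cm1` and attribute `material`.
#' @export
lac_curve <- function(spec, energies_kev) {
  if (length(energies_kev) == 0L) stop("empty energy list", call. = FALSE)
  out <- data.frame(energy_kev = as.numeric(energies_kev),
                    lac_cm1 = linear_attenuation(spec, energies_kev))
  attr(out, "material") <- spec$name
  class(out) <- c("attenuation_curve", "data.frame")
  out
}

#' @export
plot.attenuation_curve <- function(x, ..., log = "y") {
  graphics::plot(x$energy_kev, x$lac_cm1, type = "l", log = log,
                 xlab = "photon energy (keV)",
                 ylab = expression(mu ~ (cm^-1)),
                 main = attr(x, "material"), ...)
  invisible(x)
}
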