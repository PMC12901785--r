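#' Compound specification for dosing unit conversions
#'
#' @param name compound name.
#' @param mw molecular weight, g/mol.
#' @param density assumed tissue density, g/ml (water-like default).
#' @return an object of class `compound_spec`.
#' @export
compound_spec <- function(name, mw, density = 1.0) {
  if (!is.numeric(mw) || mw <= 0) stop("`mw` must be > 0")
  if (!is.numeric(density) || density <= 0) stop("`density` must be > 0")
  structure(list(name = name, mw = mw, density = density),
            class = "compound_spec")
}

#' Propofol (2,6-diisopropylphenol), MW 178.27 g/mol, water-like density
#' @return a [compound_spec()] for propofol.
#' @export
propofol <- function() compound_spec("propofol", mw = 178.27, density = 1.0)

#' Convert a molar medium concentration to a mass concentration
#'
#' `ug/ml = uM * MW / 1000` (e.g. 50 uM propofol in medium is 8.9 ug/ml).
#'
#' @param c_um concentration, uM (>= 0).
#' @param spec a [compound_spec()].
#' @return concentration, ug/ml.
#' @export
molar_to_mass_conc <- function(c_um, spec) {
  stopifnot(inherits(spec, "compound_spec"), all(c_um >= 0))
  c_um * spec$mw / 1000
}

#' Convert a mass concentration back to molar
#'
#' Inverse of [molar_to_mass_conc()].
#'
#' @param c_ug_ml concentration, ug/ml (>= 0).
#' @param spec a [compound_spec()].
#' @return concentration, uM.
#' @export
mass_to_molar <- function(c_ug_ml, spec) {
  stopifnot(inherits(spec, "compound_spec"), all(c_ug_ml >= 0))
  c_ug_ml * 1000 / spec$mw
}

#' Convert a tissue mass concentration to molar
#'
#' `uM = (ng/mg) * density * 1000 / MW` assuming the stated tissue density
#' (e.g. 7.68 ng/mg propofol in brain tissue is ~43 uM at water-like density).
#'
#' @param c_ng_mg tissue concentration, ng per mg tissue (>= 0).
#' @param spec a [compound_spec()].
#' @return concentration, uM.
#' @export
tissue_mass_to_molar <- function(c_ng_mg, spec) {
  stopifnot(inherits(spec, "compound_spec"), all(c_ng_mg >= 0))
  c_ng_mg * spec$density * 1000 / spec$mw
}

#' Convert a molar tissue concentration to mass per tissue mass
#'
#' Inverse of [tissue_mass_to_molar()].
#'
#' @param c_um concentration, uM (>= 0).
#' @param spec a [compound_spec()].
#' @return tissue concentration, ng/mg.
#' @export
molar_to_tissue_mass <- function(c_um, spec) {
  stopifnot(inherits(spec, "compound_spec"), all(c_um >= 0))
  c_um * spec$mw / (1000 * spec$density)
}

#' Vehicle dilution fraction
#'
#' Percent (v/v) of vehicle in the final medium when diluting a stock to a
#' final concentration: `percent = 100 * final / stock` after unit
#' normalization (stock in mM, final in uM). Diluting a 10 mM stock to 50 uM
#' carries 0.5% vehicle.
#'
#' @param stock_mm stock concentration, mM.
#' @param final_um final concentration, uM.
#' @return percent v/v.
#' @export
dilution_fraction <- function(stock_mm, final_um) {
  stopifnot(stock_mm > 0, final_um >= 0)
  stock_um <- stock_mm * 1000
  if (any(final_um > stock_um))
    stop("final concentration exceeds the stock: impossible dilution")
  100 * final_um / stock_um
}
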