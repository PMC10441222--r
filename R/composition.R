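#' Compound definitions for carbon bookkeeping
#'
#' A `compound` carries the molar mass and carbon content needed to convert
#' gram amounts into C-mol, the common currency of yield coefficients and the
#' carbon balance. The package ships a small table of the compounds that occur
#' in the defined cultivation medium; entries can be overridden or extended
#' through the run configuration.
#'
#' @param name Compound name (character scalar).
#' @param molar_mass Molar mass in g/mol; must be positive.
#' @param carbon_atoms Number of carbon atoms per molecule; non-negative
#'   integer.
#' @return An object of class `compound`.
#' @examples
#' glc <- compound("glucose", 180.16, 6)
#' mass_to_cmol(180.16, glc)  # one mole of glucose carries 6 C-mol
#' @export
compound <- function(name, molar_mass, carbon_atoms) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(molar_mass) || length(molar_mass) != 1L || molar_mass <= 0) {
    stop("molar_mass must be a single positive number")
  }
  if (!is.numeric(carbon_atoms) || length(carbon_atoms) != 1L ||
      carbon_atoms < 0 || carbon_atoms != round(carbon_atoms)) {
    stop("carbon_atoms must be a single non-negative integer")
  }
  structure(
    list(name = name, molar_mass = molar_mass,
         carbon_atoms = as.integer(carbon_atoms)),
    class = "compound"
  )
}

#' @export
print.compound <- function(x, ...) {
  cat(sprintf("<compound> %s: %.2f g/mol, %d C\n",
              x$name, x$molar_mass, x$carbon_atoms))
  invisible(x)
}

#' Built-in compound table
#'
#' Compounds of the defined medium: glucose, monosodium glutamate (anhydrous,
#' consistent with the 1.15 glutamate-to-MSG mass factor), glutamic acid,
#' anhydrous trehalose, and carbon dioxide.
#'
#' @param name Optional compound name; if given, the single matching
#'   `compound` is returned.
#' @return A named list of `compound` objects, or one `compound`.
#' @examples
#' compound_table("trehalose")
#' @export
compound_table <- function(name = NULL) {
  tab <- list(
    glucose       = compound("glucose", 180.16, 6),
    msg           = compound("monosodium glutamate (anhydrous)", 169.11, 5),
    glutamic_acid = compound("glutamic acid", 147.13, 5),
    trehalose     = compound("trehalose (anhydrous)", 342.30, 12),
    co2           = compound("carbon dioxide", 44.01, 1)
  )
  if (is.null(name)) return(tab)
  if (!name %in% names(tab)) {
    stop("unknown compound: ", name,
         " (known: ", paste(names(tab), collapse = ", "), ")")
  }
  tab[[name]]
}

#' Elemental biomass composition
#'
#' Dry biomass is reduced to its carbon fraction for C-mol yield calculations.
#' The default is the standard microbial composition CH1.8O0.5N0.2
#' (24.6 g/C-mol), giving 12.011/24.6 = 0.488 g carbon per g dry cell weight.
#' No measured elemental composition for *S. acidocaldarius* is assumed; the
#' value is overridable wherever a `biomass_composition` is accepted.
#'
#' @param carbon_fraction Gram carbon per gram dry cell weight, in (0, 1).
#' @param formula_label Label for the assumed elemental formula.
#' @return An object of class `biomass_composition`.
#' @export
biomass_composition <- function(carbon_fraction = 12.011 / 24.6,
                                formula_label = "CH1.8O0.5N0.2") {
  if (!is.numeric(carbon_fraction) || length(carbon_fraction) != 1L ||
      carbon_fraction <= 0 || carbon_fraction >= 1) {
    stop("carbon_fraction must be in (0, 1)")
  }
  structure(
    list(carbon_fraction = carbon_fraction, formula_label = formula_label),
    class = "biomass_composition"
  )
}

#' @export
print.biomass_composition <- function(x, ...) {
  cat(sprintf("<biomass_composition> %s (%.3f g C/g DCW)\n",
              x$formula_label, x$carbon_fraction))
  invisible(x)
}

# Molar volume of an ideal gas at norm conditions [L/mol]; used in the
# gas-phase balances and the simulator's off-gas generation.
MOLAR_VOLUME <- 22.414

#' Molar gas volume used in gas-phase balances
#'
#' @return The molar volume of air at norm conditions, 22.414 L/mol.
#' @export
molar_volume <- function() MOLAR_VOLUME

#' Convert a mass of a compound to C-mol
#'
#' @param mass Mass in grams (vectorised); non-negative.
#' @param comp A [compound()] with at least one carbon atom.
#' @return Carbon moles, `mass / molar_mass * carbon_atoms`.
#' @examples
#' mass_to_cmol(342.30, compound_table("trehalose"))  # 12
#' @export
mass_to_cmol <- function(mass, comp) {
  stopifnot(inherits(comp, "compound"))
  if (any(mass < 0)) stop("mass must be non-negative")
  if (comp$carbon_atoms == 0L) stop("compound carries no carbon")
  mass / comp$molar_mass * comp$carbon_atoms
}

#' Convert C-mol of a compound back to grams
#'
#' Inverse of [mass_to_cmol()].
#'
#' @param cmol Carbon moles (vectorised); non-negative.
#' @param comp A [compound()] with at least one carbon atom.
#' @return Mass in grams.
#' @export
cmol_to_mass <- function(cmol, comp) {
  stopifnot(inherits(comp, "compound"))
  if (any(cmol < 0)) stop("cmol must be non-negative")
  if (comp$carbon_atoms == 0L) stop("compound carries no carbon")
  cmol * comp$molar_mass / comp$carbon_atoms
}

#' Convert a glutamic acid concentration to MSG equivalents
#'
#' Photometric supernatant assays report glutamic acid; the medium substrate
#' is monosodium glutamate. The fixed factor 1.15 matches the molar-mass
#' ratio of anhydrous MSG to glutamic acid (169.11/147.13 = 1.149).
#'
#' @param glutamate_conc Glutamic acid concentration in g/L (vectorised).
#' @return MSG concentration in g/L.
#' @examples
#' msg_from_glutamate(2.0)  # 2.30
#' @export
msg_from_glutamate <- function(glutamate_conc) {
  if (any(glutamate_conc < 0)) stop("glutamate_conc must be non-negative")
  1.15 * glutamate_conc
}

#' Convert OD540 to dry cell weight
#'
#' Uses the published OD540-to-DCW correlation factor of 0.586 g/L for
#' *S. acidocaldarius*.
#'
#' @param od540 Absorbance at 540 nm (vectorised); non-negative.
#' @return Dry cell weight concentration in g/L, `od540 / 0.586`.
#' @export
dcw_from_od540 <- function(od540) {
  if (any(od540 < 0)) stop("od540 must be non-negative")
  od540 / 0.586
}

#' Convert a biomass mass to C-mol
#'
#' @param mass Dry biomass in grams (vectorised); non-negative.
#' @param comp A [biomass_composition()]; defaults to CH1.8O0.5N0.2.
#' @return Carbon moles, `mass * carbon_fraction / 12.011`.
#' @export
biomass_to_cmol <- function(mass, comp = biomass_composition()) {
  stopifnot(inherits(comp, "biomass_composition"))
  if (any(mass < 0)) stop("mass must be non-negative")
  mass * comp$carbon_fraction / 12.011
}
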