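#' Load a table of formation free energies
#'
#' Reads the two-column delimited table of Gibbs free energies of formation
#' at biochemical standard conditions (pH 7, 1 M, 25 degC), dGf0' in kJ/mol.
#' The packaged default transcribes the classical compilation of Thauer,
#' Jungermann and Decker (1977) with two deliberate choices: O2 is priced as
#' the *dissolved* species (+16.4 kJ/mol) and generic biomass CH2O as
#' one-sixth of glucose.  Redox carriers are priced through couple
#' increments (Alberty, 2003): the reduced member carries the full
#' oxidized-to-reduced increment and the oxidized member zero, so only the
#' difference -- the only quantity that ever enters a balanced reaction --
#' is meaningful.  The thiosulfate entry is a calibrated value (see the
#' methods vignette).
#'
#' @param path Path to a delimited file with a header and two columns
#'   (species, dGf0 in kJ/mol).  `NULL` loads the packaged table.
#' @return An object of class `sox_thermo_table` with elements
#'   `formation_energy` (named numeric, kJ/mol), `couple_increments`
#'   (kJ per mol reduced carrier), `atp_energy` (kJ per mol ATP) and
#'   `source` (file path).
#' @examples
#' tab <- thermo_table()
#' tab$formation_energy[["SO4"]]
#' @export
thermo_table <- function(path = NULL) {
  use_cache <- is.null(path)
  if (use_cache && !is.null(.sox_cache$thermo)) {
    return(.sox_cache$thermo)
  }
  if (is.null(path)) {
    path <- .sox_extdata("thermo_table.tsv")
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) {
    stop("thermo table must have two columns: species, dGf0 [kJ/mol]",
         call. = FALSE)
  }
  fe <- stats::setNames(as.numeric(raw[[2]]), as.character(raw[[1]]))
  if (anyNA(fe)) {
    stop("non-numeric formation energy in thermo table", call. = FALSE)
  }
  atp <- if ("ATP" %in% names(fe)) unname(fe[["ATP"]]) else 41
  fe <- fe[setdiff(names(fe), "ATP")]
  couples <- c(
    NADH   = unname(fe["NADH"] - fe["NAD+"]),
    FADH2  = unname(fe["FADH2"] - fe["FAD"]),
    Fd_red = unname(fe["Fd_red"] - fe["Fd_ox"])
  )
  out <- structure(
    list(formation_energy = fe, couple_increments = couples,
         atp_energy = atp, source = path),
    class = "sox_thermo_table"
  )
  if (use_cache) .sox_cache$thermo <- out
  out
}

#' @export
print.sox_thermo_table <- function(x, ...) {
  cat("<sox_thermo_table> ", length(x$formation_energy),
      " species, ATP = ", x$atp_energy, " kJ/mol\n", sep = "")
  cat("source: ", x$source, "\n", sep = "")
  invisible(x)
}

#' Reaction conditions
#'
#' Concentrations, pH and temperature at which a reaction quotient is
#' evaluated.  Activities are approximated by molar concentrations;
#' zero-valent sulfur and water carry unit activity.  The proton activity is
#' taken *relative to the pH 7 standard state* (`10^-(pH - 7)`) because the
#' formation energies are biochemical-standard values that already price H+
#' at pH 7; with this convention the quotient term vanishes exactly at
#' standard biochemical conditions.
#'
#' @param concentrations Named numeric vector of molar concentrations for
#'   individual species (e.g. `c(SO4 = 1e-6)`).  Species not listed fall
#'   back to `default_concentration`.
#' @param pH Unitless, in \[0, 14\].
#' @param temperature Kelvin.
#' @param default_concentration Molar concentration used for species without
#'   an explicit entry (1 M for the biochemical standard state).
#' @param warn_missing Warn when a reaction references a species that has no
#'   explicit concentration although some concentrations were supplied.
#' @param label Optional display label.
#' @return An object of class `sox_conditions`.
#' @seealso [standard_conditions()], [environmental_conditions()]
#' @export
conditions <- function(concentrations = numeric(), pH = 7,
                       temperature = 298.15, default_concentration = 1,
                       warn_missing = TRUE, label = "custom") {
  concentrations <- unlist(concentrations)
  if (length(concentrations) && is.null(names(concentrations))) {
    stop("concentrations must be a named vector", call. = FALSE)
  }
  if (any(concentrations <= 0) || default_concentration <= 0) {
    stop("all concentrations must be > 0", call. = FALSE)
  }
  if (pH < 0 || pH > 14) stop("pH must lie in [0, 14]", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0 K", call. = FALSE)
  structure(
    list(concentrations = concentrations, pH = pH,
         temperature = temperature,
         default_concentration = default_concentration,
         warn_missing = warn_missing, label = label),
    class = "sox_conditions"
  )
}

#' Standard biochemical conditions
#'
#' All concentrations 1 M, pH 7, 298.15 K.
#' @return A `sox_conditions` object.
#' @export
standard_conditions <- function() {
  conditions(label = "standard biochemical")
}

#' Environmentally scaled conditions
#'
#' All reactant concentrations equal (1 mM by default), pH 7, 25 degC -- a
#' preset used to examine how efficiency-based inversions respond when
#' activities are moved from the 1 M standard state into a range closer to
#' natural porewaters.  Carrier couples keep a ratio of one because both
#' members share the default concentration.
#'
#' @param concentration Molar concentration applied to every species.
#' @return A `sox_conditions` object.
#' @export
environmental_conditions <- function(concentration = 1e-3) {
  conditions(default_concentration = concentration,
             label = sprintf("all reactants %g M, pH 7", concentration))
}

#' @export
print.sox_conditions <- function(x, ...) {
  cat("<sox_conditions> ", x$label, ": pH ", x$pH, ", ",
      x$temperature, " K, default ", x$default_concentration, " M\n",
      sep = "")
  if (length(x$concentrations)) {
    cat("explicit: ",
        paste(sprintf("%s = %g M", names(x$concentrations),
                      x$concentrations), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Standard-condition Gibbs free energy of a reaction
#'
#' Sums coefficient-weighted formation free energies over the species of a
#' balanced reaction, products positive and reactants negative, per mole of
#' sulfur substrate.  H+ is priced at the pH 7 convention value embedded in
#' the table; redox carriers are priced through their couple increments.
#'
#' @param stoich A [sox_stoichiometry][energy_equation] object.
#' @param table A [thermo_table()].
#' @return Gibbs free energy in kJ per mole of sulfur substrate.
#' @examples
#' reaction_standard_energy(energy_equation("sulfide", "aerobic", x = 0))
#' @export
reaction_standard_energy <- function(stoich, table = thermo_table()) {
  stopifnot(inherits(stoich, "sox_stoichiometry"))
  coef <- stoich$coefficients
  fe <- table$formation_energy
  missing <- setdiff(names(coef), names(fe))
  if (length(missing)) {
    stop("unknown species (no formation energy): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sum(coef * fe[names(coef)])
}

#' Reaction quotient contribution RT ln Q
#'
#' Each species contributes its activity raised to its signed coefficient.
#' Zero-valent sulfur and water have unit activity; H+ contributes
#' `10^-(pH - 7)` per unit coefficient (relative to the pH 7 standard
#' state); all other species contribute their molar concentration.
#'
#' @inheritParams reaction_standard_energy
#' @param cond A [conditions()] object.
#' @return RT ln Q in kJ per mole of sulfur substrate; exactly 0 at
#'   standard biochemical conditions.
#' @export
reaction_quotient_term <- function(stoich, cond = standard_conditions()) {
  stopifnot(inherits(stoich, "sox_stoichiometry"),
            inherits(cond, "sox_conditions"))
  coef <- stoich$coefficients
  rt <- .R_GAS * cond$temperature
  log_q <- 0
  defaulted <- character()
  for (sp in names(coef)) {
    nu <- coef[[sp]]
    if (sp %in% rownames(.SPECIES) && .SPECIES[sp, "unit_activity"] == 1) {
      next
    }
    if (sp == "H+") {
      log_q <- log_q + nu * log(10) * (-(cond$pH - 7))
      next
    }
    if (sp %in% names(cond$concentrations)) {
      conc <- cond$concentrations[[sp]]
    } else {
      conc <- cond$default_concentration
      defaulted <- c(defaulted, sp)
    }
    log_q <- log_q + nu * log(conc)
  }
  if (length(defaulted) && length(cond$concentrations) &&
      isTRUE(cond$warn_missing)) {
    warning("no concentration supplied for ",
            paste(defaulted, collapse = ", "),
            "; using ", cond$default_concentration, " M", call. = FALSE)
  }
  rt * log_q
}

#' Gibbs free energy of a reaction at given conditions
#'
#' @inheritParams reaction_quotient_term
#' @inheritParams reaction_standard_energy
#' @return An object of class `sox_reaction_energy` with elements
#'   `standard`, `quotient_term` and `total` (all kJ per mole of sulfur
#'   substrate, `total = standard + quotient_term`).
#' @examples
#' dg <- delta_g(energy_equation("sulfide", "aerobic", x = 0))
#' dg$total  # about -829 kJ/mol at standard biochemical conditions
#' @export
delta_g <- function(stoich, cond = standard_conditions(),
                    table = thermo_table()) {
  standard <- reaction_standard_energy(stoich, table)
  quotient <- reaction_quotient_term(stoich, cond)
  structure(
    list(standard = standard, quotient_term = quotient,
         total = standard + quotient),
    class = "sox_reaction_energy"
  )
}

#' @export
print.sox_reaction_energy <- function(x, ...) {
  cat(sprintf(
    "dGr = %.2f (standard) + %.2f (RT ln Q) = %.2f kJ/mol substrate\n",
    x$standard, x$quotient_term, x$total))
  invisible(x)
}
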