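## ---- descriptors for substrates, acceptors and C-fixation pathways ----

#' Sulfur substrate descriptor
#'
#' Electron bookkeeping for the supported reduced sulfur substrates.  Both
#' sulfide and thiosulfate release 8 electrons per mole on complete
#' oxidation to sulfate; partial oxidation is parameterized by `x`, the
#' number of sulfur atoms per mole of substrate that end as zero-valent
#' sulfur.  For thiosulfate the incomplete route oxidizes the sulfane
#' sulfur only (S2O3^2- + H2O -> S0 + SO4^2- + 2H+ + 2e-), so the electron
#' yield is `8 - 6x` for both substrates.  Negative `x` (sulfide only)
#' describes co-oxidation of stored elemental sulfur.
#'
#' @param id `"sulfide"` or `"thiosulfate"`.
#' @return A list with elements `id`, `species`, `s_atoms`,
#'   `electrons_complete`, `electrons_partial`, `electron_yield(x)` and the
#'   admissible range `x_range`.
#' @export
sulfur_substrate <- function(id = c("sulfide", "thiosulfate")) {
  id <- match.arg(id)
  switch(id,
    sulfide = list(
      id = "sulfide", species = "H2S", s_atoms = 1,
      electrons_complete = 8, electrons_partial = 2,
      e0 = 8, e_slope = 6, x_range = c(-10, 1), x_warn_below = -2
    ),
    thiosulfate = list(
      id = "thiosulfate", species = "S2O3", s_atoms = 2,
      electrons_complete = 8, electrons_partial = 2,
      e0 = 8, e_slope = 6, x_range = c(0, 1), x_warn_below = 0
    )
  )
}

#' Terminal electron acceptor process descriptor
#'
#' @param id `"aerobic"` (O2 -> H2O, 4 e-), `"denitrification"`
#'   (NO3^- -> 1/2 N2, 5 e-) or `"dnra"` (NO3^- -> NH4^+, 8 e-).
#' @return A list with the acceptor species, electrons accepted per mole
#'   and the reduction half-reaction.
#' @export
tea_process <- function(id = c("aerobic", "denitrification", "dnra")) {
  id <- match.arg(id)
  switch(id,
    aerobic = list(
      id = "aerobic", species = "O2", electrons_per_mole = 4,
      half = c(O2 = -1, `H+` = -4, H2O = 2)
    ),
    denitrification = list(
      id = "denitrification", species = "NO3", electrons_per_mole = 5,
      half = c(NO3 = -1, `H+` = -6, N2 = 0.5, H2O = 3)
    ),
    dnra = list(
      id = "dnra", species = "NO3", electrons_per_mole = 8,
      half = c(NO3 = -1, `H+` = -10, NH4 = 1, H2O = 3)
    )
  )
}

#' Carbon fixation pathway descriptor
#'
#' Carrier demand and energetics of the two CO2 fixation pathways of SOB.
#' Each mole of CO2 fixed to the CH2O level consumes 4 electrons.  The
#' Calvin cycle draws them all from NADH; the reverse tricarboxylic acid
#' (rTCA) cycle draws 1/2 from NADH, 1/3 from reduced ferredoxin and 1/6
#' from FADH2 (i.e. 3 NADH + 4 Fd_red + 1 FADH2 per 3 CO2).
#'
#' @param id `"calvin"` or `"rtca"`.
#' @return A list with `dg_fix` (kJ per mol CO2 fixed), `atp_per_co2`, and
#'   `electron_fractions` per carrier.
#' @export
carbon_pathway <- function(id = c("calvin", "rtca")) {
  id <- match.arg(id)
  switch(id,
    calvin = list(
      id = "calvin", dg_fix = 69.7, atp_per_co2 = 3,
      electron_fractions = c(NADH = 1)
    ),
    rtca = list(
      id = "rtca", dg_fix = 64.3, atp_per_co2 = 5 / 3,
      electron_fractions = c(NADH = 1 / 2, Fd_red = 1 / 3, FADH2 = 1 / 6)
    )
  )
}

## electrons transferred per mole of reduced carrier formed
.CARRIER_ELECTRONS <- c(NADH = 2, FADH2 = 2, Fd_red = 1)

## reduction half-reactions of the carrier couples, per mole reduced
.CARRIER_HALF <- list(
  NADH   = c(`NAD+` = -1, `H+` = -1, NADH = 1),
  FADH2  = c(FAD = -1, `H+` = -2, FADH2 = 1),
  Fd_red = c(Fd_ox = -1, Fd_red = 1)
)

## CO2 -> CH2O reduction half-reaction (4 e- per CO2)
.CO2_HALF <- c(CO2 = -1, `H+` = -4, CH2O = 1, H2O = 1)

## ---- internal builders ----

.check_x <- function(sub, x) {
  rng <- sub$x_range
  if (x < rng[1] || x > rng[2]) {
    stop(sprintf("x = %g outside the admissible range [%g, %g] for %s",
                 x, rng[1], rng[2], sub$id), call. = FALSE)
  }
  if (x < sub$x_warn_below) {
    warning(sprintf(
      "x = %g implies a very large stored-S0 co-oxidation term", x),
      call. = FALSE)
  }
  invisible(x)
}

.electron_yield <- function(sub, x) sub$e0 - sub$e_slope * x

## oxidation half-reaction of the sulfur substrate:
## substrate + n H2O -> x S0 + (s - x) SO4^2- + n_H H+ + E(x) e-
.half_sulfur <- function(sub, x) {
  if (sub$id == "sulfide") {
    coef <- c(H2S = -1, S0 = x, SO4 = 1 - x,
              H2O = -(4 - 4 * x), `H+` = 10 - 8 * x)
  } else {
    coef <- c(S2O3 = -1, S0 = x, SO4 = 2 - x,
              H2O = -(5 - 4 * x), `H+` = 10 - 8 * x)
  }
  list(coef = coef, electrons = .electron_yield(sub, x))
}

.merge_coef <- function(...) {
  parts <- list(...)
  species <- unique(unlist(lapply(parts, names)))
  out <- stats::setNames(numeric(length(species)), species)
  for (p in parts) out[names(p)] <- out[names(p)] + p
  out
}

.drop_zeros <- function(coef, keep = character(), tol = 1e-12) {
  coef[abs(coef) > tol | names(coef) %in% keep]
}

.new_stoichiometry <- function(coef, kind, substrate, x, y = NA_real_,
                               tea = NA_character_,
                               pathway = NA_character_) {
  structure(
    list(coefficients = coef, kind = kind, substrate = substrate,
         tea = tea, pathway = pathway, x = x, y = y),
    class = "sox_stoichiometry"
  )
}

## ---- exported builders ----

#' Generalized energy-generating reaction
#'
#' Oxidation of the sulfur substrate coupled to reduction of the terminal
#' electron acceptor, with a fraction `x` of the sulfur atoms ending as
#' zero-valent sulfur and the rest as sulfate.  For sulfide/aerobic this is
#' `H2S + (2 - 1.5x) O2 -> x S0 + (1 - x) SO4^2- + x H2O + (2 - 2x) H+`.
#'
#' @param substrate `"sulfide"` or `"thiosulfate"`.
#' @param tea `"aerobic"`, `"denitrification"` or `"dnra"`.
#' @param x S0 : SO4 partition parameter (may be negative for sulfide:
#'   stored S0 is co-oxidized).
#' @return A `sox_stoichiometry` object: a named vector of signed
#'   coefficients (products positive, reactants negative) normalized to -1
#'   for the sulfur substrate, plus provenance fields.
#' @examples
#' energy_equation("sulfide", "aerobic", x = 1)   # H2S + 0.5 O2 -> S0 + H2O
#' energy_equation("sulfide", "aerobic", x = 0)   # complete oxidation
#' @export
energy_equation <- function(substrate = "sulfide", tea = "aerobic", x = 0) {
  sub <- sulfur_substrate(substrate)
  acc <- tea_process(tea)
  .check_x(sub, x)
  sh <- .half_sulfur(sub, x)
  coef <- .merge_coef(sh$coef, (sh$electrons / acc$electrons_per_mole) *
                        acc$half)
  coef <- .drop_zeros(coef, keep = sub$species)
  .new_stoichiometry(coef, "energy", sub$id, x, tea = acc$id)
}

#' Generalized CO2-assimilating reaction
#'
#' The sulfur substrate donates its electrons to CO2 reduction (to the
#' CH2O biomass level) instead of the terminal electron acceptor, with the
#' same S0 : SO4 partition `x`.  For sulfide:
#' `H2S + (2 - 1.5x) CO2 + (2 - 2.5x) H2O -> x S0 + (1 - x) SO4^2- +
#' (2 - 1.5x) CH2O + (2 - 2x) H+`.
#'
#' @inheritParams energy_equation
#' @return A `sox_stoichiometry` object.
#' @export
assimilation_equation <- function(substrate = "sulfide", x = 0) {
  sub <- sulfur_substrate(substrate)
  .check_x(sub, x)
  sh <- .half_sulfur(sub, x)
  coef <- .merge_coef(sh$coef, (sh$electrons / 4) * .CO2_HALF)
  coef <- .drop_zeros(coef, keep = sub$species)
  .new_stoichiometry(coef, "assimilation", sub$id, x)
}

#' Generalized overall reaction
#'
#' Convex combination of the energy-generating and CO2-assimilating
#' reactions: a fraction `y` of the reduced sulfur pool is oxidized for
#' energy generation and `1 - y` for CO2 fixation.
#'
#' @inheritParams energy_equation
#' @param y Fraction of the substrate pool used for energy generation,
#'   in \[0, 1\].
#' @return A `sox_stoichiometry` object with both `x` and `y` recorded.
#' @examples
#' overall_equation("sulfide", "aerobic", x = 0, y = 0.825)
#' @export
overall_equation <- function(substrate = "sulfide", tea = "aerobic",
                             x = 0, y = 1) {
  if (y < 0 || y > 1) stop("y must lie in [0, 1]", call. = FALSE)
  en <- energy_equation(substrate, tea, x)
  as <- assimilation_equation(substrate, x)
  coef <- .merge_coef(y * en$coefficients, (1 - y) * as$coefficients)
  coef <- .drop_zeros(coef, keep = sulfur_substrate(substrate)$species)
  out <- .new_stoichiometry(coef, "overall", en$substrate, x, y = y,
                            tea = en$tea)
  out
}

#' Reverse electron transport reaction
#'
#' Endergonic reduction of the carbon-fixation pathway's electron carriers
#' by the sulfur substrate, driven by proton motive force.  Carrier
#' coefficients follow the pathway's electron fractions; for
#' sulfide/Calvin: `H2S + (4 - 3x) NAD+ + (4 - 4x) H2O -> x S0 +
#' (1 - x) SO4^2- + (4 - 3x) NADH + (6 - 5x) H+`.
#'
#' @inheritParams energy_equation
#' @param pathway `"calvin"` or `"rtca"`.
#' @return A `sox_stoichiometry` object.
#' @export
ret_equation <- function(substrate = "sulfide", pathway = "calvin", x = 0) {
  sub <- sulfur_substrate(substrate)
  pw <- carbon_pathway(pathway)
  .check_x(sub, x)
  sh <- .half_sulfur(sub, x)
  parts <- lapply(names(pw$electron_fractions), function(cr) {
    moles <- sh$electrons * pw$electron_fractions[[cr]] /
      .CARRIER_ELECTRONS[[cr]]
    moles * .CARRIER_HALF[[cr]]
  })
  coef <- do.call(.merge_coef, c(list(sh$coef), parts))
  coef <- .drop_zeros(coef, keep = sub$species)
  .new_stoichiometry(coef, "ret", sub$id, x, pathway = pw$id)
}

#' Element and charge balance report
#'
#' Independent bookkeeping check for any reaction built (or edited) by the
#' package: residuals of S, O, H, C, N and charge, computed from a fixed
#' composition registry.  Carrier couples are booked relative to their
#' oxidized partner, so a reaction that creates or destroys carrier cores
#' (unequal couple coefficients) shows up in the H and charge rows.
#'
#' @param stoich A `sox_stoichiometry` object.
#' @param tol Absolute residual below which a quantity counts as balanced.
#' @return A data frame (class `sox_balance_report`) with columns
#'   `quantity` and `residual`, and an attribute `passed`.
#' @export
check_balance <- function(stoich, tol = 1e-9) {
  stopifnot(inherits(stoich, "sox_stoichiometry"))
  coef <- stoich$coefficients
  unknown <- setdiff(names(coef), rownames(.SPECIES))
  if (length(unknown)) {
    stop("species not in composition registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  comp <- .SPECIES[names(coef), c("S", "O", "H", "C", "N", "charge"),
                   drop = FALSE]
  residual <- as.numeric(coef %*% comp)
  out <- data.frame(quantity = colnames(comp), residual = residual,
                    stringsAsFactors = FALSE)
  attr(out, "passed") <- all(abs(residual) < tol)
  class(out) <- c("sox_balance_report", "data.frame")
  out
}

#' @export
print.sox_balance_report <- function(x, ...) {
  cat(if (isTRUE(attr(x, "passed"))) "balanced" else "NOT balanced", "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
format.sox_stoichiometry <- function(x, digits = 3, ...) {
  coef <- x$coefficients
  lab <- ifelse(names(coef) %in% names(.SPECIES_LABEL),
                .SPECIES_LABEL[names(coef)], names(coef))
  term <- function(v, s) {
    v <- signif(abs(v), digits)
    if (isTRUE(all.equal(v, 1))) s else paste0(format(v), " ", s)
  }
  lhs <- mapply(term, coef[coef < 0], lab[coef < 0])
  rhs <- mapply(term, coef[coef > 0], lab[coef > 0])
  paste(paste(lhs, collapse = " + "), "->", paste(rhs, collapse = " + "))
}

#' @export
print.sox_stoichiometry <- function(x, ...) {
  cat("<", x$kind, "> ", format(x), "\n", sep = "")
  meta <- sprintf("substrate = %s, x = %g", x$substrate, x$x)
  if (!is.na(x$y)) meta <- paste0(meta, sprintf(", y = %g", x$y))
  if (!is.na(x$tea)) meta <- paste0(meta, ", tea = ", x$tea)
  if (!is.na(x$pathway)) meta <- paste0(meta, ", pathway = ", x$pathway)
  cat(meta, "\n")
  invisible(x)
}

#' @export
as.data.frame.sox_stoichiometry <- function(x, ...) {
  data.frame(species = names(x$coefficients),
             coefficient = unname(x$coefficients),
             stringsAsFactors = FALSE)
}

## ---- rate sets and the (x, y) solver ----

#' Measured rate set
#'
#' Consumption/production rates of the reactants of one experiment, in any
#' single consistent unit -- only ratios enter the calculations.
#'
#' @param rates Named numeric vector, e.g.
#'   `c(H2S = 6.75, O2 = 12.4, CO2 = 12.45)`.
#' @param convention Sign convention of the values; magnitudes are used
#'   when forming ratios.
#' @param unit Free-text unit tag (documentation only).
#' @return An object of class `sox_rate_set`.
#' @export
rate_set <- function(rates, convention = c("consumption_positive",
                                           "consumption_negative"),
                     unit = "") {
  convention <- match.arg(convention)
  rates <- unlist(rates)
  if (is.null(names(rates)) || !length(rates)) {
    stop("rates must be a non-empty named vector", call. = FALSE)
  }
  structure(list(rates = rates, convention = convention, unit = unit),
            class = "sox_rate_set")
}

#' @export
print.sox_rate_set <- function(x, ...) {
  cat("<sox_rate_set> [", x$convention,
      if (nzchar(x$unit)) paste0(", ", x$unit), "]\n", sep = "")
  print(x$rates)
  invisible(x)
}

#' Recover (x, y) from measured rate ratios
#'
#' Closed-form inversion of the overall-equation coefficients.  With
#' `r = TEA : substrate` and `c = CO2 : substrate` consumption ratios, the
#' electron balance `n_tea * r + 4 * c = E(x)` fixes `x` and
#' `y = n_tea * r / E(x)` follows, where `E(x)` is the substrate's electron
#' yield and `n_tea` the electrons accepted per mole of TEA.
#'
#' @param rates A [rate_set()] containing the substrate, the acceptor
#'   species and CO2 -- or a numeric vector `c(tea = r, co2 = c)` of ratios
#'   relative to the substrate.
#' @inheritParams energy_equation
#' @return A list with `x`, `y`, the consumed `ratios` and the implied
#'   overall `stoichiometry`.
#' @examples
#' solve_xy(c(tea = 1.65, co2 = 0.35))  # x = 0, y = 0.825
#' @export
solve_xy <- function(rates, substrate = "sulfide", tea = "aerobic") {
  sub <- sulfur_substrate(substrate)
  acc <- tea_process(tea)
  if (inherits(rates, "sox_rate_set")) {
    v <- abs(rates$rates)
    need <- c(sub$species, acc$species, "CO2")
    if (!all(need %in% names(v))) {
      stop("rate set must contain ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    r <- v[[acc$species]] / v[[sub$species]]
    co2 <- v[["CO2"]] / v[[sub$species]]
  } else {
    v <- abs(unlist(rates))
    if (length(v) != 2) {
      stop("supply a rate_set or two ratios c(tea = ..., co2 = ...)",
           call. = FALSE)
    }
    if (!is.null(names(v)) && all(c("tea", "co2") %in% names(v))) {
      r <- v[["tea"]]; co2 <- v[["co2"]]
    } else {
      r <- v[[1]]; co2 <- v[[2]]
    }
  }
  total <- acc$electrons_per_mole * r + 4 * co2
  if (total <= 0) {
    stop("TEA and CO2 ratios sum to a non-positive electron flow",
         call. = FALSE)
  }
  x <- (sub$e0 - total) / sub$e_slope
  y <- acc$electrons_per_mole * r / total
  if (y < -1e-9 || y > 1 + 1e-9) {
    stop(sprintf("solved y = %.4f lies outside [0, 1]; check the rate %s",
                 y, "ratios"), call. = FALSE)
  }
  y <- min(max(y, 0), 1)
  if (x < sub$x_range[1] || x > sub$x_range[2]) {
    stop(sprintf("solved x = %.4f outside the admissible range [%g, %g]",
                 x, sub$x_range[1], sub$x_range[2]), call. = FALSE)
  }
  if (x < 0) {
    warning(sprintf(
      "x = %.4f < 0: net co-oxidation of stored elemental sulfur", x),
      call. = FALSE)
  }
  list(x = x, y = y, ratios = c(tea = r, co2 = co2),
       stoichiometry = suppressWarnings(
         overall_equation(substrate, tea, x, y)))
}

#' Correct whole-association rates for host respiration
#'
#' For symbiont-bearing animals, part of the measured whole-association O2
#' consumption is host respiration; the CO2 it releases adds to the pool
#' available to the symbionts.  Symbiont O2 = whole O2 * (1 - f); symbiont
#' CO2 = whole CO2 + RQ * f * whole O2.
#'
#' @param rates A [rate_set()] (consumption-positive) with O2 and CO2.
#' @param host_o2_fraction Fraction f of whole O2 uptake respired by the
#'   host, in \[0, 1).
#' @param respiratory_quotient Moles CO2 released per mole O2 respired.
#' @return The corrected `sox_rate_set`.
#' @examples
#' r <- rate_set(c(H2S = 6.75, O2 = 12.4, CO2 = 12.45))
#' adjust_for_host(r, host_o2_fraction = 0.25)  # O2 9.3, CO2 15.55
#' @export
adjust_for_host <- function(rates, host_o2_fraction,
                            respiratory_quotient = 1) {
  stopifnot(inherits(rates, "sox_rate_set"))
  f <- host_o2_fraction
  if (f < 0 || f >= 1) {
    stop("host_o2_fraction must lie in [0, 1)", call. = FALSE)
  }
  v <- rates$rates
  if (!all(c("O2", "CO2") %in% names(v))) {
    stop("rate set must contain O2 and CO2", call. = FALSE)
  }
  o2 <- v[["O2"]]
  v[["O2"]] <- o2 * (1 - f)
  v[["CO2"]] <- v[["CO2"]] + respiratory_quotient * f * o2
  rate_set(v, convention = rates$convention, unit = rates$unit)
}
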