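#' Energetics of a CO2 fixation pathway
#'
#' ATP-equivalent energy requirement and energy conservation efficiency of
#' the fixation step itself: `dE = atp_per_co2 * atp_energy` and
#' `epsilon_co2 = dg_fix / dE` (about 0.57 for the Calvin cycle, 69.7/123,
#' and 0.94 for the rTCA cycle, 64.3/68.3).
#'
#' @inheritParams ret_equation
#' @param table A [thermo_table()] (source of the ATP energy content).
#' @return List with `dg_fix`, `de_fix` (kJ per mol CO2) and `epsilon_co2`.
#' @export
pathway_energetics <- function(pathway = "calvin", table = thermo_table()) {
  pw <- carbon_pathway(pathway)
  de <- pw$atp_per_co2 * table$atp_energy
  list(pathway = pw$id, dg_fix = pw$dg_fix, de_fix = de,
       epsilon_co2 = pw$dg_fix / de)
}

## Gibbs-energy components shared by the efficiency definitions, all per
## mole of sulfur substrate.  dg_fix_total spreads the per-CO2 pathway
## requirement over the E(x)/4 moles of CO2 the substrate can reduce.
.dg_components <- function(x, substrate, tea, pathway = NULL,
                           cond = standard_conditions(),
                           table = thermo_table()) {
  sub <- sulfur_substrate(substrate)
  e_yield <- .electron_yield(sub, x)
  out <- list(
    e_yield = e_yield,
    dg_energy = delta_g(energy_equation(substrate, tea, x), cond,
                        table)$total,
    dg_co2red = delta_g(assimilation_equation(substrate, x), cond,
                        table)$total
  )
  if (!is.null(pathway)) {
    pw <- pathway_energetics(pathway, table)
    out$dg_ret <- delta_g(ret_equation(substrate, pathway, x), cond,
                          table)$total
    out$dg_fix_total <- e_yield / 4 * pw$dg_fix
    out$de_fix_total <- e_yield / 4 * pw$de_fix
    out$epsilon_co2 <- pw$epsilon_co2
  }
  out
}

.check_efficiency_inputs <- function(y, dg_energy, dg_endergonic) {
  if (y == 0) stop("y = 0: no substrate routed to energy generation",
                   call. = FALSE)
  if (y < 0 || y > 1) stop("y must lie in (0, 1]", call. = FALSE)
  if (dg_energy >= 0 || dg_endergonic <= 0) {
    stop(sprintf(paste0(
      "efficiency undefined: energy reaction dGr = %.2f kJ/mol must be ",
      "exergonic and the CO2-reducing side dGr = %.2f kJ/mol endergonic ",
      "at these conditions"), dg_energy, dg_endergonic), call. = FALSE)
  }
}

#' Traditional energy conservation efficiency
#'
#' Ratio of the Gibbs free energy stored by net CO2 reduction to the Gibbs
#' free energy released by the energy-generating reaction:
#' `eps_I = (1 - y) dGr(CO2 red) / (-y dGr(TEA red))`.
#'
#' @inheritParams overall_equation
#' @param cond A [conditions()] object.
#' @param table A [thermo_table()].
#' @return Unitless efficiency (0 when `y = 1`).
#' @examples
#' efficiency_traditional(x = 0, y = 0.825)  # about 0.037
#' @export
efficiency_traditional <- function(x, y, substrate = "sulfide",
                                   tea = "aerobic",
                                   cond = standard_conditions(),
                                   table = thermo_table()) {
  if (y == 1) return(0)
  dg <- .dg_components(x, substrate, tea, cond = cond, table = table)
  .check_efficiency_inputs(y, dg$dg_energy, dg$dg_co2red)
  (1 - y) * dg$dg_co2red / (-y * dg$dg_energy)
}

#' Carrier-explicit energy conservation efficiency
#'
#' Accounts for the fact that CO2 reduction proceeds in two steps -- the
#' reverse electron transport (RET) that reduces the pathway's electron
#' carriers, and the fixation reaction itself:
#' `eps_II = (1 - y) [dGr(RET) + dGr(CO2 fix)] / (-y dGr(TEA red))` with
#' `dGr(CO2 fix) = E(x)/4 * dg_fix` per mole of substrate.  Always larger
#' than the traditional efficiency.
#'
#' @inheritParams efficiency_traditional
#' @inheritParams ret_equation
#' @examples
#' efficiency_new(x = 0, y = 0.825)  # about 0.096
#' @export
efficiency_new <- function(x, y, substrate = "sulfide", tea = "aerobic",
                           pathway = "calvin",
                           cond = standard_conditions(),
                           table = thermo_table()) {
  if (y == 1) return(0)
  dg <- .dg_components(x, substrate, tea, pathway, cond, table)
  numer <- dg$dg_ret + dg$dg_fix_total
  .check_efficiency_inputs(y, dg$dg_energy, numer)
  (1 - y) * numer / (-y * dg$dg_energy)
}

#' Factorized efficiency breakdown
#'
#' Splits the carrier-explicit efficiency into the partial efficiencies of
#' ATP generation by sulfur oxidation (eps_SO), ATP use by RET (eps_RET),
#' by the fixation pathway (eps_CO2, a known constant per pathway) and ATP
#' transfer (eps_t).  Only minimum bounds of the unknown partials are
#' identifiable: e.g. `eps_SO,min = eps_II * [alpha / eps_CO2 + (1 -
#' alpha)]` with `alpha = dGr(CO2 fix) / [dGr(RET) + dGr(CO2 fix)]`,
#' attained when eps_RET = eps_t = 1.
#'
#' @inheritParams efficiency_new
#' @return An object of class `sox_efficiency_breakdown`: a list with
#'   `epsilon_I`, `epsilon_II`, the component Gibbs energies (`dg_energy`,
#'   `dg_co2red`, `dg_ret`, `dg_fix_total`, `de_fix_total`, kJ per mol
#'   substrate), `alpha`, `epsilon_co2`, and the minimum partial
#'   efficiencies `epsilon_so_min`, `epsilon_t_min`, `epsilon_ret_min`.
#' @examples
#' factorize_efficiency(x = 0, y = 0.844, substrate = "thiosulfate")
#' @export
factorize_efficiency <- function(x, y, substrate = "sulfide",
                                 tea = "aerobic", pathway = "calvin",
                                 cond = standard_conditions(),
                                 table = thermo_table()) {
  dg <- .dg_components(x, substrate, tea, pathway, cond, table)
  numer <- dg$dg_ret + dg$dg_fix_total
  if (y < 1) .check_efficiency_inputs(y, dg$dg_energy, numer)
  eps_i <- if (y == 1) 0 else
    (1 - y) * dg$dg_co2red / (-y * dg$dg_energy)
  eps_ii <- if (y == 1) 0 else (1 - y) * numer / (-y * dg$dg_energy)
  alpha <- dg$dg_fix_total / numer
  eps_co2 <- dg$epsilon_co2
  eps_so_min <- eps_ii * (alpha / eps_co2 + (1 - alpha))
  eps_ret_min <- eps_ii * (1 - alpha) * eps_co2 /
    (eps_co2 - alpha * eps_ii)
  structure(
    list(epsilon_I = eps_i, epsilon_II = eps_ii,
         dg_energy = dg$dg_energy, dg_co2red = dg$dg_co2red,
         dg_ret = dg$dg_ret, dg_fix_total = dg$dg_fix_total,
         de_fix_total = dg$de_fix_total, alpha = alpha,
         epsilon_co2 = eps_co2, epsilon_so_min = eps_so_min,
         epsilon_t_min = eps_so_min, epsilon_ret_min = eps_ret_min,
         x = x, y = y, substrate = substrate, tea = tea,
         pathway = pathway),
    class = "sox_efficiency_breakdown"
  )
}

#' @export
print.sox_efficiency_breakdown <- function(x, ...) {
  cat(sprintf(
    "eps_I = %.4f, eps_II = %.4f (x = %g, y = %g, %s/%s/%s)\n",
    x$epsilon_I, x$epsilon_II, x$x, x$y, x$substrate, x$tea, x$pathway))
  cat(sprintf(
    "  dGr: energy %.2f, CO2 red %.2f, RET %.2f, fix %.2f kJ/mol\n",
    x$dg_energy, x$dg_co2red, x$dg_ret, x$dg_fix_total))
  cat(sprintf(
    "  alpha = %.4f, eps_CO2 = %.2f, minima: SO %.4f, t %.4f, RET %.4f\n",
    x$alpha, x$epsilon_co2, x$epsilon_so_min, x$epsilon_t_min,
    x$epsilon_ret_min))
  invisible(x)
}

#' CO2 : TEA consumption ratio (growth yield proxy)
#'
#' Moles of CO2 fixed per mole of terminal electron acceptor consumed.
#' From the overall-equation coefficients this is
#' `(1 - y)/y * n_tea / 4` for every substrate and partition `x`, where
#' `n_tea` is the electrons accepted per mole of TEA (4 for O2, so the
#' aerobic ratio is simply `(1 - y)/y`; 5 for denitrification, 8 for
#' DNRA).
#'
#' @param y Fraction of the substrate pool used for energy generation,
#'   in (0, 1\].
#' @param tea Terminal electron acceptor process.
#' @return Unitless ratio (0 at `y = 1`).
#' @examples
#' co2_tea_ratio(0.825)  # 0.212: about 0.21 mol CO2 per mol O2
#' @export
co2_tea_ratio <- function(y, tea = "aerobic") {
  if (any(y <= 0)) stop("y must be > 0", call. = FALSE)
  if (any(y > 1)) stop("y must be <= 1", call. = FALSE)
  acc <- tea_process(tea)
  (1 - y) / y * acc$electrons_per_mole / 4
}
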