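#' Strain specification
#'
#' Minimal description of one organism/experiment for the sensitivity and
#' reporting tools: the substrate, acceptor process, C-fixation pathway and
#' the reaction parameters `(x, y)`.
#'
#' @inheritParams overall_equation
#' @inheritParams ret_equation
#' @param name Optional display name.
#' @return A list of class `sox_strain`.
#' @export
strain_spec <- function(substrate, tea, pathway, x, y, name = NULL) {
  sulfur_substrate(substrate); tea_process(tea); carbon_pathway(pathway)
  if (y <= 0 || y > 1) stop("y must lie in (0, 1]", call. = FALSE)
  structure(list(substrate = substrate, tea = tea, pathway = pathway,
                 x = x, y = y,
                 name = if (is.null(name)) substrate else name),
            class = "sox_strain")
}

.strain_efficiency <- function(strain, target, cond, table) {
  switch(target,
    epsilon_I = efficiency_traditional(strain$x, strain$y,
                                       strain$substrate, strain$tea,
                                       cond, table),
    epsilon_II = efficiency_new(strain$x, strain$y, strain$substrate,
                                strain$tea, strain$pathway, cond, table),
    epsilon_so_min = factorize_efficiency(
      strain$x, strain$y, strain$substrate, strain$tea, strain$pathway,
      cond, table)$epsilon_so_min,
    stop("unknown target ", target, call. = FALSE)
  )
}

## species whose concentration can influence the given target
.scan_species <- function(strain, target) {
  eqs <- list(energy_equation(strain$substrate, strain$tea, strain$x))
  if (target == "epsilon_I") {
    eqs <- c(eqs, list(assimilation_equation(strain$substrate, strain$x)))
  } else {
    eqs <- c(eqs, list(ret_equation(strain$substrate, strain$pathway,
                                    strain$x)))
  }
  sp <- unique(unlist(lapply(eqs, function(e) names(e$coefficients))))
  setdiff(sp, c("S0", "H2O", "H+"))
}

#' Efficiency sensitivity scan
#'
#' Recomputes a chosen efficiency while one reactant concentration (or the
#' pH) is varied and everything else -- including the stoichiometry `(x, y)`
#' -- is held at standard biochemical conditions.  Quantifies the error
#' introduced by unreported experimental concentrations.
#'
#' @param strain A [strain_spec()].
#' @param variable A species identifier (e.g. `"CO2"`, `"O2"`, `"NAD+"`)
#'   or `"pH"`.
#' @param values Concentrations in M (or pH values).  A pH scan moves the
#'   proton activity in every quotient simultaneously.
#' @param target `"epsilon_I"`, `"epsilon_II"` or `"epsilon_so_min"`.
#' @inheritParams efficiency_new
#' @return Data frame with columns `value` and `efficiency`.
#' @examples
#' ms816 <- strain_spec("sulfide", "aerobic", "calvin", 0, 0.825)
#' sensitivity_scan(ms816, "CO2", c(1e-3, 1), "epsilon_I")
#' @export
sensitivity_scan <- function(strain, variable, values,
                             target = c("epsilon_I", "epsilon_II",
                                        "epsilon_so_min"),
                             cond = standard_conditions(),
                             table = thermo_table()) {
  stopifnot(inherits(strain, "sox_strain"))
  target <- match.arg(target)
  if (!length(values)) {
    return(data.frame(value = numeric(), efficiency = numeric()))
  }
  if (variable != "pH" &&
      !(variable %in% .scan_species(strain, target))) {
    stop(sprintf(
      "species '%s' does not appear in the reactions behind %s",
      variable, target), call. = FALSE)
  }
  eff <- vapply(values, function(v) {
    cnd <- if (variable == "pH") {
      conditions(cond$concentrations, pH = v,
                 temperature = cond$temperature,
                 default_concentration = cond$default_concentration,
                 warn_missing = FALSE)
    } else {
      cc <- cond$concentrations
      cc[variable] <- v
      conditions(cc, pH = cond$pH, temperature = cond$temperature,
                 default_concentration = cond$default_concentration,
                 warn_missing = FALSE)
    }
    .strain_efficiency(strain, target, cnd, table)
  }, numeric(1))
  data.frame(value = values, efficiency = eff)
}

#' Concentration shift equalizing two strains' efficiencies
#'
#' Finds the fold-change in one species' concentration (applied to strain A
#' only, relative to the 1 M standard state), or the pH, at which the two
#' strains' efficiencies become equal.  Root-found to 1e-6 in log10(fold)
#' space.  Large required shifts mean the efficiency comparison is robust
#' to uncertainty in that concentration.
#'
#' @param strain_a,strain_b [strain_spec()] objects; the shift is applied
#'   to `strain_a`.
#' @inheritParams sensitivity_scan
#' @param fold_limits Log10 search interval for the fold-change.
#' @return List with `variable`, `target`, `equalizable`, and either
#'   `fold` + `log10_fold` or (for `variable = "pH"`) `pH`.
#' @export
equalizing_shift <- function(strain_a, strain_b, variable,
                             target = c("epsilon_I", "epsilon_II",
                                        "epsilon_so_min"),
                             cond = standard_conditions(),
                             table = thermo_table(),
                             fold_limits = c(-30, 30)) {
  target <- match.arg(target)
  eff_b <- .strain_efficiency(strain_b, target, cond, table)
  ## the efficiency is undefined where the shifted conditions turn the
  ## energy reaction endergonic (or the CO2-reducing side exergonic);
  ## treat such points as outside the search domain
  gap <- function(v) {
    tryCatch(
      sensitivity_scan(strain_a, variable, v, target, cond,
                       table)$efficiency - eff_b,
      error = function(e) NA_real_)
  }
  find_root <- function(axis) {
    fv <- vapply(axis, gap, numeric(1))
    ok <- which(is.finite(fv))
    hit <- ok[which(fv[ok][-1] * fv[ok][-length(ok)] <= 0)]
    if (!length(hit)) return(NA_real_)
    i <- hit[1]; j <- ok[which(ok == i) + 1]
    stats::uniroot(gap, lower = axis[i], upper = axis[j],
                   f.lower = fv[i], f.upper = fv[j], tol = 1e-6)$root
  }
  out <- list(variable = variable, target = target)
  if (variable == "pH") {
    if (abs(gap(cond$pH)) < 1e-12) {
      return(c(out, list(equalizable = TRUE, pH = cond$pH)))
    }
    root <- find_root(seq(0, 14, length.out = 57))
    if (is.na(root)) {
      warning("not equalizable within pH [0, 14]", call. = FALSE)
      return(c(out, list(equalizable = FALSE, pH = NA_real_)))
    }
    return(c(out, list(equalizable = TRUE, pH = root)))
  }
  gap_of_log <- gap
  gap <- function(lg) gap_of_log(10 ^ lg)
  if (abs(gap(0)) < 1e-12) {
    return(c(out, list(equalizable = TRUE, fold = 1, log10_fold = 0)))
  }
  lg <- find_root(seq(fold_limits[1], fold_limits[2], length.out = 121))
  if (is.na(lg)) {
    warning(sprintf("not equalizable within 10^[%g, %g]-fold",
                    fold_limits[1], fold_limits[2]), call. = FALSE)
    return(c(out, list(equalizable = FALSE, fold = NA_real_,
                       log10_fold = NA_real_)))
  }
  c(out, list(equalizable = TRUE, fold = 10 ^ lg, log10_fold = lg))
}
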