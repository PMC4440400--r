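## The carrier-explicit efficiency separates as
##   eps_II(x, y) = (1 - y)/y * K(x),
## with K(x) = [dGr(RET) + dGr(CO2 fix)] / (-dGr(TEA red)) depending on x
## (and the conditions) only.  The inverse problems below exploit this:
## given eps_II, y follows in closed form as y = K / (eps + K).
.k_ratio <- function(x, substrate, tea, pathway,
                     cond = standard_conditions(),
                     table = thermo_table()) {
  dg <- .dg_components(x, substrate, tea, pathway, cond, table)
  (dg$dg_ret + dg$dg_fix_total) / (-dg$dg_energy)
}

#' Constraint for the limited-rate inverse solver
#'
#' Second relation between `x` and `y` used when only one rate ratio was
#' measured.  `constant_efficiency` holds the carrier-explicit efficiency
#' at its reference value (typically the value calibrated at `x = 0`);
#' `linear_efficiency` interpolates it linearly from `reference_value` at
#' `x = 0` to `terminal_value` at `x = 1`; `constant_co2_tea` holds the
#' CO2 : TEA yield instead.
#'
#' @param kind One of `"constant_efficiency"`, `"constant_co2_tea"`,
#'   `"linear_efficiency"`.
#' @param reference_value Efficiency (fraction) or CO2 : TEA ratio at
#'   `x = 0`.
#' @param terminal_value Efficiency at `x = 1` (linear kind only).
#' @return An object of class `sox_constraint`.
#' @export
inverse_constraint <- function(kind = c("constant_efficiency",
                                        "constant_co2_tea",
                                        "linear_efficiency"),
                               reference_value, terminal_value = 0) {
  kind <- match.arg(kind)
  if (reference_value <= 0) {
    stop("reference_value must be > 0", call. = FALSE)
  }
  structure(list(kind = kind, reference_value = reference_value,
                 terminal_value = terminal_value),
            class = "sox_constraint")
}

.constraint_target <- function(constraint, x) {
  switch(constraint$kind,
    constant_efficiency = constraint$reference_value,
    linear_efficiency = constraint$reference_value * (1 - x) +
      constraint$terminal_value * x,
    stop("no efficiency target for kind ", constraint$kind, call. = FALSE)
  )
}

#' Full stoichiometry from one rate ratio plus a constraint
#'
#' Solves for the pair `(x, y)` that satisfies both the measured
#' TEA : substrate consumption ratio (`ratio = y * E(x)/n_tea`) and the
#' supplied constraint.  `y` is eliminated analytically through the ratio
#' relation; the residual in `x` is then root-found on a bracketed grid
#' (64 pre-scan subintervals, tolerance 1e-10 in `x`).  With several sign
#' changes the smallest root is returned with a warning.
#'
#' @param ratio_value Measured TEA : substrate consumption ratio.
#' @param constraint An [inverse_constraint()].
#' @inheritParams efficiency_new
#' @return List with `x`, `y`, the implied overall `stoichiometry` and the
#'   constraint `residual` at the solution.
#' @examples
#' con <- inverse_constraint("constant_efficiency",
#'                           efficiency_new(0, 0.825))
#' solve_constrained(0.5, con)  # x = 0.920, y = 0.807
#' @export
solve_constrained <- function(ratio_value, constraint,
                              substrate = "sulfide", tea = "aerobic",
                              pathway = "calvin",
                              cond = standard_conditions(),
                              table = thermo_table()) {
  stopifnot(inherits(constraint, "sox_constraint"))
  if (ratio_value <= 0) stop("ratio_value must be > 0", call. = FALSE)
  sub <- sulfur_substrate(substrate)
  acc <- tea_process(tea)
  y_of_x <- function(x) {
    ratio_value * acc$electrons_per_mole / .electron_yield(sub, x)
  }
  residual <- function(x) {
    y <- y_of_x(x)
    if (constraint$kind == "constant_co2_tea") {
      (1 - y) / y * acc$electrons_per_mole / 4 -
        constraint$reference_value
    } else {
      ## suppress the stored-S0 advisory while scanning the bracket;
      ## the returned root is vetted below
      k <- suppressWarnings(
        .k_ratio(x, substrate, tea, pathway, cond, table))
      (1 - y) / y * k - .constraint_target(constraint, x)
    }
  }
  lo <- sub$x_range[1]
  hi <- min(sub$x_range[2], 1) - 1e-9
  grid <- seq(lo, hi, length.out = 65)
  fval <- vapply(grid, residual, numeric(1))
  flips <- which(fval[-1] * fval[-length(fval)] <= 0 & is.finite(fval[-1]))
  if (!length(flips)) {
    stop(sprintf(paste0(
      "no solution in the admissible x domain [%g, %g]: residuals %.4g ",
      "at x = %g and %.4g at x = %g"), lo, hi, fval[1], lo,
      fval[length(fval)], hi), call. = FALSE)
  }
  roots <- vapply(flips, function(i) {
    stats::uniroot(residual, lower = grid[i], upper = grid[i + 1],
                   tol = 1e-10)$root
  }, numeric(1))
  roots <- roots[!duplicated(round(roots, 8))]
  roots <- roots[y_of_x(roots) > 0 & y_of_x(roots) <= 1 + 1e-9]
  if (!length(roots)) {
    stop("roots found, but none with y in (0, 1]", call. = FALSE)
  }
  if (length(roots) > 1) {
    warning(sprintf(
      "multiple roots (%s); returning the smallest x",
      paste(sprintf("%.4f", roots), collapse = ", ")), call. = FALSE)
  }
  x <- min(roots)
  y <- min(y_of_x(x), 1)
  if (x < sub$x_warn_below) {
    warning(sprintf(
      "x = %.4f implies a very large stored-S0 co-oxidation term", x),
      call. = FALSE)
  }
  list(x = x, y = y,
       stoichiometry = suppressWarnings(
         overall_equation(substrate, tea, x, y)),
       residual = residual(x))
}

#' CO2 : TEA yield over the product-partition range
#'
#' For each `x` of a grid, solves `y` from the efficiency constraint in
#' closed form (`y = K/(eps + K)`) and reports the implied CO2 : TEA
#' consumption ratio.  Used to judge how strongly the growth yield per
#' mole of acceptor depends on the (usually unknown) S0 : SO4 product
#' partition.
#'
#' @param x_grid Numeric vector of partition parameters.
#' @inheritParams solve_constrained
#' @return Data frame with columns `x`, `y`, `co2_tea`, `epsilon_II`.
#' @export
co2_tea_curve <- function(x_grid, constraint, substrate = "sulfide",
                          tea = "aerobic", pathway = "calvin",
                          cond = standard_conditions(),
                          table = thermo_table()) {
  stopifnot(inherits(constraint, "sox_constraint"))
  if (constraint$kind == "constant_co2_tea") {
    stop("use an efficiency-based constraint for the yield curve",
         call. = FALSE)
  }
  acc <- tea_process(tea)
  rows <- lapply(x_grid, function(x) {
    eps <- .constraint_target(constraint, x)
    k <- .k_ratio(x, substrate, tea, pathway, cond, table)
    y <- k / (eps + k)
    data.frame(x = x, y = y,
               co2_tea = (1 - y) / y * acc$electrons_per_mole / 4,
               epsilon_II = eps)
  })
  do.call(rbind, rows)
}

#' Efficiency band matching an environmental flux-ratio range
#'
#' A sulfur oxidizer that tracks a fluctuating TEA : substrate supply ratio
#' by switching between incomplete (`x = 1`, all S0) and complete (`x = 0`,
#' all sulfate) oxidation must span the efficiency band computed here:
#' `y` is solved from the ratio at each extreme and the carrier-explicit
#' efficiency evaluated at both ends.
#'
#' @param ratio_low,ratio_high Lower/upper TEA : substrate flux ratios
#'   (low is matched at `x = 1`, high at `x = 0`).
#' @inheritParams solve_constrained
#' @return Data frame with rows at `x = 1` and `x = 0`: `end`, `x`,
#'   `ratio`, `y`, `epsilon_II`.
#' @examples
#' niche_band(0.45, 1.7)  # eps_II about 4.3% and 8.0%
#' @export
niche_band <- function(ratio_low, ratio_high, substrate = "sulfide",
                       tea = "aerobic", pathway = "calvin",
                       cond = standard_conditions(),
                       table = thermo_table()) {
  if (ratio_low <= 0 || ratio_high < ratio_low) {
    stop("need 0 < ratio_low <= ratio_high", call. = FALSE)
  }
  sub <- sulfur_substrate(substrate)
  acc <- tea_process(tea)
  degenerate <- isTRUE(all.equal(ratio_low, ratio_high))
  ends <- if (degenerate) {
    data.frame(end = "complete", x = 0, ratio = ratio_high)
  } else {
    data.frame(end = c("incomplete", "complete"), x = c(1, 0),
               ratio = c(ratio_low, ratio_high))
  }
  ends$y <- ends$ratio * acc$electrons_per_mole /
    .electron_yield(sub, ends$x)
  if (any(ends$y > 1 + 1e-9)) {
    bad <- ends[ends$y > 1 + 1e-9, ]
    stop(sprintf(
      "ratio %.3g exceeds the maximum coefficient %.3g at x = %g",
      bad$ratio[1],
      .electron_yield(sub, bad$x[1]) / acc$electrons_per_mole,
      bad$x[1]), call. = FALSE)
  }
  ends$y <- pmin(ends$y, 1)
  ends$epsilon_II <- mapply(function(x, y) {
    if (y >= 1) {
      warning("y = 1 at x = ", x, ": no CO2 fixation, efficiency 0",
              call. = FALSE)
      0
    } else {
      efficiency_new(x, y, substrate, tea, pathway, cond, table)
    }
  }, ends$x, ends$y)
  ends
}
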