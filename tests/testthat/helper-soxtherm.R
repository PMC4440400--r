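## shared fixtures built in code

coef_of <- function(stoich, species) {
  v <- stoich$coefficients
  if (species %in% names(v)) unname(v[[species]]) else 0
}

## every substrate/TEA/pathway combination the builders support
all_combos <- expand.grid(
  substrate = c("sulfide", "thiosulfate"),
  tea = c("aerobic", "denitrification", "dnra"),
  stringsAsFactors = FALSE
)

## admissible x grid per substrate (interior points only)
x_grid_for <- function(substrate, n = 7) {
  if (substrate == "sulfide") seq(-1.5, 1, length.out = n)
  else seq(0, 1, length.out = n)
}

ms816 <- strain_spec("sulfide", "aerobic", "calvin", 0, 0.825,
                     "Beggiatoa MS-81-6")
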