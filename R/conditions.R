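#' Physical constants and experimental conditions
#'
#' Every fitting routine in the package works in a single unit system:
#' energies in kcal mol^-1, rates in s^-1, denaturant concentrations in
#' mol L^-1, temperatures in kelvin. A `fold_conditions` object carries the
#' temperature, the (kcal-based) gas constant and descriptive metadata so
#' that thermodynamic conversions are explicit and auditable.
#'
#' @param temperature Sample temperature in kelvin. Default 298 K, the
#'   temperature at which the stopped-flow and equilibrium experiments this
#'   package models are run.
#' @param denaturant Name of the chemical denaturant (label only).
#' @param ph_or_pd Solution pH (or pD for exchange experiments in D2O).
#'
#' @return An object of class `fold_conditions`: a list with elements
#'   `temperature`, `gas_constant` (1.9872e-3 kcal mol^-1 K^-1),
#'   `denaturant`, `ph_or_pd`.
#' @examples
#' cond <- fold_conditions()
#' rt(cond) # 0.592 kcal/mol at 298 K
#' @export
fold_conditions <- function(temperature = 298, denaturant = "urea",
                            ph_or_pd = 7.6) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive number (kelvin)")
  }
  structure(
    list(
      temperature = as.numeric(temperature),
      gas_constant = 1.9872e-3,
      denaturant = denaturant,
      ph_or_pd = ph_or_pd
    ),
    class = "fold_conditions"
  )
}

#' Thermal energy RT
#'
#' @param conditions A [fold_conditions()] object.
#' @return R*T in kcal mol^-1.
#' @examples
#' rt(fold_conditions(temperature = 310))
#' @export
rt <- function(conditions = fold_conditions()) {
  stopifnot(inherits(conditions, "fold_conditions"))
  conditions$gas_constant * conditions$temperature
}

#' @export
print.fold_conditions <- function(x, ...) {
  cat(sprintf(
    "<fold_conditions> T = %g K, RT = %.5f kcal/mol, denaturant = %s, pH/pD = %g\n",
    x$temperature, rt(x), x$denaturant, x$ph_or_pd
  ))
  invisible(x)
}
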