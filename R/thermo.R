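#' Thermodynamic context
#'
#' Bundles the absolute temperature and the gas constant so that every
#' free-energy conversion in the package uses one consistent \eqn{RT}.
#' The default temperature is 297.65 K (24.5 C, the bench temperature at
#' which the steric-trapping titrations equilibrate); molecular-dynamics
#' derived quantities typically use 310 K (the simulation thermostat) and
#' the three-state chemical denaturation fits 310.15 K (37 C incubation).
#'
#' @param temperature absolute temperature in kelvin.
#' @param gas_constant gas constant in kcal mol^-1 K^-1.
#' @return An object of class `thermo_context` with fields `temperature`,
#'   `gas_constant` and the precomputed product `rt` (kcal/mol).
#' @examples
#' ctx <- thermo_context()            # 24.5 C bench conditions
#' ctx$rt                             # ~0.5914 kcal/mol
#' thermo_context(310)$rt             # ~0.616 kcal/mol, simulation thermostat
#' @export
thermo_context <- function(temperature = 297.65, gas_constant = 1.987e-3) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L, is.finite(temperature),
            is.numeric(gas_constant), length(gas_constant) == 1L, is.finite(gas_constant))
  if (temperature <= 0) stop("temperature must be > 0 K")
  if (gas_constant <= 0) stop("gas_constant must be > 0")
  structure(
    list(temperature = temperature, gas_constant = gas_constant,
         rt = gas_constant * temperature),
    class = "thermo_context"
  )
}

#' @export
print.thermo_context <- function(x, ...) {
  cat(sprintf("Thermodynamic context: T = %.2f K, R = %.4g kcal/(mol K), RT = %.4f kcal/mol\n",
              x$temperature, x$gas_constant, x$rt))
  invisible(x)
}

as_thermo_context <- function(context) {
  if (is.null(context)) return(thermo_context())
  if (inherits(context, "thermo_context")) return(context)
  if (is.numeric(context) && length(context) == 1L) return(thermo_context(context))
  stop("`context` must be a thermo_context or a temperature in kelvin")
}

#' Thermal energy RT
#'
#' @param context a [thermo_context()] (or a bare temperature in kelvin).
#' @return RT in kcal/mol.
#' @export
rt_energy <- function(context = thermo_context()) {
  as_thermo_context(context)$rt
}

#' Convert a denaturation equilibrium constant to a folding free energy
#'
#' The folding free energy is the free-energy change of the
#' denatured-to-native transition,
#' \deqn{\Delta G^\circ_{N-D} = -RT \ln(1/K_D) = RT \ln K_D,}
#' where \eqn{K_D = [D]/[N]} is the denaturation equilibrium constant.
#' Negative values mean a stable protein. `kd_from_dg()` is the exact
#' inverse.
#'
#' @param k_denat denaturation equilibrium constant, dimensionless, > 0.
#' @param context a [thermo_context()].
#' @return Free energy in kcal/mol.
#' @examples
#' dg_from_kd(1)                 # 0
#' kd_from_dg(dg_from_kd(1e-5))  # round-trips
#' @export
dg_from_kd <- function(k_denat, context = thermo_context()) {
  ctx <- as_thermo_context(context)
  if (any(!is.finite(k_denat)) || any(k_denat <= 0))
    stop("k_denat must be finite and > 0")
  ctx$rt * log(k_denat)
}

#' @rdname dg_from_kd
#' @param dg_nd folding free energy (kcal/mol).
#' @export
kd_from_dg <- function(dg_nd, context = thermo_context()) {
  ctx <- as_thermo_context(context)
  if (any(!is.finite(dg_nd))) stop("dg_nd must be finite")
  exp(dg_nd / ctx$rt)
}
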