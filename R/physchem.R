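# Physical constants (SI). Values as conventionally printed for
# electrolyte-screening calculations.
.const <- list(
  eps0 = 8.854e-12,    # vacuum permittivity, F/m
  kB   = 1.381e-23,    # Boltzmann constant, J/K
  NA_  = 6.022e23,     # Avogadro's number, 1/mol
  e    = 1.602e-19     # elementary charge, C
)

#' Electrolyte conditions
#'
#' Container for the parameters entering the Debye screening length:
#' relative permittivity, absolute temperature and ionic strength.
#'
#' @param epsilon_r relative permittivity (dimensionless), e.g. 78.5 for
#'   water at 25 degC.
#' @param temperature absolute temperature in K.
#' @param ionic_strength ionic strength in mol/L. Either supply it directly
#'   or give `ions`, a data frame with columns `conc` (mol/L) and `z`
#'   (valence), from which I = 1/2 * sum(c_i * z_i^2) is computed.
#' @param ions optional data frame of ion concentrations and valences.
#'
#' @return An object of class `electrolyte_conditions`.
#' @examples
#' electrolyte_conditions(78.5, 298, 0.15)
#' # 150 mM KCl specified ion by ion:
#' electrolyte_conditions(78.5, 298,
#'   ions = data.frame(conc = c(0.15, 0.15), z = c(1, -1)))
#' @export
electrolyte_conditions <- function(epsilon_r, temperature,
                                   ionic_strength = NULL, ions = NULL) {
  if (is.null(ionic_strength)) {
    if (is.null(ions)) stop("supply `ionic_strength` or `ions`")
    stopifnot(is.data.frame(ions), all(c("conc", "z") %in% names(ions)))
    ionic_strength <- 0.5 * sum(ions$conc * ions$z^2)
  }
  if (!is.numeric(epsilon_r) || epsilon_r <= 0) stop("epsilon_r must be > 0")
  if (!is.numeric(temperature) || temperature <= 0) stop("temperature must be > 0")
  if (!is.numeric(ionic_strength) || ionic_strength <= 0)
    stop("ionic_strength must be > 0")
  structure(list(epsilon_r = epsilon_r, temperature = temperature,
                 ionic_strength = ionic_strength),
            class = "electrolyte_conditions")
}

#' Debye screening length
#'
#' Computes the Debye length
#' \deqn{\lambda_D = \sqrt{\frac{\varepsilon_r \varepsilon_0 k_B T}
#'                              {2 N_A e^2 I}}}
#' the distance over which electrostatic interactions are screened in an
#' electrolyte. Ionic strength is converted from mol/L to mol/m^3
#' internally; the result is returned in nm.
#'
#' @param cond an [electrolyte_conditions] object, or a relative
#'   permittivity if `temperature` and `ionic_strength` are given directly.
#' @param temperature,ionic_strength convenience scalars used when `cond`
#'   is numeric.
#'
#' @return Debye length in nm.
#' @examples
#' debye_length(electrolyte_conditions(78.5, 298, 0.15))  # ~ 0.8 nm
#' @export
debye_length <- function(cond, temperature = NULL, ionic_strength = NULL) {
  if (is.numeric(cond)) {
    cond <- electrolyte_conditions(cond, temperature, ionic_strength)
  }
  stopifnot(inherits(cond, "electrolyte_conditions"))
  I_m3 <- cond$ionic_strength * 1000   # mol/L -> mol/m^3
  lam_m <- sqrt(cond$epsilon_r * .const$eps0 * .const$kB * cond$temperature /
                  (2 * .const$NA_ * .const$e^2 * I_m3))
  lam_m * 1e9
}
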