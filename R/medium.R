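# Seawater state: mass density and kinematic viscosity from temperature and
# salinity, plus gravitational acceleration. All SI (kg m^-3, m^2 s^-1, m s^-2).

# One-atmosphere equation of state of seawater (EOS-80, Millero & Poisson
# 1981): density in kg m^-3 from temperature (deg C, ITS-68 approximated by
# ITS-90 here) and practical salinity.
sw_density <- function(temperature, salinity) {
  t <- temperature
  s <- salinity
  rho0 <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  a <- 0.824493 - 4.0899e-3 * t + 7.6438e-5 * t^2 - 8.2467e-7 * t^3 +
    5.3875e-9 * t^4
  b <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  c <- 4.8314e-4
  rho0 + a * s + b * s^1.5 + c * s^2
}

# Dynamic viscosity of seawater (Sharqawy, Lienhard & Zubair 2010), Pa s.
# Pure-water part is the IAPWS-based correlation; salinity enters as a
# quadratic correction in salt mass fraction (kg/kg).
sw_dynamic_viscosity <- function(temperature, salinity) {
  t <- temperature
  s <- salinity / 1000 # practical salinity (psu ~ g/kg) -> kg/kg
  mu_w <- 4.2844e-5 + 1 / (0.157 * (t + 64.993)^2 - 91.296)
  a <- 1.541 + 1.998e-2 * t - 9.52e-5 * t^2
  b <- 7.974 - 7.561e-2 * t + 4.724e-4 * t^2
  mu_w * (1 + a * s + b * s^2)
}

new_medium <- function(temperature, salinity, rho_sw, nu, g) {
  out <- tibble::tibble(
    temperature = as.numeric(temperature),
    salinity = as.numeric(salinity),
    rho_sw = as.numeric(rho_sw),
    nu = as.numeric(nu),
    g = as.numeric(g)
  )
  class(out) <- c("medium_properties", class(out))
  out
}

#' Seawater properties from temperature and salinity
#'
#' Derives the water-column state a settling particle experiences: mass
#' density `rho_sw` (kg m^-3) via the one-atmosphere EOS-80 equation of state
#' and kinematic viscosity `nu` (m^2 s^-1) as the Sharqawy-type dynamic
#' viscosity divided by density. Both feed the drag-based velocity models.
#'
#' @param temperature Water temperature, degrees Celsius (0 to 40).
#' @param salinity Practical salinity, psu (0 to 42).
#' @param g Gravitational acceleration, m s^-2.
#'
#' @return A one-row tibble of class `medium_properties` with columns
#'   `temperature`, `salinity`, `rho_sw`, `nu` and `g`.
#' @examples
#' water_properties(17.5, 15)
#' @seealso [medium_override()] to supply density and viscosity directly.
#' @export
water_properties <- function(temperature, salinity, g = 9.81) {
  check_range(temperature, "temperature", 0, 40)
  check_range(salinity, "salinity", 0, 42)
  check_positive(g, "g")
  rho <- sw_density(temperature, salinity)
  nu <- sw_dynamic_viscosity(temperature, salinity) / rho
  new_medium(temperature, salinity, rho, nu, g)
}

#' Medium with directly supplied density and viscosity
#'
#' Bypasses the temperature/salinity correlations, e.g. to inject the study's
#' median conditions (`rho_sw` = 1009.45 kg m^-3, `nu` = 1.0915e-6 m^2 s^-1)
#' exactly.
#'
#' @param rho_sw Water mass density, kg m^-3 (> 0).
#' @param nu Kinematic viscosity, m^2 s^-1 (> 0).
#' @param g Gravitational acceleration, m s^-2 (> 0).
#'
#' @return A one-row `medium_properties` tibble; `temperature` and `salinity`
#'   are `NA`.
#' @examples
#' medium_override(1009.45, 1.0915e-6)
#' @export
medium_override <- function(rho_sw, nu, g = 9.81) {
  check_positive(rho_sw, "rho_sw")
  check_positive(nu, "nu")
  check_positive(g, "g")
  new_medium(NA_real_, NA_real_, rho_sw, nu, g)
}

#' The study's median experimental medium
#'
#' The median conditions observed across the settling measurements
#' (`rho_sw` = 1009.45 kg m^-3, `nu` = 1.0915e-6 m^2 s^-1, g = 9.81 m s^-2),
#' used as the default medium for predictions and synthetic data.
#'
#' @return A one-row `medium_properties` tibble.
#' @export
median_study_medium <- function() {
  medium_override(rho_sw = 1009.45, nu = 1.0915e-6, g = 9.81)
}

is_medium <- function(x) inherits(x, "medium_properties")

check_medium <- function(medium) {
  if (!is_medium(medium) || nrow(medium) != 1) {
    abort_validity(
      "`medium` must be a one-row medium_properties object; see water_properties()."
    )
  }
  invisible(medium)
}
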