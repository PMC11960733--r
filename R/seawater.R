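#' Seawater density at surface pressure
#'
#' Density of seawater at zero gauge pressure from the UNESCO (EOS-80)
#' one-atmosphere equation of state (Millero & Poisson 1981), as a function
#' of in-situ temperature and practical salinity. Used to convert oxygen
#' concentrations between volumetric and gravimetric units.
#'
#' @param temperature In-situ temperature, degrees C. Vectorised.
#' @param salinity Practical salinity (PSU, dimensionless). Vectorised.
#' @return Density in kg per cubic metre.
#' @examples
#' sw_density(17, 30)
#' @export
sw_density <- function(temperature, salinity) {
  stopifnot(is.numeric(temperature), is.numeric(salinity))
  t <- temperature
  s <- salinity
  rho_w <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  a <- 8.24493e-1 - 4.0899e-3 * t + 7.6438e-5 * t^2 -
    8.2467e-7 * t^3 + 5.3875e-9 * t^4
  b <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  rho_w + a * s + b * s^1.5 + 4.8314e-4 * s^2
}

# molar mass of O2, g/mol
M_O2 <- 31.998

#' Convert dissolved oxygen between mg/L and umol/kg
#'
#' Sensor networks report dissolved oxygen volumetrically (mg per litre);
#' water-mass analyses need it per unit mass so that a parcel's oxygen
#' content is invariant under heating and mixing. The conversion uses the
#' in-situ density from [sw_density()]:
#' `DO[umol/kg] = DO[mg/L] * (1000 / 31.998) / rho[kg/L]`.
#'
#' @param do_mgL Dissolved oxygen, mg per litre.
#' @param do_umolkg Dissolved oxygen, micromoles per kilogram.
#' @param temperature In-situ temperature, degrees C.
#' @param salinity Practical salinity (PSU).
#' @return The converted oxygen concentration.
#' @examples
#' do_mgL_to_umolkg(8, 17, 30)
#' @export
do_mgL_to_umolkg <- function(do_mgL, temperature, salinity) {
  do_mgL * (1000 / M_O2) / (sw_density(temperature, salinity) / 1000)
}

#' @rdname do_mgL_to_umolkg
#' @export
do_umolkg_to_mgL <- function(do_umolkg, temperature, salinity) {
  do_umolkg * (M_O2 / 1000) * (sw_density(temperature, salinity) / 1000)
}

#' Oxygen solubility at saturation
#'
#' Saturation concentration of dissolved oxygen in equilibrium with a
#' water-saturated atmosphere, from the Garcia & Gordon (1992) combined fit
#' to the Benson & Krause data, in umol/kg. Solubility decreases with both
#' temperature and salinity, so warming and salting of a water mass lower
#' the oxygen it can hold at equilibrium; the pipeline uses the local
#' derivatives of this function to attribute observed oxygen trends.
#'
#' @inheritParams sw_density
#' @return Saturation dissolved oxygen, umol/kg.
#' @examples
#' o2_solubility(17, 30)
#' # sensitivity to 1 degree warming at S = 30:
#' o2_solubility(17, 30) - o2_solubility(18, 30)
#' @export
o2_solubility <- function(temperature, salinity) {
  stopifnot(is.numeric(temperature), is.numeric(salinity))
  ts <- log((298.15 - temperature) / (273.15 + temperature))
  a <- c(5.80871, 3.20291, 4.17887, 5.10006, -9.86643e-2, 3.80369)
  b <- c(-7.01577e-3, -7.70028e-3, -1.13864e-2, -9.51519e-3)
  c0 <- -2.75915e-7
  exp(a[1] + a[2] * ts + a[3] * ts^2 + a[4] * ts^3 + a[5] * ts^4 +
        a[6] * ts^5 +
        salinity * (b[1] + b[2] * ts + b[3] * ts^2 + b[4] * ts^3) +
        c0 * salinity^2)
}
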