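#' Two-endmember pH mixing curve
#'
#' Under conservative mixing, TA and DIC at any salinity lie on the linear
#' endmember lines; speciating those (TA, DIC) pairs at a fixed reference
#' temperature yields the pH expected from water-mass mixing alone — no
#' photosynthesis, respiration, or air-sea CO2 exchange. Observed pH above
#' the curve indicates net DIC drawdown (production); below, net DIC
#' addition (respiration). For the registered bay endmembers the TA:DIC
#' ratio falls from about 1.2 in the freshwater endmember to about 1.06 at
#' S = 33, so the curve's pH declines with salinity.
#'
#' @param endmembers An [endmember_model()]; defaults to the bay lines with
#'   the `"mixing"` DIC relation.
#' @param t_ref Reference temperature, degrees C (bay annual mean, 17).
#' @param salinity_grid Strictly increasing salinity grid.
#' @param constants Constants set label.
#' @return A tibble of class `mixing_curve` with columns `salinity`, `ta`,
#'   `dic`, `ta_dic_ratio`, `ph_total`, `ph_nbs`; the reference
#'   temperature, endmember label and constants label are attributes.
#' @examples
#' curve <- build_mixing_curve(salinity_grid = seq(0, 33, by = 1))
#' head(curve)
#' @export
build_mixing_curve <- function(endmembers = nb_endmembers(), t_ref = 17,
                               salinity_grid = seq(0, 33, by = 0.1),
                               constants = "lueker") {
  stopifnot(all(diff(salinity_grid) > 0), min(salinity_grid) >= 0,
            max(salinity_grid) <= 35)
  ta <- ta_from_salinity(salinity_grid, endmembers)
  dic <- dic_from_salinity(salinity_grid, endmembers)
  st <- carb_solve(t_ref, salinity_grid, ta = ta, dic = dic,
                   constants = constants)
  out <- tibble::tibble(
    salinity = salinity_grid, ta = ta, dic = dic,
    ta_dic_ratio = ta / dic,
    ph_total = st$ph_total, ph_nbs = st$ph_nbs
  )
  out <- tibble::new_tibble(out, class = "mixing_curve")
  attr(out, "t_ref") <- t_ref
  attr(out, "endmembers") <- endmembers$label
  attr(out, "constants") <- constants
  out
}

#' Freshwater-endmember sensitivity of the mixing curve
#'
#' The curve's low-salinity limb is controlled by the freshwater DIC
#' endmember (the DIC line's intercept), which is poorly constrained in
#' most estuaries. This helper rebuilds the curve with the freshwater DIC
#' shifted up and down by a fraction (default 10%, about 40 umol/kg for
#' the bay line) or by an absolute amount, returning the base and the two
#' perturbed curves together.
#'
#' @inheritParams build_mixing_curve
#' @param fraction Fractional change of the freshwater DIC endmember
#'   (ignored when `amount` is given). Must be within +/- 0.5.
#' @param amount Absolute change, umol/kg.
#' @return A tibble like [build_mixing_curve()] output with an extra
#'   `curve` column taking values `"base"`, `"plus"` and `"minus"`.
#' @export
perturb_endmember <- function(endmembers = nb_endmembers(), fraction = 0.10,
                              amount = NULL, t_ref = 17,
                              salinity_grid = seq(0, 33, by = 0.1),
                              constants = "lueker") {
  delta <- if (is.null(amount)) {
    stopifnot(abs(fraction) <= 0.5)
    fraction * endmembers$dic_intercept
  } else {
    amount
  }
  shift <- function(m, d) {
    endmember_model(m$ta_slope, m$ta_intercept, m$dic_slope,
                    m$dic_intercept + d,
                    label = paste0(m$label, if (d >= 0) "+" else "-",
                                   abs(round(d, 1))))
  }
  curves <- list(
    base = build_mixing_curve(endmembers, t_ref, salinity_grid, constants),
    plus = build_mixing_curve(shift(endmembers, delta), t_ref,
                              salinity_grid, constants),
    minus = build_mixing_curve(shift(endmembers, -delta), t_ref,
                               salinity_grid, constants)
  )
  out <- dplyr::bind_rows(lapply(curves, tibble::as_tibble), .id = "curve")
  attr(out, "t_ref") <- t_ref
  attr(out, "delta_dic_fw") <- delta
  out
}

#' Adjust observed pH to a reference temperature
#'
#' Observed pH varies with in-situ temperature through the carbonate
#' equilibria, so comparing observations against a fixed-temperature
#' mixing curve requires a thermodynamic adjustment: each observation is
#' speciated at in-situ temperature using salinity-estimated TA and the
#' measured pH, and the resulting (TA, DIC) pair — both
#' temperature-invariant — is re-solved at the reference temperature.
#'
#' @param observations Tibble with columns `temperature`, `salinity`,
#'   `ph_nbs`.
#' @param t_ref Reference temperature, degrees C.
#' @param endmembers Endmember model supplying the TA-salinity line.
#' @param constants Constants set label.
#' @return `observations` with added columns `ta`, `dic` and
#'   `ph_nbs_at_ref`.
#' @export
adjust_ph_to_temperature <- function(observations, t_ref = 17,
                                     endmembers = nb_endmembers(),
                                     constants = "lueker") {
  ta <- ta_from_salinity(observations$salinity, endmembers)
  insitu <- carb_solve(observations$temperature, observations$salinity,
                       ta = ta, ph = observations$ph_nbs,
                       ph_scale = "nbs", constants = constants)
  at_ref <- carb_solve(t_ref, observations$salinity, ta = ta,
                       dic = insitu$dic, constants = constants)
  dplyr::mutate(observations, ta = ta, dic = insitu$dic,
                ph_nbs_at_ref = at_ref$ph_nbs)
}

#' Deviation of observations from the mixing curve
#'
#' Interpolates the mixing curve's pH at each observation's salinity and
#' returns `delta_ph = observed - curve`. Positive deviations indicate DIC
#' drawdown relative to conservative mixing (net production); negative
#' deviations indicate DIC addition (net respiration). Observations are
#' expected to carry `ph_nbs_at_ref` from [adjust_ph_to_temperature()];
#' plain `ph_nbs` is used as a fallback. Salinities outside the curve grid
#' are excluded with a message.
#'
#' @param observations Tibble with `salinity` and `ph_nbs_at_ref` (or
#'   `ph_nbs`).
#' @param curve A [build_mixing_curve()] result.
#' @return The retained observations with added `expected_ph_nbs` and
#'   `delta_ph`.
#' @export
mixing_deviation <- function(observations, curve) {
  stopifnot(inherits(curve, "mixing_curve"))
  ph_col <- if ("ph_nbs_at_ref" %in% names(observations)) "ph_nbs_at_ref"
            else "ph_nbs"
  inside <- observations$salinity >= min(curve$salinity) &
    observations$salinity <= max(curve$salinity)
  if (any(!inside)) {
    message("mixing_deviation(): excluded ", sum(!inside),
            " observation(s) with salinity outside the curve grid")
  }
  obs <- observations[inside, ]
  expected <- approx(curve$salinity, curve$ph_nbs, xout = obs$salinity)$y
  dplyr::mutate(obs, expected_ph_nbs = expected,
                delta_ph = .data[[ph_col]] - expected)
}
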