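#' Plot a pH mixing curve
#'
#' @param object A [build_mixing_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mixing_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$salinity, y = .data$ph_nbs)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "steelblue") +
    ggplot2::labs(
      x = "Salinity (PSU)", y = "pH (NBS)",
      title = sprintf("Two-endmember pH mixing curve at %g °C",
                      attr(object, "t_ref"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a base curve with its endmember perturbations
#'
#' @param curves Output of [perturb_endmember()].
#' @return A ggplot with one line per curve variant.
#' @export
plot_mixing_family <- function(curves) {
  stopifnot("curve" %in% names(curves))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$salinity,
                                       y = .data$ph_nbs,
                                       colour = .data$curve)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "Salinity (PSU)", y = "pH (NBS)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot bay-wide anomaly series with their fitted trends
#'
#' @param object A [fit_trend()] result.
#' @param ... Unused.
#' @return A ggplot faceted by parameter and layer, showing the monthly
#'   anomalies and the fitted OLS trend line.
#' @export
autoplot.bay_trends <- function(object, ...) {
  keys <- attr(object, "keys")
  series <- attr(object, "series")
  tab <- tibble::as_tibble(object)
  pts <- purrr::map2(seq_len(nrow(tab)), series, function(i, d) {
    dplyr::bind_cols(tab[rep(i, nrow(d)), keys], d)
  })
  pts <- dplyr::bind_rows(pts)
  pts$t <- .decimal_time(pts$year, pts$month)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$t, y = .data$anomaly)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.6) +
    ggplot2::facet_wrap(keys, scales = "free_y") +
    ggplot2::labs(x = "Year", y = "Monthly anomaly") +
    ggplot2::theme_minimal()
}

#' Plot an attribution budget
#'
#' @param object An `attribution_budget` from [do_solubility_budget()] or
#'   [ph_budget()].
#' @param ... Unused.
#' @return A ggplot bar chart of the term rates, with the observed trend
#'   marked when known.
#' @export
autoplot.attribution_budget <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$driver,
                                                           .data$rate),
                                        y = .data$rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = paste0("Rate (", df$units[1], ")"),
                  title = attr(object, "target")) +
    ggplot2::theme_minimal()
  obs <- attr(object, "observed_trend")
  if (!is.null(obs) && !is.na(obs)) {
    p <- p + ggplot2::geom_hline(yintercept = obs, linetype = 2)
  }
  p
}
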