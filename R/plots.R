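#' Stacked source attribution of evolved DIC
#'
#' Shows, per depth zone, the cumulative DIC production over the incubation
#' split into its three sources: mineralized substrate, primed indigenous
#' OM, and the control-level indigenous mineralization.
#'
#' @param summary Output of [analyze_incubation()] (labelled treatments
#'   only).
#' @return A ggplot object.
#' @export
plot_dic_sources <- function(summary) {
  long <- summary |>
    dplyr::filter(.data$treatment != "control") |>
    dplyr::transmute(
      .data$treatment, .data$depth_zone, .data$day,
      `substrate (DI13C)` = .data$di13c_umol_mean,
      `priming` = pmax(.data$priming_umol, 0),
      `control` = .data$di12c_control_umol
    ) |>
    tidyr::pivot_longer(-c("treatment", "depth_zone", "day"),
                        names_to = "source", values_to = "umol")
  ggplot2::ggplot(long, ggplot2::aes(.data$day, .data$umol,
                                     fill = .data$source)) +
    ggplot2::geom_area(alpha = 0.85) +
    ggplot2::facet_grid(ggplot2::vars(.data$depth_zone),
                        ggplot2::vars(.data$treatment)) +
    ggplot2::labs(x = "day", y = "cumulative DIC production (µmol C)",
                  fill = NULL)
}

#' Carbon-use-efficiency trajectory
#'
#' @param summary Output of [analyze_incubation()] with a `cue` column.
#' @return A ggplot object.
#' @export
plot_cue <- function(summary) {
  d <- dplyr::filter(summary, !is.na(.data$cue))
  ggplot2::ggplot(d, ggplot2::aes(.data$day, .data$cue,
                                  colour = .data$depth_zone)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "day", y = "carbon use efficiency",
                  colour = "depth zone")
}

#' Plot a 2G degradation fit
#'
#' Observed cumulative fractions with the fitted two-pool curve.
#'
#' @param object A [fit_two_g()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.two_g_fit <- function(object, ...) {
  grid <- tibble::tibble(
    day = seq(0, max(object$data$day), length.out = 200)
  )
  grid$fraction <- predict(object, grid$day)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$day, .data$fraction)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "day", y = "fraction mineralized",
                  title = sprintf("2G fit: g1=%.2f k1=%.2g/yr, g2=%.2f k2=%.2g/yr",
                                  object$g1, object$k1, object$g2, object$k2))
}
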