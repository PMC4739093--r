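#' Plot extrapolation estimates
#'
#' `autoplot()` draws one of three displays from an `fgmc_estimates`
#' object: the per-country undergone estimate (`"undergone"`), the
#' undergone type-III/other composition (`"types"`), or the low-high
#' at-risk interval per country (`"risk"`).
#'
#' @param object An `fgmc_estimates` object.
#' @param type One of `"undergone"`, `"types"`, `"risk"`.
#' @param top_n Show only the `top_n` largest countries (by the plotted
#'   quantity); default 15.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fgmc_estimates
#' @export
autoplot.fgmc_estimates <- function(object, type = c("undergone", "types", "risk"),
                                    top_n = 15, ...) {
  type <- match.arg(type)
  ct <- object$countries
  switch(type,
    undergone = {
      d <- ct |>
        dplyr::slice_max(.data$undergone, n = top_n) |>
        dplyr::mutate(country = stats::reorder(.data$country, .data$undergone))
      ggplot2::ggplot(d, ggplot2::aes(x = .data$undergone, y = .data$country)) +
        ggplot2::geom_col(fill = "grey30") +
        ggplot2::labs(
          x = "Estimated already subjected to FGM/C", y = NULL,
          title = "Women and girls estimated to have undergone FGM/C"
        )
    },
    types = {
      d <- ct |>
        dplyr::slice_max(.data$undergone, n = top_n) |>
        dplyr::select("country", `Type III` = "undergone_type3",
          `Other types` = "undergone_other") |>
        tidyr::pivot_longer(-"country", names_to = "type", values_to = "n") |>
        dplyr::mutate(country = stats::reorder(.data$country, .data$n, sum))
      ggplot2::ggplot(d, ggplot2::aes(
        x = .data$n, y = .data$country, fill = .data$type
      )) +
        ggplot2::geom_col() +
        ggplot2::labs(
          x = "Estimated already subjected to FGM/C", y = NULL, fill = NULL,
          title = "Undergone FGM/C by type"
        )
    },
    risk = plot_risk_interval(object, top_n = top_n)
  )
}

#' Low-high at-risk interval per country
#'
#' @inheritParams autoplot.fgmc_estimates
#' @param est An `fgmc_estimates` object.
#' @return A ggplot object: one segment per country from the low-risk to
#'   the high-risk scenario estimate.
#' @export
plot_risk_interval <- function(est, top_n = 15) {
  d <- est$countries |>
    dplyr::slice_max(.data$risk_high, n = top_n) |>
    dplyr::mutate(country = stats::reorder(.data$country, .data$risk_high))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$country)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$risk_low, xend = .data$risk_high, yend = .data$country),
      linewidth = 1.2, colour = "grey55"
    ) +
    ggplot2::geom_point(ggplot2::aes(x = .data$risk_low), colour = "#2166ac", size = 2) +
    ggplot2::geom_point(ggplot2::aes(x = .data$risk_high), colour = "#b2182b", size = 2) +
    ggplot2::labs(
      x = "Girls at risk (low to high scenario)", y = NULL,
      title = "At-risk interval by migration scenario"
    )
}
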