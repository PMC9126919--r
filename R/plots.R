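#' Plots
#'
#' ggplot2 views of the main result types.
#'
#' @name plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot scene-level summary bias by subject
#'
#' Heatmap of %Summary bias over the subject-by-scene grid; unrecalled
#' scenes are blank.
#'
#' @param behavior Scene-behavior tibble from [scene_summary_bias()].
#' @return A ggplot object.
#' @export
plot_summary_bias <- function(behavior) {
  ggplot2::ggplot(
    behavior,
    ggplot2::aes(x = .data$scene_id, y = .data$subject_id,
                 fill = .data$summary_bias)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "%Summary bias", na.value = "grey92",
                                  limits = c(0, 1)) +
    ggplot2::labs(x = "Movie scene", y = "Subject") +
    ggplot2::theme_minimal()
}

#' @describeIn plots MR versus RR per parcel; parcels above the identity
#'   line show memory transformation (RR > MR). Filled points mark the
#'   reliability mask.
#' @param object A result object.
#' @param ... Unused.
#' @method autoplot transformation_result
#' @export
autoplot.transformation_result <- function(object, ...) {
  p <- object$parcels
  lim <- range(c(p$mr, p$rr))
  ggplot2::ggplot(
    p, ggplot2::aes(x = .data$mr, y = .data$rr,
                    shape = .data$in_reliability_mask,
                    colour = .data$t_score)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_shape_manual(
      values = c(`TRUE` = 16, `FALSE` = 1), name = "Reliable"
    ) +
    ggplot2::scale_colour_viridis_c(name = "T = RR - MR") +
    ggplot2::coord_fixed(xlim = lim, ylim = lim) +
    ggplot2::labs(x = "Movie-to-recall similarity (MR)",
                  y = "Recall-to-recall similarity (RR)") +
    ggplot2::theme_minimal()
}

#' @describeIn plots Subject-level bias-transformation correlations per
#'   parcel, sorted by the group t-statistic.
#' @method autoplot link_result
#' @export
autoplot.link_result <- function(object, ...) {
  ord <- object$parcels |>
    dplyr::arrange(.data$t) |>
    dplyr::pull("parcel_id")
  sr <- object$subject_r |>
    dplyr::filter(!is.na(.data$r)) |>
    dplyr::mutate(parcel_id = factor(.data$parcel_id, levels = ord))
  means <- object$parcels |>
    dplyr::mutate(parcel_id = factor(.data$parcel_id, levels = ord))
  ggplot2::ggplot(sr, ggplot2::aes(x = .data$parcel_id, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 1) +
    ggplot2::geom_point(
      data = means,
      ggplot2::aes(y = .data$mean_r, colour = .data$significant),
      size = 3, shape = 18
    ) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey30"),
      name = "FDR significant"
    ) +
    ggplot2::labs(x = "Parcel",
                  y = "Subject-level r (bias vs transformation)") +
    ggplot2::theme_minimal()
}

#' @describeIn plots Subject-mean reinstatement by condition, with lines
#'   joining each subject's Precise and Summary values per parcel.
#' @method autoplot reinstatement_result
#' @export
autoplot.reinstatement_result <- function(object, ...) {
  m <- object$means
  ggplot2::ggplot(
    m, ggplot2::aes(x = .data$condition, y = .data$mean_r,
                    group = .data$subject_id)
  ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~parcel_id) +
    ggplot2::labs(x = "Recall type",
                  y = "Mean encoding-recall pattern r") +
    ggplot2::theme_minimal()
}
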