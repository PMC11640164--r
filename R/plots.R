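#' Boxplots of signature scores by group
#'
#' The standard view of differential infiltration: one boxplot per group
#' per signature, faceted by signature.
#'
#' @param scores Long score tibble from [score_signatures()]
#'   (`sample_id`, `signature`, `score`).
#' @param annot Annotation tibble with `sample_id` and the grouping
#'   column.
#' @param group Name of the annotation column to group by (default
#'   `"cancer_type"`).
#' @return A ggplot object.
#' @export
plot_signature_scores <- function(scores, annot, group = "cancer_type") {
  stopifnot(group %in% names(annot))
  d <- scores |>
    dplyr::inner_join(
      dplyr::select(annot, "sample_id", dplyr::all_of(group)),
      by = "sample_id"
    )
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data[[group]], y = .data$score, fill = .data[[group]]
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(~signature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "signature score (average z-score)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a single Kaplan-Meier curve
#'
#' @param object An `immunosig_km` object.
#' @param ... Unused.
#' @return A ggplot step plot of the survival curve.
#' @method autoplot immunosig_km
#' @export
autoplot.immunosig_km <- function(object, ...) {
  d <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1),
    dplyr::select(object$curve, "time", "survival")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "survival probability") +
    ggplot2::theme_bw()
}

#' Plot the median-split survival analysis
#'
#' Faceted Kaplan-Meier curves, one panel per signature, high versus low
#' stratum, annotated with the log-rank p-value.
#'
#' @param object An `immunosig_survfit` object from [run_survival()].
#' @param horizon Right edge of the time axis in months (default 120).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot immunosig_survfit
#' @export
autoplot.immunosig_survfit <- function(object, horizon = 120, ...) {
  starts <- object$curves |>
    dplyr::distinct(.data$signature, .data$stratum) |>
    dplyr::mutate(time = 0, survival = 1)
  d <- dplyr::bind_rows(
    starts,
    dplyr::select(object$curves, "signature", "stratum", "time", "survival")
  )
  labels <- object$summary |>
    dplyr::mutate(label = sprintf("log-rank p = %.2g", .data$p))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$time, y = .data$survival, color = .data$stratum
  )) +
    ggplot2::geom_step() +
    ggplot2::geom_text(
      data = labels, inherit.aes = FALSE, size = 3, hjust = 1, vjust = 1,
      ggplot2::aes(x = horizon, y = 0.98, label = .data$label)
    ) +
    ggplot2::scale_color_manual(values = c(high = "#d73027", low = "#4575b4")) +
    ggplot2::facet_wrap(~signature) +
    ggplot2::coord_cartesian(xlim = c(0, horizon), ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "survival probability",
                  color = "expression") +
    ggplot2::theme_bw()
}

#' Bar chart of AUROC validation results
#'
#' @param auroc_table Output of [run_auroc_validation()].
#' @return A ggplot object with a reference line at 0.5 (chance).
#' @export
plot_auroc <- function(auroc_table) {
  ggplot2::ggplot(auroc_table, ggplot2::aes(
    x = .data$signature, y = .data$auroc, fill = .data$cohort
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "AUROC") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
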