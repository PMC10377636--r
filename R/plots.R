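# ggplot2 views of the result objects

#' @describeIn validate_metric box plots of the per-repetition error
#'   measures.
#' @param object the result object.
#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_rep, c("mse", "acc", "acc_adj"),
                              names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$statistic, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(
      x = NULL, y = "per-repetition value",
      title = sprintf("Repeated balanced-split validation (%d repetitions)",
                      object$n_reps)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn kmeans_cluster scatter of the similarity plane colored by
#'   cluster, centroids marked.
#' @param object the result object.
#' @method autoplot cluster_report
#' @export
autoplot.cluster_report <- function(object, ...) {
  pts <- object$assignments
  cols <- names(pts)
  # first two numeric similarity columns used at fit time are recorded in
  # the centroid tibble names; plot against the stored coordinates
  ggplot2::ggplot(pts, ggplot2::aes(
    x = .data[[cols[which(vapply(pts, is.numeric, logical(1)))[1]]]],
    y = .data[[cols[which(vapply(pts, is.numeric, logical(1)))[2]]]],
    color = factor(.data$cluster)
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_point(
      data = object$centroids,
      ggplot2::aes(x = .data$color_centroid, y = .data$texture_centroid),
      color = "black", shape = 4, size = 3, stroke = 1.5,
      inherit.aes = FALSE
    ) +
    ggplot2::labs(color = "cluster",
                  title = sprintf("k-means (k = %d) on the similarity plane",
                                  object$k)) +
    ggplot2::theme_minimal()
}

#' @describeIn compare_groups box plots of the pairwise kappas per group.
#' @param object the result object.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$group, y = .data$kappa)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::labs(
      x = NULL, y = "quadratic Cohen's kappa",
      title = sprintf("Human-Human vs System-Human agreement (p = %.3f)",
                      object$rank_sum_p)
    ) +
    ggplot2::theme_minimal()
}

#' Rank similarity metrics by validation error
#'
#' Collates several validation reports into a table ordered by increasing
#' mean MSE (best metric first), the comparison used to select the color
#' space/metric and backbone layer.
#'
#' @param reports named list of `validation_report`s; names label the
#'   metrics.
#' @return tibble with one row per metric, ranked by `mse_mean`.
#' @export
rank_metrics <- function(reports) {
  if (is.null(names(reports)) || any(names(reports) == "")) {
    abort_percsim("`reports` must be a named list.", "percsim_usage_error")
  }
  purrr::imap_dfr(reports, function(rep, nm) {
    dplyr::mutate(glance(rep), metric = nm, .before = 1)
  }) |>
    dplyr::arrange(.data$mse_mean)
}

#' Bar chart of ranked metrics
#'
#' @param ranked tibble from [rank_metrics()].
#' @return a ggplot.
#' @export
plot_metric_ranking <- function(ranked) {
  ggplot2::ggplot(
    ranked,
    ggplot2::aes(x = stats::reorder(.data$metric, .data$mse_mean),
                 y = .data$mse_mean)
  ) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mse_lo, ymax = .data$mse_hi),
      width = 0.25, color = "red"
    ) +
    ggplot2::labs(x = NULL, y = "mean MSE (95% CI)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
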