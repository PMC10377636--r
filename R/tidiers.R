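# broom-style tidiers for fitted objects

#' @describeIn fit_olreg tidy the fitted thresholds and slope.
#' @param x an `olreg_model`.
#' @param ... unused.
#' @method tidy olreg_model
#' @export
tidy.olreg_model <- function(x, ...) {
  tibble::tibble(
    term = c("theta_1", "theta_2", "theta_3", "beta"),
    estimate = c(x$thresholds, x$slope)
  )
}

#' @describeIn fit_olreg one-row model summary.
#' @method glance olreg_model
#' @export
glance.olreg_model <- function(x, ...) {
  tibble::tibble(
    logLik = x$logLik, n = x$n, converged = x$converged,
    orientation = x$orientation
  )
}

#' @describeIn validate_metric per-repetition tibble of mse/acc/acc_adj.
#' @param x a `validation_report`.
#' @param ... unused.
#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) x$per_rep

#' @describeIn validate_metric one-row summary with means and 95% CIs.
#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    mse_mean = s$mean[s$statistic == "mse"],
    mse_lo = s$ci_lo[s$statistic == "mse"],
    mse_hi = s$ci_hi[s$statistic == "mse"],
    acc_mean = s$mean[s$statistic == "acc"],
    acc_lo = s$ci_lo[s$statistic == "acc"],
    acc_hi = s$ci_hi[s$statistic == "acc"],
    acc_adj_mean = s$mean[s$statistic == "acc_adj"],
    acc_adj_lo = s$ci_lo[s$statistic == "acc_adj"],
    acc_adj_hi = s$ci_hi[s$statistic == "acc_adj"],
    n_reps = x$n_reps
  )
}

#' @describeIn kmeans_cluster item assignments as a tibble.
#' @param x a `cluster_report`.
#' @param ... unused.
#' @method tidy cluster_report
#' @export
tidy.cluster_report <- function(x, ...) x$assignments

#' @describeIn kmeans_cluster one-row clustering summary.
#' @method glance cluster_report
#' @export
glance.cluster_report <- function(x, ...) {
  tibble::tibble(k = x$k, tot_withinss = x$tot_withinss,
                 n = nrow(x$assignments))
}

#' @describeIn compare_groups pairwise kappas in long format.
#' @param x a `group_comparison`.
#' @param ... unused.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$pairs

#' @describeIn compare_groups per-group summary with the rank-sum p-value.
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  dplyr::mutate(x$summary, rank_sum_p = x$rank_sum_p)
}
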