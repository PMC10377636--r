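# Inter-rater reliability and agreement statistics for ordinal panels.

quadratic_weights <- function(levels) {
  i <- seq_len(levels)
  1 - outer(i, i, function(a, b) (a - b)^2) / (levels - 1)^2
}

linear_weights <- function(levels) {
  i <- seq_len(levels)
  1 - abs(outer(i, i, "-")) / (levels - 1)
}

agreement_weights <- function(levels, weights = c("quadratic", "linear")) {
  weights <- match.arg(weights)
  switch(weights, quadratic = quadratic_weights(levels),
         linear = linear_weights(levels))
}

#' Cronbach's alpha internal consistency
#'
#' `alpha = k/(k-1) * (1 - sum(rater variances) / var(item sums))` over an
#' items x raters table, with unbiased (n-1) variances. Values above 0.9
#' are conventionally read as excellent internal consistency.
#'
#' @param table items x raters numeric matrix (or a [rating_table()]).
#' @return scalar alpha (at most 1).
#' @export
cronbach_alpha <- function(table) {
  m <- unclass(as.matrix(table))
  if (ncol(m) < 2L || nrow(m) < 2L) {
    abort_percsim("alpha needs at least 2 raters and 2 items.",
                  "percsim_usage_error")
  }
  total_var <- var(rowSums(m))
  if (total_var == 0) {
    abort_percsim("zero total-score variance; alpha is undefined.",
                  "percsim_degenerate_error")
  }
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2L, var)) / total_var)
}

#' Alpha under single-rater removal
#'
#' Recomputes Cronbach's alpha with each rater left out in turn, to check
#' whether any single rater (e.g. the automated scorer added as an extra
#' rater) drives the panel's consistency.
#'
#' @inheritParams cronbach_alpha
#' @return tibble with columns `removed` (rater id) and `alpha`.
#' @export
alpha_drop_one <- function(table) {
  m <- unclass(as.matrix(table))
  if (ncol(m) < 3L) {
    abort_percsim("drop-one alpha needs at least 3 raters.",
                  "percsim_usage_error")
  }
  ids <- colnames(m)
  if (is.null(ids)) ids <- paste0("R", seq_len(ncol(m)))
  tibble::tibble(
    removed = ids,
    alpha = vapply(seq_len(ncol(m)), function(j) {
      cronbach_alpha(m[, -j, drop = FALSE])
    }, numeric(1))
  )
}

#' Quadratic-weighted Cohen's kappa
#'
#' Chance-corrected pairwise agreement with quadratic disagreement weights
#' `w_ij = 1 - (i - j)^2 / (levels - 1)^2`:
#' `kappa = (p_o - p_e) / (1 - p_e)` with weighted observed agreement `p_o`
#' from the confusion matrix and chance agreement `p_e` from its marginals.
#'
#' @param r1,r2 integer rating vectors of equal length with values in
#'   `1..levels`.
#' @param levels number of scale levels (default 4).
#' @return scalar kappa in `[-1, 1]`.
#' @export
cohen_kappa_quadratic <- function(r1, r2, levels = 4L) {
  if (length(r1) != length(r2)) {
    abort_percsim("rating vectors must have equal length.", "percsim_usage_error")
  }
  f1 <- factor(r1, levels = seq_len(levels))
  f2 <- factor(r2, levels = seq_len(levels))
  if (anyNA(f1) || anyNA(f2)) {
    abort_percsim(sprintf("ratings must lie in 1..%d.", levels),
                  "percsim_usage_error")
  }
  if (length(unique(r1)) == 1L && length(unique(r2)) == 1L) {
    if (r1[1] == r2[1]) return(1)
    warning("both raters are constant but different; kappa set to 0.",
            call. = FALSE)
    return(0)
  }
  w <- quadratic_weights(levels)
  tab <- table(f1, f2) / length(r1)
  po <- sum(w * tab)
  pe <- sum(w * outer(rowSums(tab), colSums(tab)))
  if (abs(1 - pe) < 1e-12) {
    if (abs(1 - po) < 1e-12) return(1) # both raters constant and equal
    warning("both raters are constant but different; kappa set to 0.",
            call. = FALSE)
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Gwet's AC2 weighted agreement
#'
#' Gwet's chance-corrected agreement coefficient for ordinal panels of two
#' or more raters, robust to skewed category prevalence. With `n` items,
#' `r` raters, `q` levels and weights `w`, the per-item weighted agreement
#' is `sum_k r_ik (r*_ik - 1) / (r (r - 1))` with
#' `r*_ik = sum_l w_kl r_il`, averaged into `p_a`; chance agreement is
#' `p_e = T_w / (q (q - 1)) * sum_k pi_k (1 - pi_k)` where `T_w` is the sum
#' of all weights and `pi_k` the mean classification proportion of level
#' `k`. `AC2 = (p_a - p_e) / (1 - p_e)`.
#'
#' @param table items x raters integer matrix (or [rating_table()]).
#' @param levels number of scale levels (default 4).
#' @param weights `"quadratic"` (default) or `"linear"`.
#' @return scalar AC2 in `[-1, 1]`.
#' @export
gwet_ac2 <- function(table, levels = 4L, weights = c("quadratic", "linear")) {
  m <- unclass(as.matrix(table))
  if (nrow(m) < 2L) {
    abort_percsim("AC2 needs at least 2 items.", "percsim_degenerate_error")
  }
  if (ncol(m) < 2L) {
    abort_percsim("AC2 needs at least 2 raters.", "percsim_usage_error")
  }
  w <- agreement_weights(levels, weights)
  r <- ncol(m)
  # r_ik: items x levels counts
  rik <- vapply(seq_len(levels), function(k) rowSums(m == k),
                numeric(nrow(m)))
  rik <- matrix(rik, nrow = nrow(m))
  rstar <- rik %*% t(w)
  pa <- mean(rowSums(rik * (rstar - 1)) / (r * (r - 1)))
  pik <- colMeans(rik / r)
  pe <- (sum(w) / (levels * (levels - 1))) * sum(pik * (1 - pik))
  if (abs(1 - pe) < 1e-12) return(1)
  (pa - pe) / (1 - pe)
}

# exact two-sided rank-sum p-value by enumeration of group assignments
rank_sum_exact_p <- function(g1, g2) {
  vals <- c(g1, g2)
  n1 <- length(g1)
  r <- rank(vals) # midranks handle ties
  obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(vals), n1)
  stats <- colSums(matrix(r[combs], nrow = n1))
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

#' Compare Human-Human with System-Human agreement
#'
#' Treats the automated score as an extra rater and asks whether it agrees
#' with the experts the way experts agree with each other. Computes the
#' quadratic kappa for every pair of human raters (`choose(k, 2)` pairs)
#' and for the system against each human (`k` pairs), summarizes both
#' groups, and compares them with a two-sided Wilcoxon rank-sum test
#' (exact enumeration when both groups have at most 10 pairs, otherwise
#' the normal approximation with tie correction).
#'
#' @param panel items x raters matrix of human ratings
#'   (or [rating_table()]).
#' @param system_scores integer vector of automated scores aligned with the
#'   panel's items.
#' @param levels number of scale levels (default 4).
#' @return an object of class `"group_comparison"`: `pairs` tibble
#'   (`group` = `"H-H"`/`"S-H"`, `rater1`, `rater2`, `kappa`), `summary`
#'   tibble (per-group median, quartiles, mean, sd, n) and `rank_sum_p`.
#' @export
compare_groups <- function(panel, system_scores, levels = 4L) {
  m <- unclass(as.matrix(panel))
  if (length(system_scores) != nrow(m)) {
    abort_percsim("system scores must align with the panel's items.",
                  "percsim_usage_error")
  }
  ids <- colnames(m)
  if (is.null(ids)) ids <- paste0("R", seq_len(ncol(m)))
  hh <- utils::combn(ncol(m), 2L)
  kap <- function(a, b) {
    tryCatch(cohen_kappa_quadratic(a, b, levels = levels),
             percsim_error = function(e) {
               abort_percsim(sprintf("kappa failed: %s", conditionMessage(e)),
                             class(e)[1])
             })
  }
  pairs <- dplyr::bind_rows(
    tibble::tibble(
      group = "H-H",
      rater1 = ids[hh[1, ]], rater2 = ids[hh[2, ]],
      kappa = vapply(seq_len(ncol(hh)), function(p) {
        kap(m[, hh[1, p]], m[, hh[2, p]])
      }, numeric(1))
    ),
    tibble::tibble(
      group = "S-H",
      rater1 = "system", rater2 = ids,
      kappa = vapply(seq_len(ncol(m)), function(j) {
        kap(system_scores, m[, j])
      }, numeric(1))
    )
  )
  summ <- pairs |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data$kappa),
      q1 = quantile(.data$kappa, 0.25, names = FALSE),
      q3 = quantile(.data$kappa, 0.75, names = FALSE),
      mean = mean(.data$kappa),
      sd = sd(.data$kappa),
      .groups = "drop"
    )
  g1 <- pairs$kappa[pairs$group == "H-H"]
  g2 <- pairs$kappa[pairs$group == "S-H"]
  p <- if (length(g1) <= 10L && length(g2) <= 10L) {
    rank_sum_exact_p(g1, g2)
  } else {
    suppressWarnings(
      wilcox.test(g1, g2, exact = FALSE, correct = TRUE)$p.value)
  }
  structure(
    list(pairs = pairs, summary = summ, rank_sum_p = p, levels = levels),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> pairwise quadratic kappas\n")
  print(x$summary)
  cat(sprintf("rank-sum p = %.4f\n", x$rank_sum_p))
  invisible(x)
}
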