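# Proportional-odds mapping from a continuous similarity to the ordinal
# 1-4 visibility scale, plus the repeated class-balanced split validation.

N_LEVELS <- 4L

# negative log-likelihood and gradient for P(Y <= j | z) = plogis(theta_j - beta z)
olreg_nll <- function(par, z, y) {
  theta <- par[1:3]; beta <- par[4]
  if (is.unsorted(theta, strictly = TRUE)) return(1e10)
  eta <- outer(z, theta, function(zz, th) th - beta * zz)
  Fm <- cbind(0, plogis(eta), 1)
  p <- Fm[cbind(seq_along(y), y + 1L)] - Fm[cbind(seq_along(y), y)]
  if (any(p <= 0)) return(1e10)
  -sum(log(p))
}

olreg_grad <- function(par, z, y) {
  theta <- par[1:3]; beta <- par[4]
  n <- length(y)
  eta <- outer(z, theta, function(zz, th) th - beta * zz)
  Fj <- plogis(eta)                       # n x 3
  fj <- Fj * (1 - Fj)                     # logistic density at eta
  Fm <- cbind(0, Fj, 1)
  fm <- cbind(0, fj, 0)
  idx <- seq_len(n)
  p <- Fm[cbind(idx, y + 1L)] - Fm[cbind(idx, y)]
  p <- pmax(p, 1e-300)
  g_theta <- numeric(3)
  for (m in 1:3) {
    num <- fj[, m] * ((y == m) - (y == m + 1L))
    g_theta[m] <- -sum(num / p)
  }
  dF_dbeta_hi <- -z * fm[cbind(idx, y + 1L)]
  dF_dbeta_lo <- -z * fm[cbind(idx, y)]
  g_beta <- -sum((dF_dbeta_hi - dF_dbeta_lo) / p)
  c(g_theta, g_beta)
}

# Newton refinement of the BFGS solution: finite-difference Hessian of the
# analytic gradient, with step halving; drives the gradient below tolerance
# on regular data and stops harmlessly at the cap under separation.
newton_polish <- function(par, z, y, grad_tol, max_steps = 50L) {
  nll <- olreg_nll(par, z, y)
  for (step in seq_len(max_steps)) {
    g <- olreg_grad(par, z, y)
    if (max(abs(g)) < grad_tol / 10) break
    h <- 1e-6 * pmax(abs(par), 1)
    H <- vapply(seq_along(par), function(j) {
      pj <- par; pj[j] <- pj[j] + h[j]
      (olreg_grad(pj, z, y) - g) / h[j]
    }, numeric(length(par)))
    H <- (H + t(H)) / 2
    delta <- tryCatch(solve(H, g), error = function(e) g) # fall back to GD
    scale <- 1
    repeat {
      cand <- par - scale * delta
      cand_nll <- olreg_nll(cand, z, y)
      if (cand_nll <= nll || scale < 1e-8) break
      scale <- scale / 2
    }
    if (cand_nll > nll) break
    par <- cand; nll <- cand_nll
  }
  par
}

#' Fit a proportional-odds visibility model
#'
#' Maximum-likelihood fit of the cumulative-logit model
#' `P(Y <= j | x) = logistic(theta_j - beta * x)` with three ordered
#' thresholds and one slope, mapping a continuous similarity or distance to
#' the ordinal 1-4 visibility scale. Thresholds are initialized at the
#' empirical cumulative class logits and the slope at zero; the likelihood
#' is maximized by quasi-Newton (BFGS) iterations, declaring convergence
#' when the gradient infinity-norm falls below `1e-8`, with a cap of 200
#' iterations. Under perfect separation the fit stops at the cap with a
#' warning instead of failing.
#'
#' Distances (color) and similarities (texture) are both accepted: with
#' `orientation = "similarity"` the predictor's sign is flipped internally
#' so that a larger working predictor always means a more visible lesion;
#' the flip is recorded in the fitted object.
#'
#' @param x numeric predictor (similarity or distance per item).
#' @param y integer visibility scores in 1..4 (at least 2 distinct values).
#' @param orientation `"distance"` (larger x = more visible, default) or
#'   `"similarity"` (larger x = less visible; x is negated internally).
#' @param max_iter iteration cap.
#' @param grad_tol convergence tolerance on the gradient infinity-norm.
#' @return an object of class `"olreg_model"` with elements `thresholds`
#'   (theta_1 < theta_2 < theta_3), `slope` (beta on the working
#'   predictor), `orientation`, `flipped`, `logLik`, `n`, `converged`.
#' @export
fit_olreg <- function(x, y, orientation = c("distance", "similarity"),
                      max_iter = 200L, grad_tol = 1e-8) {
  orientation <- match.arg(orientation)
  if (length(x) != length(y)) {
    abort_percsim("`x` and `y` must have equal length.", "percsim_usage_error")
  }
  y <- as.integer(y)
  if (any(!y %in% 1:N_LEVELS)) {
    abort_percsim("scores must be integers in 1..4.", "percsim_fit_error")
  }
  if (length(unique(y)) < 2L) {
    abort_percsim("need at least 2 distinct classes to fit.", "percsim_fit_error")
  }
  flipped <- orientation == "similarity"
  z <- if (flipped) -x else x
  n <- length(y)
  cum <- pmin(pmax(cumsum(tabulate(y, N_LEVELS))[1:3] / n, 1 / (2 * n)),
              1 - 1 / (2 * n))
  theta0 <- stats::qlogis(cum)
  # guarantee a strictly increasing start even with empty middle classes
  for (m in 2:3) theta0[m] <- max(theta0[m], theta0[m - 1] + 1e-4)
  fit <- optim(c(theta0, 0), olreg_nll, olreg_grad, z = z, y = y,
               method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-14))
  par <- newton_polish(fit$par, z, y, grad_tol)
  fit <- list(par = par, value = olreg_nll(par, z, y))
  gnorm <- max(abs(olreg_grad(fit$par, z, y)))
  converged <- gnorm < grad_tol
  if (!converged) {
    warning(sprintf(paste0("proportional-odds fit stopped with gradient norm ",
                           "%.2e (possible separation); using the last iterate."),
                    gnorm), call. = FALSE)
  }
  structure(
    list(thresholds = fit$par[1:3], slope = fit$par[4],
         orientation = orientation, flipped = flipped,
         logLik = -fit$value, n = n, converged = converged),
    class = "olreg_model"
  )
}

#' @export
print.olreg_model <- function(x, ...) {
  cat(sprintf(
    "<olreg_model> thresholds (%.3f, %.3f, %.3f), slope %.3f (%s predictor)\n",
    x$thresholds[1], x$thresholds[2], x$thresholds[3], x$slope, x$orientation))
  invisible(x)
}

#' Class probabilities and predicted visibility scores
#'
#' `class_probs()` returns the n x 4 matrix of predicted class
#' probabilities; `predict_class()` returns the class with maximal
#' probability, with ties broken toward the lower (less visible) class.
#'
#' @param model a fitted [fit_olreg()] model.
#' @param x predictor values on the original scale (the model applies its
#'   recorded orientation flip).
#' @return `class_probs()`: matrix; `predict_class()`: integer vector in
#'   1..4.
#' @export
class_probs <- function(model, x) {
  z <- if (model$flipped) -x else x
  eta <- outer(z, model$thresholds, function(zz, th) th - model$slope * zz)
  Fm <- cbind(0, plogis(eta), 1)
  p <- Fm[, 2:5, drop = FALSE] - Fm[, 1:4, drop = FALSE]
  colnames(p) <- as.character(1:N_LEVELS)
  p
}

#' @rdname class_probs
#' @export
predict_class <- function(model, x) {
  p <- class_probs(model, x)
  apply(p, 1L, function(row) which(row >= max(row) - 1e-12)[1])
}

#' Class-balanced train/validation split
#'
#' Draws `per_class` items per visibility class without replacement into
#' the training set; every remaining item goes to the validation set. With
#' four classes of 44 items and `per_class = 20` this gives the 80/96
#' train/validation design.
#'
#' @param y integer class labels 1..4.
#' @param per_class training items sampled from each class.
#' @param seed RNG seed making the split reproducible.
#' @return list with integer index vectors `train` and `validation`.
#' @export
balanced_split <- function(y, per_class = 20L, seed = 1L) {
  y <- as.integer(y)
  classes <- sort(unique(y))
  counts <- table(y)
  short <- classes[counts[as.character(classes)] < per_class]
  if (length(short)) {
    abort_percsim(
      sprintf("class(es) %s have fewer than %d items.",
              paste(short, collapse = ", "), per_class),
      "percsim_split_error"
    )
  }
  train <- withr::with_seed(seed, {
    unlist(lapply(classes, function(cl) {
      idx <- which(y == cl)
      if (length(idx) == 1L) idx else sample(idx, per_class)
    }))
  })
  train <- sort(train)
  list(train = train, validation = setdiff(seq_along(y), train))
}

#' Prediction error measures on the ordinal scale
#'
#' `mse()` is the mean squared difference between reference and predicted
#' scores. `accuracies()` returns the absolute accuracy (exact agreement)
#' and the adjacent accuracy (agreement within one scale level).
#'
#' @param y reference scores.
#' @param yhat predicted scores.
#' @return `mse()`: scalar; `accuracies()`: named vector `c(acc, acc_adj)`.
#' @export
mse <- function(y, yhat) {
  if (length(y) != length(yhat)) {
    abort_percsim("`y` and `yhat` must have equal length.", "percsim_usage_error")
  }
  mean((as.numeric(y) - as.numeric(yhat))^2)
}

#' @rdname mse
#' @export
accuracies <- function(y, yhat) {
  if (length(y) != length(yhat)) {
    abort_percsim("`y` and `yhat` must have equal length.", "percsim_usage_error")
  }
  d <- abs(as.numeric(y) - as.numeric(yhat))
  c(acc = mean(d == 0), acc_adj = mean(d <= 1))
}

#' Repeated balanced-split validation of a similarity metric
#'
#' The full validation harness: for each repetition a class-balanced
#' train/validation split is drawn (seed = master seed + repetition index),
#' a proportional-odds model is fitted on the training similarities, the
#' validation items are scored, and MSE, absolute accuracy and adjacent
#' accuracy are recorded. Means over repetitions are reported with
#' normal-approximation 95% confidence intervals
#' (`mean +- 1.96 * sd / sqrt(n_reps)`).
#'
#' @param data data frame with one row per item.
#' @param predictor column (name) holding the continuous similarity or
#'   distance.
#' @param gold column (name) holding the rounded gold-standard scores 1..4.
#' @param n_reps number of repetitions (default 100).
#' @param per_class training items per class in each split (default 20).
#' @param seed master seed; repetition r uses `seed + r`.
#' @param orientation passed to [fit_olreg()].
#' @return an object of class `"validation_report"`: `per_rep` tibble
#'   (`rep`, `seed`, `mse`, `acc`, `acc_adj`), `summary` tibble with means
#'   and CI bounds, and the split specification. Use [tidy()] / [glance()].
#' @export
validate_metric <- function(data, predictor, gold, n_reps = 100L,
                            per_class = 20L, seed = 1L,
                            orientation = c("distance", "similarity")) {
  orientation <- match.arg(orientation)
  x <- data[[rlang::as_name(rlang::ensym(predictor))]]
  y <- as.integer(data[[rlang::as_name(rlang::ensym(gold))]])
  if (is.null(x) || is.null(y)) {
    abort_percsim("predictor/gold columns not found in `data`.",
                  "percsim_usage_error")
  }
  reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
    rep_seed <- derive_seed(seed, r)
    res <- tryCatch({
      sp <- balanced_split(y, per_class = per_class, seed = rep_seed)
      m <- suppressWarnings(
        fit_olreg(x[sp$train], y[sp$train], orientation = orientation))
      yhat <- predict_class(m, x[sp$validation])
      ac <- accuracies(y[sp$validation], yhat)
      tibble::tibble(rep = r, seed = rep_seed,
                     mse = mse(y[sp$validation], yhat),
                     acc = ac[["acc"]], acc_adj = ac[["acc_adj"]])
    }, percsim_error = function(e) {
      abort_percsim(sprintf("repetition %d: %s", r, conditionMessage(e)),
                    class(e)[1])
    })
    res
  })
  ci <- function(v) {
    if (n_reps < 2L) return(c(NA_real_, NA_real_))
    half <- 1.96 * sd(v) / sqrt(n_reps)
    c(mean(v) - half, mean(v) + half)
  }
  if (n_reps < 2L) {
    warning("confidence intervals are undefined with a single repetition; ",
            "reporting point values only.", call. = FALSE)
  }
  summ <- tibble::tibble(
    statistic = c("mse", "acc", "acc_adj"),
    mean = c(mean(reps$mse), mean(reps$acc), mean(reps$acc_adj)),
    ci_lo = c(ci(reps$mse)[1], ci(reps$acc)[1], ci(reps$acc_adj)[1]),
    ci_hi = c(ci(reps$mse)[2], ci(reps$acc)[2], ci(reps$acc_adj)[2])
  )
  structure(
    list(per_rep = reps, summary = summ, n_reps = n_reps,
         split_spec = list(per_class = per_class, seed = seed,
                           orientation = orientation)),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<validation_report> %d repetitions (per-class train n = %d)\n",
              x$n_reps, x$split_spec$per_class))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-8s mean %.3f  [%.3f, %.3f]\n",
                s$statistic[i], s$mean[i], s$ci_lo[i], s$ci_hi[i]))
  }
  invisible(x)
}
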