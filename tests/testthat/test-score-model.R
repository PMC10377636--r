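test_that("the proportional-odds fit recovers known parameters", {
  sim <- simulate_olreg(2000, theta = c(-1, 0, 1), beta = 2, seed = 42)
  m <- fit_olreg(sim$x, sim$y)
  expect_true(m$converged)
  expect_lt(max(abs(m$thresholds - c(-1, 0, 1))), 0.15)
  expect_lt(abs(m$slope - 2), 0.15)
  expect_true(all(diff(m$thresholds) > 0))
})

test_that("the fit agrees with an independent proportional-odds solver", {
  sim <- simulate_olreg(600, seed = 7)
  m <- fit_olreg(sim$x, sim$y)
  ref <- MASS::polr(factor(sim$y) ~ x, data = data.frame(x = sim$x),
                    method = "logistic")
  expect_equal(unname(m$thresholds), unname(ref$zeta), tolerance = 1e-3)
  expect_equal(unname(m$slope), unname(coef(ref)), tolerance = 1e-3)
})

test_that("estimation bias shrinks with sample size", {
  bias_at <- function(n) {
    mean(vapply(1:5, function(s) {
      sim <- simulate_olreg(n, seed = 100 + s)
      m <- suppressWarnings(fit_olreg(sim$x, sim$y))
      sum(abs(c(m$thresholds, m$slope) - c(-1, 0, 1, 2)))
    }, numeric(1)))
  }
  expect_gt(bias_at(200), bias_at(2000))
})

test_that("a constant predictor yields a flat model matching class frequencies", {
  y <- rep(1:4, times = c(10, 30, 40, 20))
  m <- suppressWarnings(fit_olreg(rep(0.5, length(y)), y))
  expect_lt(abs(m$slope), 1e-4)
  p <- class_probs(m, 0.5)
  expect_equal(as.numeric(p), c(0.1, 0.3, 0.4, 0.2), tolerance = 1e-4)
})

test_that("perfect separation warns, does not crash, and reproduces labels", {
  x <- c(rep(0, 10), rep(10, 10)); y <- c(rep(1L, 10), rep(4L, 10))
  expect_warning(m <- fit_olreg(x, y), "separation")
  expect_equal(predict_class(m, x), y)
  expect_error(fit_olreg(x, rep(2L, 20)), class = "percsim_fit_error")
})

test_that("predict_class breaks probability ties toward the lower class", {
  m <- structure(list(thresholds = c(-1, 0, 1), slope = 0,
                      orientation = "distance", flipped = FALSE),
                 class = "olreg_model")
  p <- class_probs(m, 0)
  expect_equal(as.numeric(p),
               c(plogis(-1), plogis(0) - plogis(-1),
                 plogis(1) - plogis(0), 1 - plogis(1)))
  expect_equal(predict_class(m, c(0, 100)), c(1L, 1L))
})

test_that("predictions are monotone in the predictor and hit the limits", {
  sim <- simulate_olreg(800, seed = 3)
  m <- fit_olreg(sim$x, sim$y)
  xs <- seq(-6, 6, length.out = 200)
  preds <- predict_class(m, xs)
  expect_true(all(diff(preds) >= 0))
  expect_equal(predict_class(m, -1e6), 1L)
  expect_equal(predict_class(m, 1e6), 4L)
})

test_that("orientation flip makes similarities behave like distances", {
  sim <- simulate_olreg(800, seed = 9)
  m_dist <- fit_olreg(sim$x, sim$y, orientation = "distance")
  m_sim <- fit_olreg(-sim$x, sim$y, orientation = "similarity")
  expect_equal(m_dist$thresholds, m_sim$thresholds, tolerance = 1e-6)
  expect_equal(m_dist$slope, m_sim$slope, tolerance = 1e-6)
  expect_true(m_sim$flipped)
  expect_equal(predict_class(m_dist, sim$x), predict_class(m_sim, -sim$x))
})

test_that("balanced_split reproduces the 80/96 design and is deterministic", {
  y <- rep(1:4, each = 44)
  sp <- balanced_split(y, per_class = 20, seed = 5)
  expect_length(sp$train, 80L)
  expect_length(sp$validation, 96L)
  expect_length(intersect(sp$train, sp$validation), 0L)
  expect_equal(as.numeric(table(y[sp$train])), rep(20, 4))
  expect_identical(sp, balanced_split(y, per_class = 20, seed = 5))
  expect_false(identical(sp, balanced_split(y, per_class = 20, seed = 6)))
})

test_that("balanced_split handles singleton classes and shortage errors", {
  y <- c(1L, rep(2:4, each = 3))
  sp <- balanced_split(y, per_class = 1, seed = 2)
  expect_true(1L %in% sp$train)
  err <- tryCatch(balanced_split(y, per_class = 2, seed = 2),
                  error = function(e) e)
  expect_s3_class(err, "percsim_split_error")
  expect_match(conditionMessage(err), "1")
})

test_that("mse and accuracies match counting oracles", {
  expect_equal(mse(c(1, 2), c(1, 2)), 0)
  expect_equal(mse(c(1, 2), c(2, 2)), 0.5)
  withr::with_seed(8, {
    y <- sample(1:4, 50, TRUE); yhat <- sample(1:4, 50, TRUE)
    acc_loop <- 0; adj_loop <- 0; mse_loop <- 0
    for (i in 1:50) {
      acc_loop <- acc_loop + (y[i] == yhat[i])
      adj_loop <- adj_loop + (abs(y[i] - yhat[i]) <= 1)
      mse_loop <- mse_loop + (y[i] - yhat[i])^2
    }
    expect_equal(mse(y, yhat), mse_loop / 50)
    ac <- accuracies(y, yhat)
    expect_equal(unname(ac), c(acc_loop, adj_loop) / 50)
    expect_lte(ac[["acc"]], ac[["acc_adj"]])
  })
  expect_equal(unname(accuracies(c(1, 1, 1, 1), c(2, 2, 2, 3))), c(0, 0.75))
  expect_error(mse(1:3, 1:4), class = "percsim_usage_error")
})

test_that("validate_metric is near-perfect on disjoint value bands", {
  y <- rep(1:4, each = 44)
  x <- withr::with_seed(1, y * 10 + runif(length(y), -1, 1)) # disjoint bands
  vr <- validate_metric(tibble::tibble(x = x, y = y), x, y,
                        n_reps = 20, seed = 2)
  g <- glance(vr)
  expect_lt(g$mse_mean, 0.05)
  expect_gt(g$acc_mean, 0.95)
  expect_true(all(vr$per_rep$acc <= vr$per_rep$acc_adj))
})

test_that("an uninformative predictor falls back to class-frequency guessing", {
  y <- rep(1:4, each = 44)
  x <- withr::with_seed(3, rnorm(length(y)))
  vr <- suppressWarnings(
    validate_metric(tibble::tibble(x = x, y = y), x, y, n_reps = 30, seed = 4))
  g <- glance(vr)
  # every class keeps 24 of 96 validation items, so chance accuracy is 0.25
  ci_width <- g$acc_hi - g$acc_lo
  expect_lt(abs(g$acc_mean - 0.25), 3 * ci_width)
})

test_that("validation reports are bit-reproducible under one master seed", {
  y <- rep(1:4, each = 30)
  x <- withr::with_seed(5, y + rnorm(length(y)))
  df <- tibble::tibble(x = x, y = y)
  v1 <- validate_metric(df, x, y, n_reps = 10, per_class = 10, seed = 99)
  v2 <- validate_metric(df, x, y, n_reps = 10, per_class = 10, seed = 99)
  expect_identical(v1, v2)
})

test_that("a single repetition reports point values with a warning", {
  y <- rep(1:4, each = 30)
  x <- withr::with_seed(6, y + rnorm(length(y)))
  expect_warning(
    vr <- validate_metric(tibble::tibble(x = x, y = y), x, y,
                          n_reps = 1, per_class = 10, seed = 1),
    "single repetition"
  )
  expect_true(all(is.na(vr$summary$ci_lo)))
  expect_equal(nrow(vr$per_rep), 1L)
})

test_that("tidiers expose the report in tabular form", {
  sim <- simulate_olreg(400, seed = 12)
  m <- fit_olreg(sim$x, sim$y)
  td <- tidy(m)
  expect_equal(td$term, c("theta_1", "theta_2", "theta_3", "beta"))
  expect_equal(glance(m)$n, 400L)
})
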