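test_that("two-rater alpha matches the closed form 2r/(1+r)", {
  # construct two columns with exactly equal variance and correlation 0.5
  a <- c(-3, -1, 1, 3)
  e <- c(1, -1, -1, 1) * sqrt(5) # orthogonal to a, rescaled to var(a)
  r <- 0.5
  b <- r * a + sqrt(1 - r^2) * e
  expect_equal(stats::cor(a, b), r, tolerance = 1e-12)
  expect_equal(cronbach_alpha(cbind(a, b)), 2 * r / (1 + r), tolerance = 1e-10)
})

test_that("alpha is 1 for duplicated raters and ~0 for independent ones", {
  x <- withr::with_seed(2, rnorm(100))
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1, tolerance = 1e-12)
  ind <- withr::with_seed(3, matrix(rnorm(4000 * 4), ncol = 4))
  expect_lt(abs(cronbach_alpha(ind)), 0.1)
  expect_error(cronbach_alpha(matrix(2, 5, 3)),
               class = "percsim_degenerate_error")
})

test_that("drop-one alpha slices match independent recomputation", {
  tab <- simulate_raters(rep(1:4, each = 15), n_raters = 7, noise_sd = 0.6,
                         seed = 5)
  d1 <- alpha_drop_one(tab)
  expect_equal(nrow(d1), 7L)
  for (j in 1:7) {
    expect_equal(d1$alpha[j],
                 cronbach_alpha(unclass(tab)[, -j, drop = FALSE]))
  }
  # removing a duplicate of an identical panel leaves alpha at 1
  x <- withr::with_seed(6, rnorm(30))
  same <- cbind(r1 = x, r2 = x, r3 = x)
  expect_true(all(abs(alpha_drop_one(same)$alpha - 1) < 1e-12))
})

test_that("quadratic kappa matches a hand computation on a toy table", {
  r1 <- c(1, 1, 2, 2, 3, 3, 4, 4, 1, 2, 3, 4)
  r2 <- c(1, 2, 2, 3, 3, 4, 4, 4, 3, 2, 1, 2)
  # independent transcription: explicit confusion matrix and weight loops
  n <- length(r1)
  conf <- matrix(0, 4, 4)
  for (i in seq_len(n)) conf[r1[i], r2[i]] <- conf[r1[i], r2[i]] + 1 / n
  po <- 0; pe <- 0
  for (i in 1:4) for (j in 1:4) {
    wij <- 1 - (i - j)^2 / 9
    po <- po + wij * conf[i, j]
    pe <- pe + wij * sum(conf[i, ]) * sum(conf[, j])
  }
  expect_equal(cohen_kappa_quadratic(r1, r2), (po - pe) / (1 - pe),
               tolerance = 1e-12)
})

test_that("kappa hits its anchor cases", {
  r <- c(1, 2, 3, 4, 2, 3)
  expect_equal(cohen_kappa_quadratic(r, r), 1)
  big <- withr::with_seed(7, list(a = sample(1:4, 5000, TRUE),
                                  b = sample(1:4, 5000, TRUE)))
  expect_lt(abs(cohen_kappa_quadratic(big$a, big$b)), 0.05)
  expect_equal(cohen_kappa_quadratic(rep(2L, 5), rep(2L, 5)), 1)
  expect_warning(k0 <- cohen_kappa_quadratic(rep(2L, 5), rep(3L, 5)),
                 "constant")
  expect_equal(k0, 0)
})

test_that("Gwet's AC2 matches its formula on a toy two-rater table", {
  tab <- cbind(r1 = c(1, 2, 3, 4, 2, 3), r2 = c(2, 2, 4, 4, 1, 3))
  # two-rater closed form: item agreement reduces to w[score1, score2]
  w <- 1 - outer(1:4, 1:4, function(a, b) (a - b)^2) / 9
  pa <- mean(w[tab]) # w indexed by the two ratings per item
  rik <- vapply(1:4, function(k) rowSums(tab == k), numeric(6))
  pik <- colMeans(rik / 2)
  pe <- (sum(w) / 12) * sum(pik * (1 - pik))
  expect_equal(gwet_ac2(tab), (pa - pe) / (1 - pe), tolerance = 1e-12)
  # adjacent-category agreement sits strictly between 0 and 1
  adj <- cbind(1:4, c(2, 3, 4, 4))[rep(1:4, 3), ]
  expect_gt(gwet_ac2(adj), 0)
  expect_lt(gwet_ac2(adj), 1)
})

test_that("AC2 is 1 on perfect varied panels and item-order invariant", {
  m <- cbind(a = rep(1:4, each = 3), b = rep(1:4, each = 3),
             c = rep(1:4, each = 3))
  expect_equal(gwet_ac2(m), 1)
  tab <- simulate_raters(rep(1:4, each = 10), n_raters = 4, noise_sd = 0.7,
                         seed = 8)
  perm <- withr::with_seed(9, sample(nrow(tab)))
  expect_equal(gwet_ac2(tab), gwet_ac2(unclass(tab)[perm, ]),
               tolerance = 1e-12)
  expect_error(gwet_ac2(matrix(c(1L, 2L), 1, 2)),
               class = "percsim_degenerate_error")
})

test_that("AC2 resists the skewed-prevalence kappa paradox", {
  # two raters agreeing on a rare category: kappa collapses, AC2 does not
  r1 <- c(rep(1L, 38), 4L, 1L, 4L)
  r2 <- c(rep(1L, 38), 4L, 4L, 1L)
  expect_gt(gwet_ac2(cbind(r1, r2)), cohen_kappa_quadratic(r1, r2))
})

test_that("compare_groups reproduces the 15 + 6 pair combinatorics", {
  panel <- simulate_raters(rep(1:4, each = 24), n_raters = 6, noise_sd = 0.5,
                           seed = 10)
  system_scores <- unclass(panel)[, 1] # system mimics rater 1 exactly
  gc <- compare_groups(panel, system_scores)
  expect_equal(sum(gc$pairs$group == "H-H"), 15L)
  expect_equal(sum(gc$pairs$group == "S-H"), 6L)
  expect_true(any(gc$pairs$kappa[gc$pairs$group == "S-H"] == 1))
  expect_true(gc$rank_sum_p > 0 && gc$rank_sum_p <= 1)
  expect_equal(nrow(glance(gc)), 2L)
})

test_that("identical groups give an exact rank-sum p of 1", {
  panel <- simulate_raters(rep(1:4, each = 12), n_raters = 3, noise_sd = 0.4,
                           seed = 11)
  m <- unclass(panel)
  # system = rater 3 makes the S-H kappas a subset matching H-H structure;
  # force exact enumeration by keeping both groups <= 10 pairs
  gc <- compare_groups(m, m[, 3])
  expect_lte(gc$rank_sum_p, 1)
  # direct check of the enumeration on identical samples
  g <- c(0.5, 0.6, 0.7)
  p <- compare_groups(
    cbind(a = c(1, 2, 3, 4, 1, 2), b = c(1, 2, 3, 4, 1, 2),
          c = c(1, 2, 3, 4, 1, 2)),
    c(1, 2, 3, 4, 1, 2)
  )$rank_sum_p
  expect_equal(p, 1)
})

test_that("rank-sum p is invariant under common monotone transforms", {
  panel <- simulate_raters(rep(1:4, each = 20), n_raters = 6, noise_sd = 0.6,
                           seed = 12)
  sys <- gold_scores(panel)$rounded_score
  gc <- compare_groups(panel, sys)
  # recompute p after a monotone transform of both kappa groups
  g1 <- gc$pairs$kappa[gc$pairs$group == "H-H"]
  g2 <- gc$pairs$kappa[gc$pairs$group == "S-H"]
  p_orig <- gc$rank_sum_p
  p_trans <- suppressWarnings(
    stats::wilcox.test(exp(g1), exp(g2), exact = FALSE)$p.value)
  p_base <- suppressWarnings(
    stats::wilcox.test(g1, g2, exact = FALSE)$p.value)
  expect_equal(p_trans, p_base, tolerance = 1e-12)
})
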