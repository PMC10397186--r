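test_that("HDIs match closed-form quantiles for standard shapes", {
  set.seed(1)
  h <- hdi(rnorm(5e5))
  expect_equal(unname(h), c(-1.96, 1.96), tolerance = 0.02)
  expect_equal(diff(unname(hdi(runif(5e5)))), 0.95, tolerance = 0.01)
  # point mass collapses to zero width
  expect_equal(diff(unname(hdi(rep(3, 500)))), 0)
  expect_error(hdi(rnorm(50)), "at least 100")
})

test_that("HDI width grows with the mass parameter", {
  set.seed(2)
  x <- rexp(20000)
  widths <- vapply(c(0.5, 0.8, 0.9, 0.95, 0.99),
                   function(m) diff(unname(hdi(x, m))), numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("the posterior mode finds the density peak", {
  set.seed(3)
  x <- rlnorm(50000, 0, 0.5) # right-skewed: mode < median < mean
  m <- posterior_mode(x)
  expect_equal(m, exp(-0.25), tolerance = 0.05)
  expect_lt(m, median(x))
  expect_equal(posterior_mode(rep(2.5, 10)), 2.5)
})

test_that("posterior contrasts are antisymmetric and zero for identical conditions", {
  d <- simulate_ror_model(n_participants = 10, trials_per_cell = 6,
                          seed = 4)
  fit <- suppressWarnings(fit_ror(d, "free", seed = 4, draws = 1000,
                                  adapt = 200, warmup = 200))
  ab <- posterior_contrast(fit, "nont", "sim")
  ba <- posterior_contrast(fit, "sim", "nont")
  expect_equal(ab$mode, -ba$mode, tolerance = 1e-9)
  expect_equal(ab$hdi_low, -ba$hdi_high, tolerance = 1e-9)
  aa <- posterior_contrast(fit, "rel", "rel")
  expect_equal(aa$mode, 0)
  expect_equal(c(aa$hdi_low, aa$hdi_high), c(0, 0))
  expect_false(aa$excludes_zero)
  expect_error(posterior_contrast(fit, "rel", "nope"), "unknown condition")
})

test_that("JZS Bayes factors match an independent quadrature oracle", {
  # oracle: hierarchical g-prior representation of the same integral
  jzs_oracle <- function(t, n, r = 1 / sqrt(2)) {
    nu <- n - 1
    num <- integrate(function(g) {
      a <- 1 + n * g * r^2
      a^(-0.5) * (1 + t^2 / (a * nu))^(-(nu + 1) / 2) *
        dgamma(1 / g, 0.5, rate = 0.5) / g^2
    }, 0, Inf, rel.tol = 1e-10)$value
    num / (1 + t^2 / nu)^(-(nu + 1) / 2)
  }
  x <- c(1.2, 0.8, 1.5, 0.3, 0.9, 1.1, 0.2, 0.7)
  y <- c(0.9, 0.4, 1.1, 0.5, 0.6, 0.8, 0.4, 0.2)
  bf <- paired_bf(x, y)
  d <- x - y
  t_obs <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(bf$bf_10, jzs_oracle(t_obs, length(d)), tolerance = 1e-4)
  # a second fixed dataset with a null-ish effect
  x2 <- c(0.1, -0.2, 0.3, 0.05, -0.1, 0.2, -0.3, 0.15, 0.0, -0.05)
  bf2 <- paired_bf(x2, 0)
  t2 <- mean(x2) / (sd(x2) / sqrt(10))
  expect_equal(bf2$bf_10, jzs_oracle(t2, 10), tolerance = 1e-4)
  expect_lt(bf2$bf_10, 1)
})

test_that("directed and two-sided Bayes factors obey the symmetry identity", {
  set.seed(5)
  x <- rnorm(15, 0.4); y <- rnorm(15)
  two <- paired_bf(x, y)$bf_10
  plus <- paired_bf(x, y, "x_gt_y")$bf_10
  minus <- paired_bf(y, x, "x_gt_y")$bf_10
  expect_equal(two, (plus + minus) / 2, tolerance = 1e-6)
})

test_that("perfectly null and degenerate inputs are handled as specified", {
  x <- c(1, 2, 3, 4, 5)
  expect_lt(paired_bf(x, x, "x_gt_y")$bf_10, 1)
  expect_error(paired_bf(x, x - 1), "zero-variance")
  expect_error(paired_bf(1:2, 2:1), "at least 3")
})

test_that("a true standardised effect of one is detected at n = 20", {
  set.seed(6)
  hits <- vapply(1:10, function(i) {
    d <- rnorm(20, 1, 1)
    paired_bf(d, 0)$bf_10 > 10
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})

test_that("repeated-measures correlation matches its definition exactly", {
  # perfect within-participant negative lines, arbitrary intercepts
  p <- rep(1:5, each = 4)
  x <- rep(c(0, 1, 2, 3), 5)
  y <- -2 * x + rep(c(10, 20, 5, 0, -3), each = 4)
  rc <- suppressWarnings(rm_corr(x, y, p)) # exact fit: F test degenerates
  expect_equal(rc$r, -1, tolerance = 1e-9)
  # dof formula: 12 participants x 4 conditions -> 48 - 12 - 1 = 35
  set.seed(7)
  p2 <- rep(1:12, each = 4)
  x2 <- rnorm(48); y2 <- rnorm(48)
  expect_equal(rm_corr(x2, y2, p2)$df, 35)
  # normal-equations oracle on a random dataset
  y3 <- 1 - 0.6 * x2 + rep(rnorm(12), each = 4) + rnorm(48, 0, 0.4)
  rc3 <- rm_corr(x2, y3, p2)
  X0 <- stats::model.matrix(~ 0 + factor(p2))
  X1 <- cbind(X0, x2)
  b1 <- solve(t(X1) %*% X1, t(X1) %*% y3)
  sse <- sum((y3 - X1 %*% b1)^2)
  b0 <- solve(t(X0) %*% X0, t(X0) %*% y3)
  ssx <- sum((y3 - X0 %*% b0)^2) - sse
  r_oracle <- sign(b1[length(b1)]) * sqrt(ssx / (ssx + sse))
  expect_equal(rc3$r, unname(r_oracle), tolerance = 1e-8)
})

test_that("rm_corr is invariant to per-participant constant shifts", {
  set.seed(8)
  p <- rep(1:8, each = 5)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40, 0, 0.5)
  base <- rm_corr(x, y, p)$r
  shifted <- rm_corr(x + rep(rnorm(8, 0, 10), each = 5),
                     y + rep(rnorm(8, 0, 10), each = 5), p)$r
  expect_equal(base, shifted, tolerance = 1e-9)
})

test_that("the patch-leaving test labels policies by their threshold", {
  # agents leaving at the environment average: no credible deviation
  pars_mvt <- forager_params(
    group_ror_mean = setNames(rep(1.05, 4), condition_levels()),
    leave_threshold = NULL, rel_leave_bias = 1, error_prob = 0,
    policy_mix = c(collect_all = 0, mvt_threshold = 1,
                   early_threshold = 0), point_goal = 500)
  ev <- simulate_experiment(pars_mvt, 20, seed = 51)
  mv <- mvt_test(trial_records(ev))
  expect_gte(sum(mv$label == "at_average"), 3)
  # early leavers: last rates credibly above the average
  pars_early <- forager_params(
    group_ror_mean = setNames(rep(1.05, 4), condition_levels()),
    leave_threshold = 1.6, rel_leave_bias = 1, error_prob = 0,
    policy_mix = c(collect_all = 0.5, mvt_threshold = 0,
                   early_threshold = 0.5), point_goal = 500)
  ev2 <- simulate_experiment(pars_early, 20, seed = 52)
  rec2 <- trial_records(ev2)
  leavers <- classify_active_leavers(rec2)
  mv2 <- mvt_test(dplyr::semi_join(
    rec2, dplyr::filter(leavers, active_leaver), by = "participant"))
  expect_gte(sum(mv2$label == "above_average"), 3)
})
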