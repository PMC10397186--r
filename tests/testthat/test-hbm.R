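sim_small_ror <- function(seed = 1) {
  simulate_ror_model(n_participants = 12, trials_per_cell = 8, seed = seed)
}

test_that("free fit recovers generating group means on a small cohort", {
  mu <- c(0.978, 0.985, 1.136, 1.117)
  d <- simulate_ror_model(mu, n_participants = 30, trials_per_cell = 10,
                          seed = 101)
  fit <- fit_ror(d, "free", seed = 1, draws = 2000, adapt = 400,
                 warmup = 400)
  gp <- group_param_draws(fit)
  for (i in 1:4) {
    h <- hdi(gp[, i])
    expect_lt(abs(mean(gp[, i]) - mu[i]), 0.12) # loose at this small n
    expect_gt(h[2] - h[1], 0)
  }
  expect_true(all(is.finite(gp)))
})

test_that("equal generating conditions yield contrasts straddling zero", {
  d <- simulate_ror_model(rep(1, 4), n_participants = 20,
                          trials_per_cell = 8, seed = 7)
  fit <- fit_ror(d, "free", seed = 2, draws = 1600, adapt = 300,
                 warmup = 300)
  for (pair in list(c("rel", "sim"), c("nont", "opp"), c("sim", "opp"))) {
    ct <- posterior_contrast(fit, pair[1], pair[2])
    expect_false(ct$excludes_zero)
  }
})

test_that("constrained fits satisfy their orderings in every draw", {
  d <- sim_small_ror(3)
  frel <- fit_ror(d, "relational", seed = 3, draws = 1200, adapt = 300,
                  warmup = 300)
  gp <- group_param_draws(frel)
  expect_true(all(gp[, "rel"] == gp[, "sim"]))
  expect_true(all(gp[, "nont"] == gp[, "opp"]))
  expect_true(all(gp[, "sim"] <= gp[, "nont"]))
  ffs <- fit_ror(d, "feature_specific", seed = 3, draws = 1200,
                 adapt = 300, warmup = 300)
  gf <- group_param_draws(ffs)
  expect_true(all(gf[, "sim"] <= gf[, "rel"]))
  expect_true(all(gf[, "rel"] <= gf[, "opp"]))
  expect_true(all(gf[, "rel"] == gf[, "nont"]))

  cnt <- simulate_ptlb_model(n_participants = 12, trials_per_cell = 8,
                             seed = 4)
  prel <- fit_ptlb(cnt, "relational", seed = 4, draws = 1200, adapt = 300,
                   warmup = 300)
  go <- group_param_draws(prel)
  expect_true(all(go[, "rel"] == go[, "sim"]))
  expect_true(all(go[, "nont"] == go[, "opp"]))
  expect_true(all(go[, "rel"] >= go[, "nont"])) # flipped direction
  pfs <- fit_ptlb(cnt, "feature_specific", seed = 4, draws = 1200,
                  adapt = 300, warmup = 300)
  gpf <- group_param_draws(pfs)
  expect_true(all(gpf[, "sim"] >= gpf[, "rel"]))
  expect_true(all(gpf[, "rel"] >= gpf[, "opp"]))
  expect_true(all(gpf[, "rel"] == gpf[, "nont"]))
})

test_that("participant estimates shrink toward the group", {
  d <- sim_small_ror(5)
  fit <- fit_ror(d, "free", seed = 5, draws = 1600, adapt = 300,
                 warmup = 300)
  th <- participant_param_draws(fit)
  raw_p <- tapply(d$ror, d$participant, mean)
  est_p <- rowMeans(apply(th, c(2, 3), mean)) # posterior participant means
  grand <- mean(d$ror)
  # pooled participant means lie between raw means and the grand mean
  between <- (est_p - raw_p) * (grand - raw_p) >= -1e-6 &
    abs(est_p - grand) <= abs(raw_p - grand) + 1e-6
  expect_gte(mean(between), 0.9)
})

test_that("fixed-kappa single-participant reduction matches the conjugate posterior", {
  set.seed(11)
  cnt <- tibble::tibble(
    participant = 1,
    condition = rep(condition_levels(), each = 12),
    n_left = c(rbinom(12, 15, 0.25), rbinom(36, 15, 0.05))
  )
  fit <- fit_ptlb(cnt, "free", kappa_fixed = 2, seed = 6, draws = 4000,
                  adapt = 400, warmup = 400)
  th <- participant_param_draws(fit)[, 1, "rel"]
  k <- sum(cnt$n_left[cnt$condition == "rel"])
  n <- 12 * 15
  # flat prior => theta | data ~ Beta(1 + k, 1 + n - k)
  expect_equal(mean(th), (1 + k) / (2 + n), tolerance = 0.02)
  expect_equal(sd(th),
               sqrt((1 + k) * (1 + n - k) / ((2 + n)^2 * (3 + n))),
               tolerance = 0.1)
  qs <- quantile(th, c(0.1, 0.5, 0.9))
  expect_equal(unname(qs),
               qbeta(c(0.1, 0.5, 0.9), 1 + k, 1 + n - k),
               tolerance = 0.02)
})

test_that("an all-zero cohort pins the group proportion near zero", {
  cnt <- tibble::tibble(
    participant = rep(1:20, each = 16),
    condition = rep(rep(condition_levels(), each = 4), 20),
    n_left = 0L
  )
  # fixed concentration keeps the group mode identified; the all-zero
  # counts then pin it to the bottom of the unit interval
  fit <- fit_ptlb(cnt, "free", kappa_fixed = 20, seed = 7, draws = 2000,
                  adapt = 300, warmup = 300)
  gp <- group_param_draws(fit)
  for (i in 1:4) expect_lt(hdi(gp[, i])[2], 0.05)
})

test_that("pointwise log-likelihood matches closed forms and the joint", {
  d <- sim_small_ror(9)
  fit <- fit_ror(d, "free", seed = 9, draws = 800, adapt = 200,
                 warmup = 200)
  ll <- pointwise_loglik(fit)
  expect_equal(dim(ll), c(nrow(fit$draws), nrow(d)))
  # reconstruct one entry by hand: Normal log-density at the sampled
  # participant-condition mean and residual sd
  s <- 17; i <- 5
  p <- as.integer(factor(d$participant))[i]
  cc <- as.integer(factor(d$condition, levels = condition_levels()))[i]
  mu_si <- fit$draws[s, paste0("theta[", p, ",", cc, "]")]
  expect_equal(ll[s, i],
               dnorm(d$ror[i], mu_si, fit$draws[s, "sigma_w"], log = TRUE))
  # y at the sampled mean with unit sd gives -log(2 pi)/2
  expect_equal(dnorm(0, 0, 1, log = TRUE), -0.5 * log(2 * pi))
  # binomial closed form: all 15 left at theta = 0.5
  expect_equal(dbinom(15, 15, 0.5, log = TRUE), 15 * log(0.5))
  # rows sum to the joint conditional log-likelihood of the same draw
  mu_all <- fit$draws[s, paste0("theta[",
                                as.integer(factor(d$participant)), ",",
                                as.integer(factor(d$condition,
                                                  levels = condition_levels())),
                                "]")]
  expect_equal(sum(ll[s, ]),
               sum(dnorm(d$ror, mu_all, fit$draws[s, "sigma_w"],
                         log = TRUE)))
})

test_that("group-mean prior mass lies almost entirely in (0, 5) items/s", {
  set.seed(12)
  # truncated-positive Normal(1, 1.5^2) via rejection
  x <- rnorm(4e5, 1, 1.5)
  x <- x[x > 0][1:2e5]
  expect_gte(mean(x < 5), 0.99)
})

test_that("the free fit recovers the generating gap at study scale", {
  d <- simulate_ror_model(c(0.98, 0.98, 1.111, 1.111),
                          n_participants = 47, trials_per_cell = 16,
                          seed = 13)
  fit <- fit_ror(d, "free", seed = 13, draws = 1600, adapt = 300,
                 warmup = 300)
  gp <- group_param_draws(fit)
  gap <- mean(gp[, "opp"] - gp[, "sim"])
  expect_lt(abs(gap - 0.131), 0.03)
})
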