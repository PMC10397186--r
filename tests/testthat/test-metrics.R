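test_that("rate of return divides collected items by patch plus travel time", {
  expect_equal(rate_of_return(15, 14), 1.0)
  expect_equal(rate_of_return(0, 3), 0.0)
  expect_equal(rate_of_return(12, 9), 1.2)
  expect_error(rate_of_return(5, -1), "negative")
  # strictly decreasing in duration, increasing in collected count
  expect_gt(rate_of_return(10, 8), rate_of_return(10, 9))
  expect_gt(rate_of_return(11, 9), rate_of_return(10, 9))
})

test_that("instantaneous rates are elementwise reciprocals", {
  expect_equal(instantaneous_rates(c(1, 0.5, 2)), c(1, 2, 0.5))
  expect_equal(instantaneous_rates(numeric(0)), numeric(0))
  expect_error(instantaneous_rates(c(1, 0)), "non-positive")
  # Jensen: mean of reciprocals >= reciprocal of the mean
  set.seed(1)
  for (i in 1:20) {
    x <- rlnorm(30, 0, runif(1, 0.1, 1))
    expect_gte(mean(instantaneous_rates(x)), 1 / mean(x))
  }
})

test_that("proportion left and its inverse reconstruction are consistent", {
  expect_equal(proportion_left(0), 0)
  expect_equal(proportion_left(15), 1)
  expect_equal(proportion_left(3), 0.2)
  for (k in 0:15) expect_equal(proportion_left(k) * 15, k)
  expect_error(proportion_left(16), "n_left")
  expect_error(proportion_left(-1), "n_left")
})

test_that("arcsine transform is exact at landmarks and monotone", {
  expect_equal(arcsine_transform(0), 0)
  expect_equal(arcsine_transform(1), pi / 2)
  expect_equal(arcsine_transform(0.25), pi / 6)
  p <- seq(0, 1, 0.01)
  expect_true(all(diff(arcsine_transform(p)) > 0))
  expect_error(arcsine_transform(1.1), "0, 1")
})

test_that("selection delays anchor on target clicks only", {
  ev <- make_events(list(
    list(trial = 1, t_ms = c(800, 1500), roles = c("target", "target")),
    list(trial = 2, t_ms = 900, roles = "target"),
    list(trial = 3, t_ms = c(400, 800, 1500),
         roles = c("distractor", "target", "target"))
  ))
  d <- selection_delays(ev)
  expect_equal(d$first_delay_s, c(0.8, 0.9, 0.8))
  expect_equal(d$second_delay_s, c(0.7, NA, 0.7))
})

test_that("trial records summarise event logs faithfully", {
  ev <- make_events(list(
    list(trial = 1, condition = "sim",
         t_ms = c(500, 1500, 2200, 2600),
         roles = c("target", "nontarget", "target", "next_button"))
  ))
  rec <- trial_records(ev)
  expect_equal(rec$n_collected, 2)
  expect_equal(rec$n_left, 13)
  expect_equal(rec$duration_s, 2.6) # ends at the "Next" click
  expect_equal(rec$itts_s[[1]], 1.7) # wrong click does not reset the ITT
  expect_equal(rec$first_delay_s, 0.5)
  expect_equal(rec$ror, 2 / 3.6)
  expect_true(rec$left_actively)
})

test_that("metrics recomputed from a simulated log equal the simulator's record", {
  set.seed(4)
  for (pol in c("collect_all", "early_threshold")) {
    tr <- simulate_trial(forager_params(error_prob = 0.02), "nont",
                         policy = pol)
    rt <- trial_records(tr$events)
    expect_equal(as.data.frame(rt), as.data.frame(tr$record))
  }
})

test_that("last-k rates align trailing selection positions", {
  ev <- make_events(list(clean_trial(itt_ms = 1000)))
  r <- last_k_rates(trial_records(ev), k = 6)
  expect_equal(nrow(r), 6)
  expect_true(all(r$mean_rate == 1))
  # a single trial with ITTs 0.5, 1, 2 s maps to rates 2, 1, 0.5
  ev2 <- make_events(list(list(t_ms = c(100, 600, 1600, 3600),
                               roles = rep("target", 4))))
  r2 <- last_k_rates(trial_records(ev2), k = 3)
  expect_equal(r2$mean_rate[order(r2$position)], c(2, 1, 0.5))
  expect_equal(sort(r2$position), c(-3, -2, -1))
})

test_that("depleting foragers show declining instantaneous rates", {
  set.seed(9)
  pars <- forager_params(error_prob = 0)
  recs <- dplyr::bind_rows(lapply(1:150, function(i) {
    simulate_trial(pars, "opp", policy = "collect_all")$record
  }))
  r <- last_k_rates(recs, k = 6)
  means <- r$mean_rate[order(r$position)]
  expect_true(all(diff(means) < 0))
})

test_that("error rates count wrong item clicks and exclude the Next button", {
  ev <- make_events(list(
    list(participant = 1, t_ms = seq(100, 10000, length.out = 100),
         roles = c(rep("target", 99), "distractor")),
    list(participant = 2, trial = 2, t_ms = c(100, 200, 300),
         roles = c("target", "target", "next_button"))
  ))
  er <- error_rate(ev)
  expect_equal(er$error_rate[er$participant == 1], 0.01)
  expect_equal(er$error_rate[er$participant == 2], 0)
  # binomial check against the generator's error probability
  set.seed(10)
  evs <- simulate_experiment(forager_params(error_prob = 0.008,
                                            point_goal = 400), 8, seed = 31)
  cohort <- error_rate(evs)
  expect_lt(abs(mean(cohort$error_rate) - 0.008), 0.004)
  # with no error clicks and depletion policy the cohort error rate is 0
  ev0 <- simulate_experiment(
    forager_params(error_prob = 0,
                   policy_mix = c(collect_all = 1, mvt_threshold = 0,
                                  early_threshold = 0),
                   point_goal = 200), 3, seed = 32)
  expect_true(all(error_rate(ev0)$error_rate == 0))
})

test_that("active leavers leave at least one target in every condition", {
  # an all-depleting participant is not an active leaver
  rec_dep <- trial_records(clean_cohort(1))
  expect_false(classify_active_leavers(rec_dep)$active_leaver)
  # leaving one target actively in each condition qualifies
  specs <- lapply(seq_along(condition_levels()), function(i) {
    list(trial = i, condition = condition_levels()[i],
         t_ms = c(seq_len(14) * 1000, 14500),
         roles = c(rep("target", 14), "next_button"))
  })
  rec_act <- trial_records(make_events(specs))
  expect_true(classify_active_leavers(rec_act)$active_leaver)
  # leaving targets by depletion-timeout (no Next click) does not qualify
  specs2 <- lapply(seq_along(condition_levels()), function(i) {
    cl <- clean_trial(trial = i, condition = condition_levels()[i],
                      n_targets = 14)
    cl
  })
  rec_na <- trial_records(make_events(specs2))
  expect_false(classify_active_leavers(rec_na)$active_leaver)
})

test_that("the environment average pools trial rates across conditions", {
  ev <- make_events(list(
    list(trial = 1, t_ms = seq_len(15) * 1000, roles = rep("target", 15)),
    list(trial = 2, t_ms = seq_len(15) * 600, roles = rep("target", 15))
  ))
  rec <- trial_records(ev)
  expect_equal(rec$ror, c(15 / 16, 1.5))
  expect_equal(average_ror(rec), mean(c(15 / 16, 1.5)))
  expect_error(average_ror(rec[0, ]), "no trials")
})

test_that("participant summaries assemble per-condition means and flags", {
  ev <- clean_cohort(2)
  rec <- trial_records(ev)
  ps <- participant_summaries(rec, ev)
  expect_equal(nrow(ps), 2)
  expect_true(all(c("ror_rel", "ror_sim", "ror_nont", "ror_opp",
                    "total_left", "error_rate", "active_leaver") %in%
                    names(ps)))
  expect_true(all(ps$error_rate == 0))
  expect_true(all(ps$total_available == 8 * 15))
})
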