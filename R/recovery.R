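#' Generate a cohort from the rate-of-return model's generative process
#'
#' Draws trial-level rates of return directly from the hierarchical Normal
#' model: participant-condition means are group condition means plus a
#' shared participant speed offset (SD `between_sd`) plus a
#' participant-by-condition deviation (SD `interaction_sd`); trials add
#' Normal noise `sigma_w`. Used for parameter-recovery and
#' model-identification studies where the generating group pattern must be
#' exact.
#'
#' @param mu Group condition means (items/s), `condition_levels()` order.
#' @param n_participants,trials_per_cell Cohort dimensions.
#' @param between_sd,interaction_sd,sigma_w Spread parameters.
#' @param seed Integer seed.
#' @return Tibble: participant, condition, trial, `ror`.
#' @export
simulate_ror_model <- function(mu = c(0.978, 0.985, 1.136, 1.117),
                               n_participants = 47, trials_per_cell = 16,
                               between_sd = 0.18, interaction_sd = 0.05,
                               sigma_w = 0.15, seed = 1) {
  set.seed(seed)
  mu <- unname(mu)
  rows <- lapply(seq_len(n_participants), function(p) {
    th <- mu + rnorm(1, 0, between_sd) + rnorm(4, 0, interaction_sd)
    tibble::tibble(
      participant = p,
      condition = as_condition(rep(condition_levels(),
                                   each = trials_per_cell)),
      trial = rep(seq_len(trials_per_cell), 4),
      ror = rnorm(4 * trials_per_cell, rep(th, each = trials_per_cell),
                  sigma_w)
    )
  })
  dplyr::bind_rows(rows)
}

#' Generate counts from the beta-binomial model's generative process
#'
#' Participant-condition proportions are drawn from the condition-level
#' Beta distribution in mode/concentration parameterisation
#' (`Beta(omega (kappa - 2) + 1, (1 - omega)(kappa - 2) + 1)`), and trial
#' counts of targets left behind from `Binomial(n_available, theta)`.
#'
#' @param omega Group condition modes, `condition_levels()` order.
#' @param kappa Concentration (> 2), shared across conditions.
#' @param n_participants,trials_per_cell Cohort dimensions.
#' @param n_available Targets per patch.
#' @param seed Integer seed.
#' @return Tibble: participant, condition, trial, `n_left`.
#' @export
simulate_ptlb_model <- function(omega = c(0.072, 0.058, 0.030, 0.029),
                                kappa = 15, n_participants = 47,
                                trials_per_cell = 16, n_available = 15,
                                seed = 1) {
  stopifnot(kappa > 2, all(omega > 0 & omega < 1))
  set.seed(seed)
  omega <- unname(omega)
  rows <- lapply(seq_len(n_participants), function(p) {
    th <- rbeta(4, omega * (kappa - 2) + 1, (1 - omega) * (kappa - 2) + 1)
    tibble::tibble(
      participant = p,
      condition = as_condition(rep(condition_levels(),
                                   each = trials_per_cell)),
      trial = rep(seq_len(trials_per_cell), 4),
      n_left = rbinom(4 * trials_per_cell, n_available,
                      rep(th, each = trials_per_cell))
    )
  })
  dplyr::bind_rows(rows)
}
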