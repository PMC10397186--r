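#' Generative parameters of a synthetic foraging cohort
#'
#' Bundles everything the simulator needs to produce a cohort of foragers
#' with the statistical signatures the analysis assumes: condition-dependent
#' rates of return around one item per second (lower under relational and
#' target-similar distractors), between-participant speed differences, a
#' right-skewed inter-target-time distribution, rare erroneous clicks, an
#' extra first-selection latency under relational distractors, and a mixture
#' of patch-leaving policies (most foragers deplete every patch, a minority
#' leaves patches actively).
#'
#' @param group_ror_mean Named numeric: group-level mean rate of return
#'   (items/s) per condition, in `condition_levels()` order.
#' @param between_sd Between-participant SD of overall foraging speed
#'   (items/s), shared across conditions.
#' @param interaction_sd SD of the participant-by-condition deviation
#'   (items/s) on top of the shared speed offset.
#' @param itt_shape Log-scale SD (dispersion) of the log-normal inter-target
#'   times.
#' @param rate_decline_ratio Ratio of the expected instantaneous rate at the
#'   first selection to that at the fifteenth; depletion makes successive
#'   targets harder to find, so expected rates decline linearly across the
#'   15 selections by this overall factor.
#' @param first_delay_bonus_rel_ms Additive latency (ms) on the first
#'   selection only, applied in the `rel` condition (the short-lived
#'   "super-relational" capture effect).
#' @param error_prob Probability that any given click lands on a distractor
#'   or non-target (no item is removed by such clicks).
#' @param policy_mix Named probabilities over `collect_all`, `mvt_threshold`,
#'   `early_threshold`; each participant is assigned one leaving policy.
#' @param leave_threshold Instantaneous rate (items/s) at which threshold
#'   policies abandon a patch. For `mvt_threshold`, `NULL` means "use the
#'   environment's average rate of return". The default 1.1 for the
#'   `early_threshold` archetype leaves patches while intake is still above
#'   the environment average.
#' @param rel_leave_bias Multiplier (> 1 leaves earlier) on the leaving
#'   threshold in the `rel` condition; distraction-related effort makes
#'   relational patches slightly less attractive to stay in.
#' @param next_click_delay_ms Mean decision latency (ms) between the last
#'   collection and the click on the "Next" button when leaving actively.
#' @param point_goal Points (collected targets) at which the experiment ends;
#'   checked after every patch.
#' @param n_available Number of targets per patch.
#' @return A list of class `forager_params`.
#' @export
forager_params <- function(group_ror_mean = c(rel = 0.978, sim = 0.985,
                                              nont = 1.136, opp = 1.117),
                           between_sd = 0.18,
                           interaction_sd = 0.05,
                           itt_shape = 0.5,
                           rate_decline_ratio = 2.5,
                           first_delay_bonus_rel_ms = 150,
                           error_prob = 0.005,
                           policy_mix = c(collect_all = 0.745,
                                          mvt_threshold = 0,
                                          early_threshold = 0.255),
                           leave_threshold = 1.1,
                           rel_leave_bias = 1.05,
                           next_click_delay_ms = 400,
                           point_goal = 1000,
                           n_available = 15) {
  if (is.null(names(group_ror_mean))) names(group_ror_mean) <- condition_levels()
  group_ror_mean <- group_ror_mean[condition_levels()]
  stopifnot(all(group_ror_mean > 0), error_prob >= 0, error_prob < 1,
            point_goal > 0, itt_shape > 0, rate_decline_ratio >= 1)
  policy_mix <- policy_mix / sum(policy_mix)
  structure(list(
    group_ror_mean = group_ror_mean, between_sd = between_sd,
    interaction_sd = interaction_sd, itt_shape = itt_shape,
    rate_decline_ratio = rate_decline_ratio,
    first_delay_bonus_rel_ms = first_delay_bonus_rel_ms,
    error_prob = error_prob, policy_mix = policy_mix,
    leave_threshold = leave_threshold, rel_leave_bias = rel_leave_bias,
    next_click_delay_ms = next_click_delay_ms, point_goal = point_goal,
    n_available = n_available
  ), class = "forager_params")
}

#' Read generator parameters from a YAML or JSON file
#'
#' The file may contain any subset of [forager_params()] fields (missing
#' fields keep their defaults) and optionally a `patch` block with
#' [patch_config()] fields.
#'
#' @param path Path to a YAML or JSON file.
#' @return A list with elements `params` ([forager_params()]) and `patch`
#'   ([patch_config()]).
#' @export
read_forager_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  patch_fields <- raw$patch %||% list()
  raw$patch <- NULL
  if (!is.null(raw$group_ror_mean)) raw$group_ror_mean <- unlist(raw$group_ror_mean)
  if (!is.null(raw$policy_mix)) raw$policy_mix <- unlist(raw$policy_mix)
  list(params = do.call(forager_params, raw),
       patch = do.call(patch_config, patch_fields))
}
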