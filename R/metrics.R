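#' Trial-level rate of return
#'
#' Number of items collected in a patch divided by the time spent in the
#' patch plus the fixed inter-patch travel time.
#'
#' @param n_collected Targets collected in the trial.
#' @param duration_s Time from trial onset to the terminating event, seconds.
#' @param travel_s Travel time to the next patch, seconds (1 s by design).
#' @return Rate of return in items per second.
#' @export
#' @examples
#' rate_of_return(15, 14) # 1 item/s
rate_of_return <- function(n_collected, duration_s, travel_s = 1) {
  if (any(duration_s < 0)) stop("negative trial duration")
  n_collected / (duration_s + travel_s)
}

#' Instantaneous rates of return
#'
#' One divided by each inter-target time (the time since the previous
#' collection), order preserved.
#'
#' @param itts_s Inter-target times in seconds.
#' @return Numeric vector of rates, items per second.
#' @export
instantaneous_rates <- function(itts_s) {
  if (length(itts_s) == 0) return(numeric(0))
  if (any(itts_s <= 0)) {
    stop("non-positive inter-target time; check the <30 ms screening upstream")
  }
  1 / itts_s
}

#' Proportion of targets left behind
#'
#' @param n_left Targets remaining when the patch was abandoned.
#' @param n_available Targets per patch (15 by design).
#' @return Proportion in `[0, 1]`.
#' @export
proportion_left <- function(n_left, n_available = 15) {
  if (any(n_left < 0) || any(n_left > n_available)) {
    stop("n_left must lie in [0, n_available]")
  }
  n_left / n_available
}

#' Arcsine-square-root transform of a proportion
#'
#' Variance-stabilising transform used before parametric tests on proportion
#' data: `asin(sqrt(p))`.
#'
#' @param p Proportions in `[0, 1]`.
#' @return Transformed values in radians, `[0, pi/2]`.
#' @export
arcsine_transform <- function(p) {
  if (any(p < 0) || any(p > 1)) stop("proportions must lie in [0, 1]")
  asin(sqrt(p))
}

#' Summarise an event log into one record per trial
#'
#' For every (participant, block, trial): the number of targets collected and
#' left behind, the trial duration (onset to the terminating event -- the
#' "Next" click when the patch was left actively, otherwise the final
#' collection that depleted it), the ordered inter-target times, the delay
#' before the first selection, the trial's rate of return, and whether the
#' patch was left actively. Erroneous clicks never anchor inter-target times.
#'
#' @param events Event-log tibble (see [simulate_experiment()]).
#' @param travel_s Travel time added to the rate-of-return denominator.
#' @param n_available Targets per patch.
#' @return Tibble with one row per trial; `itts_s` is a list column.
#' @export
trial_records <- function(events, travel_s = 1, n_available = 15) {
  events |>
    dplyr::group_by(.data$participant, .data$block, .data$trial) |>
    dplyr::summarise(
      condition = .data$condition[1],
      n_collected = sum(.data$clicked_role == "target"),
      nb_ms = .data$t_ms[match("next_button", .data$clicked_role)],
      last_target_ms = suppressWarnings(
        max(c(.data$t_ms[.data$clicked_role == "target"], -Inf))),
      itts_s = list(diff(.data$t_ms[.data$clicked_role == "target"]) / 1000),
      first_delay_s = .data$t_ms[match("target", .data$clicked_role)] / 1000,
      left_actively = any(.data$clicked_role == "next_button"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_left = n_available - .data$n_collected,
      duration_s = dplyr::case_when(
        .data$left_actively ~ .data$nb_ms / 1000,
        is.finite(.data$last_target_ms) ~ .data$last_target_ms / 1000,
        TRUE ~ 0
      ),
      ror = rate_of_return(.data$n_collected, .data$duration_s, travel_s)
    ) |>
    dplyr::select("participant", "block", "trial", "condition",
                  "n_collected", "n_left", "duration_s", "itts_s",
                  "first_delay_s", "ror", "left_actively")
}

#' Delays before the first and second selection
#'
#' Per trial: the time from trial onset to the first collection and from the
#' first to the second collection. Erroneous clicks are ignored as anchors.
#' Trials with fewer than two (one) collections yield `NA` for the second
#' (both) delay(s).
#'
#' @param events Event-log tibble.
#' @return Tibble with one row per trial: participant, block, trial,
#'   condition, `first_delay_s`, `second_delay_s`.
#' @export
selection_delays <- function(events) {
  events |>
    dplyr::group_by(.data$participant, .data$block, .data$trial) |>
    dplyr::group_modify(function(df, key) {
      tt <- df$t_ms[df$clicked_role == "target"]
      tibble::tibble(
        condition = df$condition[1],
        first_delay_s = if (length(tt) >= 1) tt[1] / 1000 else NA_real_,
        second_delay_s = if (length(tt) >= 2) (tt[2] - tt[1]) / 1000 else NA_real_
      )
    }) |>
    dplyr::ungroup()
}

#' Mean instantaneous rate over the last k selections
#'
#' For each condition, the mean instantaneous rate of return at selection
#' positions `-k .. -1` (the last selection is position -1). Trials with at
#' least `k` inter-target times contribute to all positions; shorter trials
#' contribute to the trailing positions only.
#'
#' @param records Trial records from [trial_records()].
#' @param k Number of trailing selections.
#' @return Tibble: condition, position (negative), `mean_rate`, `n`.
#' @export
last_k_rates <- function(records, k = 6) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    itts <- records$itts_s[[i]]
    L <- min(k, length(itts))
    if (L == 0) return(NULL)
    rates <- instantaneous_rates(utils::tail(itts, L))
    tibble::tibble(condition = records$condition[i],
                   position = seq.int(-L, -1L), rate = rates)
  })
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$condition, .data$position) |>
    dplyr::summarise(mean_rate = mean(.data$rate), n = dplyr::n(),
                     .groups = "drop")
}

#' Instantaneous rate at the last selection, per participant and condition
#'
#' @param records Trial records from [trial_records()].
#' @return Tibble: participant, condition, `last_rate` (mean over trials
#'   with at least two collections).
#' @export
last_selection_rates <- function(records) {
  last <- vapply(records$itts_s, function(itts) {
    if (length(itts) == 0) NA_real_ else 1 / itts[length(itts)]
  }, numeric(1))
  tibble::tibble(participant = records$participant,
                 condition = records$condition, rate = last) |>
    dplyr::filter(!is.na(.data$rate)) |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::summarise(last_rate = mean(.data$rate), .groups = "drop")
}

#' Per-participant error rate
#'
#' Proportion of selections that landed on non-collectable items (distractors
#' or non-targets) among all item clicks; "Next"-button clicks are excluded.
#'
#' @param events Event-log tibble.
#' @return Tibble: participant, `n_clicks`, `error_rate`.
#' @export
error_rate <- function(events) {
  events |>
    dplyr::filter(.data$clicked_role != "next_button") |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      n_clicks = dplyr::n(),
      error_rate = mean(.data$clicked_role != "target"),
      .groups = "drop"
    )
}

#' Classify active leavers
#'
#' A participant is an active leaver if, in every condition, at least one
#' trial was terminated by the "Next" button with at least one target still
#' in the patch.
#'
#' @param records Trial records from [trial_records()].
#' @return Tibble: participant, `active_leaver` flag.
#' @export
classify_active_leavers <- function(records) {
  records |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::summarise(
      left_any = any(.data$left_actively & .data$n_left >= 1),
      .groups = "drop_last"
    ) |>
    dplyr::summarise(active_leaver = all(.data$left_any) &&
                       dplyr::n() == length(condition_levels()),
                     .groups = "drop")
}

#' Average rate of return of the environment
#'
#' Grand mean of per-trial rates of return pooled over all conditions (the
#' conditions are randomly intermixed, so a forager leaving a patch cannot
#' expect any particular condition next: a single reference value applies).
#'
#' @param records Trial records from [trial_records()].
#' @return Scalar, items per second.
#' @export
average_ror <- function(records) {
  if (nrow(records) == 0) stop("no trials")
  mean(records$ror)
}

#' Per-participant summaries
#'
#' Condition-wise mean rates of return, totals of targets left behind and
#' available, the participant's error rate and active-leaver flag.
#'
#' @param records Trial records from [trial_records()].
#' @param events The event log the records came from.
#' @return Tibble with one row per participant.
#' @export
participant_summaries <- function(records, events) {
  ror_wide <- records |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::summarise(ror = mean(.data$ror), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "ror",
                       names_prefix = "ror_")
  totals <- records |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(total_left = sum(.data$n_left),
                     total_available = sum(.data$n_left + .data$n_collected),
                     .groups = "drop")
  ror_wide |>
    dplyr::left_join(totals, by = "participant") |>
    dplyr::left_join(error_rate(events)[, c("participant", "error_rate")],
                     by = "participant") |>
    dplyr::left_join(classify_active_leavers(records), by = "participant")
}
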