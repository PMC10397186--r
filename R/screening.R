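#' Participant-level screening
#'
#' Excludes participants whose data indicate disengagement or technical
#' problems: more than 600 clicks on non-collectable items over the whole
#' experiment, or any inter-target time below 30 ms (faster than humanly
#' possible; indicative of technical issues or clicking aids).
#'
#' @param events Event-log tibble.
#' @return List with `events` (kept participants) and `report` (tibble of
#'   excluded participants with reason codes `wrong_clicks_gt_600` /
#'   `itt_lt_30ms`).
#' @export
screen_participants <- function(events) {
  if (nrow(events) == 0) stop("empty dataset")
  wrong <- events |>
    dplyr::filter(.data$clicked_role != "next_button") |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(n_wrong = sum(.data$clicked_role != "target"),
                     .groups = "drop")
  bad_clicks <- wrong$participant[wrong$n_wrong > 600]

  itt_min <- events |>
    dplyr::filter(.data$clicked_role == "target") |>
    dplyr::group_by(.data$participant, .data$block, .data$trial) |>
    dplyr::summarise(min_itt = if (dplyr::n() >= 2) min(diff(.data$t_ms)) else Inf,
                     .groups = "drop") |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(min_itt = min(.data$min_itt), .groups = "drop")
  bad_itt <- itt_min$participant[itt_min$min_itt < 30]

  report <- dplyr::bind_rows(
    tibble::tibble(participant = bad_clicks, reason = "wrong_clicks_gt_600"),
    tibble::tibble(participant = setdiff(bad_itt, bad_clicks),
                   reason = "itt_lt_30ms")
  )
  list(events = dplyr::filter(events,
                              !.data$participant %in% report$participant),
       report = report)
}

#' Trial-level interruption filter
#'
#' Removes trials with long interruptions: more than 10 s from trial onset
#' to the first selection, or more than 20 s between consecutive selections
#' (clicks on items; the "Next" click does not count as a selection).
#'
#' @param events Event-log tibble.
#' @return List with `events` (kept trials) and `report` (tibble of removed
#'   trials with reason codes `start_gap_gt_10s` / `gap_gt_20s`).
#' @export
filter_interruptions <- function(events) {
  flags <- events |>
    dplyr::filter(.data$clicked_role != "next_button") |>
    dplyr::group_by(.data$participant, .data$block, .data$trial) |>
    dplyr::summarise(
      start_gap = min(.data$t_ms),
      max_gap = if (dplyr::n() >= 2) max(diff(sort(.data$t_ms))) else 0,
      .groups = "drop"
    ) |>
    dplyr::mutate(reason = dplyr::case_when(
      .data$start_gap > 10000 ~ "start_gap_gt_10s",
      .data$max_gap > 20000 ~ "gap_gt_20s",
      TRUE ~ NA_character_
    ))
  report <- flags |>
    dplyr::filter(!is.na(.data$reason)) |>
    dplyr::select("participant", "block", "trial", "reason")
  kept <- dplyr::anti_join(events, report,
                           by = c("participant", "block", "trial"))
  list(events = kept, report = report)
}

# Upper-tail probability P(X >= k) of the beta-binomial posterior predictive
# Beta-Binomial(n, a, b), by direct summation.
betabinom_upper_tail <- function(k, n, a, b) {
  j <- k:n
  sum(exp(lchoose(n, j) + lbeta(a + j, b + n - j) - lbeta(a, b)))
}

#' Model-based removal of patch-leaving strategy outliers
#'
#' Trials whose targets-left-behind count is extreme relative to the other
#' trials of the same participant-condition cell are removed: such trials
#' typically reflect accidental "Next" clicks or short-lived strategy
#' changes, not the participant's strategy in that condition. For each trial,
#' the remaining trials of its cell define a beta-binomial posterior
#' predictive (binomial likelihood, Jeffreys Beta(1/2, 1/2) prior); the
#' trial is flagged when the predictive upper-tail probability of leaving at
#' least as many targets falls below `alpha`. Cells with identical counts are
#' never touched.
#'
#' @param records Trial records from [trial_records()].
#' @param alpha Predictive tail probability below which a trial is flagged.
#' @param n_available Targets per patch.
#' @return List with `records` (kept trials) and `report` (removed trials,
#'   reason code `strategy_outlier`).
#' @export
remove_strategy_outliers <- function(records, alpha = 0.005,
                                     n_available = 15) {
  flagged <- records |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::group_modify(function(df, key) {
      k <- df$n_left
      out <- vapply(seq_along(k), function(i) {
        others <- k[-i]
        if (length(others) == 0) return(FALSE)
        a <- 0.5 + sum(others)
        b <- 0.5 + sum(n_available - others)
        betabinom_upper_tail(k[i], n_available, a, b) < alpha
      }, logical(1))
      df$strategy_outlier <- out
      df
    }) |>
    dplyr::ungroup()
  report <- flagged |>
    dplyr::filter(.data$strategy_outlier) |>
    dplyr::mutate(reason = "strategy_outlier") |>
    dplyr::select("participant", "block", "trial", "reason")
  kept <- flagged |>
    dplyr::filter(!.data$strategy_outlier) |>
    dplyr::select(-"strategy_outlier")
  list(records = kept, report = report)
}

#' Full screening pipeline
#'
#' Applies, in order: participant exclusions ([screen_participants()]), the
#' interruption filter ([filter_interruptions()]) and the model-based
#' strategy-outlier removal ([remove_strategy_outliers()]). The fraction of
#' trials removed by the two trial-level filters is computed over the trials
#' of the retained participants.
#'
#' @param events Raw event-log tibble.
#' @param alpha Tail threshold for [remove_strategy_outliers()].
#' @param travel_s,n_available Passed to [trial_records()].
#' @return List of class `screening_result`: `events` (clean), `records`
#'   (clean trial records), `report` (list with `excluded_participants`,
#'   `removed_trials`, `fraction_removed`).
#' @export
screen_data <- function(events, alpha = 0.005, travel_s = 1,
                        n_available = 15) {
  ps <- screen_participants(events)
  n_total <- nrow(dplyr::distinct(ps$events, .data$participant, .data$block,
                                  .data$trial))
  fi <- filter_interruptions(ps$events)
  rec <- trial_records(fi$events, travel_s = travel_s,
                       n_available = n_available)
  so <- remove_strategy_outliers(rec, alpha = alpha,
                                 n_available = n_available)
  removed <- dplyr::bind_rows(fi$report, so$report)
  clean_events <- dplyr::anti_join(
    ps$events, removed, by = c("participant", "block", "trial"))
  structure(list(
    events = clean_events,
    records = so$records,
    report = list(excluded_participants = ps$report,
                  removed_trials = removed,
                  fraction_removed = nrow(removed) / max(n_total, 1))
  ), class = "screening_result")
}

#' Serialise a screening report to JSON
#'
#' @param screening A `screening_result` from [screen_data()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_screening_report <- function(screening, path) {
  jsonlite::write_json(screening$report, path, dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
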