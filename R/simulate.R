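# Depletion profile of expected instantaneous rates: linear decline across
# the 15 selections from `ratio` times the final level down to the final
# level. Returned on a unit scale (last element 1).
rate_profile <- function(n_available, ratio) {
  ratio - (ratio - 1) * (seq_len(n_available) - 1) / (n_available - 1)
}

# Calibrate the scale c of the expected instantaneous-rate curve r_j = c*g_j
# so that the expected trial-level rate of return (collected / (duration +
# travel)) equals `ror`, accounting for the leaving policy's truncation of
# the trial. Expected ITT for selection j is exp(s^2)/r_j (log-normal with
# E[1/ITT] = r_j). A second-order delta correction handles E[1/(D+1)].
calibrate_rate_curve <- function(ror, s, ratio, n_available, thr = NULL,
                                 bonus_s = 0, next_delay_s = 0,
                                 travel_s = 1) {
  g <- rate_profile(n_available, ratio)
  expected_ror <- function(cc) {
    r <- cc * g
    e <- exp(s^2) / r
    m <- leave_selection(r, thr, n_available)
    probs <- if (m >= n_available || m <= 2) 1 else c(0.25, 0.5, 0.25)
    ms <- if (m >= n_available || m <= 2) m else (m - 1):(m + 1)
    vals <- vapply(seq_along(ms), function(i) {
      mi <- min(ms[i], n_available)
      mu_d <- sum(e[seq_len(mi)]) + bonus_s +
        if (mi < n_available) next_delay_s else 0
      var_d <- (exp(s^2) - 1) * sum(e[seq_len(mi)]^2)
      # E[m/(D+travel)] ~ m/(mu+travel) * (1 + var/(mu+travel)^2)
      mi / (mu_d + travel_s) * (1 + var_d / (mu_d + travel_s)^2)
    }, numeric(1))
    sum(probs * vals)
  }
  lo <- 0.05; hi <- 10
  if (expected_ror(lo) > ror || expected_ror(hi) < ror) {
    stop("cannot calibrate rate curve for ror = ", ror)
  }
  for (i in 1:45) { # bisection: robust to the small steps at policy switches
    mid <- (lo + hi) / 2
    if (expected_ror(mid) < ror) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Deterministic leaving point: the patch is abandoned at the selection whose
# expected instantaneous rate is nearest the threshold (the forager leaves
# when it judges its intake to have declined to the threshold; judgments are
# granular at the selection level and unbiased on average). Returns
# n_available when the expected rate never declines to the threshold.
leave_selection <- function(r, thr, n_available) {
  if (is.null(thr) || r[n_available] >= thr) return(n_available)
  if (r[2] < thr) return(2L)
  which.min(abs(r - thr))
}

#' Simulate one foraging trial
#'
#' Draws the click events of a single patch visit. Inter-target times are
#' log-normal with expected instantaneous rates declining linearly across
#' selections (depletion), scaled so that the expected trial rate of return
#' equals `ror_pc` under the given leaving policy. Threshold policies leave
#' the patch at the selection where the expected instantaneous rate reaches
#' the threshold (with symmetric one-selection decision jitter), clicking the
#' "Next" button after a short latency; otherwise the patch depletes and
#' advances automatically. Erroneous clicks on distractors or non-targets are
#' interleaved with probability `error_prob` per click and never remove an
#' item. Uses the current RNG state.
#'
#' @param params A [forager_params()].
#' @param condition One of `condition_levels()`.
#' @param avg_env_ror Average rate of return of the environment (items/s);
#'   used as the leaving threshold by the `mvt_threshold` policy when
#'   `params$leave_threshold` is `NULL`.
#' @param ror_pc This participant's expected rate of return in this
#'   condition; defaults to the group mean.
#' @param policy Leaving policy for this trial; defaults to the highest-
#'   probability entry of `params$policy_mix`.
#' @param participant,block,trial Identifiers stamped on the events.
#' @return A list with `events` (tibble: participant, block, trial,
#'   condition, t_ms, clicked_role, auto_advance) and `record` (one-row
#'   tibble, see [trial_records()]).
#' @export
simulate_trial <- function(params = forager_params(), condition = "rel",
                           avg_env_ror = NULL, ror_pc = NULL, policy = NULL,
                           participant = 1L, block = 1L, trial = 1L) {
  core <- sim_trial_core(params, condition, avg_env_ror, ror_pc, policy)
  events <- tibble::tibble(
    participant = as.integer(participant), block = as.integer(block),
    trial = as.integer(trial), condition = as_condition(condition),
    t_ms = core$t_ms, clicked_role = core$clicked_role,
    auto_advance = core$auto_advance
  )
  list(events = events,
       record = trial_records(events, n_available = params$n_available))
}

# Fast core of one trial: plain vectors, optional calibration cache (an
# environment keyed by the participant-condition cell).
sim_trial_core <- function(params, condition, avg_env_ror = NULL,
                           ror_pc = NULL, policy = NULL, cache = NULL) {
  condition <- match.arg(condition, condition_levels())
  policy <- policy %||%
    names(params$policy_mix)[which.max(params$policy_mix)]
  ror_pc <- ror_pc %||% unname(params$group_ror_mean[condition])
  n_avail <- params$n_available
  s <- params$itt_shape
  bonus_s <- if (condition == "rel") params$first_delay_bonus_rel_ms / 1000 else 0

  thr <- NULL
  if (policy == "mvt_threshold") {
    thr <- params$leave_threshold %||% avg_env_ror
    if (is.null(thr)) stop("mvt_threshold policy needs avg_env_ror or leave_threshold")
  } else if (policy == "early_threshold") {
    thr <- params$leave_threshold
    if (is.null(thr)) stop("early_threshold policy needs leave_threshold")
  }
  if (!is.null(thr) && condition == "rel") thr <- thr * params$rel_leave_bias

  next_delay_mean <- params$next_click_delay_ms / 1000
  key <- paste(condition, ror_pc, thr %||% "none")
  cc <- if (!is.null(cache) && !is.null(cache[[key]])) {
    cache[[key]]
  } else {
    v <- calibrate_rate_curve(ror_pc, s, params$rate_decline_ratio, n_avail,
                              thr, bonus_s, next_delay_mean)
    if (!is.null(cache)) cache[[key]] <- v
    v
  }
  r <- cc * rate_profile(n_avail, params$rate_decline_ratio)

  m <- leave_selection(r, thr, n_avail)
  if (m < n_avail && m > 2) {
    m <- max(2L, min(n_avail, m + sample(c(-1L, 0L, 1L), 1,
                                         prob = c(0.25, 0.5, 0.25))))
  }

  itt <- rlnorm(m, meanlog = s^2 / 2 - log(r[seq_len(m)]), sdlog = s)
  itt[1] <- itt[1] + bonus_s
  t_target <- cumsum(itt) * 1000

  # erroneous clicks: geometric number before each collection
  n_err <- if (params$error_prob > 0) {
    rgeom(m, 1 - params$error_prob)
  } else {
    integer(m)
  }
  err_t <- err_role <- NULL
  if (sum(n_err) > 0) {
    lower <- c(0, t_target[-m])
    err_t <- unlist(lapply(which(n_err > 0), function(j) {
      sort(runif(n_err[j], lower[j], t_target[j]))
    }))
    err_role <- sample(c("distractor", "nontarget"), length(err_t),
                       replace = TRUE, prob = c(15, 60))
  }

  t_all <- c(t_target, err_t)
  role_all <- c(rep("target", m), err_role)
  ord <- order(t_all)
  t_all <- t_all[ord]; role_all <- role_all[ord]

  auto <- rep(FALSE, length(t_all))
  if (m == n_avail) {
    auto[length(auto)] <- TRUE # depletion ends the patch
  } else {
    nd <- rlnorm(1, log(next_delay_mean) - 0.3^2 / 2, 0.3) * 1000
    t_all <- c(t_all, t_all[length(t_all)] + nd)
    role_all <- c(role_all, "next_button")
    auto <- c(auto, FALSE)
  }
  list(t_ms = t_all, clicked_role = role_all, auto_advance = auto,
       n_collected = m)
}

#' Simulate a full foraging experiment
#'
#' Generates the event log of a cohort. Each participant works through blocks
#' of 12 trials (three per condition, shuffled within block), with the target
#' shape switching every two blocks, until the cumulative number of collected
#' targets reaches `params$point_goal` (checked after every patch, so the
#' final block may be incomplete). Participant-level condition means are the
#' group means plus a shared speed offset (SD `between_sd`) plus a small
#' condition-specific deviation (SD `interaction_sd`). Each participant is
#' assigned one leaving policy from `params$policy_mix`. Reproducible: one
#' root seed spawns an independent sub-stream per participant.
#'
#' @param params A [forager_params()].
#' @param n_participants Cohort size.
#' @param seed Integer root seed.
#' @return Event-log tibble (one row per click event).
#' @export
#' @examples
#' ev <- simulate_experiment(forager_params(point_goal = 60), 2, seed = 1)
#' head(ev)
simulate_experiment <- function(params = forager_params(), n_participants = 47,
                                seed = 1) {
  stopifnot(n_participants >= 1)
  set.seed(seed)
  p_seeds <- sample.int(.Machine$integer.max - 1, n_participants)
  policies <- sample(names(params$policy_mix), n_participants, replace = TRUE,
                     prob = params$policy_mix)
  colours <- rep_len(c("olive", "aqua"), n_participants)
  avg_env <- mean(params$group_ror_mean)
  conds <- condition_levels()

  logs <- lapply(seq_len(n_participants), function(p) {
    set.seed(p_seeds[p])
    ror_pc <- params$group_ror_mean + rnorm(1, 0, params$between_sd) +
      rnorm(4, 0, params$interaction_sd)
    ror_pc <- pmax(ror_pc, 0.2)
    cache <- new.env(parent = emptyenv())
    points <- 0
    block <- 0L
    rows <- list()
    while (points < params$point_goal && block < 60L) {
      block <- block + 1L
      block_conds <- sample(rep(conds, 3))
      for (tr in seq_along(block_conds)) {
        cond <- block_conds[tr]
        core <- sim_trial_core(params, cond, avg_env_ror = avg_env,
                               ror_pc = unname(ror_pc[cond]),
                               policy = policies[p], cache = cache)
        n_ev <- length(core$t_ms)
        rows[[length(rows) + 1L]] <- list(
          participant = rep(p, n_ev), block = rep(block, n_ev),
          trial = rep(tr, n_ev), condition = rep(cond, n_ev),
          t_ms = core$t_ms, clicked_role = core$clicked_role,
          auto_advance = core$auto_advance
        )
        points <- points + core$n_collected
        if (points >= params$point_goal) break
      }
    }
    rows
  })
  flat <- unlist(logs, recursive = FALSE)
  tibble::tibble(
    participant = as.integer(unlist(lapply(flat, `[[`, "participant"))),
    block = as.integer(unlist(lapply(flat, `[[`, "block"))),
    trial = as.integer(unlist(lapply(flat, `[[`, "trial"))),
    condition = as_condition(unlist(lapply(flat, `[[`, "condition"))),
    t_ms = unlist(lapply(flat, `[[`, "t_ms")),
    clicked_role = unlist(lapply(flat, `[[`, "clicked_role")),
    auto_advance = unlist(lapply(flat, `[[`, "auto_advance"))
  )
}

#' Write / read an event log as CSV
#'
#' Delimited-text interchange format for event logs: columns `participant`,
#' `block`, `trial`, `condition`, `t_ms`, `clicked_role`, `auto_advance`,
#' one header row, UTF-8.
#'
#' @param events Event-log tibble.
#' @param path File path.
#' @return `read_event_log()` returns the event-log tibble.
#' @export
write_event_log <- function(events, path) {
  write.csv(events, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_event_log
#' @param mapping Optional named character vector renaming source columns to
#'   the package schema, e.g. `c(participant = "subject_id", t_ms = "time")`
#'   (names: schema columns; values: columns in the file). Useful when
#'   ingesting externally deposited logs.
#' @export
read_event_log <- function(path, mapping = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!is.null(mapping)) {
    for (target in names(mapping)) {
      src <- mapping[[target]]
      if (!src %in% names(df)) {
        stop("mapping source column not in file: ", src)
      }
      names(df)[names(df) == src] <- target
    }
  }
  validate_event_log(df)
  tibble::as_tibble(df) |>
    dplyr::mutate(condition = as_condition(.data$condition),
                  auto_advance = as.logical(.data$auto_advance))
}

# Schema check shared by read_event_log() and the ingest pipeline mode.
validate_event_log <- function(df) {
  needed <- c("participant", "block", "trial", "condition", "t_ms",
              "clicked_role", "auto_advance")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("event log is missing column(s): ", paste(missing, collapse = ", "))
  }
  invisible(df)
}
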