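# Build a minimal event-log tibble from per-trial click specifications.
# trials: list of lists with fields participant, block, trial, condition,
# t_ms (vector), roles (vector), and optionally auto (logical vector).
make_events <- function(trials) {
  dplyr::bind_rows(lapply(trials, function(tr) {
    n <- length(tr$t_ms)
    auto <- tr$auto %||% rep(FALSE, n)
    tibble::tibble(
      participant = as.integer(tr$participant %||% 1L),
      block = as.integer(tr$block %||% 1L),
      trial = as.integer(tr$trial %||% 1L),
      condition = factor(tr$condition %||% "rel",
                         levels = condition_levels()),
      t_ms = tr$t_ms, clicked_role = tr$roles, auto_advance = auto
    )
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One clean depleting trial: targets at 1 s intervals, auto-advance.
clean_trial <- function(participant = 1, block = 1, trial = 1,
                        condition = "rel", n_targets = 15, itt_ms = 1000) {
  list(participant = participant, block = block, trial = trial,
       condition = condition,
       t_ms = seq_len(n_targets) * itt_ms,
       roles = rep("target", n_targets),
       auto = c(rep(FALSE, n_targets - 1), TRUE))
}

# A tiny but complete 4-condition cohort of clean depleting trials.
clean_cohort <- function(n_participants = 3, trials_per_cond = 2) {
  specs <- list()
  for (p in seq_len(n_participants)) {
    i <- 0
    for (cond in condition_levels()) {
      for (k in seq_len(trials_per_cond)) {
        i <- i + 1
        specs[[length(specs) + 1]] <-
          clean_trial(p, block = 1 + (i - 1) %/% 12, trial = i, cond)
      }
    }
  }
  make_events(specs)
}
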