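#' Pipeline configuration
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"ingest"`
#'   (read an event-log CSV).
#' @param params [forager_params()] for simulate mode.
#' @param n_participants Cohort size for simulate mode.
#' @param input Event-log CSV path for ingest mode.
#' @param alpha Strategy-outlier tail threshold, see
#'   [remove_strategy_outliers()].
#' @param profile Sampler profile, see [sampler_profile()].
#' @param out_dir Output directory (`NULL` for no files).
#' @param seed Root seed for simulation and samplers.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "ingest"),
                            params = forager_params(), n_participants = 47,
                            input = NULL, alpha = 0.005, profile = "test",
                            out_dir = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "ingest" && is.null(input)) stop("ingest mode needs an input path")
  structure(list(mode = mode, params = params,
                 n_participants = n_participants, input = input,
                 alpha = alpha, profile = profile, out_dir = out_dir,
                 seed = seed),
            class = "pipeline_config")
}

stage_msg <- function(stage, t0) {
  message(sprintf("[%s] done in %.1f s", stage,
                  as.numeric(proc.time()[3] - t0)))
}

#' Run the full analysis pipeline
#'
#' Simulates (or ingests) an event log, screens it, computes the foraging
#' statistics, fits the free and order-constrained hierarchical models for
#' the rate of return and the proportion of targets left behind, compares
#' the constrained variants with PSIS-LOO, and runs the auxiliary analyses
#' (posterior contrasts, first/second-selection delay tests, the
#' patch-leaving test against the average rate of return, and the
#' repeated-measures correlation for active leavers). Deterministic given
#' `seed` and profile, up to Monte-Carlo error.
#'
#' @param config A [pipeline_config()].
#' @return List of class `forage_bundle` with elements `events`, `screening`,
#'   `records`, `summaries`, `fits`, `comparisons`, `extras`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- proc.time()[3]

  t0 <- proc.time()[3]
  events <- if (config$mode == "simulate") {
    simulate_experiment(config$params, config$n_participants,
                        seed = config$seed)
  } else {
    read_event_log(config$input)
  }
  stage_msg("data", t0)

  t0 <- proc.time()[3]
  screening <- screen_data(events, alpha = config$alpha)
  records <- screening$records
  stage_msg("screening", t0)

  t0 <- proc.time()[3]
  summaries <- list(
    participants = participant_summaries(records, screening$events),
    delays = selection_delays(screening$events),
    last6 = last_k_rates(records, k = 6),
    average_ror = average_ror(records)
  )
  stage_msg("metrics", t0)

  t0 <- proc.time()[3]
  accounts <- c("free", "relational", "feature_specific")
  ror_fits <- lapply(setNames(accounts, accounts), function(a) {
    fit_ror(records, account = a, profile = config$profile,
            seed = config$seed)
  })
  ptlb_fits <- lapply(setNames(accounts, accounts), function(a) {
    fit_ptlb(records, account = a, profile = config$profile,
             seed = config$seed)
  })
  stage_msg("fit", t0)

  t0 <- proc.time()[3]
  comparisons <- list(
    ror = compare_models(list(relational = ror_fits$relational,
                              feature_specific = ror_fits$feature_specific)),
    ptlb = compare_models(list(relational = ptlb_fits$relational,
                               feature_specific = ptlb_fits$feature_specific))
  )
  stage_msg("compare", t0)

  t0 <- proc.time()[3]
  pairs <- list(c("rel", "sim"), c("nont", "opp"), c("opp", "sim"),
                c("rel", "nont"), c("rel", "opp"), c("sim", "nont"))
  contrasts <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(pairs, function(pr) {
      posterior_contrast(ror_fits$free, pr[1], pr[2])
    })) |> dplyr::mutate(outcome = "ror"),
    dplyr::bind_rows(lapply(pairs, function(pr) {
      posterior_contrast(ptlb_fits$free, pr[1], pr[2])
    })) |> dplyr::mutate(outcome = "ptlb")
  )
  delay_wide <- summaries$delays |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::summarise(first = mean(.data$first_delay_s, na.rm = TRUE),
                     second = mean(.data$second_delay_s, na.rm = TRUE),
                     .groups = "drop")
  fd <- tidyr::pivot_wider(delay_wide[, c("participant", "condition", "first")],
                           names_from = "condition", values_from = "first")
  sd2 <- tidyr::pivot_wider(delay_wide[, c("participant", "condition", "second")],
                            names_from = "condition", values_from = "second")
  delay_tests <- list(
    first_rel_gt_sim = paired_bf(fd$rel, fd$sim, direction = "x_gt_y"),
    second_rel_gt_sim = paired_bf(sd2$rel, sd2$sim, direction = "x_gt_y")
  )
  mvt <- mvt_test(records)
  extras <- list(contrasts = contrasts, delay_tests = delay_tests,
                 mvt = mvt,
                 rmcorr = tryCatch(active_leaver_rmcorr(records),
                                   error = function(e) NULL))
  stage_msg("extras", t0)

  manifest <- list(
    mode = config$mode, seed = config$seed, profile = config$profile,
    n_participants_in = length(unique(events$participant)),
    n_participants_kept = length(unique(screening$events$participant)),
    n_trials_kept = nrow(records),
    fraction_removed = screening$report$fraction_removed,
    elapsed_s = as.numeric(proc.time()[3] - t_start),
    r_version = as.character(getRversion())
  )
  bundle <- structure(list(events = screening$events, screening = screening,
                           records = records, summaries = summaries,
                           fits = list(ror = ror_fits, ptlb = ptlb_fits),
                           comparisons = comparisons, extras = extras,
                           manifest = manifest),
                      class = "forage_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' Repeated-measures correlation of efficiency and patch leaving
#'
#' For active leavers only: correlates the per-participant-condition mean
#' rate of return with the arcsine-transformed proportion of targets left
#' behind, removing participant intercepts.
#'
#' @param records Trial records.
#' @return As [rm_corr()].
#' @export
active_leaver_rmcorr <- function(records) {
  flags <- classify_active_leavers(records)
  keep <- flags$participant[flags$active_leaver]
  if (length(keep) < 2) stop("fewer than 2 active leavers")
  cell <- records |>
    dplyr::filter(.data$participant %in% keep) |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::summarise(
      ror = mean(.data$ror),
      ptlb = sum(.data$n_left) / sum(.data$n_left + .data$n_collected),
      .groups = "drop"
    )
  rm_corr(arcsine_transform(cell$ptlb), cell$ror, cell$participant)
}

# Persist the bundle's tabular artifacts and a provenance manifest.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_event_log(bundle$events, file.path(out_dir, "events_clean.csv"))
  rec <- bundle$records
  rec$itts_s <- vapply(rec$itts_s, paste, character(1), collapse = ";")
  write.csv(rec, file.path(out_dir, "trial_records.csv"), row.names = FALSE)
  write.csv(bundle$summaries$participants,
            file.path(out_dir, "participants.csv"), row.names = FALSE)
  write.csv(as.data.frame(bundle$comparisons$ror),
            file.path(out_dir, "loo_ror.csv"), row.names = FALSE)
  write.csv(as.data.frame(bundle$comparisons$ptlb),
            file.path(out_dir, "loo_ptlb.csv"), row.names = FALSE)
  write.csv(bundle$extras$contrasts, file.path(out_dir, "contrasts.csv"),
            row.names = FALSE)
  write.csv(bundle$extras$mvt, file.path(out_dir, "mvt_test.csv"),
            row.names = FALSE)
  write_screening_report(bundle$screening,
                         file.path(out_dir, "screening_report.json"))
  for (outcome in names(bundle$fits)) {
    f <- bundle$fits[[outcome]]$free
    gp <- group_param_draws(f)
    write.csv(as.data.frame(gp),
              file.path(out_dir, paste0("draws_group_", outcome, ".csv")),
              row.names = FALSE)
  }
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Render a report from a pipeline bundle
#'
#' Writes a markdown report mirroring the analysis structure (descriptives,
#' group-level posterior summaries with HDIs, the model-comparison tables,
#' the first/second-selection tests and the patch-leaving analysis) plus
#' descriptive and posterior figures.
#'
#' @param bundle A `forage_bundle` from [run_pipeline()].
#' @param out_dir Directory for the report and figures.
#' @return Path to the markdown report, invisibly.
#' @export
make_report <- function(bundle, out_dir) {
  if (!inherits(bundle, "forage_bundle") || is.null(bundle$records) ||
      nrow(bundle$records) == 0) {
    stop("empty or incomplete bundle")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cond_ror <- bundle$records |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::summarise(ror = mean(.data$ror), .groups = "drop")
  p1 <- ggplot2::ggplot(cond_ror,
                        ggplot2::aes(x = .data$condition, y = .data$ror,
                                     group = .data$participant)) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "line", linewidth = 1.2) +
    ggplot2::labs(x = "Distractor condition", y = "Rate of return (items/s)")
  ggplot2::ggsave(file.path(out_dir, "descriptive_ror.png"), p1,
                  width = 5, height = 4, dpi = 120)

  gp <- group_param_draws(bundle$fits$ror$free)
  dens <- tidyr::pivot_longer(tibble::as_tibble(gp), dplyr::everything(),
                              names_to = "condition", values_to = "value")
  dens$condition <- factor(dens$condition, levels = condition_levels())
  p2 <- ggplot2::ggplot(dens, ggplot2::aes(x = .data$value,
                                           fill = .data$condition)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "Group-level rate of return (items/s)", y = "Density")
  ggplot2::ggsave(file.path(out_dir, "posterior_ror.png"), p2,
                  width = 5, height = 4, dpi = 120)

  last6 <- bundle$summaries$last6
  p3 <- ggplot2::ggplot(last6, ggplot2::aes(x = .data$position,
                                            y = .data$mean_rate,
                                            colour = .data$condition)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = bundle$summaries$average_ror,
                        linetype = "dashed") +
    ggplot2::labs(x = "Selection (relative to last)",
                  y = "Instantaneous rate (items/s)")
  ggplot2::ggsave(file.path(out_dir, "patch_leaving.png"), p3,
                  width = 5, height = 4, dpi = 120)

  fmt_sum <- function(fit) {
    gp <- group_param_draws(fit)
    paste(vapply(colnames(gp), function(cc) {
      h <- hdi(gp[, cc])
      sprintf("- %s: %.3f [%.3f, %.3f]", cc, posterior_mode(gp[, cc]),
              h[1], h[2])
    }, character(1)), collapse = "\n")
  }
  fmt_tab <- function(tab) {
    paste(utils::capture.output(print(tab)), collapse = "\n")
  }
  dt <- bundle$extras$delay_tests
  rmc <- bundle$extras$rmcorr
  report <- c(
    "# Visual foraging analysis report", "",
    sprintf("Participants kept: %d; trials kept: %d; fraction of trials removed: %.2f%%",
            bundle$manifest$n_participants_kept,
            bundle$manifest$n_trials_kept,
            100 * bundle$manifest$fraction_removed), "",
    "## Rate of return (group-level posterior mode [95% HDI])", "",
    fmt_sum(bundle$fits$ror$free), "",
    "## Targets left behind (group-level posterior mode [95% HDI])", "",
    fmt_sum(bundle$fits$ptlb$free), "",
    "## Model comparison: rate of return", "",
    "```", fmt_tab(bundle$comparisons$ror), "```", "",
    "## Model comparison: targets left behind", "",
    "```", fmt_tab(bundle$comparisons$ptlb), "```", "",
    "## Posterior contrasts (free models)", "",
    "```", fmt_tab(bundle$extras$contrasts), "```", "",
    "## First vs second selection (rel > sim)", "",
    sprintf("- first selection: BF_+0 = %.2f", dt$first_rel_gt_sim$bf_10),
    sprintf("- second selection: BF_+0 = %.2f (BF_0+ = %.2f)",
            dt$second_rel_gt_sim$bf_10, dt$second_rel_gt_sim$bf_01), "",
    "## Patch leaving vs average rate of return", "",
    "```", fmt_tab(bundle$extras$mvt), "```", "",
    if (!is.null(rmc)) {
      sprintf("## Active leavers\n\nRepeated-measures correlation of arcsine pTLB and RoR: r(%d) = %.2f, p = %.3g",
              rmc$df, rmc$r, rmc$p)
    } else {
      "## Active leavers\n\nToo few active leavers for the repeated-measures correlation."
    }
  )
  path <- file.path(out_dir, "report.md")
  writeLines(report, path)
  invisible(path)
}
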