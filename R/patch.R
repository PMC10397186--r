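#' Patch configuration
#'
#' Geometry and content of one foraging patch: 90 moving stimuli (15 targets,
#' 15 distractors, 60 non-targets) whose start positions occupy distinct cells
#' of a centred 11 x 20 grid with 90 px spacing and a uniform positional
#' jitter of +/- 40 px, on a 1920 x 1080 display. Stimuli move at 30 px/s;
#' moving to the next patch takes a fixed 1 s travel time.
#'
#' @param n_targets,n_distractors,n_nontargets Item counts per role.
#' @param grid_rows,grid_cols Grid dimensions.
#' @param spacing_px Grid cell spacing in pixels.
#' @param jitter_px Uniform positional jitter half-range in pixels.
#' @param speed_px_s Stimulus speed in pixels per second.
#' @param display_px Display width and height in pixels.
#' @param travel_time_ms Inter-patch travel time in milliseconds.
#' @return A list of class `patch_config`.
#' @export
patch_config <- function(n_targets = 15, n_distractors = 15, n_nontargets = 60,
                         grid_rows = 11, grid_cols = 20, spacing_px = 90,
                         jitter_px = 40, speed_px_s = 30,
                         display_px = c(1920, 1080), travel_time_ms = 1000) {
  cfg <- list(
    n_targets = n_targets, n_distractors = n_distractors,
    n_nontargets = n_nontargets, grid_rows = grid_rows, grid_cols = grid_cols,
    spacing_px = spacing_px, jitter_px = jitter_px, speed_px_s = speed_px_s,
    display_px = display_px, travel_time_ms = travel_time_ms
  )
  n_items <- n_targets + n_distractors + n_nontargets
  if (any(c(n_targets, n_distractors, n_nontargets) <= 0)) {
    stop("all role counts must be positive")
  }
  if (grid_rows * grid_cols < n_items) {
    stop("grid too small: ", grid_rows, " x ", grid_cols,
         " cells cannot hold ", n_items, " items")
  }
  structure(cfg, class = "patch_config")
}

# CIELAB coordinates of the four stimulus colours (equidistant neighbours on
# the green-to-blue range of the colour wheel) and the background/UI greys.
.LAB <- list(
  green = c(41.32, -43.77, 44.71),
  olive = c(50.68, -40.51, 11.06),
  aqua  = c(49.55, -23.44, -23.50),
  blue  = c(50.19, 15.67, -77.96),
  background = c(89.53, 0, 0),
  next_label = c(42.37, 0, 0)
)

#' Condition colour table
#'
#' Maps each distractor condition and stimulus role to a named colour and its
#' CIELAB triple, given the participant's target colour. Non-targets always
#' have the non-target colour (olive for aqua targets and vice versa), which
#' dominates the display and establishes the colour context. The distractor
#' colour defines the condition: in `rel` it lies one colour step beyond the
#' target (away from the non-targets), in `sim` it equals the target colour,
#' in `nont` it equals the non-target colour, and in `opp` it lies one step
#' beyond the non-targets, opposite to the target direction.
#'
#' @param target_colour `"aqua"` or `"olive"`.
#' @return A tibble with columns `condition`, `role`, `colour`, `L`, `a`, `b`.
#' @export
colour_table <- function(target_colour = c("olive", "aqua")) {
  target_colour <- match.arg(target_colour)
  other <- if (target_colour == "olive") "aqua" else "olive"
  beyond_target <- if (target_colour == "olive") "green" else "blue"
  beyond_nontgt <- if (target_colour == "olive") "blue" else "green"
  distractor <- c(rel = beyond_target, sim = target_colour,
                  nont = other, opp = beyond_nontgt)
  rows <- do.call(rbind, lapply(condition_levels(), function(cond) {
    cols <- c(target = target_colour, nontarget = other,
              distractor = unname(distractor[cond]))
    data.frame(condition = cond, role = names(cols), colour = unname(cols),
               stringsAsFactors = FALSE)
  }))
  lab <- t(vapply(rows$colour, function(cl) .LAB[[cl]], numeric(3)))
  tibble::as_tibble(cbind(rows, data.frame(L = lab[, 1], a = lab[, 2],
                                           b = lab[, 3])))
}

#' Generate the stimuli of one foraging patch
#'
#' Places 15 targets, 15 distractors and 60 non-targets on distinct cells of
#' the centred grid, applies uniform positional jitter, assigns random motion
#' headings and the condition's colours. Targets and non-targets share a
#' shape; distractors have the other shape. Uses the current RNG state, so
#' seed with [set.seed()] for reproducible layouts.
#'
#' @param config A [patch_config()].
#' @param condition One of `condition_levels()`.
#' @param target_colour `"aqua"` or `"olive"`.
#' @param target_shape `"square"` or `"disk"` (alternates every two blocks in
#'   the experiment's design).
#' @return A tibble with one row per stimulus: `role`, `x`, `y`, `heading`
#'   (radians), `shape`, `colour`, `L`, `a`, `b`.
#' @export
#' @examples
#' set.seed(1)
#' patch <- generate_patch(patch_config(), "opp")
#' table(patch$role)
generate_patch <- function(config = patch_config(),
                           condition = condition_levels(),
                           target_colour = c("olive", "aqua"),
                           target_shape = c("square", "disk")) {
  if (!inherits(config, "patch_config")) config <- do.call(patch_config, config)
  condition <- match.arg(condition, condition_levels())
  target_colour <- match.arg(target_colour)
  target_shape <- match.arg(target_shape)
  other_shape <- if (target_shape == "square") "disk" else "square"

  n_items <- config$n_targets + config$n_distractors + config$n_nontargets
  roles <- c(rep("target", config$n_targets),
             rep("distractor", config$n_distractors),
             rep("nontarget", config$n_nontargets))

  cells <- sample.int(config$grid_rows * config$grid_cols, n_items)
  row <- (cells - 1) %/% config$grid_cols + 1
  col <- (cells - 1) %% config$grid_cols + 1
  cx <- config$display_px[1] / 2
  cy <- config$display_px[2] / 2
  x <- cx + (col - (config$grid_cols + 1) / 2) * config$spacing_px +
    runif(n_items, -config$jitter_px, config$jitter_px)
  y <- cy + (row - (config$grid_rows + 1) / 2) * config$spacing_px +
    runif(n_items, -config$jitter_px, config$jitter_px)

  ctab <- colour_table(target_colour)
  ctab <- ctab[ctab$condition == condition, ]
  idx <- match(roles, ctab$role)
  tibble::tibble(
    role = roles, x = x, y = y,
    heading = runif(n_items, 0, 2 * pi),
    shape = ifelse(roles == "distractor", other_shape, target_shape),
    colour = ctab$colour[idx],
    L = ctab$L[idx], a = ctab$a[idx], b = ctab$b[idx]
  )
}
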