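#' Highest-density interval of posterior draws
#'
#' The narrowest contiguous interval containing the target probability mass,
#' found by sliding a fixed-mass window over the sorted draws.
#'
#' @param draws Numeric vector of posterior draws (at least 100).
#' @param mass Probability mass of the interval.
#' @return Named numeric `c(lower, upper)`.
#' @export
#' @examples
#' set.seed(1)
#' hdi(rnorm(10000)) # about (-1.96, 1.96)
hdi <- function(draws, mass = 0.95) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 100) stop("need at least 100 draws for an HDI")
  stopifnot(mass > 0, mass < 1)
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(mass * n)
  widths <- x[m:n] - x[seq_len(n - m + 1)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m - 1])
}

#' Posterior mode via kernel density
#'
#' Point estimate reported for posterior distributions: the maximiser of a
#' Gaussian kernel density (Silverman's rule-of-thumb bandwidth) over the
#' pooled draws.
#'
#' @param draws Numeric vector of draws.
#' @return Scalar mode estimate.
#' @export
posterior_mode <- function(draws) {
  draws <- draws[is.finite(draws)]
  if (length(draws) == 0) stop("no finite draws")
  if (stats::sd(draws) == 0) return(draws[1])
  d <- density(draws, bw = "nrd0", n = 2048)
  d$x[which.max(d$y)]
}

#' Summarise posterior draws
#'
#' @param draws Numeric vector of draws.
#' @param mass HDI mass.
#' @return One-row tibble: `mode`, `hdi_low`, `hdi_high`, `n_draws`.
#' @export
posterior_summary <- function(draws, mass = 0.95) {
  h <- hdi(draws, mass)
  tibble::tibble(mode = posterior_mode(draws), hdi_low = h[[1]],
                 hdi_high = h[[2]], n_draws = length(draws))
}

#' Posterior contrast between two conditions
#'
#' Draw-wise difference of the group-level condition parameters of a fit
#' (`condition_a` minus `condition_b`), summarised by its posterior mode and
#' 95% HDI, with a flag for whether the HDI excludes zero.
#'
#' @param fit An `hbm_fit`.
#' @param condition_a,condition_b Condition labels.
#' @param mass HDI mass.
#' @return One-row tibble: contrast label, mode, HDI bounds,
#'   `excludes_zero`.
#' @export
posterior_contrast <- function(fit, condition_a, condition_b, mass = 0.95) {
  gp <- group_param_draws(fit)
  for (cc in c(condition_a, condition_b)) {
    if (!cc %in% colnames(gp)) stop("unknown condition: ", cc)
  }
  d <- gp[, condition_a] - gp[, condition_b]
  if (sd(d) == 0) {
    return(tibble::tibble(
      contrast = paste0(condition_a, " - ", condition_b),
      mode = d[1], hdi_low = d[1], hdi_high = d[1],
      excludes_zero = d[1] != 0, n_draws = length(d)
    ))
  }
  s <- posterior_summary(d, mass)
  tibble::tibble(contrast = paste0(condition_a, " - ", condition_b),
                 mode = s$mode, hdi_low = s$hdi_low, hdi_high = s$hdi_high,
                 excludes_zero = s$hdi_low > 0 | s$hdi_high < 0,
                 n_draws = s$n_draws)
}

# JZS marginal likelihood ratio for a one-sample t statistic: Cauchy(0, r)
# prior on the standardised effect, numerator integrated over the prior via
# the non-central t density of the observed statistic.
jzs_bf <- function(t, n, rscale, one_sided = FALSE) {
  nu <- n - 1
  dens <- function(delta) {
    # dt() warns that the non-central beta tail may lose a few ulps at
    # extreme non-centrality; immaterial at the quadrature tolerance used.
    vapply(delta, function(dl) {
      suppressWarnings(dt(t, df = nu, ncp = dl * sqrt(n)))
    }, numeric(1)) * dcauchy(delta, 0, rscale)
  }
  m0 <- dt(t, df = nu)
  if (one_sided) {
    m1 <- integrate(dens, 0, Inf, rel.tol = 1e-9)$value * 2
  } else {
    m1 <- integrate(dens, -Inf, Inf, rel.tol = 1e-9)$value
  }
  m1 / m0
}

#' Paired (or one-sample) JZS Bayes-factor t test
#'
#' Default Bayes factor for the mean of the paired differences, with a
#' Cauchy prior of scale `rscale` (0.707 by default) on the standardised
#' effect size. Directed tests (`"x_gt_y"`) truncate the prior to positive
#' effects. When all differences are exactly zero the data are perfectly
#' null and the test reports the corresponding (null-favouring) Bayes
#' factor; zero-variance differences with a nonzero mean are an error.
#'
#' @param x,y Paired numeric vectors (`y` may be a scalar reference value,
#'   making this a one-sample test of `x - y`).
#' @param direction `"two_sided"` or `"x_gt_y"`.
#' @param rscale Cauchy prior scale.
#' @return List: `bf_10` (alternative over null; the directed BF for
#'   directed tests), `bf_01`, `t`, `df`, `n`, `mean_diff`, `direction`.
#' @export
paired_bf <- function(x, y = 0, direction = c("two_sided", "x_gt_y"),
                      rscale = 1 / sqrt(2)) {
  direction <- match.arg(direction)
  if (length(y) == 1) y <- rep(y, length(x))
  stopifnot(length(x) == length(y))
  keep <- complete.cases(x, y)
  d <- (x - y)[keep]
  n <- length(d)
  if (n < 3) stop("need at least 3 complete pairs")
  if (sd(d) == 0) {
    if (all(d == 0)) {
      t <- 0
    } else {
      stop("zero-variance differences with nonzero mean")
    }
  } else {
    t <- mean(d) / (sd(d) / sqrt(n))
  }
  bf <- jzs_bf(t, n, rscale, one_sided = direction == "x_gt_y")
  list(bf_10 = bf, bf_01 = 1 / bf, t = t, df = n - 1, n = n,
       mean_diff = mean(d), direction = direction)
}

#' Repeated-measures correlation
#'
#' Common within-participant association between two variables after
#' removing participant-level intercepts (the ANCOVA formulation): a model
#' with participant factor plus a common slope is fitted, and the
#' correlation is the signed square root of the slope's share of the
#' non-participant variance. Degrees of freedom are
#' `n_obs - n_participants - 1`.
#'
#' @param x,y Numeric vectors of paired observations.
#' @param participant Participant labels (repeated measures).
#' @return List: `r`, `df`, `p`.
#' @export
rm_corr <- function(x, y, participant) {
  stopifnot(length(x) == length(y), length(x) == length(participant))
  keep <- complete.cases(x, y, participant)
  x <- x[keep]; y <- y[keep]; p <- factor(participant[keep])
  if (nlevels(p) < 2 || length(x) < nlevels(p) + 2) {
    stop("need >= 2 participants with repeated measures")
  }
  fit <- lm(y ~ p + x)
  if (any(is.na(coef(fit)))) stop("singular design in rm_corr")
  a <- anova(fit)
  ss_x <- a["x", "Sum Sq"]
  ss_e <- a["Residuals", "Sum Sq"]
  dof <- a["Residuals", "Df"]
  r <- sign(coef(fit)[["x"]]) * sqrt(ss_x / (ss_x + ss_e))
  f <- a["x", "F value"]
  list(r = unname(r), df = dof,
       p = stats::pf(f, 1, dof, lower.tail = FALSE))
}

#' Patch-leaving test against the average rate of return
#'
#' Tests, per condition, whether the instantaneous rate of return at the
#' last selection in a patch matches the environment's single average rate
#' of return (the marginal value theorem's leaving rule). Participant-level
#' mean last-selection rates are compared with the grand average by a
#' two-sided JZS paired test; conditions are labelled `at_average` when the
#' Bayes factor does not exceed `bf_threshold`, otherwise `above_average` /
#' `below_average` by the sign of the mean difference.
#'
#' @param records Trial records from [trial_records()].
#' @param bf_threshold Evidence threshold for declaring a deviation.
#' @param rscale Cauchy prior scale of the test.
#' @return Tibble: condition, `n`, `mean_last_rate`, `avg_ror`, `bf_10`,
#'   `bf_01`, `label`.
#' @export
mvt_test <- function(records, bf_threshold = 3, rscale = 1 / sqrt(2)) {
  avg <- average_ror(records)
  rates <- last_selection_rates(records)
  conds <- intersect(condition_levels(), unique(as.character(rates$condition)))
  rows <- lapply(conds, function(cc) {
    v <- rates$last_rate[rates$condition == cc]
    bf <- paired_bf(v, avg, rscale = rscale)
    tibble::tibble(
      condition = cc, n = length(v), mean_last_rate = mean(v),
      avg_ror = avg, bf_10 = bf$bf_10, bf_01 = bf$bf_01,
      label = if (bf$bf_10 <= bf_threshold) "at_average"
              else if (bf$mean_diff > 0) "above_average" else "below_average"
    )
  })
  dplyr::bind_rows(rows)
}
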