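# Model code ---------------------------------------------------------------
#
# Rate of return: Normal likelihood at the trial level. Participant-condition
# means are hierarchically centred on group condition mean + participant
# speed offset, with a (typically small) participant-by-condition deviation:
#   y_t     ~ Normal(theta[p, c], sigma_w)
#   theta   ~ Normal(mu_c[c] + b[p], sigma_int)
#   b[p]    ~ Normal(0, sigma_b)
# Group condition means mu_c are free, or reparameterised so that every
# posterior draw satisfies the ordering of the relational account
# (rel = sim <= nont = opp) or of the feature-specific account (sim lowest,
# opp highest, rel = nont anywhere in between: the two conditions share one
# intermediate level because their target-distractor colour distances are
# equal). Equalities are enforced by parameter sharing, inequalities by a
# non-negative gap delta and an interpolation weight u in [0, 1] -- hard
# reparameterisation, never rejection.

.ror_group_block <- list(
  free = "
  for (c in 1:C) { mu_c[c] ~ dnorm(1, 0.4444) T(0,) }",
  relational = "
  base ~ dnorm(1, 0.4444) T(0,)
  delta ~ dnorm(0, 1) T(0,)
  mu_c[1] <- base
  mu_c[2] <- base
  mu_c[3] <- base + delta
  mu_c[4] <- base + delta",
  feature_specific = "
  base ~ dnorm(1, 0.4444) T(0,)
  delta ~ dnorm(0, 1) T(0,)
  u ~ dunif(0, 1)
  mu_c[2] <- base
  mu_c[4] <- base + delta
  mu_c[1] <- base + u * delta
  mu_c[3] <- base + u * delta"
)

.ror_model <- function(account) {
  paste0("model {
  for (i in 1:N) { y[i] ~ dnorm(theta[p[i], cond[i]], tau_w) }
  for (j in 1:P) {
    b[j] ~ dnorm(0, tau_b)
    for (c in 1:C) { theta[j, c] ~ dnorm(mu_c[c] + b[j], tau_int) }
  }
  sigma_w ~ dnorm(0, 0.25) T(0,)
  sigma_b ~ dnorm(0, 0.25) T(0,)
  sigma_int ~ dnorm(0, 0.25) T(0,)
  tau_w <- pow(sigma_w, -2)
  tau_b <- pow(sigma_b, -2)
  tau_int <- pow(sigma_int, -2)",
  .ror_group_block[[account]], "\n}")
}

# Targets left behind: hierarchical beta-binomial in mode/concentration
# parameterisation. Group level per condition: mode omega_c and
# concentration kappa_c (> 2); participant-condition proportions
#   theta ~ Beta(omega (kappa - 2) + 1, (1 - omega)(kappa - 2) + 1)
# and trial counts ~ Binomial(n_avail, theta). Inequality directions are
# flipped relative to the rate of return: more distraction = a HIGHER
# proportion of targets left behind.

.ptlb_omega_block <- list(
  free = "
  for (c in 1:C) { omega[c] ~ dbeta(1, 1) }",
  relational = "
  omega_lo ~ dbeta(1, 1)
  gap ~ dunif(0, 1 - omega_lo)
  omega[1] <- omega_lo + gap
  omega[2] <- omega_lo + gap
  omega[3] <- omega_lo
  omega[4] <- omega_lo",
  feature_specific = "
  omega_lo ~ dbeta(1, 1)
  gap ~ dunif(0, 1 - omega_lo)
  u ~ dunif(0, 1)
  omega[2] <- omega_lo + gap
  omega[4] <- omega_lo
  omega[1] <- omega_lo + u * gap
  omega[3] <- omega_lo + u * gap"
)

.ptlb_model <- function(account, kappa_fixed = NULL) {
  kappa_block <- if (is.null(kappa_fixed)) "
  for (c in 1:C) { km2[c] ~ dnorm(0, 4.0E-4) T(0,) }" else "
  for (c in 1:C) { km2[c] <- kappa_fixed - 2 }"
  paste0("model {
  for (i in 1:N) { k[i] ~ dbin(theta[p[i], cond[i]], n_avail) }
  for (j in 1:P) {
    for (c in 1:C) {
      theta[j, c] ~ dbeta(omega[c] * km2[c] + 1,
                          (1 - omega[c]) * km2[c] + 1)
    }
  }
  for (c in 1:C) { kappa[c] <- km2[c] + 2 }",
  kappa_block, .ptlb_omega_block[[account]], "\n}")
}

#' Sampler configuration profiles
#'
#' `"test"` is a desk-scale profile for development and automated checks;
#' `"full"` matches a long production run (20,000 retained draws after
#' 2,000 adaptation/burn-in iterations per chain).
#'
#' @param profile `"test"` or `"full"`.
#' @return List with `chains`, `adapt`, `warmup`, `draws` (total retained
#'   draws across chains).
#' @export
sampler_profile <- function(profile = c("test", "full")) {
  profile <- match.arg(profile)
  switch(profile,
    test = list(chains = 2, adapt = 500, warmup = 500, draws = 2500),
    full = list(chains = 4, adapt = 2000, warmup = 2000, draws = 20000)
  )
}

# Shared JAGS driver. Returns the stacked draws matrix plus diagnostics.
run_jags <- function(model_string, data, monitors, chains, adapt, warmup,
                     draws, seed, inits_fn = NULL) {
  inits <- lapply(seq_len(chains), function(ch) {
    ini <- if (is.null(inits_fn)) list() else inits_fn(ch)
    ini$.RNG.name <- "base::Mersenne-Twister"
    ini$.RNG.seed <- (seed * 1000L + ch) %% .Machine$integer.max
    ini
  })
  model <- rjags::jags.model(textConnection(model_string), data = data,
                             inits = inits, n.chains = chains,
                             n.adapt = adapt, quiet = TRUE)
  if (warmup > 0) stats::update(model, warmup, progress.bar = "none")
  samp <- rjags::coda.samples(model, monitors,
                              n.iter = ceiling(draws / chains),
                              progress.bar = "none")
  list(samples = samp)
}

# Sum-to-zero recentering of participant offsets: the likelihood involves
# mu_c + b_p only, and the Gibbs sampler mixes slowly over the shared
# location, so the realised mean offset is folded into the group means
# (adding a common constant to all mu_c preserves every equality and order
# constraint). Draws of theta are untouched.
recenter_offsets <- function(samples, mu_idx, b_prefix = "b[") {
  coda::as.mcmc.list(lapply(samples, function(ch) {
    m <- as.matrix(ch)
    b_cols <- grep(b_prefix, colnames(m), fixed = TRUE)
    if (length(b_cols) > 0) {
      bbar <- rowMeans(m[, b_cols, drop = FALSE])
      m[, mu_idx] <- m[, mu_idx, drop = FALSE] + bbar
      m[, b_cols] <- m[, b_cols, drop = FALSE] - bbar
    }
    coda::mcmc(m, start = stats::start(ch), thin = coda::thin(ch))
  }))
}

# Stack chains and extract convergence diagnostics for the group-level
# parameters of interest.
collect_draws <- function(samples, group_idx) {
  ess <- tryCatch(coda::effectiveSize(samples), error = function(e) NULL)
  psrf <- if (length(samples) >= 2) {
    tryCatch({
      gd <- coda::gelman.diag(samples, multivariate = FALSE,
                              autoburnin = FALSE)
      gd$psrf[, 1]
    }, error = function(e) NULL)
  }
  list(draws = as.matrix(samples), ess = ess[group_idx],
       psrf = psrf[group_idx])
}

new_hbm_fit <- function(outcome, account, draws, loglik, obs, group_names,
                        diagnostics, meta) {
  structure(list(outcome = outcome, account = account, draws = draws,
                 loglik = loglik, obs = obs, group_names = group_names,
                 diagnostics = diagnostics, meta = meta),
            class = "hbm_fit")
}

#' @export
print.hbm_fit <- function(x, ...) {
  cat(sprintf("<hbm_fit> outcome = %s, account = %s\n", x$outcome, x$account))
  cat(sprintf("  %d draws x %d observations; min ESS (group) = %.0f\n",
              nrow(x$draws), nrow(x$obs),
              suppressWarnings(min(x$diagnostics$ess_group, na.rm = TRUE))))
  gp <- group_param_draws(x)
  summ <- apply(gp, 2, function(d) {
    h <- hdi(d)
    sprintf("%.3f [%.3f, %.3f]", posterior_mode(d), h[1], h[2])
  })
  for (nm in colnames(gp)) cat(sprintf("  %s: %s\n", nm, summ[nm]))
  invisible(x)
}

# Flag (never fail) when the sampler looks unconverged.
check_diagnostics <- function(diag, outcome, account) {
  ok <- TRUE
  if (!is.null(diag$psrf_group) && any(diag$psrf_group > 1.1, na.rm = TRUE)) ok <- FALSE
  if (!is.null(diag$ess_group) && any(diag$ess_group < 100, na.rm = TRUE)) ok <- FALSE
  if (!ok) {
    warning(sprintf("possible non-convergence in %s/%s fit (PSRF > 1.1 or ESS < 100 on group parameters); result returned anyway",
                    outcome, account), call. = FALSE)
  }
  ok
}

#' Fit the hierarchical model for the rate of return
#'
#' Trial-level Normal likelihood with participant speed offsets and
#' participant-by-condition deviations; group condition means either free or
#' order-constrained under the relational / feature-specific account (see
#' the package vignette). Priors are identical across conditions and vague
#' at the data's scale: group means Normal(1, 1.5^2) truncated positive,
#' spreads half-Normal(2), constraint gap half-Normal(1).
#'
#' @param trials Tibble with columns `participant`, `condition`, `ror` (one
#'   row per trial).
#' @param account `"free"`, `"relational"` or `"feature_specific"`.
#' @param profile Sampler profile name, see [sampler_profile()]; individual
#'   settings can be overridden via `...`.
#' @param seed Integer seed for the MCMC RNG streams.
#' @param ... Overrides for `chains`, `adapt`, `warmup`, `draws`.
#' @return An `hbm_fit` object: posterior draws (group means `mu_c`,
#'   participant-condition means `theta`, spreads), a draws-by-observations
#'   pointwise log-likelihood matrix, and sampler diagnostics.
#' @export
fit_ror <- function(trials, account = c("free", "relational",
                                        "feature_specific"),
                    profile = "test", seed = 1, ...) {
  account <- match.arg(account)
  cfg <- utils::modifyList(sampler_profile(profile), list(...))
  stopifnot(all(c("participant", "condition", "ror") %in% names(trials)))
  trials <- trials[!is.na(trials$ror), ]
  pid <- factor(trials$participant)
  if (nlevels(pid) < 2) stop("need at least 2 participants")
  cond <- as_condition(trials$condition)
  dat <- list(N = nrow(trials), P = nlevels(pid), C = 4,
              y = trials$ror, p = as.integer(pid), cond = as.integer(cond))

  monitors <- c("mu_c", "theta", "b", "sigma_w", "sigma_b", "sigma_int")
  if (account != "free") monitors <- c(monitors, "delta")
  if (account == "feature_specific") monitors <- c(monitors, "u")
  ybar <- mean(trials$ror)
  inits_fn <- function(ch) {
    if (account == "free") list(mu_c = rep(ybar, 4), sigma_w = sd(trials$ror),
                                sigma_b = 0.2, sigma_int = 0.1)
    else list(base = ybar, delta = 0.05, sigma_w = sd(trials$ror),
              sigma_b = 0.2, sigma_int = 0.1)
  }
  raw <- run_jags(.ror_model(account), dat, monitors, cfg$chains, cfg$adapt,
                  cfg$warmup, cfg$draws, seed, inits_fn)
  mu_idx <- paste0("mu_c[", 1:4, "]")
  res <- collect_draws(recenter_offsets(raw$samples, mu_idx), mu_idx)
  # The recentred group means are cohort-level (they absorb the realised
  # mean participant offset, which is what the Gibbs sampler identifies
  # quickly). Population-level condition means add back the sampling
  # uncertainty of the cohort's mean offset, N(0, sigma_b / sqrt(P)),
  # shared across conditions so that contrasts and order constraints are
  # untouched.
  set.seed((seed * 7919L + 13L) %% .Machine$integer.max)
  pop_shift <- rnorm(nrow(res$draws), 0,
                     res$draws[, "sigma_b"] / sqrt(dat$P))
  res$draws[, mu_idx] <- res$draws[, mu_idx, drop = FALSE] - pop_shift

  theta_cols <- paste0("theta[", dat$p, ",", dat$cond, "]")
  ll <- dnorm(matrix(dat$y, nrow(res$draws), dat$N, byrow = TRUE),
              mean = res$draws[, theta_cols, drop = FALSE],
              sd = res$draws[, "sigma_w"], log = TRUE)

  diag <- list(ess_group = res$ess, psrf_group = res$psrf)
  diag$converged <- check_diagnostics(diag, "ror", account)
  obs <- trials[, intersect(c("participant", "block", "trial", "condition",
                              "ror"), names(trials))]
  new_hbm_fit("ror", account, res$draws, ll, obs,
              group_names = setNames(mu_idx, condition_levels()),
              diagnostics = diag,
              meta = c(cfg, list(seed = seed, participants = levels(pid))))
}

#' Fit the hierarchical beta-binomial model for targets left behind
#'
#' Per-trial counts of targets left behind (out of `n_available`) are
#' Binomial with participant-condition proportions drawn from condition-level
#' Beta distributions in mode (`omega`) / concentration (`kappa`)
#' parameterisation. Group modes are free or order-constrained (inequalities
#' flipped relative to the rate of return: more distraction leaves more
#' targets behind). Priors: omega uniform, kappa - 2 half-Normal(50).
#'
#' @param counts Tibble with columns `participant`, `condition`, `n_left`.
#' @param account `"free"`, `"relational"` or `"feature_specific"`.
#' @param profile,seed,... As in [fit_ror()].
#' @param n_available Targets per patch.
#' @param kappa_fixed Optional: fix all condition concentrations to this
#'   value instead of estimating them (`kappa_fixed = 2` makes the
#'   participant-level Beta flat, the conjugate reduction).
#' @return An `hbm_fit` object.
#' @export
fit_ptlb <- function(counts, account = c("free", "relational",
                                         "feature_specific"),
                     profile = "test", seed = 1, n_available = 15,
                     kappa_fixed = NULL, ...) {
  account <- match.arg(account)
  cfg <- utils::modifyList(sampler_profile(profile), list(...))
  stopifnot(all(c("participant", "condition", "n_left") %in% names(counts)))
  if (any(counts$n_left < 0 | counts$n_left > n_available)) {
    stop("n_left out of range [0, n_available]")
  }
  pid <- factor(counts$participant)
  cond <- as_condition(counts$condition)
  dat <- list(N = nrow(counts), P = nlevels(pid), C = 4,
              k = as.integer(counts$n_left), p = as.integer(pid),
              cond = as.integer(cond), n_avail = n_available)
  if (!is.null(kappa_fixed)) {
    stopifnot(kappa_fixed >= 2)
    dat$kappa_fixed <- kappa_fixed
  }

  monitors <- c("omega", "kappa", "theta")
  if (account != "free") monitors <- c(monitors, "gap")
  if (account == "feature_specific") monitors <- c(monitors, "u")
  pbar <- min(max(mean(counts$n_left) / n_available, 0.01), 0.9)
  inits_fn <- function(ch) {
    ini <- if (account == "free") list(omega = rep(pbar, 4))
           else list(omega_lo = pbar * 0.8, gap = pbar * 0.2)
    if (is.null(kappa_fixed)) ini$km2 <- rep(10, 4)
    ini
  }
  raw <- run_jags(.ptlb_model(account, kappa_fixed), dat, monitors,
                  cfg$chains, cfg$adapt, cfg$warmup, cfg$draws, seed,
                  inits_fn)
  om_idx <- paste0("omega[", 1:4, "]")
  res <- collect_draws(raw$samples, om_idx)

  theta_cols <- paste0("theta[", dat$p, ",", dat$cond, "]")
  ll <- dbinom(matrix(dat$k, nrow(res$draws), dat$N, byrow = TRUE),
               size = n_available,
               prob = res$draws[, theta_cols, drop = FALSE], log = TRUE)

  diag <- list(ess_group = res$ess, psrf_group = res$psrf)
  diag$converged <- check_diagnostics(diag, "ptlb", account)
  obs <- counts[, intersect(c("participant", "block", "trial", "condition",
                              "n_left"), names(counts))]
  new_hbm_fit("ptlb", account, res$draws, ll, obs,
              group_names = setNames(om_idx, condition_levels()),
              diagnostics = diag,
              meta = c(cfg, list(seed = seed, participants = levels(pid),
                                 n_available = n_available,
                                 kappa_fixed = kappa_fixed)))
}

#' Group-level condition parameter draws
#'
#' The posterior draws of the group-level central-tendency parameter per
#' condition: condition means for the rate of return, condition modes
#' (omega) for the proportion of targets left behind.
#'
#' @param fit An `hbm_fit`.
#' @return Matrix (draws x 4) with columns `rel`, `sim`, `nont`, `opp`.
#' @export
group_param_draws <- function(fit) {
  stopifnot(inherits(fit, "hbm_fit"))
  m <- fit$draws[, fit$group_names, drop = FALSE]
  colnames(m) <- names(fit$group_names)
  m
}

#' Participant-level parameter draws
#'
#' @param fit An `hbm_fit`.
#' @return A draws x participants x 4 array of participant-condition
#'   parameters (means for `ror`, proportions for `ptlb`).
#' @export
participant_param_draws <- function(fit) {
  stopifnot(inherits(fit, "hbm_fit"))
  P <- length(fit$meta$participants)
  arr <- array(NA_real_, c(nrow(fit$draws), P, 4),
               dimnames = list(NULL, fit$meta$participants,
                               condition_levels()))
  for (j in seq_len(P)) {
    for (c in 1:4) {
      arr[, j, c] <- fit$draws[, paste0("theta[", j, ",", c, "]")]
    }
  }
  arr
}

#' Pointwise log-likelihood matrix of a fit
#'
#' Log-density of every retained observation under every posterior draw,
#' evaluated at the sampled participant-condition parameters (the
#' beta-binomial likelihood is evaluated at the sampled theta; theta is not
#' integrated out per draw). This matrix is the input to [psis_loo()].
#'
#' @param fit An `hbm_fit`.
#' @return Matrix, draws x observations.
#' @export
pointwise_loglik <- function(fit) {
  stopifnot(inherits(fit, "hbm_fit"))
  if (ncol(fit$loglik) != nrow(fit$obs)) {
    stop("log-likelihood matrix misaligned with observations")
  }
  fit$loglik
}
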