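logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Generalised Pareto fit to sample exceedances (profile-posterior method of
# Zhang & Stephens 2009), with a weak prior nudging the shape toward 1/2 for
# stability at small tail sizes. Returns shape k and scale sigma.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior <- 3
  m <- 30 + floor(sqrt(n))
  j <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (j - 0.5))) / (prior * xstar)
  # profile log-likelihood in the theta = -shape/scale parameterisation:
  # conditional ML shape is xi(theta) = mean(log1p(-theta x))
  k_j <- vapply(theta, function(th) -mean(log1p(-th * x)), numeric(1))
  l_j <- n * (log(theta / k_j) + k_j - 1)
  w <- 1 / vapply(seq_len(m), function(i) sum(exp(l_j - l_j[i])), numeric(1))
  theta_hat <- sum(theta * w)
  xi <- mean(log1p(-theta_hat * x))
  sigma <- -xi / theta_hat
  xi <- (n * xi + 10 * 0.5) / (n + 10) # weakly informative adjustment
  list(k = xi, sigma = sigma)
}

# Generalised Pareto quantile function (location 0).
gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smoothed importance weights for one observation. lw = raw log
# ratios; returns smoothed, truncated log weights (max 0) and the tail
# shape estimate k-hat. Degenerate (constant) ratios are reported with
# k-hat = -Inf, the stable extreme.
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  khat <- -Inf
  if (M >= 5) {
    ord <- order(lw, decreasing = TRUE)
    tail_ids <- ord[seq_len(M)]
    cutoff <- lw[ord[M + 1]]
    exceed <- exp(lw[tail_ids]) - exp(cutoff)
    if (max(exceed) > sqrt(.Machine$double.eps)) {
      fit <- gpd_fit(exceed)
      khat <- fit$k
      if (is.finite(fit$k) && fit$sigma > 0) {
        qq <- gpd_quantile((rank(lw[tail_ids]) - 0.5) / M, fit$k, fit$sigma)
        lw[tail_ids] <- pmin(log(qq + exp(cutoff)), 0)
      }
    }
  }
  list(lw = pmin(lw, 0), khat = khat)
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Approximates exact leave-one-out cross-validation from the posterior
#' draws of a fitted model: per observation, importance ratios proportional
#' to one over its likelihood are stabilised by replacing the largest 20%
#' (at most 3 * sqrt(S)) with quantiles of a generalised Pareto distribution
#' fitted to that upper tail, then truncated at the raw maximum.
#' Observations whose tail-shape estimate exceeds 0.7 are flagged via a
#' warning (the estimate is still used).
#'
#' @param fit An `hbm_fit`, or a draws-by-observations pointwise
#'   log-likelihood matrix.
#' @return List of class `psis_loo`: `elpd` (expected log pointwise
#'   predictive density, the "loo" score), `p_loo` (effective number of
#'   parameters), `se`, `pointwise` (tibble with `elpd_i`, `lpd_i`,
#'   `khat`), `n_obs`, `n_draws`.
#' @export
psis_loo <- function(fit) {
  ll <- if (inherits(fit, "hbm_fit")) pointwise_loglik(fit) else fit
  S <- nrow(ll); N <- ncol(ll)
  elpd_i <- lpd_i <- khat <- numeric(N)
  for (i in seq_len(N)) {
    lli <- ll[, i]
    sm <- psis_smooth(-lli)
    elpd_i[i] <- logsumexp(sm$lw + lli) - logsumexp(sm$lw)
    lpd_i[i] <- logsumexp(lli) - log(S)
    khat[i] <- sm$khat
  }
  n_bad <- sum(khat > 0.7)
  if (n_bad > 0) {
    warning(sprintf("%d of %d observations have Pareto k-hat > 0.7; their PSIS-LOO estimates may be unstable", n_bad, N), call. = FALSE)
  }
  structure(list(
    elpd = sum(elpd_i),
    p_loo = sum(lpd_i - elpd_i),
    se = sqrt(N * var(elpd_i)),
    pointwise = tibble::tibble(elpd_i = elpd_i, lpd_i = lpd_i, khat = khat),
    n_obs = N, n_draws = S
  ), class = "psis_loo")
}

#' @export
print.psis_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO: elpd = %.2f (se %.2f), p_loo = %.2f, n = %d\n",
              x$elpd, x$se, x$p_loo, x$n_obs))
  cat(sprintf("Pareto k-hat: max %.2f, %d > 0.7\n",
              max(x$pointwise$khat), sum(x$pointwise$khat > 0.7)))
  invisible(x)
}

# Log-score stacking weights over a simplex, by optimising a softmax
# parameterisation (the objective is concave in the weights; K is small).
stacking_weights <- function(elpd_mat) {
  K <- ncol(elpd_mat)
  if (K == 1) return(1)
  center <- apply(elpd_mat, 1, max)
  ex <- exp(elpd_mat - center)
  obj <- function(z) {
    w <- exp(c(z, 0)); w <- w / sum(w)
    -sum(log(as.vector(ex %*% w)))
  }
  # BFGS from the equal-weight point: on a flat objective (indistinguishable
  # models) it stays there, which is the correct tie-break
  opt <- optim(rep(0, K - 1), obj, method = "BFGS")
  w <- exp(c(opt$par, 0))
  w / sum(w)
}

# Pseudo-BMA weights (no Bayesian bootstrap): softmax of the elpd scores.
pseudobma_weights <- function(elpd_mat) {
  elpd <- colSums(elpd_mat)
  w <- exp(elpd - max(elpd))
  w / sum(w)
}

#' Compare fitted model variants with PSIS-LOO
#'
#' Ranks models by their expected log pointwise predictive density and
#' reports the comparison-table fields: `rank` (0 = best), `loo` (elpd),
#' `p_loo`, `d_loo` (difference to the best model), `weight`
#' (model-averaging weight; log-score stacking by default), `se` and `dse`
#' (standard error of the elpd and of the pairwise difference, from the
#' pointwise values).
#'
#' @param fits Named list of `hbm_fit` objects fitted to the identical
#'   observations.
#' @param method `"stacking"` (default) or `"pseudobma"`.
#' @return A tibble of class `loo_report`, one row per model, sorted by
#'   rank. The per-model `psis_loo` objects are attached as attribute
#'   `"loos"`.
#' @export
compare_models <- function(fits, method = c("stacking", "pseudobma")) {
  method <- match.arg(method)
  stopifnot(is.list(fits), length(fits) >= 2)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$account, character(1))
  }
  keys <- lapply(fits, function(f) {
    interaction(f$obs[["participant"]],
                f$obs[["block"]] %||% seq_len(nrow(f$obs)),
                f$obs[["trial"]] %||% 0, drop = FALSE)
  })
  n_obs <- vapply(fits, function(f) nrow(f$obs), numeric(1))
  if (length(unique(n_obs)) != 1 ||
      !all(vapply(keys[-1], identical, logical(1), y = keys[[1]]))) {
    stop("models were not fitted to identical observation sets")
  }
  loos <- lapply(fits, psis_loo)
  elpd_mat <- vapply(loos, function(l) l$pointwise$elpd_i,
                     numeric(n_obs[[1]]))
  elpd <- colSums(elpd_mat)
  ord <- order(elpd, decreasing = TRUE)
  best <- ord[1]
  d_loo <- elpd[best] - elpd
  dse <- vapply(seq_along(fits), function(k) {
    if (k == best) return(0)
    d <- elpd_mat[, best] - elpd_mat[, k]
    sqrt(length(d) * var(d))
  }, numeric(1))
  weight <- if (method == "stacking") stacking_weights(elpd_mat)
            else pseudobma_weights(elpd_mat)
  out <- tibble::tibble(
    model = names(fits),
    rank = match(seq_along(fits), ord) - 1L,
    loo = unname(elpd),
    p_loo = unname(vapply(loos, `[[`, numeric(1), "p_loo")),
    d_loo = unname(d_loo),
    weight = unname(weight),
    se = unname(vapply(loos, `[[`, numeric(1), "se")),
    dse = dse
  )
  out <- out[order(out$rank), ]
  attr(out, "loos") <- loos
  class(out) <- c("loo_report", class(out))
  out
}

#' @export
print.loo_report <- function(x, ...) {
  df <- as.data.frame(x)
  df$loo <- round(df$loo, 2); df$p_loo <- round(df$p_loo, 2)
  df$d_loo <- round(df$d_loo, 2); df$weight <- round(df$weight, 2)
  df$se <- round(df$se, 2); df$dse <- round(df$dse, 2)
  print(df, row.names = FALSE)
  invisible(x)
}
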