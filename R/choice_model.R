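#' Expected post-test rating under the social-influence model
#'
#' The model assumes the post-test rating is centred on a linear combination
#' of the participant's initial rating and the group rating, weighted by the
#' social-influence parameter delta:
#' \deqn{\mu = x_{ini} (1 - \delta) + x_{group} \delta}
#' delta = 0 means the group is ignored, delta = 1 means the participant
#' adopts the group rating; negative delta represents adjustment away from
#' the group.
#'
#' @param x_ini Initial rating(s), 1..8 scale.
#' @param x_group Group rating(s), 1..8 scale.
#' @param delta Social-influence weight.
#' @return Numeric vector of means (not rounded to the discrete scale).
#' @export
#' @examples
#' post_mean(4, 7, 0.5)
post_mean <- function(x_ini, x_group, delta) {
  x_ini * (1 - delta) + x_group * delta
}

#' Probability mass over the 1..8 rating scale
#'
#' The discrete rating distribution obtained by integrating a normal density
#' with mean `mu` and standard deviation `sigma` over unit-width bins centred
#' on each rating, `p(x) = Phi(x + 1/2) - Phi(x - 1/2)`. Mass beyond the
#' scale ends is absorbed into the boundary ratings (`p(1)` integrates from
#' `-Inf` to 1.5, `p(8)` from 7.5 to `Inf`), so the vector sums to 1 exactly.
#'
#' @param mu Mean of the underlying normal (rating units).
#' @param sigma Standard deviation, must be > 0 (rating units).
#' @return Numeric vector of length 8; `p[x]` is the probability of rating x.
#' @export
#' @examples
#' rating_pmf(4.5, 1)  # symmetric about the 4/5 boundary
rating_pmf <- function(mu, sigma) {
  if (length(mu) != 1L || length(sigma) != 1L) {
    stop("mu and sigma must be scalars", call. = FALSE)
  }
  if (!is.finite(sigma) || sigma <= 0) {
    stop("sigma must be > 0", call. = FALSE)
  }
  upper <- c(1.5, 2.5, 3.5, 4.5, 5.5, 6.5, 7.5, Inf)
  lower <- c(-Inf, 1.5, 2.5, 3.5, 4.5, 5.5, 6.5, 7.5)
  pnorm(upper, mu, sigma) - pnorm(lower, mu, sigma)
}

# Per-trial probabilities of the observed post-test ratings, vectorized over
# trials. Boundary ratings absorb the out-of-scale tail mass.
.trial_probs <- function(x_post, mu, sigma) {
  hi <- ifelse(x_post >= 8, Inf, x_post + 0.5)
  lo <- ifelse(x_post <= 1, -Inf, x_post - 0.5)
  pnorm(hi, mu, sigma) - pnorm(lo, mu, sigma)
}

# Keep only trials that displayed a group rating (disagreement + agreement);
# the model is defined on trials that integrate a social feedback.
feedback_trials <- function(trials) {
  trials[!is.na(trials$x_group) & trials$condition != "NO_FEEDBACK", ,
         drop = FALSE]
}

#' Negative log-likelihood of post-test ratings
#'
#' Sum over feedback trials (disagreement and agreement; no-feedback trials
#' carry no group rating and are excluded) of `-log p(x_post)` under
#' [rating_pmf] with mean [post_mean]`(x_ini, x_group, delta)`. Probabilities
#' are floored at 1e-300 so the result stays finite.
#'
#' @param trials Data.frame with columns `x_ini`, `x_group`, `x_post`,
#'   `condition`.
#' @param delta Social-influence weight.
#' @param sigma Internal noise standard deviation, > 0.
#' @return Scalar negative log-likelihood.
#' @export
neg_log_likelihood <- function(trials, delta, sigma) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  ft <- feedback_trials(trials)
  if (nrow(ft) == 0L) {
    stop("unfittable participant: no feedback trials", call. = FALSE)
  }
  mu <- post_mean(ft$x_ini, ft$x_group, delta)
  p <- .trial_probs(ft$x_post, mu, sigma)
  -sum(log(pmax(p, 1e-300)))
}

default_fit_bounds <- function() {
  list(delta = c(-1, 1), sigma = c(0.05, 5))
}

# Interior multi-start grid over the bounds box.
.start_grid <- function(bounds, n_starts) {
  d <- seq(bounds$delta[1], bounds$delta[2], length.out = n_starts[1] + 2L)
  s <- seq(bounds$sigma[1], bounds$sigma[2], length.out = n_starts[2] + 2L)
  expand.grid(delta = d[-c(1, n_starts[1] + 2L)],
              sigma = s[-c(1, n_starts[2] + 2L)])
}

#' Maximum-likelihood fit of the two-parameter choice model
#'
#' Minimizes [neg_log_likelihood] over (delta, sigma) by bounded
#' quasi-Newton search (`optim`, L-BFGS-B) from a fixed grid of starting
#' points, keeping the best end point. Deterministic given the data and
#' settings.
#'
#' @param trials A participant's trial data.frame (columns `condition`,
#'   `x_ini`, `x_group`, `x_post`); no-feedback trials are ignored.
#' @param bounds List with elements `delta` and `sigma`, each `c(lower,
#'   upper)`. Defaults: delta in \[-1, 1\] (negative values = adjustment away
#'   from the group), sigma in \[0.05, 5\] rating units.
#' @param n_starts Integer vector `c(n_delta, n_sigma)` of interior grid
#'   starts per axis (default 5 x 5).
#' @return List of class `choice_model_fit`: `delta`, `sigma`, `nll`,
#'   `n_trials_used`, `converged`, `n_starts`.
#' @export
#' @examples
#' sched <- build_schedule(1)
#' trials <- simulate_trials(sched, delta = 0.4, sigma = 0.8, seed = 2)
#' fit_participant(trials)
fit_participant <- function(trials, bounds = default_fit_bounds(),
                            n_starts = c(5L, 5L)) {
  ft <- feedback_trials(trials)
  if (nrow(ft) == 0L) {
    stop("unfittable participant: no feedback trials", call. = FALSE)
  }
  x_ini <- ft$x_ini; x_group <- ft$x_group
  hi <- ifelse(ft$x_post >= 8, Inf, ft$x_post + 0.5)
  lo <- ifelse(ft$x_post <= 1, -Inf, ft$x_post - 0.5)
  obj <- function(par) {
    mu <- x_ini * (1 - par[1]) + x_group * par[1]
    -sum(log(pmax(pnorm(hi, mu, par[2]) - pnorm(lo, mu, par[2]), 1e-300)))
  }
  starts <- .start_grid(bounds, n_starts)
  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(c(starts$delta[i], starts$sigma[i]), obj, method = "L-BFGS-B",
            lower = c(bounds$delta[1], bounds$sigma[1]),
            upper = c(bounds$delta[2], bounds$sigma[2]),
            control = list(factr = 1e7)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("all optimizer starts failed", call. = FALSE)
  }
  if (!any_conv) {
    warning("no optimizer start reported convergence; returning best found",
            call. = FALSE)
  }
  structure(
    list(delta = best$par[1], sigma = best$par[2], nll = best$value,
         n_trials_used = nrow(ft), converged = any_conv,
         n_starts = nrow(starts)),
    class = "choice_model_fit"
  )
}

#' @export
print.choice_model_fit <- function(x, ...) {
  cat(sprintf(
    "choice model fit: delta = %.3f, sigma = %.3f (nll %.3f over %d trials%s)\n",
    x$delta, x$sigma, x$nll, x$n_trials_used,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Exhaustive grid-search fit (test oracle)
#'
#' Evaluates the negative log-likelihood on a regular (delta, sigma) grid and
#' returns the grid argmin. Intended as an independent check on
#' [fit_participant], not for production fitting.
#'
#' @inheritParams fit_participant
#' @param step Grid spacing on both axes.
#' @return A `choice_model_fit` list (with `n_starts` = number of grid
#'   points).
#' @export
fit_oracle_grid <- function(trials, bounds = default_fit_bounds(),
                            step = 0.01) {
  ft <- feedback_trials(trials)
  if (nrow(ft) == 0L) {
    stop("unfittable participant: no feedback trials", call. = FALSE)
  }
  dgrid <- seq(bounds$delta[1], bounds$delta[2], by = step)
  sgrid <- seq(bounds$sigma[1], bounds$sigma[2], by = step)
  x_ini <- ft$x_ini; x_group <- ft$x_group; x_post <- ft$x_post
  hi <- ifelse(x_post >= 8, Inf, x_post + 0.5)
  lo <- ifelse(x_post <= 1, -Inf, x_post - 0.5)
  # mu for every (delta, trial) pair: n_delta x n_trials
  mu <- outer(dgrid, seq_along(x_ini),
              function(d, j) x_ini[j] * (1 - d) + x_group[j] * d)
  best <- list(value = Inf)
  for (s in sgrid) {
    p <- pnorm(rep(hi, each = length(dgrid)), mu, s) -
      pnorm(rep(lo, each = length(dgrid)), mu, s)
    nll <- -rowSums(log(pmax(matrix(p, nrow = length(dgrid)), 1e-300)))
    k <- which.min(nll)
    if (nll[k] < best$value) best <- list(value = nll[k], delta = dgrid[k],
                                          sigma = s)
  }
  structure(
    list(delta = best$delta, sigma = best$sigma, nll = best$value,
         n_trials_used = nrow(ft), converged = TRUE,
         n_starts = length(dgrid) * length(sgrid)),
    class = "choice_model_fit"
  )
}

#' Model-predicted alignment scores
#'
#' For each disagreement trial, the expected post-test rating under the
#' fitted model, `E[x] = sum(x * p(x))`, gives a predicted rating change
#' `E[x] - x_ini`; condition means are sign-flipped for negative-disagreement
#' conditions exactly as in [social_alignment], so predictions are directly
#' comparable with the behavioural alignment scores.
#'
#' @param fit A `choice_model_fit` (or any list with `delta` and `sigma`).
#' @param trials The participant's trial data.frame.
#' @return List with `alignment` (named over the four disagreement
#'   conditions) and `overall` (their unweighted mean).
#' @export
predict_alignment <- function(fit, trials) {
  dis <- trials[is_disagreement(trials$condition), , drop = FALSE]
  scale_pts <- 1:8
  e_post <- vapply(seq_len(nrow(dis)), function(i) {
    mu <- post_mean(dis$x_ini[i], dis$x_group[i], fit$delta)
    sum(scale_pts * rating_pmf(mu, fit$sigma))
  }, numeric(1))
  change <- e_post - dis$x_ini
  conds <- c("NEG_STRONG", "NEG_MODERATE", "POS_MODERATE", "POS_STRONG")
  mean_change <- vapply(conds, function(cc) {
    idx <- dis$condition == cc
    if (!any(idx)) NA_real_ else mean(change[idx])
  }, numeric(1))
  flip <- ifelse(grepl("^NEG", conds), -1, 1)
  alignment <- flip * mean_change
  list(alignment = alignment, overall = mean(alignment))
}

#' Fit the choice model to every participant in a trial table
#'
#' @param trials Trial table with a `participant_id` column plus the columns
#'   [fit_participant] needs.
#' @inheritParams fit_participant
#' @return Data.frame with one row per participant: `participant_id`,
#'   `delta`, `sigma`, `nll`, `n_trials_used`, `converged`.
#' @export
fit_cohort <- function(trials, bounds = default_fit_bounds(),
                       n_starts = c(5L, 5L)) {
  ids <- unique(trials$participant_id)
  rows <- lapply(ids, function(id) {
    fit <- fit_participant(trials[trials$participant_id == id, , drop = FALSE],
                           bounds = bounds, n_starts = n_starts)
    data.frame(participant_id = id, delta = fit$delta, sigma = fit$sigma,
               nll = fit$nll, n_trials_used = fit$n_trials_used,
               converged = fit$converged)
  })
  do.call(rbind, rows)
}
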