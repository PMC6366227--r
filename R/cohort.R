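#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the generator emulates: a 24-face
#' schedule per participant, a mid-scale-peaked initial-rating tendency, a
#' zero-inflated positively-skewed childhood-unpredictability scale (about a
#' third of participants report none at all), a bimodal/negatively-skewed
#' harshness scale moderately correlated with unpredictability, and a linear
#' link from the adversity composite to the social-influence weight delta
#' with slope 0.03 per adversity unit.
#'
#' @param n_participants Cohort size (>= 2). Default 262, the replication
#'   study's final sample size.
#' @param seed Master seed; every participant draws from a stream derived
#'   from it.
#' @param delta_intercept,delta_slope_adversity,delta_noise_sd Linear link
#'   `delta = intercept + slope * adversity + N(0, noise_sd)`, clipped to
#'   \[0, 1\].
#' @param sigma_mean,sigma_sd Per-participant internal noise drawn from a
#'   normal truncated below at 0.05 rating units.
#' @param p_zero_unpredictability Probability that a participant reports no
#'   unpredictability at all (all three items = 1); these are the lower tail
#'   of the latent trait.
#' @param initial_rating_pmf Probability mass over ratings 1..8 for initial
#'   ratings; default is a discrete triangular distribution peaked at 4-5.
#' @param n_faces Faces per participant (positive multiple of 8).
#' @param latent_cor Correlation of the latent unpredictability and harshness
#'   traits (calibrated so observed composite correlation is about 0.37).
#' @param u_trait_scale Rating-units-per-latent-sd slope of the
#'   unpredictability trait above the zero threshold.
#' @param u_item_sd,h_item_sd Item-level noise standard deviations
#'   (calibrated so Cronbach's alpha is about 0.79 / 0.77).
#' @param harsh_mix Two-component normal mixture for the harshness trait on
#'   the reversed (1..7, higher = harsher) scale: list with `p` (weight of
#'   the low-harshness component), `mean`, `sd` (length-2 each).
#' @param clip_retry_cap Number of condition-assignment re-draws attempted to
#'   keep all bogus feedback on-scale before accepting a clipped trial.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 262L,
                          seed = 1L,
                          delta_intercept = 0.2,
                          delta_slope_adversity = 0.03,
                          delta_noise_sd = 0.05,
                          sigma_mean = 0.9,
                          sigma_sd = 0.2,
                          p_zero_unpredictability = 1 / 3,
                          initial_rating_pmf = c(1, 2, 3, 4, 4, 3, 2, 1) / 20,
                          n_faces = 24L,
                          latent_cor = 0.50,
                          u_trait_scale = 1.6,
                          u_item_sd = 1.45,
                          h_item_sd = 1.50,
                          harsh_mix = list(p = 0.35, mean = c(2.0, 4.9),
                                           sd = c(0.7, 0.9)),
                          clip_retry_cap = 200L) {
  if (n_participants < 2) stop("n_participants must be >= 2", call. = FALSE)
  if (abs(sum(initial_rating_pmf) - 1) > 1e-8 || length(initial_rating_pmf) != 8 ||
      any(initial_rating_pmf < 0)) {
    stop("initial_rating_pmf must be a length-8 probability vector",
         call. = FALSE)
  }
  if (p_zero_unpredictability < 0 || p_zero_unpredictability > 1) {
    stop("p_zero_unpredictability must be a probability", call. = FALSE)
  }
  structure(as.list(environment()), class = "cohort_config")
}

# Derived per-participant seed, kept under 2^31.
.participant_seed <- function(seed, id, phase = 0L) {
  as.integer((as.double(seed) %% 1e6 * 1000003 + id * 7919 + phase * 104729) %%
               2147483629) + 1L
}

# Quantile map onto the harshness trait mixture: monotone in the latent
# normal, so it preserves the latent correlation while giving the trait an
# exactly bimodal marginal.
.harsh_trait <- function(z, mix) {
  u <- pnorm(z)
  grid <- seq(-2, 10, by = 0.01)
  cdf <- mix$p * pnorm(grid, mix$mean[1], mix$sd[1]) +
    (1 - mix$p) * pnorm(grid, mix$mean[2], mix$sd[2])
  approx(cdf, grid, xout = u, rule = 2, ties = "ordered")$y
}

#' Generate questionnaire item responses
#'
#' Draws childhood unpredictability and harshness items for `n` participants
#' from the current RNG state. Each participant has a pair of correlated
#' latent traits; participants in the lower `p_zero_unpredictability` tail of
#' the unpredictability trait answer (1, 1, 1) on that scale, others answer
#' around a positively-skewed trait value; harshness items are generated on
#' the reversed scale from a bimodal trait and stored as the raw (wealth)
#' responses.
#'
#' @param cfg A [cohort_config].
#' @param n Number of participants to draw.
#' @return Data.frame with integer columns `u1..u3`, `h1..h3` in 1..7.
#' @export
generate_questionnaire <- function(cfg, n = 1L) {
  z_u <- rnorm(n)
  z_h <- cfg$latent_cor * z_u + sqrt(1 - cfg$latent_cor^2) * rnorm(n)
  thr <- qnorm(cfg$p_zero_unpredictability)
  u_trait <- 1 + cfg$u_trait_scale * pmax(z_u - thr, 0)
  u_items <- matrix(
    pmin(pmax(round(rep(u_trait, 3) + rnorm(3 * n, 0, cfg$u_item_sd)), 1), 7),
    nrow = n)
  u_items[z_u < thr, ] <- 1
  h_trait <- .harsh_trait(z_h, cfg$harsh_mix)
  # items are phrased as wealth: reverse the harshness trait back to 8 - x
  h_items <- matrix(
    pmin(pmax(round(8 - (rep(h_trait, 3) + rnorm(3 * n, 0, cfg$h_item_sd))), 1), 7),
    nrow = n)
  out <- data.frame(u_items, h_items)
  names(out) <- c("u1", "u2", "u3", "h1", "h2", "h3")
  out
}

#' Simulate one participant's trials under the choice model
#'
#' Draws initial ratings per face, assigns the schedule's conditions
#' (re-drawing the assignment up to `retry_cap` times so that the bogus
#' feedback stays on the 1..8 scale, then clipping), computes the group
#' ratings with [compute_feedback], and draws post-test ratings from
#' [rating_pmf] with mean [post_mean]; agreement and no-feedback trials use
#' `mu = x_ini`.
#'
#' @param schedule A [build_schedule] result (its condition multiset is
#'   reused; assignment to faces is re-drawn here as needed).
#' @param delta,sigma True choice-model parameters for this participant.
#' @param seed Integer seed (trials are deterministic given it).
#' @param initial_rating_pmf Probability mass over 1..8 for initial ratings.
#' @param retry_cap Re-draw attempts before accepting clipped feedback.
#' @return Trial data.frame: `face_id`, `trial_index_test`,
#'   `trial_index_post`, `condition`, `offset_nominal`, `clipped`, `x_ini`,
#'   `x_group`, `x_post`.
#' @export
#' @examples
#' simulate_trials(build_schedule(1), delta = 0.5, sigma = 0.5, seed = 2)
simulate_trials <- function(schedule, delta, sigma, seed,
                            initial_rating_pmf = c(1, 2, 3, 4, 4, 3, 2, 1) / 20,
                            retry_cap = 200L) {
  with_preserved_seed(seed, {
    n <- nrow(schedule)
    x_ini <- sample(1:8, n, replace = TRUE, prob = initial_rating_pmf)
    conditions <- schedule$condition
    fb <- compute_feedback(x_ini, conditions)
    tries <- 0L
    while (any(fb$clipped) && tries < retry_cap) {
      conditions <- sample(schedule$condition)
      fb <- compute_feedback(x_ini, conditions)
      tries <- tries + 1L
    }
    x_group_eff <- ifelse(is.na(fb$group_rating), x_ini, fb$group_rating)
    mu <- post_mean(x_ini, x_group_eff, delta)
    x_post <- vapply(mu, function(m) {
      sample(1:8, 1L, prob = rating_pmf(m, sigma))
    }, integer(1))
    data.frame(
      face_id = schedule$face_id,
      trial_index_test = seq_len(n),
      trial_index_post = sample(n),
      condition = conditions,
      offset_nominal = unname(.CONDITION_OFFSETS[conditions]),
      clipped = fb$clipped,
      x_ini = x_ini,
      x_group = fb$group_rating,
      x_post = x_post,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a full synthetic cohort
#'
#' Generates questionnaires, demographics and ground-truth parameters for
#' every participant, scores adversity across the cohort, applies the linear
#' adversity-to-delta link, and simulates each participant's 24 trials from
#' the choice model. Deterministic given `cfg$seed`; each participant draws
#' from an id-derived stream.
#'
#' @param cfg A [cohort_config].
#' @return List of class `socialign_cohort`: `participants` (id,
#'   demographics, items, and the ground truth `delta_true`, `sigma_true`,
#'   `adversity_true`), `trials` (one row per participant x face) and
#'   `config`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(n_participants = 5, seed = 7))
#' str(coh$participants)
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_participants
  # phase A: questionnaires, demographics, per-participant nuisance draws
  part <- do.call(rbind, lapply(seq_len(n), function(i) {
    with_preserved_seed(.participant_seed(cfg$seed, i, 0L), {
      q <- generate_questionnaire(cfg, 1L)
      data.frame(
        participant_id = i,
        age = max(18L, round(rnorm(1, 38, 12))),
        gender = sample(c("female", "male"), 1L, prob = c(0.59, 0.41)),
        q,
        sigma_true = max(rnorm(1, cfg$sigma_mean, cfg$sigma_sd), 0.05),
        delta_noise = rnorm(1, 0, cfg$delta_noise_sd),
        stringsAsFactors = FALSE
      )
    })
  }))
  # phase B: cohort-level scoring fixes each participant's adversity, which
  # the delta link needs; a no-variance composite (possible in tiny cohorts)
  # carries no adversity signal, so it contributes 0 rather than failing
  part$adversity_true <- tryCatch(score_cohort(part)$adversity,
                                  error = function(e) rep(0, n))
  part$delta_true <- pmin(pmax(
    cfg$delta_intercept + cfg$delta_slope_adversity * part$adversity_true +
      part$delta_noise, 0), 1)
  part$delta_noise <- NULL
  # phase C: trials
  trials <- do.call(rbind, lapply(seq_len(n), function(i) {
    sched <- build_schedule(.participant_seed(cfg$seed, i, 1L), cfg$n_faces)
    tr <- simulate_trials(sched, part$delta_true[i], part$sigma_true[i],
                          seed = .participant_seed(cfg$seed, i, 2L),
                          initial_rating_pmf = cfg$initial_rating_pmf,
                          retry_cap = cfg$clip_retry_cap)
    cbind(participant_id = i, tr)
  }))
  structure(list(participants = part, trials = trials, config = cfg),
            class = "socialign_cohort")
}

#' @export
print.socialign_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d participants x %d trials (seed %d)\n",
              nrow(x$participants), x$config$n_faces, x$config$seed))
  invisible(x)
}
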