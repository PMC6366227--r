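test_that("the post-test mean interpolates between own and group rating", {
  expect_equal(post_mean(4, 7, 0), 4)
  expect_equal(post_mean(4, 7, 1), 7)
  expect_equal(post_mean(4, 7, 0.5), 5.5)
  expect_equal(post_mean(4, 7, -0.5), 2.5)  # adjustment away from the group
})

test_that("the rating pmf is a proper, symmetric discrete distribution", {
  p <- rating_pmf(4.5, 1.3)
  expect_equal(p[4], p[5])
  expect_equal(sum(p), 1)
  expect_gt(rating_pmf(4, 0.05)[4], 0.999)
  p1 <- rating_pmf(4, 1)
  expect_equal(p1[3], p1[5])
  expect_equal(sum(p1), 1)
  # boundary absorption keeps normalization exact even far off scale
  for (mu in c(-5, 0.7, 8.2, 20)) {
    for (sg in c(0.06, 1, 4.9)) {
      expect_equal(sum(rating_pmf(mu, sg)), 1)
    }
  }
  expect_error(rating_pmf(4, 0), "sigma")
  expect_error(rating_pmf(4, -1), "sigma")
})

test_that("the likelihood is additive and matches a numeric-integration oracle", {
  tr <- make_trials(delta = 0.3, sigma = 0.9, seed = 4)
  ft <- tr[tr$condition != "NO_FEEDBACK", ]
  per_trial <- vapply(seq_len(nrow(ft)), function(i)
    neg_log_likelihood(ft[i, ], 0.3, 0.9), numeric(1))
  expect_equal(neg_log_likelihood(tr, 0.3, 0.9), sum(per_trial))
  # independent oracle: integrate the normal density over each rating bin
  int_oracle <- sum(vapply(seq_len(nrow(ft)), function(i) {
    mu <- post_mean(ft$x_ini[i], ft$x_group[i], 0.3)
    lo <- if (ft$x_post[i] == 1) -Inf else ft$x_post[i] - 0.5
    hi <- if (ft$x_post[i] == 8) Inf else ft$x_post[i] + 0.5
    -log(integrate(dnorm, lo, hi, mean = mu, sd = 0.9,
                   rel.tol = 1e-12)$value)
  }, numeric(1)))
  expect_equal(neg_log_likelihood(tr, 0.3, 0.9), int_oracle, tolerance = 1e-8)
  expect_error(neg_log_likelihood(tr, 0.3, 0), "sigma")
  only_nofb <- tr[tr$condition == "NO_FEEDBACK", ]
  expect_error(neg_log_likelihood(only_nofb, 0.3, 0.9), "unfittable")
})

test_that("agreement trials carry no information about delta", {
  tr <- make_trials(delta = 0.5, sigma = 0.8, seed = 6)
  agree <- tr[tr$condition == "AGREE", ]
  nlls <- vapply(seq(-1, 1, by = 0.25), function(d)
    neg_log_likelihood(agree, d, 0.8), numeric(1))
  expect_equal(max(nlls) - min(nlls), 0)
})

test_that("the likelihood stays finite even at absurd parameter values", {
  tr <- manual_trials(c(4L, 5L), c("POS_STRONG", "NEG_STRONG"),
                      x_post = c(1L, 8L))
  expect_true(is.finite(neg_log_likelihood(tr, 1, 0.05)))
})

test_that("fitting recovers the saturating identity cases", {
  tr1 <- make_trials(delta = 1, sigma = 0.2, seed = 8, n_faces = 96L)
  fit1 <- fit_participant(tr1)
  expect_gt(fit1$delta, 0.9)
  expect_true(fit1$converged)
  tr0 <- make_trials(delta = 0.6, sigma = 0.5, seed = 9)
  tr0$x_post <- tr0$x_ini  # no influence at all
  fit0 <- fit_participant(tr0)
  expect_lt(abs(fit0$delta), 0.05)
})

test_that("the bounded optimizer is at least as good as a grid oracle", {
  set.seed(41)
  for (i in 1:4) {
    tr <- make_trials(delta = runif(1), sigma = runif(1, 0.5, 1.5),
                      seed = 50 + i)
    fit <- fit_participant(tr)
    oracle <- fit_oracle_grid(tr, step = 0.02)
    expect_lte(fit$nll, oracle$nll + 1e-3)
  }
})

test_that("the grid argmin is stable under refinement", {
  tr <- make_trials(delta = 0.35, sigma = 0.8, seed = 12)
  coarse <- fit_oracle_grid(tr, step = 0.02)
  fine <- fit_oracle_grid(tr, step = 0.01)
  expect_lte(fine$nll, coarse$nll)
  expect_lt(abs(fine$delta - coarse$delta), 0.03)
  expect_lt(abs(fine$sigma - coarse$sigma), 0.03)
  tr0 <- make_trials(delta = 0.5, sigma = 0.5, seed = 13)
  tr0$x_post <- tr0$x_ini
  expect_lte(abs(fit_oracle_grid(tr0, step = 0.02)$delta), 0.02 + 1e-9)
})

test_that("predicted alignment follows delta times offset when noise is small", {
  fit0 <- list(delta = 0, sigma = 0.05)
  tr <- manual_trials(rep(4L, 4),
                      c("NEG_STRONG", "NEG_MODERATE", "POS_MODERATE",
                        "POS_STRONG"))
  pa0 <- predict_alignment(fit0, tr)
  expect_true(all(abs(pa0$alignment) < 1e-6))
  # mid-scale initials keep all feedback unclipped
  tr5 <- manual_trials(rep(4L, 8),
                       rep(c("NEG_STRONG", "NEG_MODERATE", "POS_MODERATE",
                             "POS_STRONG"), 2))
  pa <- predict_alignment(list(delta = 0.5, sigma = 0.05), tr5)
  expect_equal(unname(pa$alignment["NEG_MODERATE"]), 1.0, tolerance = 1e-3)
  expect_equal(unname(pa$alignment["POS_MODERATE"]), 1.0, tolerance = 1e-3)
  expect_equal(unname(pa$alignment["NEG_STRONG"]), 1.5, tolerance = 1e-3)
  expect_equal(unname(pa$alignment["POS_STRONG"]), 1.5, tolerance = 1e-3)
})

test_that("expected predicted alignment is nondecreasing in delta", {
  tr <- manual_trials(rep(c(4L, 5L), each = 4),
                      rep(c("NEG_STRONG", "NEG_MODERATE", "POS_MODERATE",
                            "POS_STRONG"), 2))
  overall <- vapply(seq(0, 1, by = 0.1), function(d)
    predict_alignment(list(delta = d, sigma = 0.9), tr)$overall, numeric(1))
  expect_true(all(diff(overall) >= -1e-10))
})

test_that("delta recovery sharpens with more trials", {
  set.seed(17)
  deltas <- runif(12)
  err <- function(n_faces) {
    vapply(seq_along(deltas), function(i) {
      tr <- make_trials(deltas[i], sigma = 1, seed = 100 + i,
                        n_faces = n_faces)
      fit_participant(tr, n_starts = c(3L, 3L))$delta - deltas[i]
    }, numeric(1))
  }
  rmse18 <- sqrt(mean(err(24L)^2))    # 18 feedback trials
  rmse180 <- sqrt(mean(err(240L)^2))  # 180 feedback trials
  expect_lt(rmse180, rmse18)
  expect_lt(abs(mean(err(240L))), 0.08)
})
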