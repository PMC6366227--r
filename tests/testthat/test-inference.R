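test_that("a perfect linear relation gives exact slope and zero influence", {
  d <- data.frame(score = seq(-2, 2, length.out = 20))
  d$y <- 2 * d$score
  r <- suppressWarnings(env_regression(d, "y", "score"))
  expect_equal(unname(r$coefficients["score", "estimate"]), 2)
  expect_lt(max(abs(residuals(r$model))), 1e-12)
  expect_equal(r$cooks_distance, rep(0, 20))
  expect_equal(r$cutoff, 4 / 20)
})

test_that("regression guards degenerate designs", {
  d <- data.frame(y = rnorm(10), score = rep(1, 10))
  expect_error(env_regression(d, "y", "score"), "zero variance")
  d2 <- data.frame(y = rnorm(10), a = rnorm(10))
  d2$b <- d2$a
  expect_error(env_regression(d2, "y", "a", covariates = "b"), "singular")
  expect_error(env_regression(d2, "y", "missing_col"), "not found")
  expect_error(env_regression(d2[1:2, ], "y", "a"), "at least 3")
})

test_that("Cook's distance agrees with brute-force leave-one-out refits", {
  set.seed(51)
  d <- data.frame(score = rnorm(15))
  d$y <- 0.5 + 0.8 * d$score + rnorm(15, sd = 0.4)
  r <- env_regression(d, "y", "score")
  fit <- lm(y ~ score, d)
  p <- 2
  s2 <- sum(residuals(fit)^2) / (15 - p)
  yhat <- fitted(fit)
  loo <- vapply(1:15, function(i) {
    fi <- lm(y ~ score, d[-i, ])
    yhat_i <- predict(fi, newdata = d)
    sum((yhat - yhat_i)^2) / (p * s2)
  }, numeric(1))
  expect_equal(r$cooks_distance, loo, tolerance = 1e-10)
})

test_that("a planted high-leverage point is the unique slope outlier", {
  # clean cloud with alternating equal-magnitude residuals, so every clean
  # point's influence sits well below the 4/N cutoff; the planted point is
  # far out in x and off the line
  n <- 41
  d <- data.frame(score = c(seq(-1, 1, length.out = n - 1), 4))
  d$y <- 0.3 * d$score + c(rep(c(0.05, -0.05), (n - 1) / 2), -2.5)
  r <- env_regression(d, "y", "score")
  expect_equal(which(r$cooks_distance > r$cutoff), n)
  set.seed(52)
  d$score2 <- rnorm(n)  # unrelated second regression for the union
  filt <- slope_outlier_filter(d, "y", c("score", "score2"))
  expect_true(n %in% filt$removed)
  refit <- filt$refits$score
  expect_lt(abs(refit$coefficients["score", "estimate"] - 0.3), 0.02)
})

test_that("the union rule removes a point outlying in only one regression", {
  set.seed(53)
  n <- 30
  d <- data.frame(a = rnorm(n), b = rnorm(n))
  d$y <- 0.5 * d$a + rnorm(n, sd = 0.1)
  d$a[n] <- 5; d$y[n] <- -3    # outlier for y ~ a only
  ra <- env_regression(d, "y", "a")
  rb <- env_regression(d, "y", "b")
  expect_true(ra$cooks_distance[n] > ra$cutoff)
  filt <- slope_outlier_filter(d, "y", c("a", "b"))
  expect_true(n %in% filt$removed)
  tiny <- data.frame(a = c(0, 1, 2, 3), y = c(0, 1, 2, 30))
  expect_error(slope_outlier_filter(tiny, "y", "a"), "fewer than 3")
})

test_that("clean linear data loses nothing to the slope-outlier filter", {
  d <- data.frame(score = seq(-2, 2, length.out = 25))
  d$y <- 1 + 0.4 * d$score
  filt <- suppressWarnings(slope_outlier_filter(d, "y", "score"))
  expect_equal(filt$n_removed, 0)
})

test_that("fixed-effects pooling matches its closed forms and symmetries", {
  m <- meta_fixed(c(0.1, 0.1), c(0.05, 0.05))
  expect_equal(m$beta_pooled, 0.1)
  expect_equal(m$se_pooled, 0.05 / sqrt(2))
  expect_equal(m$Q, 0)
  set.seed(54)
  b <- rnorm(4); s <- runif(4, 0.02, 0.2)
  m4 <- meta_fixed(b, s)
  expect_gte(m4$beta_pooled, min(b)); expect_lte(m4$beta_pooled, max(b))
  expect_equal(sum(m4$weights), 1)
  perm <- c(3, 1, 4, 2)
  expect_equal(meta_fixed(b[perm], s[perm])$beta_pooled, m4$beta_pooled)
  w <- 1 / s^2
  expect_equal(m4$Q, sum(w * (b - sum(w * b) / sum(w))^2))
  expect_error(meta_fixed(0.1, 0.05), "at least 2")
  expect_error(meta_fixed(c(0.1, 0.2), c(0.05, 0)), "> 0")
})

test_that("pooling agrees with metafor's fixed-effects model", {
  skip_if_not_installed("metafor")
  b <- c(0.13, 0.037); s <- c(0.05, 0.03)
  m <- meta_fixed(b, s)
  rma <- suppressWarnings(metafor::rma(yi = b, sei = s, method = "FE"))
  expect_equal(m$beta_pooled, as.numeric(rma$beta), tolerance = 1e-10)
  expect_equal(m$se_pooled, rma$se, tolerance = 1e-10)
  expect_equal(m$z, as.numeric(rma$zval), tolerance = 1e-10)
  expect_equal(m$Q, rma$QE, tolerance = 1e-10)
})

test_that("participant-mean OLS equals the balanced random-intercept GLS", {
  # balanced design: 4 condition-level rows per participant, one
  # between-participant predictor; the GLS fixed effect under a random
  # intercept must match OLS on participant means
  set.seed(55)
  n <- 24; k <- 4
  x <- rnorm(n)
  u <- rnorm(n, sd = 0.5)
  y <- as.vector(vapply(1:n, function(i)
    0.2 + 0.3 * x[i] + u[i] + rnorm(k, sd = 0.4), numeric(k)))
  long_x <- rep(x, each = k)
  X <- cbind(1, long_x)
  sa2 <- 0.25; se2 <- 0.16
  Vi <- diag(k) * se2 + matrix(sa2, k, k)
  V <- kronecker(diag(n), Vi)
  beta_gls <- solve(t(X) %*% solve(V) %*% X, t(X) %*% solve(V) %*% y)
  d <- data.frame(score = x, ymean = colMeans(matrix(y, k)))
  r <- env_regression(d, "ymean", "score")
  expect_equal(unname(r$coefficients["score", "estimate"]),
               as.numeric(beta_gls[2, 1]), tolerance = 1e-10)
})

test_that("study-effects tables are validated on ingestion", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# provenance", "study\tbeta\tse",
               "pilot\t0.13\t0.05", "replication\t0.037\t0.03"), path)
  eff <- read_study_effects(path)
  expect_equal(nrow(eff), 2)
  m <- meta_fixed(eff$beta, eff$se, eff$study)
  expect_equal(round(m$beta_pooled, 2), 0.06)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("study\tbeta", "pilot\t0.1"), bad)
  expect_error(read_study_effects(bad), "columns")
})
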