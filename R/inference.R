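#' Participant-level regression with influence diagnostics
#'
#' Ordinary least squares of a participant-level outcome (overall alignment
#' score, or the fitted social-influence weight delta) on an environment
#' score, optionally adjusted for covariates. Reports the coefficient table
#' and each observation's Cook's distance with the 4/N slope-outlier cutoff.
#'
#' @param data Data.frame of participant-level variables.
#' @param outcome,predictor Column names of the outcome and the environment
#'   score.
#' @param covariates Optional character vector of additional column names
#'   (e.g. age, gender).
#' @return List of class `env_regression`: `model` (the `lm` fit),
#'   `coefficients` (estimate, se, t, p per term), `cooks_distance`,
#'   `cutoff` (= 4/N), `n`, `outcome`, `predictor`.
#' @export
#' @examples
#' d <- data.frame(score = rnorm(50))
#' d$y <- 0.5 * d$score + rnorm(50, sd = 0.2)
#' env_regression(d, "y", "score")
env_regression <- function(data, outcome, predictor, covariates = character()) {
  vars <- c(outcome, predictor, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(data)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (sd(data[[predictor]]) == 0) {
    stop("predictor has zero variance", call. = FALSE)
  }
  fml <- reformulate(c(predictor, covariates), response = outcome)
  fit <- lm(fml, data = data)
  if (any(is.na(coef(fit)))) {
    stop("singular design: collinear predictors", call. = FALSE)
  }
  ct <- summary(fit)$coefficients
  colnames(ct) <- c("estimate", "se", "t", "p")
  cd <- unname(cooks.distance(fit))
  # an exact fit has D_i = 0; numerically it degenerates to 0/0 noise
  if (sum(residuals(fit)^2) <= 1e-20 * max(1, sum(fitted(fit)^2))) cd[] <- 0
  structure(
    list(model = fit,
         coefficients = ct,
         cooks_distance = cd,
         cutoff = 4 / n,
         n = n, outcome = outcome, predictor = predictor),
    class = "env_regression"
  )
}

#' @export
print.env_regression <- function(x, ...) {
  sl <- x$coefficients[x$predictor, ]
  cat(sprintf("OLS %s ~ %s (n = %d): beta = %.4f +/- %.4f, t = %.2f, p = %.3g\n",
              x$outcome, x$predictor, x$n, sl["estimate"], sl["se"],
              sl["t"], sl["p"]))
  cat(sprintf("  %d observation(s) with Cook's D > 4/N = %.4f\n",
              sum(x$cooks_distance > x$cutoff), x$cutoff))
  invisible(x)
}

#' Remove slope outliers across a set of regressions
#'
#' Flags observations whose Cook's distance exceeds 4/N in *any* of the
#' configured regressions (the union rule), removes them, and re-fits every
#' regression on the retained participants.
#'
#' @param data Participant-level data.frame.
#' @param outcome Outcome column name.
#' @param predictors Character vector of environment-score columns; one
#'   regression is run per predictor.
#' @param covariates Optional covariate column names shared by all
#'   regressions.
#' @return List: `removed` and `kept` (row indices of `data`), `n_removed`,
#'   `refits` (named list of `env_regression` on the retained set), and
#'   `initial` (the pre-removal regressions).
#' @export
slope_outlier_filter <- function(data, outcome, predictors,
                                 covariates = character()) {
  initial <- lapply(predictors, function(p)
    env_regression(data, outcome, p, covariates))
  names(initial) <- predictors
  out_any <- rep(FALSE, nrow(data))
  for (r in initial) {
    cd <- r$cooks_distance
    cd[!is.finite(cd)] <- 0  # zero-residual fits give 0/0
    out_any <- out_any | (cd > r$cutoff)
  }
  kept <- which(!out_any)
  if (length(kept) < 3) {
    stop("slope-outlier removal would leave fewer than 3 observations",
         call. = FALSE)
  }
  refits <- lapply(predictors, function(p)
    env_regression(data[kept, , drop = FALSE], outcome, p, covariates))
  names(refits) <- predictors
  list(removed = which(out_any), kept = kept, n_removed = sum(out_any),
       refits = refits, initial = initial)
}

#' Fixed-effects (inverse-variance) meta-analysis
#'
#' Pools per-study regression coefficients under a common-effect model:
#' weights `w_i = 1/se_i^2`, pooled effect `sum(w b)/sum(w)`, pooled SE
#' `1/sqrt(sum(w))`, normal z test, 95\% CI at +/- 1.96 SE, heterogeneity
#' `Q = sum(w (b - pooled)^2)` on k - 1 df, and each study's contribution as
#' its normalized weight.
#'
#' @param beta Numeric vector of per-study effect estimates.
#' @param se Positive per-study standard errors.
#' @param labels Optional study labels.
#' @return List of class `meta_fixed`: `beta_pooled`, `se_pooled`, `z`, `p`,
#'   `ci_low`, `ci_high`, `Q`, `df`, `q_p`, `weights` (normalized, summing
#'   to 1), `studies` (input table).
#' @export
#' @examples
#' meta_fixed(c(0.13, 0.037), c(0.05, 0.03),
#'            labels = c("pilot", "replication"))
meta_fixed <- function(beta, se, labels = NULL) {
  k <- length(beta)
  if (k < 2) stop("need at least 2 studies", call. = FALSE)
  if (length(se) != k) stop("beta and se lengths differ", call. = FALSE)
  if (any(!is.finite(se) | se <= 0)) {
    stop("all standard errors must be > 0", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("study", seq_len(k))
  w <- 1 / se^2
  bp <- sum(w * beta) / sum(w)
  sp <- 1 / sqrt(sum(w))
  z <- bp / sp
  q <- sum(w * (beta - bp)^2)
  structure(
    list(beta_pooled = bp, se_pooled = sp, z = z,
         p = 2 * (1 - pnorm(abs(z))),
         ci_low = bp - 1.96 * sp, ci_high = bp + 1.96 * sp,
         Q = q, df = k - 1L, q_p = 1 - pchisq(q, k - 1L),
         weights = w / sum(w),
         studies = data.frame(label = labels, beta = beta, se = se)),
    class = "meta_fixed"
  )
}

#' @export
print.meta_fixed <- function(x, digits = 3, ...) {
  cat("Fixed-effects meta-analysis\n")
  st <- x$studies
  span <- max(abs(c(st$beta - 1.96 * st$se, st$beta + 1.96 * st$se,
                    x$ci_low, x$ci_high, 0)))
  bar <- function(b, lo, hi) {
    w <- 30
    pos <- function(v) 1 + round((v + span) / (2 * span) * (w - 1))
    line <- rep("-", w)
    line[pos(lo):pos(hi)] <- "="
    line[pos(0)] <- "|"
    line[pos(b)] <- "*"
    paste(line, collapse = "")
  }
  for (i in seq_len(nrow(st))) {
    cat(sprintf("  %-14s %s  %6.3f [%6.3f, %6.3f]  w = %2.0f%%\n",
                st$label[i],
                bar(st$beta[i], st$beta[i] - 1.96 * st$se[i],
                    st$beta[i] + 1.96 * st$se[i]),
                st$beta[i], st$beta[i] - 1.96 * st$se[i],
                st$beta[i] + 1.96 * st$se[i], 100 * x$weights[i]))
  }
  cat(sprintf("  %-14s %s  %6.3f [%6.3f, %6.3f]\n", "pooled",
              bar(x$beta_pooled, x$ci_low, x$ci_high),
              x$beta_pooled, x$ci_low, x$ci_high))
  cat(sprintf("  z = %.2f, p = %.3g; Q = %.2f (df %d, p = %.3g)\n",
              x$z, x$p, x$Q, x$df, x$q_p))
  invisible(x)
}

#' Read a study-effects table for meta-analysis
#'
#' Expects delimited text with columns `study`, `beta`, `se` (comment lines
#' starting with `#` ignored).
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return The validated data.frame.
#' @export
read_study_effects <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("study", "beta", "se")
  if (!all(need %in% names(d))) {
    stop("study-effects table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(d$se) | d$se <= 0)) {
    stop("all se values must be positive", call. = FALSE)
  }
  d
}
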