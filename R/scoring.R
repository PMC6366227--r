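#' Score childhood unpredictability items
#'
#' Averages the three household-chaos items (1..7 agreement scale) and
#' z-scores the mean against a cohort reference. Higher scores mean a less
#' predictable childhood environment.
#'
#' @param items Numeric matrix (n x 3) or vector of 3 item responses in 1..7.
#' @param cohort_mean,cohort_sd Reference mean and sd for z-scoring; when
#'   `NULL` (default) they are taken from `items` itself, which must then
#'   contain at least 2 rows.
#' @return Data.frame with columns `raw` and `z`.
#' @export
#' @examples
#' score_unpredictability(c(1, 1, 1), cohort_mean = 2.5, cohort_sd = 1)
score_unpredictability <- function(items, cohort_mean = NULL,
                                   cohort_sd = NULL) {
  items <- .check_items(items, scale_max = 7)
  raw <- rowMeans(items)
  .zscore_against(raw, cohort_mean, cohort_sd)
}

#' Score childhood harshness items
#'
#' The three items ask about perceived childhood wealth; responses are
#' reverse-coded (`8 - item` on the 1..7 scale) before averaging so that
#' higher scores mean a harsher (more resource-scarce) environment, then
#' z-scored against a cohort reference.
#'
#' @inheritParams score_unpredictability
#' @return Data.frame with columns `raw` and `z`.
#' @export
#' @examples
#' score_harshness(c(7, 7, 7))[, "raw"]  # reversed to (1,1,1) -> 1
score_harshness <- function(items, cohort_mean = NULL, cohort_sd = NULL) {
  items <- .check_items(items, scale_max = 7)
  raw <- rowMeans(8 - items)
  .zscore_against(raw, cohort_mean, cohort_sd)
}

.check_items <- function(items, scale_max) {
  if (is.vector(items)) items <- matrix(items, nrow = 1)
  items <- as.matrix(items)
  ok <- is.finite(items) & items >= 1 & items <= scale_max
  if (!all(ok)) {
    stop("item responses must lie in 1..", scale_max, call. = FALSE)
  }
  items
}

.zscore_against <- function(raw, cohort_mean, cohort_sd) {
  if (is.null(cohort_mean)) cohort_mean <- mean(raw)
  if (is.null(cohort_sd)) cohort_sd <- sd(raw)
  if (!is.finite(cohort_sd) || cohort_sd <= 0) {
    stop("degenerate cohort: zero variance in composite scores, ",
         "z-scores undefined", call. = FALSE)
  }
  data.frame(raw = raw, z = (raw - cohort_mean) / cohort_sd)
}

#' Childhood adversity composite
#'
#' The sum of the z-scored unpredictability and harshness composites.
#'
#' @param unpredictability_z,harshness_z Numeric vectors of z-scores.
#' @return Numeric vector, exact sum.
#' @export
score_adversity <- function(unpredictability_z, harshness_z) {
  stopifnot(is.finite(unpredictability_z), is.finite(harshness_z))
  unpredictability_z + harshness_z
}

#' Score a participant table
#'
#' Computes the questionnaire composites for a whole cohort: raw means,
#' cohort z-scores and the adversity sum. z-references are the scored
#' cohort's own mean and sd.
#'
#' @param participants Data.frame with item columns `u1..u3` (unpredictability)
#'   and `h1..h3` (wealth items, reverse-coded internally).
#' @return `participants` with columns `unpredictability_raw`,
#'   `unpredictability_z`, `harshness_raw`, `harshness_z`, `adversity`
#'   appended.
#' @export
score_cohort <- function(participants) {
  u <- as.matrix(participants[, c("u1", "u2", "u3")])
  h <- as.matrix(participants[, c("h1", "h2", "h3")])
  su <- score_unpredictability(u)
  sh <- score_harshness(h)
  participants$unpredictability_raw <- su$raw
  participants$unpredictability_z <- su$z
  participants$harshness_raw <- sh$raw
  participants$harshness_z <- sh$z
  participants$adversity <- score_adversity(su$z, sh$z)
  participants
}

#' Mean rating change per feedback condition
#'
#' The signed mean of `x_post - x_ini` over a participant's trials of each
#' condition. Positive values mean ratings increased at post-test.
#'
#' @param trials A participant's trial data.frame with columns `condition`,
#'   `x_ini`, `x_post`.
#' @return Named numeric vector over the six conditions; `NA` marks a
#'   condition with no retained trials.
#' @export
mean_rating_change <- function(trials) {
  change <- trials$x_post - trials$x_ini
  vapply(FEEDBACK_CONDITIONS, function(cc) {
    idx <- trials$condition == cc
    if (!any(idx)) NA_real_ else mean(change[idx])
  }, numeric(1))
}

#' Social alignment scores
#'
#' Flips the sign of the mean rating change in the two negative-disagreement
#' conditions, so that positive alignment always means adjustment towards
#' the group opinion; the overall score is the unweighted mean over the four
#' disagreement conditions.
#'
#' @param mean_change Named numeric vector as returned by
#'   [mean_rating_change] (only the four disagreement entries are used).
#' @return List with `alignment` (named vector over the four disagreement
#'   conditions) and `overall`.
#' @export
#' @examples
#' mc <- c(NEG_STRONG = -0.99, NEG_MODERATE = -0.6,
#'         POS_MODERATE = 0.42, POS_STRONG = 0.75)
#' social_alignment(mc)
social_alignment <- function(mean_change) {
  conds <- c("NEG_STRONG", "NEG_MODERATE", "POS_MODERATE", "POS_STRONG")
  if (!all(conds %in% names(mean_change))) {
    stop("mean_change must carry the four disagreement conditions",
         call. = FALSE)
  }
  flip <- ifelse(grepl("^NEG", conds), -1, 1)
  alignment <- flip * mean_change[conds]
  list(alignment = alignment, overall = mean(alignment))
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a k-item scale:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item sums))`, using
#' n-1 sample variances.
#'
#' @param item_matrix Numeric matrix, participants in rows, items in columns
#'   (n >= 2, k >= 2).
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need n >= 2 rows and k >= 2 items", call. = FALSE)
  total_var <- var(rowSums(m))
  if (!is.finite(total_var) || total_var <= 0) {
    stop("undefined alpha: total-score variance is zero", call. = FALSE)
  }
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
}

#' Interquartile-range outlier screen
#'
#' Flags values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`. Quartiles use linear
#' interpolation (`quantile(type = 7)`, R's default); exclusion counts can
#' depend on this choice, which is therefore fixed.
#'
#' @param values Numeric vector, length >= 4.
#' @return Logical vector, `TRUE` for excluded values, with attributes
#'   `lower` and `upper` giving the fences.
#' @export
#' @examples
#' iqr_exclude(c(1, 2, 3, 4, 100))
iqr_exclude <- function(values) {
  if (length(values) < 4) stop("need at least 4 values", call. = FALSE)
  q <- quantile(values, c(0.25, 0.75), na.rm = TRUE, names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lower <- q[1] - 1.5 * iqr
  upper <- q[2] + 1.5 * iqr
  out <- !is.na(values) & (values < lower | values > upper)
  attr(out, "lower") <- lower
  attr(out, "upper") <- upper
  out
}

#' Behavioural summary of a trial table
#'
#' Per participant: mean rating change in each condition, the four alignment
#' scores and the overall alignment score.
#'
#' @param trials Trial table with a `participant_id` column.
#' @return Data.frame, one row per participant, columns `change_<condition>`,
#'   `align_<disagreement condition>`, `alignment_overall`.
#' @export
summarise_alignment <- function(trials) {
  ids <- unique(trials$participant_id)
  rows <- lapply(ids, function(id) {
    tr <- trials[trials$participant_id == id, , drop = FALSE]
    mc <- mean_rating_change(tr)
    al <- social_alignment(mc)
    out <- data.frame(participant_id = id)
    for (cc in FEEDBACK_CONDITIONS) out[[paste0("change_", cc)]] <- mc[[cc]]
    for (cc in names(al$alignment)) out[[paste0("align_", cc)]] <- al$alignment[[cc]]
    out$alignment_overall <- al$overall
    out
  })
  do.call(rbind, rows)
}
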