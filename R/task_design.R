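#' Feedback condition labels
#'
#' The six trial types of the face re-rating task. Twelve disagreement trials
#' are split 3/3/3/3 over the four offset conditions, and the two control
#' conditions (agreement, no feedback) get six trials each.
#'
#' @format Character vector of the six condition labels.
#' @export
FEEDBACK_CONDITIONS <- c(
  "NEG_STRONG", "NEG_MODERATE", "AGREE",
  "POS_MODERATE", "POS_STRONG", "NO_FEEDBACK"
)

# trials per condition in one 24-face block
.CONDITION_COUNTS_24 <- c(
  NEG_STRONG = 3L, NEG_MODERATE = 3L, POS_MODERATE = 3L, POS_STRONG = 3L,
  AGREE = 6L, NO_FEEDBACK = 6L
)

.CONDITION_OFFSETS <- c(
  NEG_STRONG = -3L, NEG_MODERATE = -2L, AGREE = 0L,
  POS_MODERATE = 2L, POS_STRONG = 3L, NO_FEEDBACK = NA_integer_
)

#' Nominal group-rating offset of a feedback condition
#'
#' @param condition Character vector of condition labels (see
#'   [FEEDBACK_CONDITIONS]).
#' @return Integer vector of nominal offsets: -3, -2, 0, +2, +3; `NA` for
#'   `NO_FEEDBACK` trials, which display no group rating.
#' @export
#' @examples
#' condition_offset(c("NEG_STRONG", "AGREE", "NO_FEEDBACK"))
condition_offset <- function(condition) {
  if (!all(condition %in% FEEDBACK_CONDITIONS)) {
    stop("unknown condition label(s): ",
         paste(setdiff(condition, FEEDBACK_CONDITIONS), collapse = ", "),
         call. = FALSE)
  }
  unname(.CONDITION_OFFSETS[condition])
}

#' Is a condition a disagreement condition?
#'
#' @inheritParams condition_offset
#' @return Logical vector; `TRUE` for the four +/-2, +/-3 conditions.
#' @export
is_disagreement <- function(condition) {
  condition %in% c("NEG_STRONG", "NEG_MODERATE", "POS_MODERATE", "POS_STRONG")
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build a randomized trial schedule
#'
#' Assigns the condition multiset (3/3/3/3 disagreement, 6 agreement,
#' 6 no-feedback per 24 faces) to faces by a uniformly random permutation.
#' The condition is a property of the face: the same face carries the same
#' feedback type in the test and post-test phases.
#'
#' @param seed Integer seed; the schedule is deterministic given `seed`.
#' @param n_faces Number of faces; must be a positive multiple of 8 so the
#'   3:3:3:3:6:6 design ratio is preserved (24 in the study).
#' @return A data.frame of class `trial_schedule` with columns `face_id`,
#'   `condition`, `offset_nominal`, one row per face, and attribute `seed`.
#' @export
#' @examples
#' sched <- build_schedule(seed = 1)
#' table(sched$condition)
build_schedule <- function(seed, n_faces = 24L) {
  if (length(n_faces) != 1L || !is.finite(n_faces) || n_faces <= 0 ||
      n_faces %% 8 != 0) {
    stop("invalid design: `n_faces` must be a positive multiple of 8, got ",
         n_faces, call. = FALSE)
  }
  n_faces <- as.integer(n_faces)
  counts <- .CONDITION_COUNTS_24 * (n_faces / 24)
  multiset <- rep(names(counts), times = counts)
  conditions <- with_preserved_seed(seed, sample(multiset))
  out <- data.frame(
    face_id = seq_len(n_faces),
    condition = conditions,
    offset_nominal = unname(.CONDITION_OFFSETS[conditions]),
    stringsAsFactors = FALSE
  )
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("trial_schedule", class(out))
  out
}

#' Compute the bogus group rating for a trial
#'
#' Agreement trials echo the participant's initial rating; disagreement
#' trials add the condition's nominal offset, clipped to the 1..8 scale with
#' a flag when clipping changed the displayed deviation; no-feedback trials
#' return `NA`.
#'
#' @param initial_rating Integer vector of initial ratings on the 1..8 scale.
#' @param condition Character vector of condition labels, recycled against
#'   `initial_rating`.
#' @return A data.frame with columns `group_rating` (integer or `NA`) and
#'   `clipped` (logical; `FALSE` for agreement/no-feedback trials).
#' @export
#' @examples
#' compute_feedback(c(5L, 4L, 7L), c("POS_STRONG", "AGREE", "POS_STRONG"))
compute_feedback <- function(initial_rating, condition) {
  if (any(!is.finite(initial_rating) | initial_rating < 1 |
          initial_rating > 8 | initial_rating != round(initial_rating))) {
    stop("initial_rating must be integers on the 1..8 scale", call. = FALSE)
  }
  if (!all(condition %in% FEEDBACK_CONDITIONS)) {
    stop("unknown condition label(s): ",
         paste(setdiff(condition, FEEDBACK_CONDITIONS), collapse = ", "),
         call. = FALSE)
  }
  n <- max(length(initial_rating), length(condition))
  initial_rating <- as.integer(rep_len(initial_rating, n))
  condition <- rep_len(condition, n)
  offset <- .CONDITION_OFFSETS[condition]
  raw <- initial_rating + offset
  group <- pmin(pmax(raw, 1L), 8L)
  clipped <- !is.na(raw) & group != raw
  group[condition == "NO_FEEDBACK"] <- NA_integer_
  clipped[condition == "NO_FEEDBACK"] <- FALSE
  data.frame(group_rating = as.integer(group), clipped = clipped)
}
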