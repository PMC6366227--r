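# Table schemas for the two input tables and validation helpers.

.TRIAL_COLS <- c("participant_id", "face_id", "condition", "x_ini",
                 "x_group", "x_post")
.PARTICIPANT_COLS <- c("participant_id", "u1", "u2", "u3", "h1", "h2", "h3",
                       "age", "gender")

.check_range <- function(d, col, lo, hi, what, allow_na = FALSE) {
  v <- d[[col]]
  bad <- !is.na(v) & (v < lo | v > hi | v != round(v))
  if (!allow_na) bad <- bad | is.na(v)
  if (any(bad)) {
    stop(sprintf("%s: column '%s' out of range %d..%d at row(s) %s",
                 what, col, lo, hi,
                 paste(utils::head(which(bad), 5), collapse = ", ")),
         call. = FALSE)
  }
}

.check_cols <- function(d, cols, what) {
  missing_cols <- setdiff(cols, names(d))
  if (length(missing_cols)) {
    stop(what, ": missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
}

#' Read and validate a trial-level table
#'
#' Delimited text with one row per participant x face: `participant_id`,
#' `face_id`, `condition`, `x_ini`, `x_group` (empty/NA on no-feedback
#' trials), `x_post`. Lines starting with `#` (provenance headers) are
#' skipped. Ratings are checked against the 1..8 scale and condition labels
#' against [FEEDBACK_CONDITIONS]; errors name the offending rows.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return Validated data.frame.
#' @export
read_trial_table <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                         stringsAsFactors = FALSE)
  .check_cols(d, .TRIAL_COLS, "trial table")
  bad <- !d$condition %in% FEEDBACK_CONDITIONS
  if (any(bad)) {
    stop("trial table: unknown condition at row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  .check_range(d, "x_ini", 1L, 8L, "trial table")
  .check_range(d, "x_post", 1L, 8L, "trial table")
  .check_range(d, "x_group", 1L, 8L, "trial table", allow_na = TRUE)
  no_fb <- d$condition == "NO_FEEDBACK"
  if (any(!is.na(d$x_group[no_fb]))) {
    stop("trial table: NO_FEEDBACK rows must have empty x_group",
         call. = FALSE)
  }
  if (any(is.na(d$x_group[!no_fb]))) {
    stop("trial table: missing x_group on feedback rows ",
         paste(utils::head(which(!no_fb & is.na(d$x_group)), 5),
               collapse = ", "), call. = FALSE)
  }
  d
}

#' Read and validate a participant-level table
#'
#' Delimited text with columns `participant_id`, questionnaire items
#' `u1..u3`, `h1..h3` (1..7), `age`, `gender`.
#'
#' @inheritParams read_trial_table
#' @return Validated data.frame.
#' @export
read_participant_table <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                         stringsAsFactors = FALSE)
  .check_cols(d, .PARTICIPANT_COLS, "participant table")
  for (cc in c("u1", "u2", "u3", "h1", "h2", "h3")) {
    .check_range(d, cc, 1L, 7L, "participant table")
  }
  d
}

#' Write a table as delimited text with a provenance header
#'
#' Prepends a single `#` comment line recording the package version, seed
#' and a config digest, so every artifact records how it was produced;
#' [read_trial_table] and friends skip it on ingestion.
#'
#' @param d Data.frame.
#' @param path Output path.
#' @param seed Seed to record (or `NA`).
#' @param config_hash Short string identifying the run configuration.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_table_prov <- function(d, path, seed = NA, config_hash = "", sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# socialign %s | seed=%s | config=%s",
                     as.character(utils::packageVersion("socialign")),
                     as.character(seed), config_hash), con)
  utils::write.table(d, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Small stable digest of a configuration list (no external deps).
.config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251 + 1)) %%
            4294967291)
}
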