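TRIAL_COLUMNS <- c("participant_id", "condition", "status", "probe",
                   "study_list", "response", "rt_seconds")

#' Read and write trial tables
#'
#' The trial-table interchange format is a UTF-8 CSV with a header row and
#' columns `participant_id`, `condition`, `status` (`target`/`lure`),
#' `probe`, `study_list` (the studied words joined by semicolons),
#' `response` (`old`/`new`, possibly empty) and `rt_seconds`.  Malformed
#' rows are reported with their line numbers.
#'
#' @param path File path.
#' @return `read_trial_table()`: a data.frame of trials.
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(miss) > 0L) {
    stop("trial table missing column(s): ", paste(miss, collapse = ", "))
  }
  rt <- suppressWarnings(as.numeric(df$rt_seconds))
  bad <- which(!is.na(df$rt_seconds) & nzchar(df$rt_seconds) & is.na(rt))
  if (length(bad) > 0L) {
    stop("non-numeric rt_seconds at data line(s) ",
         paste(utils::head(bad + 1L, 5L), collapse = ", "))
  }
  df$rt_seconds <- rt
  df$response[!nzchar(df$response)] <- NA_character_
  bad_status <- which(!df$status %in% c("target", "lure"))
  if (length(bad_status) > 0L) {
    stop("unknown status label at data line(s) ",
         paste(utils::head(bad_status + 1L, 5L), collapse = ", "),
         " (expected 'target' or 'lure')")
  }
  bad_resp <- which(!is.na(df$response) & !df$response %in% c("old", "new"))
  if (length(bad_resp) > 0L) {
    stop("unknown response label at data line(s) ",
         paste(utils::head(bad_resp + 1L, 5L), collapse = ", "))
  }
  df[TRIAL_COLUMNS]
}

#' @rdname read_trial_table
#' @param trials Trial-table data.frame.
#' @return `write_trial_table()`: `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  miss <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(miss) > 0L) {
    stop("trial table missing column(s): ", paste(miss, collapse = ", "))
  }
  utils::write.csv(trials[TRIAL_COLUMNS], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

# Split the semicolon-joined study lists of a trial table.
study_lists <- function(trials) {
  strsplit(trials$study_list, ";", fixed = TRUE)
}

#' Read and write run configurations
#'
#' A run configuration is a flat JSON object capturing everything needed to
#' reproduce a model run: data paths, the similarity scheme, sampler
#' settings and the seed.  Round-trips through
#' [jsonlite::write_json()]/[jsonlite::read_json()].
#'
#' @param config Named list.
#' @param path File path.
#' @return `read_run_config()`: a named list; `write_run_config()`: `path`,
#'   invisibly.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
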