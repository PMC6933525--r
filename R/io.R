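# Canonical CSV interchange for trial tables.
#
# Column order: subject, trial, s1_choice, transition, s2_state, s2_choice,
# reward, rt1, rt2, option_latent. RT columns and the latent flag are written
# only when present; the "observed" export always drops the latent flag.

TRIAL_COLUMNS <- c(
  "subject", "trial", "s1_choice", "transition", "s2_state",
  "s2_choice", "reward", "rt1", "rt2", "option_latent"
)
REQUIRED_COLUMNS <- TRIAL_COLUMNS[1:7]

# Expected transition label for an (s1_choice, s2_state) pair under a variant.
expected_transition <- function(variant, s1_choice, s2_state) {
  designated <- ifelse(s1_choice == "L1", "green", "yellow")
  if (variant == "redstate_expt2") {
    ifelse(s2_state == "red", "rare",
      ifelse(s2_state == designated, "common", NA_character_)
    )
  } else {
    ifelse(s2_state == designated, "common",
      ifelse(s2_state %in% c("green", "yellow"), "rare", NA_character_)
    )
  }
}

#' Validate a trial table
#'
#' Checks the schema (required columns, enum domains), per-subject trial
#' contiguity (1-based consecutive indices), and -- when a task variant is
#' given -- consistency of each row's transition label with its
#' (`s1_choice`, `s2_state`) pair. Errors name the offending rows.
#'
#' @param data A trial table.
#' @param variant Optional task variant name for transition validation.
#' @return The table, invisibly, if valid.
#' @export
validate_trials <- function(data, variant = NULL) {
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(data))
  if (length(missing_cols) > 0) {
    stop("Missing required column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(data) == 0) stop("Empty trial table.", call. = FALSE)
  if (anyDuplicated(data[c("subject", "trial")])) {
    stop("Duplicate (subject, trial) keys.", call. = FALSE)
  }
  bad_enum <- which(
    !data$s1_choice %in% STAGE1_ACTIONS |
      !data$s2_choice %in% STAGE2_ACTIONS |
      !data$s2_state %in% STAGE2_STATES |
      !data$transition %in% c("common", "rare")
  )
  if (length(bad_enum) > 0) {
    stop("Invalid label(s) at row(s): ", paste(utils::head(bad_enum, 5), collapse = ", "),
      call. = FALSE
    )
  }
  contiguous <- data |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(
      ok = all(sort(.data$trial) == seq_along(.data$trial)),
      .groups = "drop"
    )
  if (!all(contiguous$ok)) {
    stop(
      "Non-contiguous trial indices for subject(s): ",
      paste(utils::head(contiguous$subject[!contiguous$ok], 5), collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.null(variant)) {
    exp_tr <- expected_transition(variant, data$s1_choice, data$s2_state)
    bad <- which(is.na(exp_tr) | exp_tr != data$transition)
    if (length(bad) > 0) {
      stop(
        "Transition label inconsistent with (s1_choice, s2_state) under '",
        variant, "' at row(s): ", paste(utils::head(bad, 5), collapse = ", "),
        call. = FALSE
      )
    }
  }
  invisible(data)
}

#' Write a trial table to CSV
#'
#' Deterministic column order, full-precision floats, UTF-8, `\n` newlines.
#' With `observed = TRUE` (default) the latent sequence-use column is
#' dropped, matching what a human study records.
#'
#' @param data A trial table.
#' @param path Output file path.
#' @param observed Drop the `option_latent` column.
#' @return `path`, invisibly.
#' @export
write_trials <- function(data, path, observed = TRUE) {
  cols <- intersect(TRIAL_COLUMNS, names(data))
  if (observed) cols <- setdiff(cols, "option_latent")
  out <- as.data.frame(data)[, cols]
  for (nm in intersect(c("reward", "rt1", "rt2"), cols)) {
    out[[nm]] <- formatC(out[[nm]], digits = 15, format = "g")
  }
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Reads a CSV in the documented schema and validates it (see
#' [validate_trials()]).
#'
#' @param path Input file path.
#' @param variant Optional task variant name for transition validation.
#' @return A validated tibble.
#' @export
read_trials <- function(path, variant = NULL) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("Empty input file: ", path, call. = FALSE)
  data <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (nrow(data) == 0) stop("Input file has a header but no rows: ", path, call. = FALSE)
  if ("option_latent" %in% names(data)) {
    data$option_latent <- as.logical(data$option_latent)
  }
  validate_trials(data, variant = variant)
  data
}
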