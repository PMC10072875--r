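#' Write signals to the package's on-disk container
#'
#' The container is a directory holding one little-endian float64 `.bin` file
#' per channel plus a `meta.json` sidecar with the format version and the
#' per-channel sampling rate, start time, units and sample count. Raw binary
#' doubles round-trip bit-exactly and remain readable from any language.
#'
#' @param signals A list of [cont_signal] objects with unique labels.
#' @param path Directory to create (or overwrite) as the container.
#' @return `path`, invisibly.
#' @seealso [read_signal_container()]
#' @export
write_signal_container <- function(signals, path) {
  if (inherits(signals, "cont_signal")) signals <- list(signals)
  stopifnot(length(signals) >= 1)
  labels <- vapply(signals, function(s) attr(s, "label"), character(1))
  if (anyDuplicated(labels)) stop("duplicate channel labels: ",
    paste(unique(labels[duplicated(labels)]), collapse = ", "))
  for (s in signals) {
    if (!all(is.finite(as.numeric(s)))) stop("non-finite samples in channel ", attr(s, "label"))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    format = "attnephys-signal-container",
    version = 1L,
    channels = lapply(seq_along(signals), function(i) {
      s <- signals[[i]]
      list(
        label = attr(s, "label"), file = paste0("ch", i, ".bin"),
        fs = signal_fs(s), t0 = signal_t0(s),
        units = attr(s, "units"), n = length(s)
      )
    })
  )
  for (i in seq_along(signals)) {
    con <- file(file.path(path, paste0("ch", i, ".bin")), "wb")
    writeBin(as.numeric(signals[[i]]), con, size = 8, endian = "little")
    close(con)
  }
  jsonlite::write_json(meta, file.path(path, "meta.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read signals back from a container directory
#'
#' Exact inverse of [write_signal_container()]: sample values, sampling rates,
#' start times, labels and units are restored bit-for-bit.
#'
#' @param path Container directory written by [write_signal_container()].
#' @return A named list of [cont_signal] objects (names = channel labels).
#' @export
read_signal_container <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("missing metadata sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path)
  for (key in c("format", "version", "channels")) {
    if (is.null(meta[[key]])) stop("corrupt metadata sidecar: missing key '", key, "'")
  }
  if (!identical(as.integer(meta$version), 1L)) {
    stop("unknown container format version: ", meta$version)
  }
  out <- lapply(meta$channels, function(ch) {
    for (key in c("label", "file", "fs", "t0", "units", "n")) {
      if (is.null(ch[[key]])) stop("corrupt channel metadata: missing key '", key, "'")
    }
    f <- file.path(path, ch$file)
    if (!file.exists(f)) stop("missing channel data file: ", f)
    n <- as.integer(ch$n)
    if (file.size(f) != 8 * n) stop("truncated channel data file: ", f)
    con <- file(f, "rb")
    vals <- readBin(con, "double", n = n, size = 8, endian = "little")
    close(con)
    cont_signal(vals, fs = as.numeric(ch$fs), t0 = as.numeric(ch$t0),
                label = ch$label, units = ch$units)
  })
  names(out) <- vapply(out, function(s) attr(s, "label"), character(1))
  out
}

trial_csv_columns <- c(
  "index", "task", "cue_length_s", "delay_s", "correct_port", "chosen_port",
  "init_time_s", "cue_on_s", "cue_off_s", "choice_time_s", "outcome"
)

#' Construct and validate a behavioral session table
#'
#' One row per initiated trial, ordered in time. Enforces the trial-record
#' invariants: cue offset equals onset plus cue length, omissions are exactly
#' the trials with no chosen port, choices never precede cue onset, trial
#' times strictly increase, and a session holds at most 100 trials or lasts at
#' most 80 minutes (animals work until 80 min have passed or 100 trials are
#' done, whichever comes first).
#'
#' @param trials A data frame with columns `r paste(trial_csv_columns, collapse = ", ")`.
#'   Missing times and `chosen_port` for omissions are `NA`.
#' @param session_duration_s Total session length in seconds.
#' @param animal_id,genotype,day Metadata strings, carried as attributes.
#' @return A tibble of class `session_table`.
#' @export
session_table <- function(trials, session_duration_s,
                          animal_id = "sim", genotype = "WT", day = "1") {
  trials <- tibble::as_tibble(trials)
  missing_cols <- setdiff(trial_csv_columns, names(trials))
  if (length(missing_cols) > 0) stop("trial table missing columns: ",
    paste(missing_cols, collapse = ", "))
  trials <- trials[trial_csv_columns]
  if (!is.numeric(session_duration_s) || session_duration_s <= 0) {
    stop("session_duration_s must be positive")
  }
  n <- nrow(trials)
  if (n > 100 && session_duration_s > 4800) {
    stop("session exceeds both the 100-trial and the 80-minute cap")
  }
  if (n > 0) {
    bad_task <- !trials$task %in% c("AET", "VDST")
    if (any(bad_task)) stop("unknown task in rows: ", paste(which(bad_task), collapse = ", "))
    bad_cue <- abs(trials$cue_off_s - (trials$cue_on_s + trials$cue_length_s)) > 1e-9
    bad_cue[is.na(bad_cue)] <- FALSE
    if (any(bad_cue)) stop("cue_off_s != cue_on_s + cue_length_s in rows: ",
      paste(which(bad_cue), collapse = ", "))
    is_none <- is.na(trials$chosen_port) | trials$chosen_port == "none"
    bad_om <- xor(is_none, trials$outcome == "omission")
    if (any(bad_om)) stop("outcome inconsistent with chosen_port in rows: ",
      paste(which(bad_om), collapse = ", "))
    resp <- !is_none & !is.na(trials$choice_time_s)
    bad_choice <- resp & trials$choice_time_s < trials$cue_on_s
    if (any(bad_choice)) stop("choice_time_s precedes cue_on_s in rows: ",
      paste(which(bad_choice), collapse = ", "))
    wrong <- !is_none &
      ((trials$chosen_port == trials$correct_port) != (trials$outcome == "correct"))
    if (any(wrong)) stop("outcome column inconsistent with ports in rows: ",
      paste(which(wrong), collapse = ", "))
    if (n > 1 && any(diff(trials$init_time_s) <= 0)) {
      stop("trial init times must be strictly increasing")
    }
  }
  structure(trials,
    session_duration_s = as.numeric(session_duration_s),
    animal_id = animal_id, genotype = genotype, day = day,
    class = c("session_table", class(trials))
  )
}

#' @rdname session_table
#' @param session A `session_table`.
#' @export
session_duration <- function(session) {
  d <- attr(session, "session_duration_s")
  if (is.null(d)) stop("session_duration_s attribute missing; rebuild with session_table()")
  d
}

#' Read / write behavioral trial tables as CSV
#'
#' Comma-separated, '.' decimal, UTF-8, mandatory header; one column per trial
#' field plus three metadata columns (`animal_id`, `genotype`, `day`) and the
#' session duration repeated per row. Round-trips a [session_table] exactly;
#' the outcome column is re-validated against chosen vs correct port and the
#' omission rule on read, and inconsistent rows raise an error naming them.
#'
#' @param session A [session_table].
#' @param path CSV file path.
#' @return `read_trial_csv()` returns a [session_table];
#'   `write_trial_csv()` returns `path` invisibly.
#' @export
write_trial_csv <- function(session, path) {
  df <- tibble::as_tibble(as.data.frame(session))
  df$session_duration_s <- rep(session_duration(session), length.out = max(nrow(df), 0))
  meta <- tibble::tibble(
    animal_id = character(0), genotype = character(0), day = character(0)
  )
  if (nrow(df) > 0) {
    df$animal_id <- attr(session, "animal_id")
    df$genotype <- attr(session, "genotype")
    df$day <- attr(session, "day")
  } else {
    df <- tibble::as_tibble(c(
      stats::setNames(
        lapply(trial_csv_columns, function(x) if (x %in% c("task", "correct_port", "chosen_port", "outcome")) character(0) else numeric(0)),
        trial_csv_columns
      ),
      list(session_duration_s = numeric(0)), meta
    ))
  }
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  if (!file.exists(path)) stop("no such trial CSV: ", path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      index = readr::col_integer(), task = readr::col_character(),
      cue_length_s = readr::col_double(), delay_s = readr::col_double(),
      correct_port = readr::col_character(), chosen_port = readr::col_character(),
      init_time_s = readr::col_double(), cue_on_s = readr::col_double(),
      cue_off_s = readr::col_double(), choice_time_s = readr::col_double(),
      outcome = readr::col_character(), session_duration_s = readr::col_double(),
      animal_id = readr::col_character(), genotype = readr::col_character(),
      day = readr::col_character()
    ))
  if (nrow(df) == 0) {
    return(session_table(df[trial_csv_columns[trial_csv_columns %in% names(df)]],
      session_duration_s = 4800))
  }
  session_table(df[trial_csv_columns],
    session_duration_s = df$session_duration_s[[1]],
    animal_id = df$animal_id[[1]], genotype = df$genotype[[1]], day = df$day[[1]]
  )
}
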