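#' Accuracy by cue length
#'
#' Percent correct per cue length over responded trials only
#' (`correct / (correct + incorrect) * 100`); omissions are excluded from the
#' denominator and reported separately. Cue lengths with no responded trials
#' are absent from the output.
#'
#' @param session A [session_table] (or trial tibble with `cue_length_s` and
#'   `outcome`).
#' @return A tibble: `cue_length_s`, `n_responded`, `n_correct`,
#'   `pct_correct`, `n_omissions`, `pct_omissions` (over all trials at that
#'   cue), sorted by descending cue length.
#' @export
score_accuracy <- function(session) {
  tibble::as_tibble(as.data.frame(session)) |>
    dplyr::group_by(.data$cue_length_s) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_responded = sum(.data$outcome != "omission"),
      n_correct = sum(.data$outcome == "correct"),
      n_omissions = sum(.data$outcome == "omission"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_correct = ifelse(.data$n_responded > 0,
        100 * .data$n_correct / .data$n_responded, NA_real_),
      pct_omissions = 100 * .data$n_omissions / .data$n_trials
    ) |>
    dplyr::filter(.data$n_responded > 0) |>
    dplyr::arrange(dplyr::desc(.data$cue_length_s))
}

#' Re-apply the omission rule to recorded choices
#'
#' A trial is an omission when the animal makes no choice, or takes longer
#' than `limit_s` (default 5 s) after cue termination to choose. Returns the
#' session with the `outcome` column updated; trials reclassified as
#' omissions keep their chosen port cleared.
#'
#' @param session A [session_table].
#' @param limit_s Post-cue response limit in seconds.
#' @return An updated [session_table].
#' @export
classify_omissions <- function(session, limit_s = 5) {
  tr <- tibble::as_tibble(as.data.frame(session))
  late <- !is.na(tr$choice_time_s) &
    (tr$choice_time_s - tr$cue_off_s) > limit_s
  none <- is.na(tr$chosen_port) | tr$chosen_port == "none" | is.na(tr$choice_time_s)
  omit <- late | none
  tr$outcome[omit] <- "omission"
  tr$chosen_port[omit] <- NA_character_
  tr$choice_time_s[omit] <- NA_real_
  tr$outcome[!omit] <- ifelse(tr$chosen_port[!omit] == tr$correct_port[!omit],
                              "correct", "incorrect")
  session_table(tr, session_duration_s = session_duration(session),
    animal_id = attr(session, "animal_id"), genotype = attr(session, "genotype"),
    day = attr(session, "day"))
}

#' Per-trial reaction times
#'
#' Reaction time is either the time from cue termination to port selection
#' (`anchor = "cue_off"`, the definition used for the accuracy split) or from
#' trial initiation to the response (`anchor = "init"`). Omissions are
#' excluded; trials with negative RT are flagged and excluded.
#'
#' @param session A [session_table].
#' @param anchor "cue_off" or "init".
#' @return A tibble: `index`, `cue_length_s`, `outcome`, `rt_s`.
#' @export
reaction_times <- function(session, anchor = c("cue_off", "init")) {
  anchor <- match.arg(anchor)
  tr <- tibble::as_tibble(as.data.frame(session)) |>
    dplyr::filter(.data$outcome != "omission", !is.na(.data$choice_time_s))
  ref <- if (anchor == "cue_off") tr$cue_off_s else tr$init_time_s
  tr$rt_s <- tr$choice_time_s - ref
  neg <- tr$rt_s < 0
  if (any(neg)) warning(sum(neg), " trial(s) with negative reaction time excluded")
  tr[!neg, c("index", "cue_length_s", "outcome", "rt_s")]
}

#' Repetitive-responding score
#'
#' Counts disjoint blocks of five consecutive same-port choices (omissions
#' excluded): each maximal run of identical ports of length L contributes
#' `floor(L / 5)` blocks; the total is divided by the number of responded
#' trials. With `mode = "sliding"` every window of five within a run counts
#' (`L - 4` per run), for comparison.
#'
#' @param session A [session_table] (or trial tibble).
#' @param mode "disjoint" (default) or "sliding".
#' @return A single score >= 0. Sessions with fewer than 5 responded trials
#'   score 0 with a warning.
#' @export
repetitive_score <- function(session, mode = c("disjoint", "sliding")) {
  mode <- match.arg(mode)
  ch <- session$chosen_port[!is.na(session$chosen_port) &
                            session$chosen_port != "none"]
  n <- length(ch)
  if (n < 5) {
    warning("fewer than 5 responded trials; repetitive score is 0")
    return(0)
  }
  runs <- rle(ch)$lengths
  blocks <- if (mode == "disjoint") sum(runs %/% 5) else sum(pmax(runs - 4, 0))
  blocks / n
}

#' First day the training criterion is met
#'
#' Criterion: at least 70% correct on 3 consecutive days, or at least 90%
#' correct on 2 consecutive days.
#'
#' @param daily_accuracy Vector of daily percent-correct values in \[0, 100\].
#' @return The earliest (1-based) day index satisfying either rule, or
#'   `NA_integer_` if never met.
#' @export
training_criterion <- function(daily_accuracy) {
  stopifnot(all(daily_accuracy >= 0 & daily_accuracy <= 100))
  n <- length(daily_accuracy)
  for (d in seq_len(n)) {
    if (d >= 3 && all(daily_accuracy[(d - 2):d] >= 70)) return(d)
    if (d >= 2 && all(daily_accuracy[(d - 1):d] >= 90)) return(d)
  }
  NA_integer_
}

#' Task-engagement filter
#'
#' A session counts as engaged when trials were initiated at a rate of at
#' least `rate_per_min` (default 1) per minute of session time.
#'
#' @param session A [session_table].
#' @param rate_per_min Required initiation rate.
#' @return Logical.
#' @export
engagement_filter <- function(session, rate_per_min = 1) {
  nrow(session) / (session_duration(session) / 60) >= rate_per_min
}

#' One-row behavioral summary of a session
#'
#' @param session A [session_table].
#' @param rt_anchor Reaction-time anchor (see [reaction_times()]).
#' @return A list: `by_cue` (the [score_accuracy()] table joined with mean RT
#'   for correct and incorrect trials) and `session` (one-row tibble:
#'   `n_trials`, `repetitive_score`, `engaged`, `animal_id`, `genotype`,
#'   `day`).
#' @export
behavior_summary <- function(session, rt_anchor = "cue_off") {
  acc <- score_accuracy(session)
  rt <- reaction_times(session, anchor = rt_anchor) |>
    dplyr::group_by(.data$cue_length_s, .data$outcome) |>
    dplyr::summarise(mean_rt_s = mean(.data$rt_s), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "outcome", values_from = "mean_rt_s",
                       names_prefix = "mean_rt_")
  list(
    by_cue = dplyr::left_join(acc, rt, by = "cue_length_s"),
    session = tibble::tibble(
      n_trials = nrow(session),
      repetitive_score = suppressWarnings(repetitive_score(session)),
      engaged = engagement_filter(session),
      animal_id = attr(session, "animal_id") %||% NA_character_,
      genotype = attr(session, "genotype") %||% NA_character_,
      day = attr(session, "day") %||% NA_character_
    )
  )
}
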