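#' Reduce fixation event streams to word-level fixation measures
#'
#' For each (participant, trial, word): First Fixation (FF) is the duration of
#' the chronologically first fixation on the word; Gaze Duration (GD) is the
#' summed duration of the maximal run of consecutive fixations on the word
#' starting at that first fixation (first pass, ending when the gaze first
#' leaves the word); Total Fixation (TF) is the sum of all fixation durations
#' on the word within the trial. Words bearing no fixation are marked skipped
#' with `NA` measures. The three measures always satisfy `FF <= GD <= TF`.
#'
#' @param fixations Tibble of fixation events with columns `participant_id`,
#'   `trial_id`, `word_index`, `onset`, `duration` (ms). Events must be in
#'   chronological order (non-decreasing onset) within each
#'   (participant, trial); unordered input is an error.
#' @param words Optional tibble `(trial_id, word_index)` enumerating the words
#'   of each trial, so never-fixated words appear as skipped rows. When `NULL`
#'   only fixated words are returned.
#' @return Tibble `(participant_id, trial_id, word_index, skipped, ff, gd,
#'   tf)`.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   participant_id = "p1", trial_id = "t1",
#'   word_index = c(3, 3, 4, 3), onset = c(0, 150, 250, 430),
#'   duration = c(150, 100, 180, 120)
#' )
#' compute_measures(ev) # w3: ff 150, gd 250, tf 370
compute_measures <- function(fixations, words = NULL) {
  need <- c("participant_id", "trial_id", "word_index", "onset", "duration")
  if (!all(need %in% names(fixations))) {
    abort_lexcon(
      paste("fixation events need columns:", paste(need, collapse = ", ")),
      "lexcon_config_error"
    )
  }
  if (any(fixations$duration <= 0)) {
    abort_lexcon("fixation durations must be positive", "lexcon_parse_error")
  }
  bad <- fixations |>
    dplyr::group_by(.data$participant_id, .data$trial_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$onset), .groups = "drop")
  if (any(!bad$ok)) {
    abort_lexcon("fixation onsets are not chronologically ordered within a trial", "lexcon_order_error")
  }
  measured <- fixations |>
    dplyr::group_by(.data$participant_id, .data$trial_id) |>
    dplyr::group_modify(function(d, key) {
      runs <- rle(d$word_index)
      run_id <- rep(seq_along(runs$values), runs$lengths)
      per_run <- tibble::tibble(
        word_index = runs$values,
        run_dur = unname(vapply(split(d$duration, run_id), sum, numeric(1)))
      )
      first_pass <- per_run[!duplicated(per_run$word_index), ]
      first_fix <- d[!duplicated(d$word_index), c("word_index", "duration")]
      tot <- stats::aggregate(duration ~ word_index, d, sum)
      out <- tibble::tibble(
        word_index = first_fix$word_index,
        ff = unname(first_fix$duration),
        gd = unname(first_pass$run_dur[match(first_fix$word_index, first_pass$word_index)]),
        tf = unname(tot$duration[match(first_fix$word_index, tot$word_index)])
      )
      out$skipped <- FALSE
      out
    }) |>
    dplyr::ungroup()
  if (!is.null(words)) {
    grid <- tidyr::expand_grid(
      participant_id = unique(fixations$participant_id),
      dplyr::distinct(words[, c("trial_id", "word_index")])
    )
    measured <- dplyr::left_join(
      grid, measured,
      by = c("participant_id", "trial_id", "word_index")
    ) |>
      dplyr::mutate(skipped = is.na(.data$skipped))
  }
  dplyr::select(
    measured, "participant_id", "trial_id", "word_index",
    "skipped", "ff", "gd", "tf"
  ) |>
    dplyr::arrange(.data$participant_id, .data$trial_id, .data$word_index)
}
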