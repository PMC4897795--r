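# Trial- and sentence-level scoring of response traces.
#
# Nondeterministic slots (those following a box-1 word) cannot be predicted
# with certainty and are masked throughout; sentence-level accuracy
# (SentAcc) is 1 only when every unmasked slot of the sentence was
# predicted correctly.  The final sentence of a sequence lacks a target for
# its trailing slot, so it is excluded from sentence-level summaries.

#' Per-slot accuracy profile of one sentence
#'
#' Extracts the trace's correctness values for one sentence, masking the
#' nondeterministic slots (and any slot without a target) as `NA`.  Entry
#' `i` scores the prediction of word `i + 1` made after observing word `i`;
#' the last entry (`4n` for a level-n sentence) scores the prediction of the
#' following sentence's first word and so houses the trailing 4 -> 1
#' transition.
#'
#' @param trace A single-subject response trace (see [simulate_agent()]).
#' @param sentence_id Sentence id within the driving sequence.
#' @return Numeric vector of length `4n` with values 0, 1, or `NA`
#'   (masked), with attribute `level`.
#' @export
profile_vector <- function(trace, sentence_id) {
  rows <- trace[trace$sentence_id == sentence_id, ]
  if (nrow(rows) == 0L) {
    stop("trace contains no slots for sentence ", sentence_id, call. = FALSE)
  }
  rows <- rows[order(rows$position_in_sentence), ]
  prof <- as.numeric(rows$correct)
  prof[rows$kind == "nondeterministic"] <- NA_real_
  attr(prof, "level") <- rows$sentence_level[1L]
  prof
}

#' Sentence-level accuracy of a profile
#'
#' `SentAcc = 1` iff every unmasked entry of the profile is 1.  A profile
#' with no unmasked entries (impossible for the target language, possible
#' for custom fillers) is vacuously scored 1 with a warning.
#'
#' @param profile Output of [profile_vector()].
#' @return 0 or 1.
#' @export
sentence_accuracy <- function(profile) {
  unmasked <- profile[!is.na(profile)]
  if (length(unmasked) == 0L) {
    warning("all-masked profile: SentAcc is vacuously 1", call. = FALSE)
    return(1L)
  }
  as.integer(all(unmasked == 1))
}

#' Per-sentence SentAcc table for one subject
#'
#' The final sentence of the sequence is excluded (its trailing slot has no
#' target).
#'
#' @param trace Single-subject trace.
#' @param sequence The driving `experiment_sequence`.
#' @return Tibble: `sentence_id`, `sentence_level`, `sent_acc`.
#' @export
sentacc_table <- function(trace, sequence) {
  ids <- sequence$sentences$sentence_id
  ids <- ids[-length(ids)]
  tibble::tibble(
    sentence_id = ids,
    sentence_level = sequence$sentences$level[ids],
    sent_acc = vapply(ids, function(i) {
      sentence_accuracy(profile_vector(trace, i))
    }, integer(1))
  )
}

#' Cohort trajectory of mean sentence prediction accuracy
#'
#' For each sentence position in the sequence, the proportion of subjects
#' who correctly predicted all deterministic transitions of that sentence
#' (mean SentAcc), separated by sentence level.
#'
#' @param traces Cohort trace tibble (see [simulate_cohort()]).
#' @param sequence The driving `experiment_sequence`.
#' @return Tibble: `sentence_id`, `sentence_level`, `phase`, `mean_sentacc`,
#'   `n_subjects`.
#' @export
sentacc_trajectory <- function(traces, sequence) {
  subjects <- unique(traces$subject_id)
  if (length(subjects) == 0L) stop("empty cohort", call. = FALSE)
  per_subj <- dplyr::bind_rows(lapply(subjects, function(s) {
    tab <- sentacc_table(traces[traces$subject_id == s, ], sequence)
    tab$subject_id <- s
    tab
  }))
  out <- dplyr::summarise(
    dplyr::group_by(per_subj, .data$sentence_id, .data$sentence_level),
    mean_sentacc = mean(.data$sent_acc),
    n_subjects = dplyr::n(),
    .groups = "drop"
  )
  out$phase <- sequence$sentences$phase[out$sentence_id]
  out[order(out$sentence_id),
      c("sentence_id", "sentence_level", "phase", "mean_sentacc",
        "n_subjects")]
}

#' Spontaneous generalization at the first instance of a level
#'
#' The fraction of subjects with `SentAcc = 1` on the first sentence of the
#' given embedding level — perfect performance at first encounter of a level
#' deeper than any trained is the signature of recursive generalization.
#'
#' @param traces Cohort trace tibble.
#' @param sequence The driving `experiment_sequence`.
#' @param level Embedding level whose first instance is probed.
#' @return List: `proportion`, `successes`, `n`, `sentence_id`.
#' @export
first_instance_generalization <- function(traces, sequence, level) {
  ids <- sequence$sentences$sentence_id[sequence$sentences$level == level]
  if (length(ids) == 0L) {
    stop("sequence contains no level-", level, " sentence", call. = FALSE)
  }
  first_id <- ids[1L]
  subjects <- unique(traces$subject_id)
  acc <- vapply(subjects, function(s) {
    sentence_accuracy(profile_vector(traces[traces$subject_id == s, ],
                                     first_id))
  }, integer(1))
  list(proportion = mean(acc), successes = sum(acc), n = length(acc),
       sentence_id = first_id)
}

#' Chance level of perfect performance on a novel level-n sentence
#'
#' Conservative binary-guess model: a learner who has not induced the
#' recursive pattern is credited with the certain transitions (2 -> 3 and
#' 3 -> 4), nondeterministic slots are ignored, and at each of the `n`
#' word-4 slots the learner guesses between the two continuations ever
#' observed after a 4 (boxes 1 and 2), succeeding with probability 1/2.
#' The chance of a perfect sentence is therefore `(1/2)^n`.
#'
#' @param n Embedding level (number of word-4 prediction slots).
#' @return Probability `(1/2)^n`.
#' @export
chance_level <- function(n) {
  if (!is.numeric(n) || any(n < 1) || any(n != round(n))) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  0.5^n
}
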