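# Grammar Bearing Point Language Classification Algorithm (GBPLCA).
#
# Bearing-point grammars G_1..G_4 are finite-state approximations of the
# recursive grammar G_R: G_k generates exactly the sentences of levels
# 1..k.  The classifier compares each sentence's empirical accuracy profile
# with the model profiles expected under each grammar and assigns one label
# per processed sentence, yielding an individual grammar trajectory.  G_0
# labels behavior matching no bearing point.

#' Ordered grammar labels
#'
#' @return Character vector `G0 < G1 < G2 < G3 < G4 < GR`.
#' @export
grammar_levels <- function() c("G0", "G1", "G2", "G3", "G4", "GR")

grammar_rank <- function(label) match(label, grammar_levels())

#' Model accuracy profile of grammar G_k on a level-m sentence
#'
#' Expected trial-level accuracies under a learner holding the finite-state
#' grammar G_k (k rules, generating levels 1..k): the certain transitions
#' (2 -> 3, 3 -> 4) are always correct; at the j-th word-4 slot the learner
#' predicts 2 while `j < min(m, k)` and 1 afterwards, so it errs exactly at
#' the 4 -> 2 slots with `k <= j < m` and is correct at the sentence-final
#' 4 -> 1 slot.  Nondeterministic slots (after a 1) are `NA`.
#'
#' @param k Grammar index 1..4 (or `"R"` for the recursive grammar, which
#'   is correct everywhere).
#' @param level Sentence level m >= 1.
#' @return Numeric vector of length `4 * level` with entries 1, 0, `NA`.
#' @export
finite_profile <- function(k, level) {
  m <- as.integer(level)
  cap <- if (identical(k, "R")) m else as.integer(k)
  prof <- rep(1, 4L * m)
  prof[seq_len(m)] <- NA_real_          # after-1 slots, nondeterministic
  four_pos <- m + 3L * seq_len(m)       # word-4 slots, j = 1..m
  j <- seq_len(m)
  prof[four_pos] <- as.numeric((j < pmin(m, cap)) == (j < m))
  prof
}

#' Match an empirical profile against the model profile rows
#'
#' @param profile Profile vector (see [profile_vector()]) with attribute
#'   `level` (or supply `level`).
#' @param level Sentence level if not carried by the profile.
#' @return Integer vector of matching rows `k` (at most one, since rows are
#'   pairwise distinct); empty if none match.
#' @export
match_profile <- function(profile, level = attr(profile, "level")) {
  if (is.null(level)) stop("sentence level unknown", call. = FALSE)
  obs <- !is.na(profile)
  hits <- integer(0)
  for (k in seq_len(min(level, 4L))) {
    expected <- finite_profile(k, level)
    if (all(profile[obs] == expected[obs], na.rm = FALSE)) hits <- c(hits, k)
  }
  hits
}

# Does `other_prof` (most recent profile at another level) show G_k-level
# competence: no unmasked error at any slot where G_k is correct there?
at_least_as_good_as <- function(other_prof, k, other_level) {
  expected <- finite_profile(k, other_level)
  obs <- !is.na(other_prof) & !is.na(expected)
  all(other_prof[obs] >= expected[obs])
}

#' One classification step of the GBPLCA
#'
#' A pure function of the previous label, the current sentence's profile,
#' the most recent profile per other sentence level, and whether this
#' sentence is a first encounter of a novel deepest level.  Rules: perfect
#' performance on a level-N sentence yields the higher of G_N and the
#' previous status, upgraded to G_R when the sentence is the first-ever
#' instance of a level deeper than all levels seen before (and N >= 2 —
#' perfection at the very first level-1 sentence carries no evidence of
#' generalization).  An imperfect profile matching model row k yields G_k
#' provided the learner has recently done at least as well as G_k at every
#' other sentence length; any other (aberrant) behavior yields G_0.
#'
#' @param prev_label Previous grammar label.
#' @param profile Current sentence profile (with `level` attribute).
#' @param recent_profiles Named list, one most-recent profile per sentence
#'   level already seen (names are the levels); levels never seen impose no
#'   constraint.
#' @param first_encounter `TRUE` when the sentence is the first-ever
#'   instance of the deepest level presented so far.
#' @return A grammar label (see [grammar_levels()]).
#' @export
classify_step <- function(prev_label, profile, recent_profiles = list(),
                          first_encounter = FALSE) {
  level <- attr(profile, "level")
  if (is.null(level)) stop("profile lacks a `level` attribute", call. = FALSE)
  unmasked <- profile[!is.na(profile)]
  perfect <- length(unmasked) > 0L && all(unmasked == 1)
  if (level == 0L) {
    # filler sentence: carries no bearing-point evidence; perfect
    # performance preserves the standing label, errors are aberrant
    return(if (perfect) prev_label else "G0")
  }
  if (level > 4L) stop("model profiles are defined for levels 1..4",
                       call. = FALSE)
  if (perfect) {
    if (isTRUE(first_encounter) && level >= 2L) return("GR")
    lab <- paste0("G", level)
    return(grammar_levels()[max(grammar_rank(lab), grammar_rank(prev_label))])
  }
  hits <- match_profile(profile, level)
  for (k in hits) {
    others <- setdiff(names(recent_profiles), as.character(level))
    ok <- all(vapply(others, function(lv) {
      at_least_as_good_as(recent_profiles[[lv]], k, as.integer(lv))
    }, logical(1)))
    if (ok) return(paste0("G", k))
  }
  "G0"
}

#' Grammar trajectory of one subject
#'
#' Applies [classify_step()] sentence-by-sentence with running state (the
#' previous label, the most recent profile per level, and the set of levels
#' seen so far).  Every sentence of the sequence receives a label; the
#' final sentence's trailing slot, which has no target, is simply masked in
#' its profile.
#'
#' @param trace Single-subject response trace.
#' @param sequence The driving `experiment_sequence`.
#' @return Tibble: `sentence_id`, `sentence_level`, `label`.
#' @export
grammar_trajectory <- function(trace, sequence) {
  sents <- sequence$sentences
  labels <- character(nrow(sents))
  prev <- "G0"
  recent <- list()
  seen <- integer(0)
  # The G_R upgrade marks spontaneous generalization: perfection at the
  # first instance of the sequence's deepest embedding level, the one the
  # design withholds until every shallower level has been experienced.
  # Earlier staged introductions (e.g. the first S2 after only S1s) do not
  # qualify: perfection there is indistinguishable online from a
  # finite-state learner one step ahead.
  deepest <- max(sents$level)
  for (i in seq_len(nrow(sents))) {
    lvl <- sents$level[i]
    prof <- profile_vector(trace, sents$sentence_id[i])
    first_enc <- lvl >= 2L && lvl == deepest && !(lvl %in% seen)
    lab <- classify_step(prev, prof, recent, first_encounter = first_enc)
    labels[i] <- lab
    prev <- lab
    recent[[as.character(lvl)]] <- prof
    if (lvl >= 1L) seen <- union(seen, lvl)
  }
  tibble::tibble(sentence_id = sents$sentence_id,
                 sentence_level = sents$level, label = labels)
}

#' Transition count matrix of a grammar trajectory
#'
#' Counts consecutive label pairs.  With `collapse_g0 = TRUE`, runs of G_0
#' are deleted before pairing, so e.g. the series G_1 -> G_0 -> G_2 counts
#' as the single transition G_1 -> G_2 and the G_0 row and column are zero.
#'
#' @param labels Character vector of grammar labels (or a
#'   [grammar_trajectory()] tibble).
#' @param collapse_g0 Drop G_0 states before pairing.
#' @return 6 x 6 integer matrix with dimnames `G0..GR`.
#' @export
transition_count_matrix <- function(labels, collapse_g0 = TRUE) {
  if (is.data.frame(labels)) labels <- labels$label
  lv <- grammar_levels()
  if (collapse_g0) labels <- labels[labels != "G0"]
  mat <- matrix(0L, 6L, 6L, dimnames = list(from = lv, to = lv))
  if (length(labels) >= 2L) {
    from <- labels[-length(labels)]
    to <- labels[-1L]
    for (i in seq_along(from)) {
      mat[from[i], to[i]] <- mat[from[i], to[i]] + 1L
    }
  }
  mat
}

#' Progression statistic over a cohort of trajectories
#'
#' For each subject, the number of grammar transitions toward deeper
#' embedding (strict upper triangle of the G_0-collapsed transition count
#' matrix, under the order G_1 < G_2 < G_3 < G_4 < G_R) versus transitions
#' toward shallower embedding (strict lower triangle), with a two-sided
#' paired t-test of the difference.  Staged progression predicts more
#' upward than downward transitions.
#'
#' @param trajectories List of label vectors (or trajectory tibbles), one
#'   per subject.
#' @return List: `per_subject` tibble (`subject`, `upper`, `lower`),
#'   `t_test` (an `htest`, or `NULL` when untestable), `testable`.
#' @export
progression_statistic <- function(trajectories) {
  if (length(trajectories) < 2L) {
    stop("need at least 2 subjects for the progression test", call. = FALSE)
  }
  tri <- lapply(trajectories, function(tr) {
    mat <- transition_count_matrix(tr, collapse_g0 = TRUE)
    list(upper = sum(mat[upper.tri(mat)]), lower = sum(mat[lower.tri(mat)]))
  })
  per_subject <- tibble::tibble(
    subject = seq_along(tri),
    upper = vapply(tri, `[[`, 0, "upper"),
    lower = vapply(tri, `[[`, 0, "lower")
  )
  diffs <- per_subject$upper - per_subject$lower
  if (stats::sd(diffs) == 0) {
    return(list(per_subject = per_subject, t_test = NULL, testable = FALSE))
  }
  tt <- stats::t.test(per_subject$upper, per_subject$lower, paired = TRUE)
  list(per_subject = per_subject, t_test = tt, testable = TRUE)
}

#' Extract the two transitional G_0 subsets of a trajectory
#'
#' `g0_23`: indices of G_0 states between the first G_2 and the first G_3;
#' `g0_34r`: indices of G_0 states between the first G_3 and the first G_4
#' or G_R.  A set is empty when either of its boundary labels is absent.
#' The two sets are disjoint by construction.
#'
#' @param labels Character label vector (or trajectory tibble).
#' @return List of integer index vectors `g0_23` and `g0_34r`.
#' @export
g0_subsets <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  first_of <- function(whats) {
    idx <- which(labels %in% whats)
    if (length(idx)) idx[1L] else NA_integer_
  }
  i2 <- first_of("G2"); i3 <- first_of("G3"); i4r <- first_of(c("G4", "GR"))
  between_g0 <- function(a, b) {
    if (is.na(a) || is.na(b) || b <= a + 1L) return(integer(0))
    idx <- (a + 1L):(b - 1L)
    idx[labels[idx] == "G0"]
  }
  list(g0_23 = between_g0(i2, i3), g0_34r = between_g0(i3, i4r))
}

#' Concentration of off-diagonal transitions in the G_0 row and column
#'
#' For an uncollapsed aggregate transition count matrix, the fraction of
#' off-diagonal mass lying in the G_0 row or G_0 column — high values mean
#' transitions between bearing-point states happen largely via G_0.
#'
#' @param mat 6 x 6 transition count matrix.
#' @return Fraction in `[0, 1]`, or `NA` (with a warning) when there is no
#'   off-diagonal mass.
#' @export
row1_col1_fraction <- function(mat) {
  off <- mat
  diag(off) <- 0
  total <- sum(off)
  if (total == 0) {
    warning("no off-diagonal transitions: fraction undefined", call. = FALSE)
    return(NA_real_)
  }
  (sum(off["G0", ]) + sum(off[, "G0"])) / total
}

#' Write per-subject trajectories as CSV
#' @param trajectories Named list of trajectory tibbles.
#' @param path Output path.
#' @export
write_trajectories_csv <- function(trajectories, path) {
  rows <- dplyr::bind_rows(lapply(names(trajectories), function(s) {
    tr <- trajectories[[s]]
    tibble::tibble(subject_id = s, sentence_id = tr$sentence_id,
                   sentence_level = tr$sentence_level, label = tr$label)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
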