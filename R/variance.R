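# Variance-vector interpolation analysis.
#
# If transitional (G_0) behavior interpolates between bearing-point
# grammars, a learner's trial-to-trial accuracy should vary most on the
# transitions where the grammars disagree (the word-4 slots) and little on
# the transitions where they all agree (2 -> 3, 3 -> 4).  Each learner gets
# a 40-dimensional variance vector over the transition types of the
# Sequence 3 test phase; its angular alignment with a model-derived global
# variance vector, versus a uniform vector, discriminates interpolation
# from uniform noise.

#' The 40 transition types of levels 1..4
#'
#' One type per within-sentence slot position: 4 from level-1, 8 from
#' level-2, 12 from level-3, and 16 from level-4 sentences.
#'
#' @return Tibble: `type_id` (e.g. `"L3.s9"`), `level`, `position`,
#'   `kind`, `four_index` (ordinal of word-4 slots, `NA` elsewhere).
#' @export
transition_types <- function() {
  rows <- lapply(1:4, function(m) {
    pos <- seq_len(4L * m)
    from <- generate_sentence(m)
    four_index <- rep(NA_integer_, 4L * m)
    four_index[from == 4L] <- seq_len(m)
    tibble::tibble(
      type_id = paste0("L", m, ".s", pos),
      level = m,
      position = pos,
      kind = ifelse(from == 1L, "nondeterministic", "deterministic"),
      four_index = four_index
    )
  })
  dplyr::bind_rows(rows)
}

#' Model expected-accuracy vector over the 40 transition types
#'
#' For the bearing-point grammars G_1..G_4: deterministic slots take the
#' model-profile values of [finite_profile()]; nondeterministic slots take
#' 0.5 (two admissible continuations).  `"GRND"`, the random baseline,
#' expects 0.25 everywhere.
#'
#' @param grammar `"G1"`, `"G2"`, `"G3"`, `"G4"`, or `"GRND"`.
#' @param nondet_value Expected accuracy assigned at nondeterministic
#'   slots for the symbolic grammars (default 0.5).
#' @return Named numeric vector of length 40.
#' @export
model_accuracy_vector <- function(grammar, nondet_value = 0.5) {
  tt <- transition_types()
  if (grammar == "GRND") {
    return(stats::setNames(rep(0.25, nrow(tt)), tt$type_id))
  }
  k <- as.integer(sub("^G", "", grammar))
  stopifnot(k %in% 1:4)
  vals <- unlist(lapply(1:4, function(m) {
    prof <- finite_profile(k, m)
    prof[is.na(prof)] <- nondet_value
    prof
  }))
  stats::setNames(vals, tt$type_id)
}

#' Global variance vector from the bearing-point model vectors
#'
#' Elementwise `v = m (1 - m)` (Bernoulli variance), where `m` is the
#' expected accuracy averaged over the five model vectors G_1..G_4 and
#' G_RND — learners are assumed to start at the random baseline.
#'
#' @inheritParams model_accuracy_vector
#' @return Named numeric vector of length 40 (entries at most 0.25).
#' @export
global_variance_vector <- function(nondet_value = 0.5) {
  grammars <- c("G1", "G2", "G3", "G4", "GRND")
  mat <- sapply(grammars, model_accuracy_vector, nondet_value = nondet_value)
  m <- rowMeans(mat)
  m * (1 - m)
}

#' Individual variance vector from a test-phase trace
#'
#' For each of the 40 transition types, the population variance (divide by
#' n) of the subject's binary prediction accuracies across the type's
#' instances in the test phase.  Types with a single instance contribute 0;
#' types absent from the test phase are `NA` and flagged.
#'
#' @param trace Single-subject response trace.
#' @param phase Which phase to use (default `"test"`).
#' @return Named numeric vector of length 40, with attribute `missing`
#'   listing absent types.
#' @export
individual_variance_vector <- function(trace, phase = "test") {
  tt <- transition_types()
  rows <- trace[trace$phase == phase & !is.na(trace$correct), ]
  pop_var <- function(x) mean((x - mean(x))^2)
  v <- vapply(tt$type_id, function(id) {
    x <- rows$correct[rows$type_id == id]
    if (length(x) == 0L) NA_real_ else pop_var(x)
  }, numeric(1))
  miss <- tt$type_id[is.na(v)]
  if (length(miss)) {
    attr(v, "missing") <- miss
  }
  v
}

#' Cosine of the angle between two nonnegative vectors
#'
#' @param u,v Numeric vectors of equal length (pairwise-complete entries
#'   are used).
#' @return Cosine in `[0, 1]` for nonnegative input; `NA` (with a warning)
#'   when either vector is zero.
#' @export
vec_cosine <- function(u, v) {
  ok <- !is.na(u) & !is.na(v)
  u <- u[ok]; v <- v[ok]
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    warning("cosine undefined for a zero vector", call. = FALSE)
    return(NA_real_)
  }
  sum(u * v) / (nu * nv)
}

#' Variance-vector alignment test over a cohort
#'
#' For each subject, the cosine of the individual variance vector with the
#' model-derived global variance vector and with the uniform vector
#' `(1, ..., 1)`; then a two-sided paired t-test of the difference.  Under
#' interpolation between bearing points the individual vectors align more
#' with the global vector than with the uniform one; under uniform noise
#' the difference attenuates toward zero.
#'
#' @param traces Cohort trace tibble.
#' @param nondet_value Passed to [global_variance_vector()].
#' @return List: `per_subject` tibble (`subject_id`, `cos_model`,
#'   `cos_uniform`), `t_test` (`htest` or `NULL`), `testable`,
#'   `n_excluded` (subjects with undefined cosines).
#' @export
alignment_test <- function(traces, nondet_value = 0.5) {
  vt <- global_variance_vector(nondet_value = nondet_value)
  vu <- rep(1, length(vt))
  subjects <- unique(traces$subject_id)
  rows <- lapply(subjects, function(s) {
    vi <- suppressWarnings(
      individual_variance_vector(traces[traces$subject_id == s, ]))
    tibble::tibble(subject_id = s,
                   cos_model = suppressWarnings(vec_cosine(vi, vt)),
                   cos_uniform = suppressWarnings(vec_cosine(vi, vu)))
  })
  per_subject <- dplyr::bind_rows(rows)
  ok <- stats::complete.cases(per_subject[, c("cos_model", "cos_uniform")])
  n_excluded <- sum(!ok)
  usable <- per_subject[ok, ]
  if (nrow(usable) < 2L ||
      stats::sd(usable$cos_model - usable$cos_uniform) == 0) {
    return(list(per_subject = per_subject, t_test = NULL, testable = FALSE,
                n_excluded = n_excluded))
  }
  tt <- stats::t.test(usable$cos_model, usable$cos_uniform, paired = TRUE)
  list(per_subject = per_subject, t_test = tt, testable = TRUE,
       n_excluded = n_excluded)
}
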