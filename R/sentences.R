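#' Generate the unique level-n sentence of the counting-recursion grammar
#'
#' The target language is generated by the context-free grammar
#' `S -> 1 S 2 3 4 | 1 2 3 4`: the level-n sentence consists of `n` copies of
#' box 1 followed by `n` copies of the block (2, 3, 4), for a total length of
#' `4n`.  Level 1 is `1 2 3 4`, level 2 is `1 1 2 3 4 2 3 4`, and so on.
#'
#' @param level Positive integer embedding depth.
#' @return Integer vector of box indices of length `4 * level`.
#' @examples
#' generate_sentence(1)  # 1 2 3 4
#' generate_sentence(3)  # 1 1 1 2 3 4 2 3 4 2 3 4
#' @export
generate_sentence <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level < 1 || level != round(level)) {
    stop("`level` must be a single integer >= 1", call. = FALSE)
  }
  level <- as.integer(level)
  c(rep(1L, level), rep(c(2L, 3L, 4L), level))
}

#' The non-recursive filler sentence S2*
#'
#' An eight-word filler matched in length and symbol inventory to the level-2
#' sentence but with no recursive relationship to the level-1 sentence.  Used
#' to build the control sequence (Sequence 2).
#'
#' @return Integer vector `1 1 4 3 2 4 2 3`.
#' @export
filler_sentence <- function() {
  c(1L, 1L, 4L, 3L, 2L, 4L, 2L, 3L)
}

#' Recognize a word list as a grammar sentence, the filler, or neither
#'
#' Inverse of [generate_sentence()]: returns the embedding level `n` if
#' `words` is exactly the level-n sentence, `0` if it is the filler S2*, and
#' `NA` otherwise.
#'
#' @param words Integer vector of box indices.
#' @return Integer: the level, `0L` for the filler, `NA_integer_` if invalid.
#' @export
recognize <- function(words) {
  words <- as.integer(words)
  if (identical(words, filler_sentence())) return(0L)
  n <- length(words) %/% 4L
  if (n >= 1L && length(words) == 4L * n && identical(words, generate_sentence(n))) {
    return(n)
  }
  NA_integer_
}

# Sentence-type table used by composition handling.  Types are named by the
# conventional labels S1..S4 for levels 1..4 and "S2star" for the filler.
sentence_type_words <- function(type) {
  switch(type,
    S1 = generate_sentence(1L),
    S2 = generate_sentence(2L),
    S3 = generate_sentence(3L),
    S4 = generate_sentence(4L),
    S2star = filler_sentence(),
    stop("unknown sentence type: ", type, call. = FALSE)
  )
}

sentence_type_level <- function(type) {
  switch(type, S1 = 1L, S2 = 2L, S3 = 3L, S4 = 4L, S2star = 0L,
         stop("unknown sentence type: ", type, call. = FALSE))
}

#' Default sentence-type compositions for the three experimental sequences
#'
#' Sequence 1 (two trained levels plus a novel third level in the test
#' phase): a 300-word study phase of 31 S1 and 22 S2, then a 104-word test
#' phase of 8 S1, 3 S2, and 4 S3 that begins with the first S3 and ends with
#' an S1.  Sequence 2 is Sequence 1 with every S2 replaced by the filler
#' S2*.  Sequence 3 (three trained levels, novel fourth level): a 304-word
#' study phase of 24 S1, 14 S2, and 8 S3, then a 152-word test phase of
#' 5 S1, 4 S2, 3 S3, and 4 S4 that begins with the first S4.
#'
#' @param condition One of `"sequence1"`, `"sequence2"`, `"sequence3"`.
#' @return List with named integer vectors `study` and `test` (counts per
#'   sentence type) and, where declared, `study_words`/`test_words` totals.
#' @export
default_composition <- function(condition) {
  switch(condition,
    sequence1 = list(study = c(S1 = 31L, S2 = 22L),
                     test = c(S1 = 8L, S2 = 3L, S3 = 4L),
                     study_words = 300L, test_words = 104L,
                     test_first = "S3", ends_with = "S1"),
    sequence2 = list(study = c(S1 = 31L, S2star = 22L),
                     test = c(S1 = 8L, S2star = 3L, S3 = 4L),
                     study_words = 300L, test_words = 104L,
                     test_first = "S3", ends_with = "S1"),
    sequence3 = list(study = c(S1 = 24L, S2 = 14L, S3 = 8L),
                     test = c(S1 = 5L, S2 = 4L, S3 = 3L, S4 = 4L),
                     study_words = 304L, test_words = 152L,
                     test_first = "S4", ends_with = "S1"),
    stop("no default composition for condition: ", condition, call. = FALSE)
  )
}

phase_word_total <- function(counts) {
  sum(vapply(names(counts), function(t) length(sentence_type_words(t)), 1L) *
        as.integer(counts))
}

# Order the study-phase sentence types so that longer sentences become more
# frequent toward the end of the phase: sampling without replacement where a
# type's selection weight is its remaining count times a position weight
# rising with the fractional position p — constant for the shortest type and
# proportional to p^d for a type d depth units longer (linear for the next
# depth, steeper for deeper ones).  The phase therefore opens with the
# shortest type and concentrates each deeper type progressively later,
# while the drawn counts still match the composition exactly.
order_study_types <- function(counts) {
  types <- names(counts)
  depth <- vapply(types, function(t) length(sentence_type_words(t)) %/% 4L, 1L)
  depth <- depth - min(depth)
  remaining <- as.integer(counts)
  n_total <- sum(remaining)
  out <- character(n_total)
  for (i in seq_len(n_total)) {
    p <- if (n_total == 1L) 1 else (i - 1) / (n_total - 1)
    w <- remaining * (depth + 1) * p^depth
    if (all(w == 0)) w <- remaining  # only depth-0 types left at p = 0
    pick <- sample.int(length(types), 1L, prob = w)
    out[i] <- types[pick]
    remaining[pick] <- remaining[pick] - 1L
  }
  out
}

# Order the test-phase types: the first sentence introduces the novel
# deepest type, the phase ends with an S1, and the rest are shuffled.
order_test_types <- function(counts, first_type, end_type) {
  pool <- rep(names(counts), times = as.integer(counts))
  stopifnot(first_type %in% pool)
  pool <- pool[-match(first_type, pool)]
  end <- NULL
  if (!is.null(end_type) && end_type %in% pool) {
    pool <- pool[-match(end_type, pool)]
    end <- end_type
  }
  c(first_type, if (length(pool)) sample(pool), end)
}

#' Build an experimental word sequence from a sentence-type composition
#'
#' Concatenates sentences drawn from the composition into one long word
#' stream, pseudo-randomly ordered under the task's constraints: deeper
#' sentence types occur less frequently at the beginning of the study phase
#' and more frequently at the end; the test phase begins with the first
#' instance of the deepest (novel) type and the sequence ends with an S1.
#' Prediction slots are classified (see [classify_transitions()]) and words
#' are colored (see [annotate_colors()]).
#'
#' @param condition `"sequence1"`, `"sequence2"`, `"sequence3"`, or
#'   `"custom"`.
#' @param composition Optional composition list as returned by
#'   [default_composition()]; required for `condition = "custom"`.
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @return An object of class `experiment_sequence`: a list with elements
#'   `condition`, `sentences` (tibble: sentence_id, type, level, length,
#'   phase), `words` (tibble: word_index, box, sentence_id, sentence_level,
#'   position_in_sentence, phase, color), `slots` (tibble, one prediction
#'   slot per word; see [classify_transitions()]), and
#'   `study_test_boundary` (index of the last study-phase word).
#' @export
build_experiment_sequence <- function(condition = c("sequence1", "sequence2",
                                                    "sequence3", "custom"),
                                      composition = NULL, seed = 1L) {
  condition <- match.arg(condition)
  if (is.null(composition)) {
    if (condition == "custom") {
      stop("a `composition` must be supplied for condition = \"custom\"",
           call. = FALSE)
    }
    composition <- default_composition(condition)
  }
  for (phase in c("study", "test")) {
    declared <- composition[[paste0(phase, "_words")]]
    if (!is.null(declared) && phase_word_total(composition[[phase]]) != declared) {
      stop("inconsistent composition: ", phase, " phase totals ",
           phase_word_total(composition[[phase]]), " words but ", declared,
           " were declared", call. = FALSE)
    }
  }

  withr::with_seed(as.integer(seed), {
    study_types <- order_study_types(composition$study)
    test_counts <- composition$test
    first_type <- composition$test_first
    if (is.null(first_type)) {
      first_type <- names(test_counts)[which.max(vapply(names(test_counts),
                                                        sentence_type_level, 1L))]
    }
    test_types <- order_test_types(test_counts, first_type,
                                   composition$ends_with)
    types <- c(study_types, test_types)
  })

  n_study <- length(study_types)
  sentences <- tibble::tibble(
    sentence_id = seq_along(types),
    type = types,
    level = vapply(types, sentence_type_level, 1L),
    length = vapply(types, function(t) length(sentence_type_words(t)), 1L),
    phase = rep(c("study", "test"), c(n_study, length(types) - n_study))
  )
  word_list <- lapply(types, sentence_type_words)
  words <- tibble::tibble(
    word_index = seq_len(sum(sentences$length)),
    box = unlist(word_list),
    sentence_id = rep(sentences$sentence_id, sentences$length),
    sentence_level = rep(sentences$level, sentences$length),
    position_in_sentence = unlist(lapply(sentences$length, seq_len)),
    phase = rep(sentences$phase, sentences$length)
  )
  words$color <- annotate_colors(words$box)
  boundary <- sum(sentences$length[sentences$phase == "study"])

  seq_obj <- structure(
    list(condition = condition, composition = composition,
         sentences = sentences, words = words,
         study_test_boundary = boundary, seed = as.integer(seed)),
    class = "experiment_sequence"
  )
  seq_obj$slots <- classify_transitions(seq_obj)
  seq_obj
}

#' @export
print.experiment_sequence <- function(x, ...) {
  cat("<experiment_sequence> ", x$condition, ": ", nrow(x$words), " words, ",
      nrow(x$sentences), " sentences (study phase ends at word ",
      x$study_test_boundary, ")\n", sep = "")
  counts <- table(x$sentences$type, x$sentences$phase)
  print(counts)
  invisible(x)
}

#' Classify every prediction slot of a sequence
#'
#' Slot `i` is the prediction, made after observing word `i`, of word
#' `i + 1`; the final slot of a sentence predicts the first word of the next
#' sentence (always a 1).  A slot is nondeterministic when, given the
#' sentence-position context, the language admits more than one
#' continuation: exactly the slots following a box-1 word (continuations
#' `{1, 2}` in Sequences 1 and 3, `{1, 2, 4}` in Sequence 2).  All other
#' slots (2 -> 3, 3 -> 4, mid-sentence 4 -> 2, sentence-final 4 -> 1, and the
#' filler's internal transitions) are deterministic.  The very last word of
#' the sequence has no target; its slot is kept with `to_box = NA`.
#'
#' @param sequence An `experiment_sequence`.
#' @return Tibble with one row per word: `word_index`, `from_box`, `to_box`,
#'   `kind` (`"deterministic"`/`"nondeterministic"`), `transition_label`
#'   (e.g. `"T42"`), `sentence_id`, `sentence_level`, `position_in_sentence`,
#'   `type_id` (transition type, e.g. `"L3.s9"`), `phase`, and `four_index`
#'   (ordinal of the 4-slot within its sentence, `NA` elsewhere).
#' @export
classify_transitions <- function(sequence) {
  w <- sequence$words
  n <- nrow(w)
  to_box <- c(w$box[-1L], NA_integer_)
  kind <- ifelse(w$box == 1L, "nondeterministic", "deterministic")
  label <- ifelse(is.na(to_box), NA_character_,
                  paste0("T", w$box, to_box))
  # ordinal of each 4 within its sentence (1-based); drives bearing-point
  # grammar predictions and the T42/T41 distinction
  four_index <- rep(NA_integer_, n)
  is4 <- w$box == 4L
  four_index[is4] <- stats::ave(rep(1L, sum(is4)), w$sentence_id[is4],
                                FUN = cumsum)
  tibble::tibble(
    word_index = w$word_index,
    from_box = w$box,
    to_box = to_box,
    kind = kind,
    transition_label = label,
    sentence_id = w$sentence_id,
    sentence_level = w$sentence_level,
    position_in_sentence = w$position_in_sentence,
    type_id = paste0("L", w$sentence_level, ".s", w$position_in_sentence),
    phase = w$phase,
    four_index = four_index
  )
}

#' Color labels for a word stream
#'
#' In the task display every highlighted box is green except when a 1
#' immediately follows another 1 (the nondeterministic repetition), which is
#' shown blue or cyan; two successive repeated-1 highlights never share a
#' color.  Colors are presentation metadata only and are never used in
#' scoring.  Alternation starts with blue.
#'
#' @param boxes Integer vector of box indices.
#' @return Character vector of `"green"`, `"blue"`, `"cyan"`.
#' @export
annotate_colors <- function(boxes) {
  n <- length(boxes)
  colors <- rep("green", n)
  special <- which(boxes == 1L & c(FALSE, boxes[-n] == 1L))
  if (length(special)) {
    colors[special] <- rep(c("blue", "cyan"), length.out = length(special))
  }
  colors
}

#' Write a sequence as tidy CSV (one row per word) and return the path
#'
#' Columns: word_index, box, sentence_id, sentence_level,
#' position_in_sentence, slot_kind, color, phase.
#'
#' @param sequence An `experiment_sequence`.
#' @param path Output CSV path.
#' @export
write_sequence_csv <- function(sequence, path) {
  out <- dplyr::mutate(sequence$words,
                       slot_kind = sequence$slots$kind)
  out <- out[, c("word_index", "box", "sentence_id", "sentence_level",
                 "position_in_sentence", "slot_kind", "color", "phase")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
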