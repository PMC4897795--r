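test_that("level-n sentences have the a^n b^n structure", {
  expect_identical(generate_sentence(1), c(1L, 2L, 3L, 4L))
  expect_identical(generate_sentence(2), c(1L, 1L, 2L, 3L, 4L, 2L, 3L, 4L))
  for (n in 1:12) {
    s <- generate_sentence(n)
    expect_length(s, 4L * n)
    expect_identical(s[seq_len(n)], rep(1L, n))
    expect_identical(recognize(s), n)
  }
  expect_error(generate_sentence(0), "level")
  expect_error(generate_sentence(2.5), "level")
})

test_that("recognition distinguishes grammar sentences, the filler, and junk", {
  expect_identical(recognize(c(1, 2, 3, 4)), 1L)
  expect_identical(recognize(filler_sentence()), 0L)
  expect_identical(recognize(c(1, 2, 3)), NA_integer_)
  expect_identical(recognize(c(1, 1, 2, 3, 4, 2, 4, 3)), NA_integer_)
})

test_that("default compositions reproduce the experimental word arithmetic", {
  s1 <- seq1_default()
  expect_identical(s1$study_test_boundary, 300L)
  expect_identical(nrow(s1$words), 404L)
  # test phase begins at the first S3 and the sequence ends with an S1
  test_sents <- s1$sentences[s1$sentences$phase == "test", ]
  expect_identical(test_sents$type[1], "S3")
  expect_identical(s1$sentences$type[nrow(s1$sentences)], "S1")
  expect_false(any(s1$sentences$type[s1$sentences$phase == "study"] == "S3"))

  s3 <- seq3_default()
  expect_identical(s3$study_test_boundary, 304L)
  expect_identical(nrow(s3$words), 456L)
  expect_identical(s3$sentences$type[s3$sentences$phase == "test"][1], "S4")
  expect_false(any(s3$sentences$type[s3$sentences$phase == "study"] == "S4"))

  # word-count conservation: flattened length = sum of sentence lengths
  for (s in list(s1, seq2_default(), s3)) {
    expect_identical(nrow(s$words), sum(s$sentences$length))
  }
})

test_that("inconsistent compositions are rejected", {
  comp <- default_composition("sequence1")
  comp$study["S1"] <- 30L
  expect_error(build_experiment_sequence("sequence1", composition = comp),
               "inconsistent composition")
})

test_that("sequence construction is deterministic in the seed and staged in depth", {
  a <- build_experiment_sequence("sequence3", seed = 42)
  b <- build_experiment_sequence("sequence3", seed = 42)
  expect_identical(a$words, b$words)
  d <- build_experiment_sequence("sequence3", seed = 43)
  expect_false(identical(a$words$box, d$words$box))
  # deeper types occur later in the study phase on average
  st <- a$sentences[a$sentences$phase == "study", ]
  pos <- seq_len(nrow(st))
  expect_gt(mean(pos[st$type == "S2"]), mean(pos[st$type == "S1"]))
  expect_identical(st$type[1], "S1")
})

test_that("slots following a 1 are nondeterministic, all others deterministic", {
  s1 <- seq1_default()
  expect_identical(unique(s1$slots$kind[s1$slots$from_box == 1]),
                   "nondeterministic")
  expect_identical(unique(s1$slots$kind[s1$slots$from_box != 1]),
                   "deterministic")
  # nondeterministic labels are T11/T12 in Sequence 1 and gain T14 in
  # Sequence 2 (the filler's 1 -> 4 transition)
  nlab1 <- unique(na.omit(s1$slots$transition_label[s1$slots$kind ==
                                                      "nondeterministic"]))
  expect_setequal(nlab1, c("T11", "T12"))
  s2 <- seq2_default()
  nlab2 <- unique(na.omit(s2$slots$transition_label[s2$slots$kind ==
                                                      "nondeterministic"]))
  expect_setequal(nlab2, c("T11", "T12", "T14"))
})

test_that("deterministic slots have a unique continuation given context (brute force)", {
  # the learner's context is the within-sentence word prefix (sentence
  # boundaries are invisible, so the prefix is all position information
  # available); enumerate continuations per prefix over a small
  # composition: every deterministic slot must have a unique continuation
  s <- build_experiment_sequence("custom", composition = list(
    study = c(S1 = 3L, S2 = 2L), test = c(S1 = 2L, S3 = 2L),
    test_first = "S3", ends_with = "S1"), seed = 9)
  sl <- s$slots[!is.na(s$slots$to_box), ]
  prefix <- vapply(seq_len(nrow(sl)), function(i) {
    words <- s$words$box[s$words$sentence_id == sl$sentence_id[i]]
    paste(words[seq_len(sl$position_in_sentence[i])], collapse = "")
  }, character(1))
  n_cont <- tapply(sl$to_box, prefix, function(x) length(unique(x)))
  for (cc in names(n_cont)) {
    kinds <- unique(sl$kind[prefix == cc])
    expect_length(kinds, 1L)
    if (kinds == "deterministic") expect_identical(unname(n_cont[cc]), 1L)
  }
  # and some nondeterministic context really does continue in more than
  # one way (after an initial 1 the stream shows both 1 and 2)
  expect_gt(n_cont[["1"]], 1L)
})

test_that("a level-n sentence contributes 4n slots; levels 1-4 give 40 types", {
  s3 <- seq3_default()
  per_sent <- table(s3$slots$sentence_id)
  expect_identical(as.integer(per_sent),
                   as.integer(4L * s3$sentences$level))
  expect_identical(nrow(transition_types()), 40L)
  expect_identical(sum(4L * (1:4)), 40L)
})

test_that("repeated 1s are colored blue/cyan with alternation, all else green", {
  expect_identical(annotate_colors(c(1, 2, 3, 4)), rep("green", 4))
  cols <- annotate_colors(c(1, 1, 1, 2))
  expect_identical(cols, c("green", "blue", "cyan", "green"))
  # two successive repeated-1 events never share a color
  s3 <- seq3_default()
  special <- s3$words$color[s3$words$color != "green"]
  expect_true(all(special[-1] != special[-length(special)]))
  # a 1 after a non-1 stays green
  expect_identical(annotate_colors(c(4, 1, 2)), rep("green", 3))
})

test_that("sequence CSV round-trips the word stream", {
  s <- make_fixtures(2)$sequence
  path <- withr::local_tempfile(fileext = ".csv")
  write_sequence_csv(s, path)
  back <- read.csv(path)
  expect_identical(back$box, s$words$box)
  expect_identical(back$slot_kind, s$slots$kind)
})
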