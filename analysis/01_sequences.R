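#!/usr/bin/env Rscript
# Build the three experimental word sequences and check their arithmetic.
#
# Sequence 1: two trained embedding levels (S1, S2), a novel S3 in the
# test phase.  Sequence 2: the non-recursive control (S2 replaced by the
# filler S2*).  Sequence 3: three trained levels, a novel S4 opening the
# test phase.

library(locuspred)

dir.create("results/sequences", showWarnings = FALSE, recursive = TRUE)
seed <- 20160608

for (cond in c("sequence1", "sequence2", "sequence3")) {
  s <- build_experiment_sequence(cond, seed = seed)
  write_sequence_csv(s, file.path("results/sequences", paste0(cond, ".csv")))
  message(sprintf("%s: %d words (%d study + %d test), %d sentences",
                  cond, nrow(s$words), s$study_test_boundary,
                  nrow(s$words) - s$study_test_boundary, nrow(s$sentences)))
  tst <- s$sentences[s$sentences$phase == "test", ]
  message("  test phase opens with ", tst$type[1],
          "; sequence ends with ", s$sentences$type[nrow(s$sentences)])
  nd <- unique(na.omit(s$slots$transition_label[s$slots$kind ==
                                                  "nondeterministic"]))
  message("  nondeterministic transitions: ", paste(sort(nd), collapse = ", "))
}

# the deeper types drift toward the end of the study phase
s3 <- build_experiment_sequence("sequence3", seed = seed)
st <- s3$sentences[s3$sentences$phase == "study", ]
mp <- tapply(seq_len(nrow(st)), st$type, mean)
message("mean study-phase position by type (staging check): ",
        paste(names(mp), round(mp, 1), sep = "=", collapse = ", "))
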