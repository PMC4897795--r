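# Shared fixtures, built once per test run.  Everything is generated in
# code from fixed seeds; no data files.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

seq1_default <- function() memo("seq1", build_experiment_sequence("sequence1", seed = 101))
seq2_default <- function() memo("seq2", build_experiment_sequence("sequence2", seed = 101))
seq3_default <- function() memo("seq3", build_experiment_sequence("sequence3", seed = 101))

# literal model-profile rows (trial-level accuracy at unmasked slots,
# stars = masked), frozen from the published table of bearing-point
# grammar profiles
table2_rows <- list(
  "1" = list("1" = c(1, 1, 1),
             "2" = c(1, 1, 0, 1, 1, 1),
             "3" = c(1, 1, 0, 1, 1, 0, 1, 1, 1),
             "4" = c(1, 1, 0, 1, 1, 0, 1, 1, 0, 1, 1, 1)),
  "2" = list("2" = c(1, 1, 1, 1, 1, 1),
             "3" = c(1, 1, 1, 1, 1, 0, 1, 1, 1),
             "4" = c(1, 1, 1, 1, 1, 0, 1, 1, 0, 1, 1, 1)),
  "3" = list("3" = c(1, 1, 1, 1, 1, 1, 1, 1, 1),
             "4" = c(1, 1, 1, 1, 1, 1, 1, 1, 0, 1, 1, 1)),
  "4" = list("4" = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1))
)

# a cohort of staged learners, heterogeneous in how far they progress and
# when each stage of grammatical competence begins
staged_cohort <- function(sequence, n = 20, seed = 404) {
  withr::with_seed(seed, {
    first_s4 <- which(sequence$sentences$level == 4)[1]
    lapply(seq_len(n), function(i) {
      depth <- sample(2:4, 1)  # how many stages this learner reaches
      ks <- list(c(1, 2), c(1, 2, 3), c(1, 2, 3, "R"))[[depth - 1]]
      br <- sort(c(1, sample(5:20, 1), sample(21:40, 1),
                   first_s4 + sample(0:5, 1)))[seq_len(depth)]
      cfg <- agent_config("staged", stage_at = br, stage_k = ks)
      simulate_agent(cfg, sequence, seed = seed + i)
    })
  })
}
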