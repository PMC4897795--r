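#!/usr/bin/env Rscript
# Simulate the main synthetic cohorts.
#
# The 68-learner cohort on Sequence 3 mixes the hypothesis classes the
# analyses are designed to discriminate: committed recursive learners,
# finite-state learners stuck at level 3, probabilistic mixtures between
# G_3 and G_R, dynamically perturbed learners, and staged progressors.
# Companion cohorts of 50 and 48 learners run Sequences 1 and 2 for the
# between-condition contrast.

library(locuspred)

dir.create("results/cohorts", showWarnings = FALSE, recursive = TRUE)
seed <- 20160608

seq3 <- build_experiment_sequence("sequence3", seed = seed)
configs <- c(
  rep(list(agent_config("bearing", k = "R", label = "recursive")), 24),
  rep(list(agent_config("bearing", k = 3, label = "finite3")), 12),
  rep(list(agent_config("pmbp", g_a = 3, g_b = "R", w = 0.5,
                        label = "mixture")), 12),
  rep(list(agent_config("dynamical", k = 3, delta0 = 0.8, rho = 0.5,
                        label = "dynamical")), 10),
  rep(list(agent_config("ngram", n = 14, policy = "argmax",
                        label = "ngram14")), 10)
)
stopifnot(length(configs) == 68)
traces3 <- simulate_cohort(configs, seq3, seed = seed + 1)
write_traces_csv(traces3, "results/cohorts/sequence3_traces.csv")
message("Sequence 3 cohort: 68 agents, ",
        length(unique(traces3$subject_id)), " traces of ",
        nrow(seq3$slots), " slots each")

# Sequence 1 (n = 50) carries mostly finite-state learners: its two
# trained levels give little footing for recursion.  Sequence 2 (n = 48)
# carries none.
seq1 <- build_experiment_sequence("sequence1", seed = seed)
cfg1 <- c(
  rep(list(agent_config("bearing", k = "R", label = "recursive")), 5),
  rep(list(agent_config("bearing", k = 2, label = "finite2")), 25),
  rep(list(agent_config("ngram", n = 14, policy = "argmax",
                        label = "ngram14")), 20)
)
traces1 <- simulate_cohort(cfg1, seq1, seed = seed + 2)
write_traces_csv(traces1, "results/cohorts/sequence1_traces.csv")

seq2 <- build_experiment_sequence("sequence2", seed = seed)
cfg2 <- c(
  rep(list(agent_config("bearing", k = 2, label = "finite2")), 28),
  rep(list(agent_config("ngram", n = 14, policy = "argmax",
                        label = "ngram14")), 20)
)
traces2 <- simulate_cohort(cfg2, seq2, seed = seed + 3)
write_traces_csv(traces2, "results/cohorts/sequence2_traces.csv")
message("Sequence 1 cohort: 50 agents; Sequence 2 cohort: 48 agents")
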