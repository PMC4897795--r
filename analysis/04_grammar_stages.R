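#!/usr/bin/env Rscript
# Grammar-stage analysis of the Sequence 3 cohort: GBPLCA trajectories,
# transition count matrices, the forward-progression statistic, the
# concentration of transitions in the G_0 row/column, and the
# transitional G_0 subsets.

library(locuspred)

seed <- 20160608
seq3 <- build_experiment_sequence("sequence3", seed = seed)
traces <- tibble::as_tibble(read.csv("results/cohorts/sequence3_traces.csv"))

traj <- lapply(split(traces, traces$subject_id), grammar_trajectory,
               sequence = seq3)
write_trajectories_csv(traj, "results/trajectories.csv")
message("classified ", length(traj), " trajectories of ",
        nrow(seq3$sentences), " sentences")

agg <- Reduce(`+`, lapply(traj, transition_count_matrix, collapse_g0 = FALSE))
write.csv(agg, "results/transition_matrix.csv", quote = FALSE)
message("aggregate off-diagonal mass in the G0 row/column: ",
        round(100 * row1_col1_fraction(agg), 1), "%")

ps <- progression_statistic(traj)
if (ps$testable) {
  message(sprintf(
    "progression: mean %.2f forward vs %.2f backward transitions, t(%d) = %.2f, p = %.3g",
    mean(ps$per_subject$upper), mean(ps$per_subject$lower),
    unname(ps$t_test$parameter), unname(ps$t_test$statistic),
    ps$t_test$p.value))
} else {
  message("progression: untestable (zero-variance difference)")
}
write.csv(ps$per_subject, "results/progression_triangles.csv",
          row.names = FALSE)

g0 <- lapply(traj, g0_subsets)
n23 <- sum(lengths(lapply(g0, `[[`, "g0_23")))
n34 <- sum(lengths(lapply(g0, `[[`, "g0_34r")))
message("transitional G0 states: ", n23, " between first G2 and first G3, ",
        n34, " between first G3 and first G4/GR")
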