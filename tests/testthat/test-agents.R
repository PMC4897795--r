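test_that("bearing-agent unmasked profiles equal the model-profile rows verbatim", {
  s3 <- seq3_default()
  for (k in 1:4) {
    tr <- simulate_agent(agent_config("bearing", k = k), s3, seed = 50 + k)
    for (lvl in k:4) {
      ids <- s3$sentences$sentence_id[s3$sentences$level == lvl]
      for (id in ids[-length(ids)]) {
        prof <- profile_vector(tr, id)
        expect_identical(unname(prof[!is.na(prof)]),
                         table2_rows[[as.character(k)]][[as.character(lvl)]],
                         label = sprintf("G%d on level-%d sentence %d", k, lvl, id))
      }
    }
    # levels below k are processed perfectly
    for (lvl in seq_len(k - 1)) {
      ids <- s3$sentences$sentence_id[s3$sentences$level == lvl]
      ids <- setdiff(ids, max(s3$sentences$sentence_id))
      for (id in ids) {
        prof <- profile_vector(tr, id)
        expect_true(all(prof[!is.na(prof)] == 1))
      }
    }
  }
})

test_that("the recursive agent is perfect on every unmasked slot", {
  s3 <- seq3_default()
  tr <- simulate_agent(agent_config("bearing", k = "R"), s3, seed = 7)
  det <- tr[tr$kind == "deterministic" & !is.na(tr$correct), ]
  expect_true(all(det$correct == 1))
})

test_that("progression-noise reduces to the bearing agent at epsilon 0 and to chance at 1", {
  s3 <- seq3_default()
  a <- simulate_agent(agent_config("bearing", k = 2), s3, seed = 31)
  b <- simulate_agent(agent_config("progression_noise", k = 2, epsilon = 0),
                      s3, seed = 31)
  expect_identical(a$predicted, b$predicted)
  coh <- simulate_cohort(agent_config("progression_noise", k = 2, epsilon = 1),
                         s3, seed = 32, n_agents = 40)
  det <- coh[!is.na(coh$correct) & coh$kind == "deterministic", ]
  expect_equal(mean(det$correct), 0.25, tolerance = 0.05)
})

test_that("progression-noise accuracy follows the closed-form mixture", {
  # on a slot where the base grammar is correct:
  # accuracy = (1 - eps) + eps/4 = 0.85 at eps = 0.2
  s3 <- seq3_default()
  coh <- simulate_cohort(agent_config("progression_noise", k = 2,
                                      epsilon = 0.2),
                         s3, seed = 33, n_agents = 60)
  base_right <- which(bearing_expected_correct(s3, 2) == 1)
  acc <- vapply(split(coh, coh$subject_id), function(tr) {
    tr <- tr[order(tr$word_index), ]
    mean(tr$correct[base_right], na.rm = TRUE)
  }, numeric(1))
  expect_equal(mean(acc), 0.85, tolerance = 0.02)
})

test_that("pmbp degenerates to its components at w = 1 and w = 0", {
  s3 <- seq3_default()
  pa <- simulate_agent(agent_config("pmbp", g_a = 2, g_b = 3, w = 1),
                       s3, seed = 21)
  pb <- simulate_agent(agent_config("pmbp", g_a = 2, g_b = 3, w = 0),
                       s3, seed = 21)
  # deterministic slots match the pure grammars exactly
  det <- s3$slots$kind == "deterministic"
  a2 <- bearing_expected_correct(s3, 2); a3 <- bearing_expected_correct(s3, 3)
  expect_identical(pa$correct[det & !is.na(a2)], as.integer(a2[det & !is.na(a2)]))
  expect_identical(pb$correct[det & !is.na(a3)], as.integer(a3[det & !is.na(a3)]))
})

test_that("pmbp at w = 0.5 is near 0.5 accurate where exactly one grammar is right", {
  s3 <- seq3_default()
  coh <- simulate_cohort(agent_config("pmbp", g_a = 2, g_b = 3, w = 0.5),
                         s3, seed = 22, n_agents = 60)
  a2 <- bearing_expected_correct(s3, 2); a3 <- bearing_expected_correct(s3, 3)
  disc <- which(!is.na(a2) & !is.na(a3) & (a2 != a3))
  acc <- vapply(split(coh, coh$subject_id), function(tr) {
    tr <- tr[order(tr$word_index), ]
    mean(tr$correct[disc], na.rm = TRUE)
  }, numeric(1))
  expect_equal(mean(acc), 0.5, tolerance = 0.05)
})

test_that("dynamical agent reduces to bearing at delta0 = 0 and has the stated corruption schedule", {
  s3 <- seq3_default()
  a <- simulate_agent(agent_config("bearing", k = 2), s3, seed = 41)
  b <- simulate_agent(agent_config("dynamical", k = 2, delta0 = 0, rho = 0.5),
                      s3, seed = 41)
  expect_identical(a$predicted, b$predicted)
  # empirically, error rate at distance d from the last error tracks
  # delta0 * rho^(d-1) on slots the base grammar predicts correctly
  coh <- simulate_cohort(agent_config("dynamical", k = 2, delta0 = 0.8,
                                      rho = 0.5), s3, seed = 42,
                         n_agents = 150)
  est <- estimate_dynamical(coh, s3, 2)
  bd <- est$by_distance
  expect_equal(bd$error_rate[bd$d == 1], 0.8, tolerance = 0.05)
  expect_equal(bd$error_rate[bd$d == 2], 0.4, tolerance = 0.05)
})

test_that("cohort simulation is reproducible and scores first-encounter generalization", {
  s3 <- seq3_default()
  c1 <- simulate_cohort(agent_config("bearing", k = "R"), s3, seed = 5,
                        n_agents = 10)
  c2 <- simulate_cohort(agent_config("bearing", k = "R"), s3, seed = 5,
                        n_agents = 10)
  expect_identical(c1, c2)
  # recursive agents are perfect on the first S4; G3 agents never are
  # (they err at its third 4 -> 2 transition)
  expect_equal(first_instance_generalization(c1, s3, 4)$proportion, 1)
  c3 <- simulate_cohort(agent_config("bearing", k = 3), s3, seed = 6,
                        n_agents = 10)
  expect_equal(first_instance_generalization(c3, s3, 4)$proportion, 0)
  first_s4 <- s3$sentences$sentence_id[s3$sentences$level == 4][1]
  third_t42 <- vapply(split(c3, c3$subject_id), function(tr) {
    tr$correct[tr$sentence_id == first_s4 & tr$transition_label == "T42" &
                 !is.na(tr$correct)][3]
  }, integer(1))
  expect_true(all(third_t42 == 0))
})

test_that("agent configs validate their parameters", {
  expect_error(agent_config("bearing", k = 5), "must be 1, 2, 3, 4")
  expect_error(agent_config("pmbp", g_a = 2, g_b = 3, w = 1.2), "probability")
  expect_error(agent_config("dynamical", k = 1, delta0 = 0.5, rho = 1), "rho")
  expect_error(agent_config("ngram", n = 1), "n")
})

test_that("traces serialize to JSONL and CSV", {
  fx <- make_fixtures(4)
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_traces_jsonl(fx$traces, p1)
  write_traces_csv(fx$traces, p2)
  expect_identical(length(readLines(p1)), nrow(fx$traces))
  back <- read.csv(p2)
  expect_identical(nrow(back), nrow(fx$traces))
  expect_identical(back$predicted, fx$traces$predicted)
})
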