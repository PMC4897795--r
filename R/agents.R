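# Synthetic learner agents for the Locus Prediction task.
#
# Every agent consumes an experiment_sequence slot-by-slot and emits one box
# prediction per word (the prediction of the *next* word).  Agents embody
# the competing accounts of learning behavior: finite-state bearing-point
# grammars G_1..G_4 and the recursive grammar G_R, uniform guessing,
# progression-plus-noise, probabilistic mixtures of two bearing points,
# dynamical post-error perturbation, incremental backoff n-gram prediction,
# and staged progression through successive bearing points.

#' Agent configuration
#'
#' @param kind One of `"bearing"`, `"random"`, `"progression_noise"`,
#'   `"pmbp"`, `"dynamical"`, `"ngram"`, `"staged"`.
#' @param k Grammar level for bearing-based kinds: an integer 1..4 or `"R"`
#'   for the full recursive grammar.
#' @param epsilon Uniform-noise probability in `[0, 1]`
#'   (`progression_noise`): with probability `epsilon` the agent replaces
#'   its grammar prediction with a uniform draw over all four boxes.
#' @param g_a,g_b Component grammars for `pmbp` (each 1..4 or `"R"`).
#' @param w Mixture weight in `[0, 1]`: probability of following `g_a` at
#'   each slot, independently across slots.
#' @param delta0 Initial corruption probability in `[0, 1]` (`dynamical`).
#' @param rho Geometric decay rate in `(0, 1)` of the corruption
#'   probability with distance from the most recent prediction error.
#' @param n Context window length for `ngram` (the model remembers
#'   sequences `n` symbols long).
#' @param policy `"argmax"` (modal prediction, ties broken toward the lowest
#'   box index) or `"sample"` (proportional draw) for `ngram`.
#' @param stage_at,stage_k Parallel vectors for `staged`: `stage_at[i]` is
#'   the first sentence id of stage `i`, during which the agent behaves as
#'   the bearing-point grammar `stage_k[i]`.
#' @param label Optional subject label.
#' @return An object of class `agent_config`.
#' @export
agent_config <- function(kind = c("bearing", "random", "progression_noise",
                                  "pmbp", "dynamical", "ngram", "staged"),
                         k = NULL, epsilon = NULL, g_a = NULL, g_b = NULL,
                         w = NULL, delta0 = NULL, rho = NULL, n = NULL,
                         policy = c("argmax", "sample"),
                         stage_at = NULL, stage_k = NULL, label = NULL) {
  kind <- match.arg(kind)
  policy <- match.arg(policy)
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop("`", nm, "` must be a probability in [0, 1]", call. = FALSE)
  }
  chk_k <- function(x, nm) {
    ok <- identical(x, "R") ||
      (length(x) == 1L && !is.na(suppressWarnings(as.numeric(x))) &&
         as.numeric(x) %in% 1:4)
    if (!ok) stop("`", nm, "` must be 1, 2, 3, 4 or \"R\"", call. = FALSE)
  }
  switch(kind,
    bearing = chk_k(k, "k"),
    random = NULL,
    progression_noise = { chk_k(k, "k"); chk_prob(epsilon, "epsilon") },
    pmbp = { chk_k(g_a, "g_a"); chk_k(g_b, "g_b"); chk_prob(w, "w") },
    dynamical = {
      chk_k(k, "k"); chk_prob(delta0, "delta0")
      if (!is.numeric(rho) || rho <= 0 || rho >= 1)
        stop("`rho` must lie in (0, 1)", call. = FALSE)
    },
    ngram = {
      if (!is.numeric(n) || n < 2) stop("`n` must be >= 2", call. = FALSE)
    },
    staged = {
      stopifnot(length(stage_at) == length(stage_k), length(stage_at) >= 1)
      for (kk in stage_k) chk_k(kk, "stage_k")
    }
  )
  structure(list(kind = kind, k = k, epsilon = epsilon, g_a = g_a,
                 g_b = g_b, w = w, delta0 = delta0, rho = rho, n = n,
                 policy = policy, stage_at = stage_at, stage_k = stage_k,
                 label = label),
            class = "agent_config")
}

# Effective counting cap of grammar k on a level-m sentence: a G_k learner
# expects the (2,3,4) block to repeat min(m, k) times; G_R tracks the full
# count m.
bearing_cap <- function(k, level) {
  if (identical(k, "R")) level else pmin(level, as.numeric(k))
}

# Empirical continuation distribution after a box-1 word, estimated from
# the driving sequence.  Bearing-based agents draw their (masked,
# analysis-neutral) nondeterministic predictions from it.
continuation_after_one <- function(sequence) {
  s <- sequence$slots
  to <- s$to_box[s$from_box == 1L & !is.na(s$to_box)]
  tab <- tabulate(to, nbins = 4L)
  if (sum(tab) == 0L) tab <- rep(1L, 4L)
  tab / sum(tab)
}

#' Bearing-point grammar prediction for every slot of a sequence
#'
#' The deterministic core of grammars G_1..G_4 and G_R: after a 2 predict 3,
#' after a 3 predict 4; after the j-th 4 of a level-m sentence predict 2
#' while `j < min(m, k)` (for G_R, while `j < m`) and predict 1 otherwise —
#' so a G_k learner closes the sentence after its k-th (2,3,4) block and,
#' having been surprised, keeps predicting 1 at every later 4 of the
#' sentence, which makes the sentence-final 4 -> 1 transition correct for
#' every grammar.  After a 1 the continuation is nondeterministic; the
#' returned value is a draw from the sequence's empirical continuation
#' rates (these slots are masked in all scoring).
#'
#' @param sequence An `experiment_sequence`.
#' @param k 1..4 or `"R"`; may be a vector with one entry per slot (used by
#'   staged agents).
#' @return Integer vector of predicted boxes, one per slot.
#' @export
bearing_point_predict <- function(sequence, k) {
  s <- sequence$slots
  n <- nrow(s)
  cap <- if (length(k) == 1L) bearing_cap(k, s$sentence_level) else {
    vapply(seq_len(n), function(i) bearing_cap(k[[i]], s$sentence_level[i]), 1)
  }
  pred <- integer(n)
  pred[s$from_box == 2L] <- 3L
  pred[s$from_box == 3L] <- 4L
  is4 <- s$from_box == 4L
  pred[is4] <- ifelse(s$four_index[is4] < cap[is4], 2L, 1L)
  is1 <- s$from_box == 1L
  p1 <- continuation_after_one(sequence)
  pred[is1] <- sample(1:4, sum(is1), replace = TRUE, prob = p1)
  pred
}

# --- incremental backoff n-gram model ---------------------------------------

#' Backoff n-gram next-word distribution from a word history
#'
#' Counts, over the history seen so far, the continuations of the longest
#' context of length at most `n - 1` that has occurred at least once before
#' with a continuation, and normalizes those counts into a distribution over
#' the four boxes.  When even no length-1 context matches (possible only
#' before the first repeated symbol), it backs off to the unigram
#' distribution of the history.  Counts are incremental: only n-grams fully
#' contained in the history are used, so the model's knowledge at word `t`
#' reflects exactly the words `1..t`.
#'
#' @param history Integer vector of observed boxes (nonempty).
#' @param n Model order (context length `n - 1`).
#' @return List with `dist` (numeric length 4, sums to 1), `context_length`
#'   (the backoff length used; 0 for the unigram fallback), `argmax` (modal
#'   box, lowest index on ties).
#' @export
ngram_predict <- function(history, n) {
  t <- length(history)
  if (t == 0L) stop("no context: history is empty", call. = FALSE)
  for (c_len in seq(min(n - 1L, t), 1L)) {
    ctx <- history[(t - c_len + 1L):t]
    counts <- numeric(4L)
    # occurrences of ctx ending at position e <= t - 1 (continuation inside
    # the history)
    if (t - 1L >= c_len) {
      for (e in c_len:(t - 1L)) {
        if (all(history[(e - c_len + 1L):e] == ctx)) {
          counts[history[e + 1L]] <- counts[history[e + 1L]] + 1
        }
      }
    }
    if (sum(counts) > 0) {
      return(list(dist = counts / sum(counts), context_length = c_len,
                  argmax = which.max(counts)))
    }
  }
  counts <- tabulate(history, nbins = 4L)
  list(dist = counts / sum(counts), context_length = 0L,
       argmax = which.max(counts))
}

# Slot-by-slot n-gram distributions over a whole sequence, via hashed
# incremental counts (one pass, O(n) work per word).
ngram_slot_distributions <- function(sequence, n) {
  w <- sequence$words$box
  t_max <- length(w)
  grams <- new.env(hash = TRUE, parent = emptyenv())
  bump <- function(key) {
    grams[[key]] <- (if (is.null(grams[[key]])) 0 else grams[[key]]) + 1
  }
  unigram <- numeric(4L)
  dist <- matrix(NA_real_, nrow = t_max, ncol = 4L)
  ctx_used <- integer(t_max)
  for (t in seq_len(t_max)) {
    # register n-grams ending at t (context of length c followed by w[t])
    unigram[w[t]] <- unigram[w[t]] + 1
    if (t >= 2L) {
      for (c_len in seq_len(min(n - 1L, t - 1L))) {
        ctx_key <- paste(w[(t - c_len):(t - 1L)], collapse = ".")
        bump(paste0("c", c_len, ":", ctx_key))
        bump(paste0("g", c_len, ":", ctx_key, ">", w[t]))
      }
    }
    if (t == t_max) break
    # predict word t + 1 from the longest matching context
    found <- FALSE
    for (c_len in seq(min(n - 1L, t), 1L)) {
      ctx_key <- paste(w[(t - c_len + 1L):t], collapse = ".")
      tot <- grams[[paste0("c", c_len, ":", ctx_key)]]
      if (!is.null(tot) && tot > 0) {
        counts <- vapply(1:4, function(b) {
          v <- grams[[paste0("g", c_len, ":", ctx_key, ">", b)]]
          if (is.null(v)) 0 else v
        }, numeric(1))
        dist[t, ] <- counts / sum(counts)
        ctx_used[t] <- c_len
        found <- TRUE
        break
      }
    }
    if (!found) {
      dist[t, ] <- unigram / sum(unigram)
      ctx_used[t] <- 0L
    }
  }
  list(dist = dist, context_length = ctx_used)
}

#' Expected n-gram prediction accuracy per slot
#'
#' The probability mass the incremental backoff n-gram model places on the
#' word that actually occurs next, for every slot of the sequence (the
#' model's expected trial-level accuracy).
#'
#' @param sequence An `experiment_sequence`.
#' @param n Model order.
#' @return Numeric vector, one entry per slot (`NA` for the final word).
#' @export
ngram_expected_accuracy <- function(sequence, n) {
  d <- ngram_slot_distributions(sequence, n)$dist
  actual <- sequence$slots$to_box
  out <- rep(NA_real_, nrow(d))
  ok <- !is.na(actual)
  out[ok] <- d[cbind(which(ok), actual[ok])]
  out
}

# --- per-agent simulation ---------------------------------------------------

predict_for_agent <- function(config, sequence) {
  s <- sequence$slots
  n_slots <- nrow(s)
  switch(config$kind,
    random = sample(1:4, n_slots, replace = TRUE),
    bearing = bearing_point_predict(sequence, config$k),
    progression_noise = {
      base <- bearing_point_predict(sequence, config$k)
      noisy <- stats::runif(n_slots) < config$epsilon
      base[noisy] <- sample(1:4, sum(noisy), replace = TRUE)
      base
    },
    pmbp = {
      pa <- bearing_point_predict(sequence, config$g_a)
      pb <- bearing_point_predict(sequence, config$g_b)
      ifelse(stats::runif(n_slots) < config$w, pa, pb)
    },
    staged = {
      idx <- findInterval(s$sentence_id, config$stage_at)
      idx[idx < 1L] <- 1L
      k_slot <- config$stage_k[idx]
      bearing_point_predict(sequence, k_slot)
    },
    ngram = {
      d <- ngram_slot_distributions(sequence, config$n)$dist
      if (config$policy == "argmax") {
        apply(d, 1L, function(p) if (anyNA(p)) NA_integer_ else which.max(p))
      } else {
        vapply(seq_len(n_slots), function(t) {
          if (anyNA(d[t, ])) NA_integer_
          else sample(1:4, 1L, prob = d[t, ])
        }, integer(1))
      }
    },
    dynamical = {
      base <- bearing_point_predict(sequence, config$k)
      actual <- s$to_box
      pred <- base
      last_err <- NA_integer_
      for (t in seq_len(n_slots)) {
        if (!is.na(last_err)) {
          d_t <- t - last_err
          if (stats::runif(1L) < config$delta0 * config$rho^(d_t - 1L) &&
              !is.na(actual[t])) {
            pred[t] <- sample(setdiff(1:4, actual[t]), 1L)
          }
        }
        if (!is.na(actual[t]) && pred[t] != actual[t]) last_err <- t
      }
      pred
    }
  )
}

#' Simulate one agent on a sequence
#'
#' @param config An [agent_config()].
#' @param sequence An `experiment_sequence`.
#' @param seed Integer seed (the trace is reproducible given the seed).
#' @return A response-trace tibble with one row per slot: `word_index`,
#'   `predicted`, `actual`, `correct` (0/1, `NA` at the final targetless
#'   slot), plus the slot metadata columns of `sequence$slots`.
#' @export
simulate_agent <- function(config, sequence, seed = 1L) {
  pred <- withr::with_seed(as.integer(seed), predict_for_agent(config, sequence))
  s <- sequence$slots
  tibble::tibble(
    word_index = s$word_index,
    predicted = as.integer(pred),
    actual = s$to_box,
    correct = ifelse(is.na(s$to_box) | is.na(pred), NA_integer_,
                     as.integer(pred == s$to_box)),
    kind = s$kind,
    transition_label = s$transition_label,
    sentence_id = s$sentence_id,
    sentence_level = s$sentence_level,
    position_in_sentence = s$position_in_sentence,
    type_id = s$type_id,
    phase = s$phase
  )
}

#' Simulate a cohort of agents
#'
#' One trace per configuration; subject `i` uses seed `seed + i` so the
#' whole cohort is reproducible from the single cohort seed.
#'
#' @param configs List of [agent_config()] objects (a single config may be
#'   replicated with `n_agents`).
#' @param sequence An `experiment_sequence`.
#' @param seed Integer cohort seed.
#' @param n_agents If `configs` is a single config, replicate it this many
#'   times.
#' @return Tibble of stacked traces with a `subject_id` column.
#' @export
simulate_cohort <- function(configs, sequence, seed = 1L, n_agents = NULL) {
  if (inherits(configs, "agent_config")) {
    configs <- rep(list(configs), if (is.null(n_agents)) 1L else n_agents)
  }
  traces <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    tr <- simulate_agent(cfg, sequence, seed = as.integer(seed) + i)
    tr$subject_id <- if (!is.null(cfg$label)) paste0(cfg$label, "_", i)
                     else paste0("subj", i)
    tr
  })
  dplyr::bind_rows(traces)[, c("subject_id", "word_index", "predicted",
                               "actual", "correct", "kind",
                               "transition_label", "sentence_id",
                               "sentence_level", "position_in_sentence",
                               "type_id", "phase")]
}

#' Write cohort traces as JSON Lines (one record per slot)
#' @param traces Cohort trace tibble.
#' @param path Output path.
#' @export
write_traces_jsonl <- function(traces, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  jsonlite::stream_out(as.data.frame(traces), con, verbose = FALSE)
  invisible(path)
}

#' Write cohort traces as tidy CSV
#' @param traces Cohort trace tibble.
#' @param path Output path.
#' @export
write_traces_csv <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
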