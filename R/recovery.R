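# Parameter recovery for the mixture and dynamical agents.
#
# These estimators close the simulation loop: cohorts generated at known
# parameters must give those parameters back, which both validates the
# generators and shows the hypotheses are empirically discriminable.

# Expected correctness of bearing grammar k at every slot of a sequence
# (1/0 at deterministic slots, NA at nondeterministic and targetless ones).
bearing_expected_correct <- function(sequence, k) {
  s <- sequence$slots
  cap <- bearing_cap(k, s$sentence_level)
  out <- rep(NA_real_, nrow(s))
  det <- s$kind == "deterministic" & !is.na(s$to_box)
  pred <- rep(NA_integer_, nrow(s))
  pred[s$from_box == 2L] <- 3L
  pred[s$from_box == 3L] <- 4L
  is4 <- s$from_box == 4L
  pred[is4] <- ifelse(s$four_index[is4] < cap[is4], 2L, 1L)
  out[det] <- as.numeric(pred[det] == s$to_box[det])
  out
}

#' Moment estimator of the mixture weight of a PMBP cohort
#'
#' At slots where the two component grammars disagree and exactly one is
#' correct, a probabilistic-mixture agent is correct with probability `w`
#' (when grammar A is the correct one) or `1 - w` (when grammar B is).
#' Averaging the suitably oriented correctness over all such slots and
#' subjects estimates `w` in closed form.
#'
#' @param traces Cohort trace tibble from PMBP agents.
#' @param sequence The driving `experiment_sequence`.
#' @param g_a,g_b The two component grammars (1..4 or `"R"`), in the same
#'   roles as in the generating [agent_config()].
#' @return List: `w_hat`, `n_obs` (number of discriminating trials).
#' @export
estimate_pmbp_weight <- function(traces, sequence, g_a, g_b) {
  acc_a <- bearing_expected_correct(sequence, g_a)
  acc_b <- bearing_expected_correct(sequence, g_b)
  a_right <- which(!is.na(acc_a) & !is.na(acc_b) & acc_a == 1 & acc_b == 0)
  b_right <- which(!is.na(acc_a) & !is.na(acc_b) & acc_a == 0 & acc_b == 1)
  if (length(a_right) + length(b_right) == 0L) {
    stop("the two grammars do not disagree anywhere in this sequence",
         call. = FALSE)
  }
  vals <- c()
  for (s in unique(traces$subject_id)) {
    tr <- traces[traces$subject_id == s, ]
    tr <- tr[order(tr$word_index), ]
    vals <- c(vals, tr$correct[a_right], 1 - tr$correct[b_right])
  }
  vals <- vals[!is.na(vals)]
  list(w_hat = mean(vals), n_obs = length(vals))
}

# Distance (in slots) from each slot to the subject's most recent
# prediction error strictly before it; NA before the first error.
distance_since_error <- function(correct) {
  n <- length(correct)
  d <- rep(NA_integer_, n)
  last_err <- NA_integer_
  for (t in seq_len(n)) {
    if (!is.na(last_err)) d[t] <- t - last_err
    if (!is.na(correct[t]) && correct[t] == 0L) last_err <- t
  }
  d
}

#' Grid maximum-likelihood recovery of the dynamical perturbation parameters
#'
#' Under the dynamical agent, a slot at distance `d` from the most recent
#' prediction error is corrupted (and therefore wrong, when the baseline
#' grammar is correct there) with probability `delta0 * rho^(d - 1)`.
#' Restricting to deterministic slots where the baseline grammar is
#' correct, the per-distance error counts follow independent binomials;
#' the likelihood is maximized over a (delta0, rho) grid.
#'
#' @param traces Cohort trace tibble from dynamical agents.
#' @param sequence The driving `experiment_sequence`.
#' @param k Baseline bearing grammar of the generating agents.
#' @param delta0_grid,rho_grid Candidate values searched.
#' @return List: `delta0_hat`, `rho_hat`, `loglik`, `by_distance` tibble
#'   (`d`, `n`, `errors`, `error_rate`).
#' @export
estimate_dynamical <- function(traces, sequence, k,
                               delta0_grid = seq(0.05, 1, by = 0.025),
                               rho_grid = seq(0.05, 0.95, by = 0.025)) {
  base_ok <- which(bearing_expected_correct(sequence, k) == 1)
  all_d <- integer(0); all_err <- integer(0)
  for (s in unique(traces$subject_id)) {
    tr <- traces[traces$subject_id == s, ]
    tr <- tr[order(tr$word_index), ]
    d <- distance_since_error(tr$correct)
    use <- intersect(base_ok, which(!is.na(d) & !is.na(tr$correct)))
    all_d <- c(all_d, d[use])
    all_err <- c(all_err, 1L - tr$correct[use])
  }
  ds <- sort(unique(all_d))
  n_d <- vapply(ds, function(x) sum(all_d == x), 0)
  e_d <- vapply(ds, function(x) sum(all_err[all_d == x]), 0)
  clip <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  best <- c(NA, NA); best_ll <- -Inf
  for (d0 in delta0_grid) {
    for (r in rho_grid) {
      p <- clip(d0 * r^(ds - 1))
      ll <- sum(e_d * log(p) + (n_d - e_d) * log(1 - p))
      if (ll > best_ll) { best_ll <- ll; best <- c(d0, r) }
    }
  }
  list(delta0_hat = best[1], rho_hat = best[2], loglik = best_ll,
       by_distance = tibble::tibble(d = ds, n = n_d, errors = e_d,
                                    error_rate = e_d / n_d))
}
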