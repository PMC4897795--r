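# Statistical tests used by the generalization and dynamical-stability
# analyses: exact binomial tests with Clopper-Pearson intervals,
# chi-square contrasts, cluster-bootstrap logistic fits with odds-ratio
# transforms, and conditional post-error accuracy tables.

#' Exact binomial test with Clopper-Pearson 95% confidence interval
#'
#' Two-sided exact test of `k` successes in `n` trials against the null
#' probability `p0` (minimum-likelihood method: the p-value sums the
#' probabilities of all outcomes no more likely than the observed one),
#' with the exact Clopper-Pearson interval for the proportion.
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p0 Null success probability.
#' @param conf_level Confidence level (default 0.95).
#' @return List: `estimate` (k/n), `p_value`, `conf_int` (length-2),
#'   `k`, `n`, `p0`.
#' @export
exact_binomial <- function(k, n, p0 = 0.5, conf_level = 0.95) {
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  bt <- stats::binom.test(k, n, p = p0, conf.level = conf_level)
  list(estimate = k / n, p_value = bt$p.value,
       conf_int = as.numeric(bt$conf.int), k = k, n = n, p0 = p0)
}

#' Chi-square test on a 2 x 2 contingency table
#'
#' Pearson statistic with 1 degree of freedom; Yates continuity correction
#' is applied by default (the convention for 2 x 2 tables of small counts).
#'
#' @param table 2 x 2 matrix of nonnegative counts.
#' @param continuity Apply the Yates correction (default `TRUE`).
#' @return List: `statistic`, `df`, `p_value`.
#' @export
chi_square_2x2 <- function(table, continuity = TRUE) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("chi-square undefined: zero marginal", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = continuity))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

# Detect (quasi-)complete separation in a fitted logit: some coefficient
# diverging, or fitted probabilities pinned at 0/1.
logit_separated <- function(fit) {
  any(abs(stats::coef(fit)) > 15, na.rm = TRUE) ||
    any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
}

fit_logit_once <- function(formula, data) {
  fit <- suppressWarnings(stats::glm(formula, data = data,
                                     family = stats::binomial()))
  if (!logit_separated(fit)) {
    return(list(coef = stats::coef(fit), separated = FALSE))
  }
  # ridge-stabilized fallback for separated resamples/fits
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- stats::model.matrix(formula, mf)[, -1L, drop = FALSE]
  if (ncol(x) == 0L) return(list(coef = stats::coef(fit), separated = TRUE))
  rf <- glmnet::glmnet(cbind(x, 0), y, family = "binomial", alpha = 0,
                       lambda = 1e-3, standardize = FALSE)
  beta <- as.numeric(rf$beta)[seq_len(ncol(x))]
  cf <- c(as.numeric(rf$a0), beta)
  names(cf) <- c("(Intercept)", colnames(x))
  list(coef = cf, separated = TRUE)
}

#' Logistic fit of binary trial accuracy with by-subject cluster bootstrap
#'
#' Fixed-effects maximum-likelihood logit of a binary outcome on a design
#' (e.g. accuracy on word type, or on previous-transition accuracy), with
#' odds ratios `exp(b)` and percentile confidence intervals from a
#' bootstrap that resamples whole subjects (clusters) with replacement —
#' respecting the within-subject dependence of trial-level data.  Complete
#' separation is flagged and handled with a lightly ridge-penalized refit.
#'
#' @param formula Model formula (left side binary 0/1).
#' @param data Data frame of trials.
#' @param cluster Name of the subject/cluster column.
#' @param n_boot Number of bootstrap resamples (default 200).
#' @param conf_level Confidence level for the percentile intervals.
#' @param seed Integer seed for the bootstrap.
#' @return List: `coef`, `odds_ratio`, `ci_coef` (matrix), `ci_or`,
#'   `separated`, `n_boot`.
#' @export
logistic_fit <- function(formula, data, cluster = "subject_id",
                         n_boot = 200L, conf_level = 0.95, seed = 1L) {
  ids <- unique(data[[cluster]])
  if (length(ids) < 2L) stop("need at least 2 clusters", call. = FALSE)
  main <- fit_logit_once(formula, data)
  alpha <- (1 - conf_level) / 2
  boots <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_boot), function(b) {
      take <- sample(ids, length(ids), replace = TRUE)
      dat <- dplyr::bind_rows(lapply(take, function(id) {
        data[data[[cluster]] == id, ]
      }))
      out <- try(fit_logit_once(formula, dat)$coef, silent = TRUE)
      if (inherits(out, "try-error")) rep(NA_real_, length(main$coef)) else out
    })
  })
  bmat <- do.call(rbind, boots)
  ci <- t(apply(bmat, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE))
  rownames(ci) <- names(main$coef)
  list(coef = main$coef, odds_ratio = exp(main$coef), ci_coef = ci,
       ci_or = exp(ci), separated = main$separated, n_boot = n_boot)
}

#' Conditional accuracy on a target transition, split by previous accuracy
#'
#' Takes every occurrence of the target transition (e.g. 2 -> 3)
#' immediately following the conditioning transition (e.g. 4 -> 2) in the
#' word stream and cross-tabulates the target's correctness by whether the
#' conditioning prediction was correct (`prev_acc` 0 vs 1).  Under
#' dynamical post-error perturbation, accuracy after an error is depressed
#' even on transitions every grammar predicts with certainty; under a pure
#' grammar mixture the two conditional rates coincide.
#'
#' @param traces Cohort trace tibble.
#' @param target_label Transition label to score (default `"T23"`).
#' @param cond_label Required label of the immediately preceding slot
#'   (default `"T42"`).
#' @return Tibble: `prev_acc`, `n`, `n_correct`, `accuracy` (empty cells
#'   reported with `n = 0`).
#' @export
conditional_accuracy <- function(traces, target_label = "T23",
                                 cond_label = "T42") {
  per_subject <- split(traces, traces$subject_id)
  rows <- lapply(per_subject, function(tr) {
    tr <- tr[order(tr$word_index), ]
    idx <- which(tr$transition_label == target_label &
                   c(NA, tr$transition_label[-nrow(tr)]) == cond_label)
    idx <- idx[idx > 1L]
    if (length(idx) == 0L) return(NULL)
    tibble::tibble(subject_id = tr$subject_id[1L],
                   prev_acc = tr$correct[idx - 1L],
                   correct = tr$correct[idx])
  })
  dat <- dplyr::bind_rows(rows)
  dat <- dat[!is.na(dat$prev_acc) & !is.na(dat$correct), ]
  out <- dplyr::summarise(dplyr::group_by(dat, .data$prev_acc),
                          n = dplyr::n(),
                          n_correct = sum(.data$correct),
                          accuracy = mean(.data$correct), .groups = "drop")
  # report empty cells explicitly
  for (pa in c(0L, 1L)) {
    if (!pa %in% out$prev_acc) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        prev_acc = pa, n = 0L, n_correct = 0L, accuracy = NA_real_))
    }
  }
  out[order(out$prev_acc), ]
}

#' Trial-level data for the conditional analyses
#'
#' Convenience reshaping: every target-transition trial with its preceding
#' slot's correctness attached, ready for [logistic_fit()].
#'
#' @inheritParams conditional_accuracy
#' @return Tibble: `subject_id`, `word_index`, `correct`, `prev_acc`.
#' @export
conditional_trials <- function(traces, target_label = "T23",
                               cond_label = "T42") {
  per_subject <- split(traces, traces$subject_id)
  rows <- lapply(per_subject, function(tr) {
    tr <- tr[order(tr$word_index), ]
    idx <- which(tr$transition_label == target_label &
                   c(NA, tr$transition_label[-nrow(tr)]) == cond_label)
    idx <- idx[idx > 1L]
    if (length(idx) == 0L) return(NULL)
    tibble::tibble(subject_id = tr$subject_id[1L],
                   word_index = tr$word_index[idx],
                   correct = tr$correct[idx],
                   prev_acc = tr$correct[idx - 1L])
  })
  dat <- dplyr::bind_rows(rows)
  dat[!is.na(dat$prev_acc) & !is.na(dat$correct), ]
}
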