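#' Consensus scoring parameters
#'
#' Bundles the reference values against which multicentre evidence is
#' judged: `c`, the minimum net number of direction-agreeing centres;
#' `q_hat`, the expected q-value under a real effect; `rho_hat`, the
#' expected standardised effect size; and `M`, the total number of centres
#' in the study (which may exceed the number reporting any one trait).
#' The recommended defaults for high-throughput screens are `c = 3`,
#' `q_hat = 0.05` and a moderate `rho_hat = 0.5`; `rho_hat` can instead be
#' calibrated from data with [calibrate_rho_hat()].
#'
#' @param c Non-negative integer threshold on the net centre count.
#' @param q_hat Expected q-value, in `(0, 1]`.
#' @param rho_hat Expected standardised effect size, positive.
#' @param M Total centres in the study; defaults at scoring time to the
#'   number of centres reporting the trait.
#' @return An object of class `consensus_params`.
#' @export
consensus_params <- function(c = 3L, q_hat = 0.05, rho_hat = 0.5, M = NULL) {
  if (length(c) != 1L || c < 0 || c != round(c)) {
    stop("consensus_params: 'c' must be a non-negative integer", call. = FALSE)
  }
  if (length(q_hat) != 1L || q_hat <= 0 || q_hat > 1) {
    stop("consensus_params: 'q_hat' must be in (0, 1]", call. = FALSE)
  }
  if (length(rho_hat) != 1L || rho_hat <= 0) {
    stop("consensus_params: 'rho_hat' must be positive", call. = FALSE)
  }
  if (!is.null(M) && (length(M) != 1L || M < 1 || M != round(M))) {
    stop("consensus_params: 'M' must be a positive integer", call. = FALSE)
  }
  structure(list(c = as.integer(c), q_hat = q_hat, rho_hat = rho_hat,
                 M = if (is.null(M)) NULL else as.integer(M)),
            class = "consensus_params")
}

#' Directionality penalty
#'
#' `P = |sum_i sign(rho_i)| / M_bar`, with `sign(0) = 0`: the absolute net
#' fraction of centres agreeing on the direction of the effect.  `P = 1`
#' when every centre points the same way, `0` when directions balance.
#' `P * M_bar` is always the integer `|sum_i sign(rho_i)|`, so the gate
#' `M_bar * P > c` is an exact integer comparison.
#'
#' @param effect_sizes Non-empty numeric vector of per-centre standardised
#'   effect sizes.
#' @return A number in `[0, 1]`.
#' @examples
#' direction_penalty(c(0.5, 0.3, 0.9, -0.1))  # |3 - 1| / 4 = 0.5
#' @export
direction_penalty <- function(effect_sizes) {
  if (length(effect_sizes) == 0L) {
    stop("direction_penalty: empty effect-size vector", call. = FALSE)
  }
  if (!all(is.finite(effect_sizes))) {
    stop("direction_penalty: effect sizes must be finite", call. = FALSE)
  }
  abs(sum(sign(effect_sizes))) / length(effect_sizes)
}

#' Multicentre consensus score for one trait
#'
#' Aggregates per-centre q-values and standardised effect sizes into the
#' global consensus score
#' \deqn{s = \frac{\sum_i q_i \sqrt{|\rho_i|}}{\bar{M}^2\, \hat{q}\,
#'   \sqrt{\hat{\rho}}} \times \max(M/2, \bar{M})}
#' computed only when the directionality gate `M_bar * P > c` passes; when
#' the gate fails the score is 1 by definition (no usable information on
#' agreement).  Scoring requires strictly more than `c` reporting centres;
#' with the default `c = 3` a trait measured by three or fewer centres is
#' below the minimum requirement.  Evidence is read off `-log10(s)`:
#' positive values mean the centres agree more strongly than the expected
#' reference evidence (`q_hat`, `rho_hat`) would, and consensus is
#' declared with direction given by the sign of the mean effect size.
#'
#' The score is non-decreasing in every `q_i` and every `|rho_i|`
#' (more significant centres can only strengthen consensus), invariant to
#' centre ordering, and equals 1 exactly when all centres sit exactly at
#' the expected values with `M = M_bar`.
#'
#' @param results Data frame of per-centre results for a single trait with
#'   `effect_size` and `q_value` set on every row (run [apply_fdr()]
#'   first).  `M_bar` is its number of rows.
#' @param params A [consensus_params()] object; if its `M` is `NULL` the
#'   number of reporting centres is used.  `params$M` must be `>= M_bar`.
#' @param weighted_mean If `TRUE` the reported mean effect size is weighted
#'   by per-centre sample size (`n_male + n_female`); default is the
#'   unweighted arithmetic mean.
#' @return An object of class `consensus_outcome`: a list with `trait_id`,
#'   `m_bar`, `penalty`, `score`, `neglog_score`, `decision` (one of
#'   `"INSUFFICIENT_CENTRES"`, `"INSUFFICIENT_INFO"`, `"CONSENSUS"`,
#'   `"NO_CONSENSUS"`), `direction` (`"MALE_HIGHER"`, `"FEMALE_HIGHER"`,
#'   `"NONE"`) and `mean_effect`.
#' @examples
#' res <- data.frame(centre_id = paste0("C", 1:4), trait_id = "rbc",
#'                   effect_size = c(0.6, 0.5, 0.7, 0.55),
#'                   q_value = c(0.01, 0.02, 0.03, 0.04))
#' consensus_score(res, consensus_params())
#' @export
consensus_score <- function(results, params = consensus_params(),
                            weighted_mean = FALSE) {
  stopifnot(is.data.frame(results), inherits(params, "consensus_params"))
  if (nrow(results) == 0L) {
    stop("consensus_score: no per-centre results supplied", call. = FALSE)
  }
  trait_id <- if ("trait_id" %in% names(results)) as.character(results$trait_id[1]) else NA_character_
  if (!"effect_size" %in% names(results) || anyNA(results$effect_size)) {
    stop("consensus_score: every centre needs an effect_size", call. = FALSE)
  }
  if (!"q_value" %in% names(results) || anyNA(results$q_value)) {
    stop("consensus_score: q_value missing; run apply_fdr() on the results first",
         call. = FALSE)
  }

  m_bar <- nrow(results)
  M <- if (is.null(params$M)) m_bar else params$M
  if (M < m_bar) {
    stop(sprintf("consensus_score: total centres M (%d) cannot be smaller than reporting centres M_bar (%d)",
                 M, m_bar), call. = FALSE)
  }

  rho <- results$effect_size
  # q-values are probabilities; clamp defensively
  q <- pmin(pmax(results$q_value, 0), 1)

  mean_effect <- if (weighted_mean) {
    w <- results$n_male + results$n_female
    stats::weighted.mean(rho, w)
  } else {
    mean(rho)
  }

  penalty <- direction_penalty(rho)
  net <- abs(sum(sign(rho)))   # == m_bar * penalty, an exact integer

  if (m_bar <= params$c) {
    return(.outcome(trait_id, m_bar, penalty, NA_real_, NA_real_,
                    "INSUFFICIENT_CENTRES", "NONE", mean_effect))
  }
  if (net <= params$c) {
    return(.outcome(trait_id, m_bar, penalty, 1, 0,
                    "INSUFFICIENT_INFO", "NONE", mean_effect))
  }

  score <- sum(q * sqrt(abs(rho))) /
    (m_bar^2 * params$q_hat * sqrt(params$rho_hat)) * max(M / 2, m_bar)
  nls <- neglog_score(score)
  decision <- if (nls > 0) "CONSENSUS" else "NO_CONSENSUS"
  direction <- if (decision != "CONSENSUS") "NONE"
               else if (mean_effect > 0) "MALE_HIGHER" else "FEMALE_HIGHER"
  .outcome(trait_id, m_bar, penalty, score, nls, decision, direction,
           mean_effect)
}

.outcome <- function(trait_id, m_bar, penalty, score, neglog, decision,
                     direction, mean_effect) {
  structure(list(trait_id = trait_id, m_bar = m_bar, penalty = penalty,
                 score = score, neglog_score = neglog, decision = decision,
                 direction = direction, mean_effect = mean_effect),
            class = "consensus_outcome")
}

#' @export
print.consensus_outcome <- function(x, digits = 2, ...) {
  cat(sprintf("Consensus outcome for trait '%s'\n", x$trait_id))
  cat(sprintf("  centres reporting (M_bar): %d, penalty P: %.2f\n",
              x$m_bar, x$penalty))
  if (is.na(x$score)) {
    cat("  score: not computed\n")
  } else {
    cat(sprintf("  score: %s, -log10(score): %s\n",
                format(round(x$score, digits), nsmall = digits),
                format(round(x$neglog_score, digits), nsmall = digits)))
  }
  cat(sprintf("  decision: %s  ->  %s\n", x$decision, classify(x)))
  invisible(x)
}

#' Negative log10 of a consensus score
#'
#' The decision scale of the method: `-log10(s) > 0` (that is, `s < 1`)
#' indicates cross-centre agreement stronger than the expected reference
#' evidence.  Base 10 is used throughout the package.
#'
#' @param score Positive consensus score.
#' @return `-log10(score)`.
#' @export
neglog_score <- function(score) {
  if (!is.numeric(score) || any(!is.finite(score)) || any(score <= 0)) {
    stop("neglog_score: score must be positive and finite", call. = FALSE)
  }
  -log10(score)
}

#' Report phrase for a consensus outcome
#'
#' Maps the decision and direction of a [consensus_score()] outcome to the
#' standard reporting phrases: `"Males Higher"`, `"Female Higher"`,
#' `"Not enough signal between or across centres to detect SD"` (covers
#' both a score of 1 from the directionality gate and `-log10(s) <= 0`),
#' and `"Does not reach the minimum requirements for this analysis"` when
#' too few centres report the trait.
#'
#' @param outcome A `consensus_outcome` object.
#' @return A single string.
#' @export
classify <- function(outcome) {
  stopifnot(inherits(outcome, "consensus_outcome"))
  switch(outcome$decision,
    INSUFFICIENT_CENTRES = "Does not reach the minimum requirements for this analysis",
    INSUFFICIENT_INFO = "Not enough signal between or across centres to detect SD",
    NO_CONSENSUS = "Not enough signal between or across centres to detect SD",
    CONSENSUS = if (outcome$direction == "MALE_HIGHER") "Males Higher" else "Female Higher",
    stop("classify: unknown decision ", outcome$decision, call. = FALSE)
  )
}

#' Calibrate the expected effect size from observed effects
#'
#' Empirical alternative to the default `rho_hat = 0.5`: the trimmed mean
#' of the absolute observed standardised effect sizes, removing
#' `floor(trim_fraction * n)` values from each tail of the sorted
#' magnitudes.  A 10% trim is the conventional choice.
#'
#' @param effect_sizes Non-empty numeric vector of standardised effect
#'   sizes (signs are ignored).
#' @param trim_fraction Fraction trimmed from each tail, in `[0, 0.5)`.
#' @return Positive number usable as `rho_hat` in [consensus_params()].
#' @examples
#' calibrate_rho_hat(1:10, trim_fraction = 0.1)  # mean of 2..9 = 5.5
#' @export
calibrate_rho_hat <- function(effect_sizes, trim_fraction = 0.10) {
  if (length(effect_sizes) == 0L) {
    stop("calibrate_rho_hat: empty effect-size vector", call. = FALSE)
  }
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    stop("calibrate_rho_hat: trim_fraction must be in [0, 0.5)", call. = FALSE)
  }
  x <- sort(abs(effect_sizes))
  k <- floor(trim_fraction * length(x))
  if (2 * k >= length(x)) {
    stop("calibrate_rho_hat: trimming removed every value", call. = FALSE)
  }
  mean(x[(k + 1):(length(x) - k)])
}

#' Score every trait in a per-centre results table
#'
#' Applies [consensus_score()] and [classify()] to each trait of a q-value
#' annotated results table and returns a per-trait summary suitable for
#' reporting.
#'
#' @param results Per-centre results with `q_value` set (see
#'   [apply_fdr()]).
#' @param params A [consensus_params()] object.  If its `M` is `NULL` the
#'   total number of distinct centres in `results` is used for every trait,
#'   so traits measured by a subset of centres are still judged against the
#'   study-wide centre count.
#' @param weighted_mean Passed to [consensus_score()].
#' @param rounding Decimal places for the reported `score` and
#'   `neglog_score` columns (full precision is kept internally and used for
#'   all decisions); `NULL` disables rounding.
#' @return Data frame with one row per trait: `trait_id`, `m_bar`,
#'   `penalty`, `score`, `neglog_score`, `decision`, `direction`,
#'   `mean_effect_size`, `inference`.
#' @export
score_traits <- function(results, params = consensus_params(),
                         weighted_mean = FALSE, rounding = NULL) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0L) stop("score_traits: empty results", call. = FALSE)
  if (is.null(params$M)) {
    params$M <- length(unique(results$centre_id))
  }
  traits <- unique(as.character(results$trait_id))
  rows <- lapply(traits, function(tr) {
    out <- consensus_score(results[results$trait_id == tr, , drop = FALSE],
                           params, weighted_mean = weighted_mean)
    data.frame(trait_id = tr,
               m_bar = out$m_bar,
               penalty = out$penalty,
               score = out$score,
               neglog_score = out$neglog_score,
               decision = out$decision,
               direction = out$direction,
               mean_effect_size = out$mean_effect,
               inference = classify(out),
               stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, rows)
  if (!is.null(rounding)) {
    scores$score <- round(scores$score, rounding)
    scores$neglog_score <- round(scores$neglog_score, rounding)
  }
  rownames(scores) <- NULL
  scores
}
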