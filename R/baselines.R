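#' All-centres-agree baseline rule
#'
#' The binary vote-counting comparison method: consensus is declared only
#' when every reporting centre is significant (`q_value < alpha`) and all
#' effect sizes share one sign.  Unlike the consensus score, this rule has
#' no minimum-centre gate and no notion of strength of agreement.
#'
#' @param results Per-centre results for one trait, `q_value` set.
#' @param alpha Significance threshold on the q-values (default 0.05).
#' @return List with `agree` (logical) and `direction` (`"MALE_HIGHER"`,
#'   `"FEMALE_HIGHER"` or `"NONE"`).
#' @export
all_agree <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0L) {
    stop("all_agree: no per-centre results supplied", call. = FALSE)
  }
  if (anyNA(results$q_value)) {
    stop("all_agree: q_value missing; run apply_fdr() first", call. = FALSE)
  }
  sgn <- sign(results$effect_size)
  agree <- all(results$q_value < alpha) &&
    all(sgn != 0) && length(unique(sgn)) == 1L
  direction <- if (!agree) "NONE" else if (sgn[1] > 0) "MALE_HIGHER" else "FEMALE_HIGHER"
  list(agree = agree, direction = direction)
}

#' Random-effects meta-analysis (DerSimonian-Laird)
#'
#' Inverse-variance pooling of per-centre effects with the closed-form
#' DerSimonian-Laird moment estimator of the between-centre variance:
#' fixed-effect weights `w = 1/se^2`, Cochran's
#' `Q = sum(w * (y - y_FE)^2)`,
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))`, then
#' random-effect weights `1/(se^2 + tau2)`.  The pooled effect is tested
#' two-sided against a standard normal and heterogeneity via `Q` against a
#' chi-square with `k - 1` degrees of freedom.  When `tau2 = 0` the pooled
#' estimate reduces to the fixed-effect estimate; it always lies between
#' the smallest and largest input effect.
#'
#' @param effects Numeric vector of per-centre effect sizes.
#' @param ses Matching vector of positive standard errors.
#' @return Object of class `meta_outcome`: list with `k`, `pooled_effect`,
#'   `pooled_se`, `z`, `p_pooled`, `tau2`, `Q`, `df`, `p_heterogeneity`.
#'   With a single study the pooled effect is that study's effect and the
#'   heterogeneity fields are `NA`.
#' @examples
#' random_effects_meta(c(0.2, 0.8), c(0.2, 0.2))
#' @export
random_effects_meta <- function(effects, ses) {
  k <- length(effects)
  if (k == 0L) stop("random_effects_meta: no studies", call. = FALSE)
  if (length(ses) != k) {
    stop("random_effects_meta: 'effects' and 'ses' lengths differ", call. = FALSE)
  }
  if (any(!is.finite(effects)) || any(!is.finite(ses)) || any(ses <= 0)) {
    stop("random_effects_meta: effects must be finite and ses positive",
         call. = FALSE)
  }
  if (k == 1L) {
    return(structure(list(k = 1L, pooled_effect = effects, pooled_se = ses,
                          z = effects / ses,
                          p_pooled = 2 * stats::pnorm(-abs(effects / ses)),
                          tau2 = 0, Q = NA_real_, df = 0L,
                          p_heterogeneity = NA_real_),
                     class = "meta_outcome"))
  }
  w <- 1 / ses^2
  y_fe <- sum(w * effects) / sum(w)
  Q <- sum(w * (effects - y_fe)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  w_re <- 1 / (ses^2 + tau2)
  pooled <- sum(w_re * effects) / sum(w_re)
  se <- sqrt(1 / sum(w_re))
  z <- pooled / se
  structure(list(k = as.integer(k), pooled_effect = pooled, pooled_se = se,
                 z = z, p_pooled = 2 * stats::pnorm(-abs(z)),
                 tau2 = tau2, Q = Q, df = k - 1L,
                 p_heterogeneity = stats::pchisq(Q, df = k - 1, lower.tail = FALSE)),
            class = "meta_outcome")
}

#' @export
print.meta_outcome <- function(x, digits = 4, ...) {
  cat(sprintf("Random-effects meta-analysis (DerSimonian-Laird), k = %d\n", x$k))
  cat(sprintf("  pooled effect %s (se %s), z = %s, p = %s\n",
              signif(x$pooled_effect, digits), signif(x$pooled_se, digits),
              signif(x$z, digits), signif(x$p_pooled, digits)))
  if (x$df > 0L) {
    cat(sprintf("  tau2 = %s, Q = %s (df %d), heterogeneity p = %s\n",
                signif(x$tau2, digits), signif(x$Q, digits), x$df,
                signif(x$p_heterogeneity, digits)))
  }
  invisible(x)
}

#' Side-by-side comparison of consensus score and baselines
#'
#' For each trait in a q-value annotated results table, computes the
#' consensus decision, the all-centres-agree flag and the random-effects
#' meta-analysis (pooled-effect p and heterogeneity p).  The meta-analysis
#' column of multicentre reports is ambiguous between the two p-values, so
#' both are emitted.
#'
#' @param results Per-centre results with `q_value`, `effect_size` and
#'   `effect_se` set.
#' @param params A [consensus_params()] object.
#' @param alpha Threshold for the all-agree rule.
#' @return Data frame: `trait_id`, `decision`, `all_agree`,
#'   `meta_pooled_effect`, `meta_p_pooled`, `meta_tau2`,
#'   `meta_p_heterogeneity`.
#' @export
compare_baselines <- function(results, params = consensus_params(),
                              alpha = 0.05) {
  stopifnot(is.data.frame(results))
  if (is.null(params$M)) params$M <- length(unique(results$centre_id))
  traits <- unique(as.character(results$trait_id))
  rows <- lapply(traits, function(tr) {
    r <- results[results$trait_id == tr, , drop = FALSE]
    cons <- consensus_score(r, params)
    agg <- all_agree(r, alpha = alpha)
    meta <- random_effects_meta(r$effect_size, r$effect_se)
    data.frame(trait_id = tr,
               decision = cons$decision,
               all_agree = agg$agree,
               meta_pooled_effect = meta$pooled_effect,
               meta_p_pooled = meta$p_pooled,
               meta_tau2 = meta$tau2,
               meta_p_heterogeneity = meta$p_heterogeneity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
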