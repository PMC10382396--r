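#' Standardise a vector of measurements
#'
#' Centres and scales a vector to sample mean 0 and sample standard
#' deviation 1 (denominator `n - 1`).  Within the pipeline this is applied
#' to all animals of one centre x trait group, both sexes pooled, so that
#' centre-specific location and scale shifts -- typically due to equipment
#' differences between laboratories -- are removed before any effect is
#' estimated.
#'
#' @param values Numeric vector, at least two finite values with non-zero
#'   variance.
#' @param centre_id,trait_id Optional identifiers used only to make error
#'   messages traceable to the offending group.
#' @return Numeric vector of the same length with sample mean 0 and sample
#'   SD 1.  The transformation is affine-equivariant: `standardise(a*x + b)`
#'   equals `standardise(x)` for any `a > 0`.
#' @examples
#' standardise(c(2, 4, 6))   # -1 0 1
#' @export
standardise <- function(values, centre_id = NULL, trait_id = NULL) {
  ctx <- .group_label(centre_id, trait_id)
  if (!is.numeric(values)) {
    stop("standardise: 'values' must be numeric", ctx, call. = FALSE)
  }
  if (length(values) < 2L) {
    stop("standardise: need at least 2 values", ctx, call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("standardise: all values must be finite", ctx, call. = FALSE)
  }
  s <- stats::sd(values)
  if (s == 0) {
    stop("standardise: zero variance (all values identical)", ctx,
         call. = FALSE)
  }
  (values - mean(values)) / s
}

.group_label <- function(centre_id, trait_id) {
  parts <- c(if (!is.null(centre_id)) paste0("centre ", centre_id),
             if (!is.null(trait_id)) paste0("trait ", trait_id))
  if (length(parts) == 0L) "" else paste0(" [", paste(parts, collapse = ", "), "]")
}

#' Cohen's d standardised mean difference
#'
#' `(mean(a) - mean(b)) / s_pooled`, where the pooled standard deviation
#' uses the classical pooled-variance formula with `n_a + n_b - 2` in the
#' denominator.  With the male group first, positive values mean males are
#' higher.
#'
#' @param group_a,group_b Numeric vectors with at least two values each.
#' @return A single number; antisymmetric in its arguments.
#' @examples
#' cohens_d(c(3, 4, 5), c(1, 2, 3))  # 2
#' @export
cohens_d <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("cohens_d: each group needs at least 2 values", call. = FALSE)
  }
  if (!all(is.finite(group_a)) || !all(is.finite(group_b))) {
    stop("cohens_d: values must be finite", call. = FALSE)
  }
  na <- length(group_a)
  nb <- length(group_b)
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 <= 0) {
    stop("cohens_d: zero pooled variance", call. = FALSE)
  }
  (mean(group_a) - mean(group_b)) / sqrt(sp2)
}

#' Large-sample standard error of Cohen's d
#'
#' The usual asymptotic formula
#' `sqrt((n_a + n_b) / (n_a * n_b) + d^2 / (2 * (n_a + n_b)))`, needed to
#' feed per-centre effects into the inverse-variance meta-analysis
#' baseline.
#'
#' @param d Standardised effect size.
#' @param n_a,n_b Group sizes, both at least 2.
#' @return Positive number, strictly increasing in `|d|` at fixed sizes.
#' @examples
#' effect_se(0, 50, 50)  # 0.2
#' @export
effect_se <- function(d, n_a, n_b) {
  if (!is.finite(d)) stop("effect_se: 'd' must be finite", call. = FALSE)
  if (n_a < 2 || n_b < 2) {
    stop("effect_se: group sizes must be at least 2", call. = FALSE)
  }
  sqrt((n_a + n_b) / (n_a * n_b) + d^2 / (2 * (n_a + n_b)))
}

#' Per-centre test of sexual dimorphism for one centre x trait group
#'
#' Standardises the values within the group (both sexes pooled), then fits
#' the linear mixed model `value ~ sex + body_weight + (1 | batch)` and
#' reports the two-sided p-value of the sex term together with a
#' model-adjusted standardised effect size: the sex coefficient divided by
#' the model's residual standard deviation, positive when adjusted male
#' means exceed female means (Cohen's d scale).  When fewer than three
#' distinct batches are present, or the mixed fit is singular or fails, an
#' ordinary least-squares fit of `value ~ sex + body_weight` is used
#' instead and a message is logged.  A constant body-weight column is
#' dropped from the fixed effects automatically.
#'
#' With constant body weight and a single batch the result coincides with
#' the two-sample equal-variance t-test and Cohen's d computed on the raw
#' groups.
#'
#' @param records Data frame for one centre x trait with columns `sex`
#'   (`"male"`/`"female"`), `value`, and optionally `body_weight` and
#'   `batch`.  Rows with missing body weight are dropped (with a logged
#'   count) because the covariate is part of the model.
#' @param min_per_sex Minimum animals per sex required (default 2).
#' @return One-row data frame with columns `centre_id`, `trait_id`,
#'   `n_male`, `n_female`, `effect_size`, `effect_se`, `p_value`,
#'   `q_value` (NA; set later by [apply_fdr()]).
#' @seealso [centre_statistics()] to map this over a full measurement table.
#' @export
fit_sex_model <- function(records, min_per_sex = 2L) {
  stopifnot(is.data.frame(records))
  centre_id <- if ("centre_id" %in% names(records)) as.character(records$centre_id[1]) else NA_character_
  trait_id  <- if ("trait_id" %in% names(records)) as.character(records$trait_id[1]) else NA_character_
  ctx <- .group_label(centre_id, trait_id)

  sex <- .normalise_sex(records$sex)
  value <- records$value
  has_bw <- "body_weight" %in% names(records)
  bw <- if (has_bw) records$body_weight else rep(NA_real_, nrow(records))

  if (has_bw && anyNA(bw)) {
    keep <- !is.na(bw)
    message(sprintf("fit_sex_model: dropped %d record(s) with missing body weight%s",
                    sum(!keep), ctx))
    sex <- sex[keep]; value <- value[keep]; bw <- bw[keep]
    records <- records[keep, , drop = FALSE]
  }

  n_male <- sum(sex == "male")
  n_female <- sum(sex == "female")
  if (n_male < min_per_sex || n_female < min_per_sex) {
    stop(sprintf("fit_sex_model: need at least %d animals per sex (got %d male, %d female)%s",
                 min_per_sex, n_male, n_female, ctx), call. = FALSE)
  }

  z <- standardise(value, centre_id, trait_id)
  dat <- data.frame(z = z, sex = factor(sex, levels = c("female", "male")))
  use_bw <- has_bw && stats::sd(bw) > 0
  if (use_bw) dat$body_weight <- bw

  batch <- if ("batch" %in% names(records)) as.character(records$batch) else rep("b1", nrow(dat))
  dat$batch <- batch
  n_batches <- length(unique(batch))

  fixed <- if (use_bw) z ~ sex + body_weight else z ~ sex
  fit <- NULL
  if (n_batches >= 3L) {
    mixed_formula <- stats::update(fixed, . ~ . + (1 | batch))
    fit <- tryCatch({
      m <- lmerTest::lmer(mixed_formula, data = dat, REML = TRUE)
      if (lme4::isSingular(m, tol = 1e-4)) NULL else m
    }, error = function(e) NULL)
    if (is.null(fit)) {
      message(sprintf("fit_sex_model: batch random effect singular or unfittable, falling back to fixed-effects model%s", ctx))
    }
  } else if (n_batches > 1L) {
    message(sprintf("fit_sex_model: only %d batch(es), using fixed-effects model%s",
                    n_batches, ctx))
  }

  if (is.null(fit)) {
    m <- stats::lm(fixed, data = dat)
    cf <- summary(m)$coefficients
    beta <- cf["sexmale", "Estimate"]
    p <- cf["sexmale", "Pr(>|t|)"]
    sigma <- stats::sigma(m)
  } else {
    cf <- stats::coef(summary(fit))
    beta <- cf["sexmale", "Estimate"]
    p <- cf["sexmale", "Pr(>|t|)"]
    sigma <- stats::sigma(fit)
  }

  d <- beta / sigma
  data.frame(
    centre_id = centre_id,
    trait_id = trait_id,
    n_male = n_male,
    n_female = n_female,
    effect_size = d,
    effect_se = effect_se(d, n_male, n_female),
    p_value = min(max(p, 0), 1),
    q_value = NA_real_,
    stringsAsFactors = FALSE
  )
}

.normalise_sex <- function(sex) {
  s <- tolower(trimws(as.character(sex)))
  s[s == "m"] <- "male"
  s[s == "f"] <- "female"
  bad <- !s %in% c("male", "female")
  if (any(bad)) {
    stop(sprintf("unknown sex token(s): %s",
                 paste(unique(sex[bad]), collapse = ", ")), call. = FALSE)
  }
  s
}

#' Per-centre statistics for every centre x trait group
#'
#' Splits a long-format measurement table by centre and trait and applies
#' [fit_sex_model()] to each group, returning a stacked per-centre results
#' table ready for FDR correction and consensus scoring.  Groups that fail
#' the per-sex sample-size requirement are skipped with a message rather
#' than aborting the run.
#'
#' @param measurements Data frame in the measurement layout (see
#'   [read_measurements()]).
#' @param min_per_sex Minimum animals per sex for a group to be analysed.
#'   Consortium-scale screens conventionally require 50 per sex; pass
#'   `impc_mode = TRUE` to apply that filter.
#' @param impc_mode If `TRUE`, raises `min_per_sex` to 50.
#' @return Data frame with one row per analysed centre x trait:
#'   `centre_id`, `trait_id`, `n_male`, `n_female`, `effect_size`,
#'   `effect_se`, `p_value`, `q_value` (NA until [apply_fdr()] is run).
#' @export
centre_statistics <- function(measurements, min_per_sex = 2L, impc_mode = FALSE) {
  stopifnot(is.data.frame(measurements))
  if (nrow(measurements) == 0L) {
    stop("centre_statistics: empty measurement table", call. = FALSE)
  }
  if (impc_mode) min_per_sex <- max(min_per_sex, 50L)
  groups <- split(measurements,
                  list(measurements$centre_id, measurements$trait_id),
                  drop = TRUE)
  out <- lapply(groups, function(g) {
    tryCatch(fit_sex_model(g, min_per_sex = min_per_sex),
             error = function(e) {
               message("centre_statistics: skipping group: ",
                       conditionMessage(e))
               NULL
             })
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    stop("centre_statistics: no centre x trait group could be analysed",
         call. = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$trait_id, res$centre_id), , drop = FALSE]
}
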