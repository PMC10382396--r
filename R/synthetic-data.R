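#' Simulation configuration for synthetic multicentre data
#'
#' Describes a multicentre phenotyping study with known ground truth.
#' Each centre has its own additive offset and multiplicative scale
#' (emulating equipment differences between laboratories), animals are
#' grouped into batches (test dates) sharing a random batch effect, and
#' each trait has a true standardised sex effect and a body-weight slope.
#'
#' `true_d` is the standardised male-minus-female difference net of body
#' weight and batch, in units of the residual standard deviation -- the
#' quantity the per-centre model estimates.  It may be a single number or
#' a vector of one value per centre, which lets presets emulate centres
#' disagreeing in direction.
#'
#' @param n_centres Number of centres.
#' @param traits List of trait specifications, each a list with
#'   `trait_id`, `true_d` (scalar or length `n_centres`) and `beta_bw`
#'   (trait units per gram).
#' @param n_per_sex Animals per sex per centre.
#' @param centre_offsets,centre_scales Numeric vectors of length
#'   `n_centres`; scales must be positive.
#' @param n_batches Batches (test dates) per centre.
#' @param batch_sd SD of the shared batch effect (standardised units).
#' @param residual_sd Residual SD (standardised units).
#' @param bw_mean_male,bw_mean_female,bw_sd Body-weight distribution in
#'   grams.
#' @param seed Integer seed making [simulate_measurements()] reproducible.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_centres,
                              traits,
                              n_per_sex = 50L,
                              centre_offsets = rep(0, n_centres),
                              centre_scales = rep(1, n_centres),
                              n_batches = 8L,
                              batch_sd = 0.25,
                              residual_sd = 1,
                              bw_mean_male = 30,
                              bw_mean_female = 25,
                              bw_sd = 3,
                              seed = 1L) {
  stopifnot(n_centres >= 1, n_per_sex >= 1, n_batches >= 1)
  if (length(centre_offsets) != n_centres || length(centre_scales) != n_centres) {
    stop("simulation_config: centre_offsets and centre_scales must have one value per centre",
         call. = FALSE)
  }
  if (any(centre_scales <= 0)) {
    stop("simulation_config: centre_scales must be positive", call. = FALSE)
  }
  if (batch_sd < 0 || residual_sd <= 0 || bw_sd <= 0) {
    stop("simulation_config: SDs must be positive (batch_sd may be 0)",
         call. = FALSE)
  }
  if (!is.list(traits) || length(traits) == 0L) {
    stop("simulation_config: 'traits' must be a non-empty list", call. = FALSE)
  }
  for (tr in traits) {
    if (is.null(tr$trait_id) || is.null(tr$true_d)) {
      stop("simulation_config: each trait needs 'trait_id' and 'true_d'",
           call. = FALSE)
    }
    if (!length(tr$true_d) %in% c(1L, n_centres)) {
      stop("simulation_config: 'true_d' must be scalar or one value per centre",
           call. = FALSE)
    }
  }
  structure(list(n_centres = as.integer(n_centres), traits = traits,
                 n_per_sex = as.integer(n_per_sex),
                 centre_offsets = centre_offsets,
                 centre_scales = centre_scales,
                 n_batches = as.integer(n_batches), batch_sd = batch_sd,
                 residual_sd = residual_sd, bw_mean_male = bw_mean_male,
                 bw_mean_female = bw_mean_female, bw_sd = bw_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic multicentre measurement table
#'
#' Draws a long-format per-animal measurement table from a
#' [simulation_config()].  Each centre gets `n_per_sex` animals per sex
#' with body weights `N(mean_sex, bw_sd^2)`, randomly assigned to batches;
#' all traits of one animal share its batch (test date).  On the
#' standardised scale the value for an animal is
#' `true_d * I(male) + beta_bw * (bw - bw_ref) + batch_effect + noise`,
#' with `batch_effect ~ N(0, batch_sd^2)` shared within a centre x trait x
#' batch cell and `noise ~ N(0, residual_sd^2)`; the centre's offset and
#' scale are then applied, so raw values differ across centres by an
#' affine map that downstream standardisation removes exactly.
#'
#' @param config A [simulation_config()].
#' @param seed Overrides `config$seed` when given.  The same seed always
#'   yields an identical table; the caller's RNG state is left untouched.
#' @return Data frame in the measurement layout: `centre_id`,
#'   `specimen_id`, `sex`, `body_weight`, `batch` (ISO date), `strain`,
#'   `trait_id`, `value`.
#' @export
simulate_measurements <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  bw_ref <- (config$bw_mean_male + config$bw_mean_female) / 2
  centres <- sprintf("C%02d", seq_len(config$n_centres))
  dates <- as.Date("2024-01-01") + 7L * (seq_len(config$n_batches) - 1L)

  out <- vector("list", config$n_centres)
  for (ci in seq_len(config$n_centres)) {
    n <- 2L * config$n_per_sex
    sex <- rep(c("male", "female"), each = config$n_per_sex)
    bw <- stats::rnorm(n,
                       mean = ifelse(sex == "male", config$bw_mean_male,
                                     config$bw_mean_female),
                       sd = config$bw_sd)
    bw <- pmax(bw, 5)  # body weight is physically positive
    batch_idx <- sample.int(config$n_batches, n, replace = TRUE)
    spec <- sprintf("%s_%04d", centres[ci], seq_len(n))

    per_trait <- lapply(config$traits, function(tr) {
      d <- if (length(tr$true_d) == 1L) tr$true_d else tr$true_d[ci]
      beta_bw <- if (is.null(tr$beta_bw)) 0 else tr$beta_bw
      batch_eff <- stats::rnorm(config$n_batches, 0, config$batch_sd)
      z <- d * (sex == "male") + beta_bw * (bw - bw_ref) +
        batch_eff[batch_idx] + stats::rnorm(n, 0, config$residual_sd)
      data.frame(centre_id = centres[ci],
                 specimen_id = spec,
                 sex = sex,
                 body_weight = bw,
                 batch = dates[batch_idx],
                 strain = "C57BL/6N",
                 trait_id = tr$trait_id,
                 value = config$centre_offsets[ci] + config$centre_scales[ci] * z,
                 stringsAsFactors = FALSE)
    })
    out[[ci]] <- do.call(rbind, per_trait)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default consortium-scale haematology-like configuration
#'
#' An 11-centre, 22-trait configuration mimicking the structure of a
#' multicentre haematology screen: 50 animals per sex per centre, true
#' standardised sex effects spanning roughly -1 to +1.25 across traits,
#' centre offsets drawn once from `N(0, 2^2)` (equipment shifts), mild
#' centre scale differences, and batch variation across 8 test dates.
#'
#' @param seed Seed for both the one-off draw of centre offsets/scales and
#'   the downstream measurement simulation.
#' @param n_per_sex Animals per sex per centre (default 50).
#' @return A [simulation_config()].
#' @export
impc_mimic_config <- function(seed = 1L, n_per_sex = 50L) {
  true_d <- c(
    platelet_count = 1.25, wbc_count = 1.17, lymphocyte_count = 1.01,
    neutrophil_count = 0.80, monocyte_count = 0.62, rbc_count = 0.55,
    rbc_distribution_width = 0.53, haematocrit = 0.38,
    eosinophil_count = 0.35, lymphocyte_diff = -0.32, mean_cell_volume = -0.47,
    mean_platelet_volume = -0.51, mchc = -0.52, mch = -0.90,
    luc_count = 0.50, luc_diff = 0.20, neutrophil_diff = 0.35,
    basophil_count = 0.25, haemoglobin = 0.13, monocyte_diff = 0.03,
    eosinophil_diff = -0.06, basophil_diff = -0.16
  )
  traits <- Map(function(id, d) list(trait_id = id, true_d = d, beta_bw = 0.03),
                names(true_d), unname(true_d))
  names(traits) <- NULL
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  offsets <- stats::rnorm(11, 0, 2)
  scales <- exp(stats::rnorm(11, 0, 0.15))
  simulation_config(n_centres = 11L, traits = traits, n_per_sex = n_per_sex,
                    centre_offsets = offsets, centre_scales = scales,
                    seed = seed)
}

#' Four-centre scenario presets
#'
#' Configurations reproducing the qualitative multicentre outcome patterns
#' used to motivate the consensus score, each with 4 centres and one
#' trait.  Borderline or null p-values are induced by the true effect and
#' sample size, never injected, so every preset exercises the full
#' pipeline:
#'
#' * `S1` -- all four centres carry the same strong effect (global
#'   consensus expected);
#' * `S2` -- two centres with a real effect, two null;
#' * `S3` -- two real, one borderline, one null;
#' * `S4` -- two strong effects, two clear nulls at large n;
#' * `S5` -- all significant but two positive and two negative
#'   (directionality gate fires, score 1);
#' * `S6` -- two positive, one significant negative, one borderline.
#'
#' @param name One of `"S1"` ... `"S6"`.
#' @param n_per_sex Overrides the preset's per-sex sample size.
#' @param seed Seed stored in the returned configuration.
#' @return A [simulation_config()] with per-centre `true_d`.
#' @export
scenario_preset <- function(name, n_per_sex = NULL, seed = 1L) {
  presets <- list(
    S1 = list(d = c(1.0, 1.0, 1.0, 1.0),   n = 100L),
    S2 = list(d = c(1.0, 1.0, 0.0, 0.0),   n = 100L),
    S3 = list(d = c(1.0, 1.0, 0.35, 0.0),  n = 60L),
    S4 = list(d = c(1.2, 1.2, 0.0, 0.0),   n = 150L),
    S5 = list(d = c(1.0, 1.0, -1.0, -1.0), n = 100L),
    S6 = list(d = c(1.0, 1.0, -1.0, 0.3),  n = 100L)
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets)) {
    stop("scenario_preset: 'name' must be one of S1..S6", call. = FALSE)
  }
  p <- presets[[name]]
  simulation_config(
    n_centres = 4L,
    traits = list(list(trait_id = paste0("trait_", name), true_d = p$d,
                       beta_bw = 0.02)),
    n_per_sex = if (is.null(n_per_sex)) p$n else as.integer(n_per_sex),
    centre_offsets = c(0, 1.5, -1, 0.5),
    centre_scales = c(1, 1.2, 0.9, 1.05),
    n_batches = 6L, batch_sd = 0.15, seed = seed
  )
}
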