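MEASUREMENT_COLUMNS <- c("centre_id", "specimen_id", "sex", "body_weight",
                         "batch", "strain", "trait_id", "value")
RESULT_COLUMNS <- c("centre_id", "trait_id", "n_male", "n_female",
                    "effect_size", "effect_se", "p_value", "q_value")

#' Read a long-format measurement CSV
#'
#' Expects the header `centre_id,specimen_id,sex,body_weight,batch,strain,
#' trait_id,value`.  Sex tokens are case-insensitive, with `M`/`F`
#' accepted as aliases; `batch` must be an ISO-8601 date.  Rows with a
#' missing body weight are kept (the model-fitting step drops them with a
#' logged count); a missing or non-finite `value` is an error, reported
#' with its row number.
#'
#' @param path CSV file path.
#' @return Validated measurement data frame; `(centre_id, specimen_id,
#'   trait_id)` is unique.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("read_measurements: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, MEASUREMENT_COLUMNS]
  df$sex <- .normalise_sex(df$sex)

  val <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(val) | !is.finite(val))
  if (length(bad)) {
    stop("read_measurements: non-numeric or missing value at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  df$value <- val

  bw <- suppressWarnings(as.numeric(df$body_weight))
  newly_na <- which(is.na(bw) & !(is.na(df$body_weight) | df$body_weight == ""))
  if (length(newly_na)) {
    stop("read_measurements: non-numeric body_weight at row(s): ",
         paste(utils::head(newly_na, 10), collapse = ", "), call. = FALSE)
  }
  if (anyNA(bw)) {
    message(sprintf("read_measurements: %d record(s) with missing body weight",
                    sum(is.na(bw))))
  }
  df$body_weight <- bw

  batch <- as.Date(as.character(df$batch), format = "%Y-%m-%d")
  if (anyNA(batch)) {
    stop("read_measurements: unparseable ISO-8601 batch date at row(s): ",
         paste(utils::head(which(is.na(batch)), 10), collapse = ", "),
         call. = FALSE)
  }
  df$batch <- batch

  key <- paste(df$centre_id, df$specimen_id, df$trait_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("read_measurements: duplicate (centre_id, specimen_id, trait_id) at row(s): ",
         paste(utils::head(which(duplicated(key)), 10), collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read a per-centre results CSV
#'
#' Entry point for users bringing their own per-centre statistics, since
#' the consensus score only needs each centre's q-value and standardised
#' effect size.  Requires `centre_id`, `trait_id`, `effect_size` and at
#' least one of `p_value` / `q_value`; when only p-values are present,
#' [apply_fdr()] must be run before scoring (scoring without q-values says
#' so explicitly).
#'
#' @param path CSV file path.
#' @return Validated results data frame with all standard columns
#'   (missing ones filled with `NA`).
#' @export
read_centre_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("centre_id", "trait_id", "effect_size")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("read_centre_results: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!any(c("p_value", "q_value") %in% names(df))) {
    stop("read_centre_results: need a p_value or q_value column", call. = FALSE)
  }
  for (col in setdiff(RESULT_COLUMNS, names(df))) df[[col]] <- NA_real_
  df <- df[, RESULT_COLUMNS]

  for (col in c("p_value", "q_value")) {
    v <- df[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad)) {
      stop(sprintf("read_centre_results: %s outside [0, 1] at row(s): %s",
                   col, paste(utils::head(bad, 10), collapse = ", ")),
           call. = FALSE)
    }
  }
  key <- paste(df$centre_id, df$trait_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("read_centre_results: duplicate (centre_id, trait_id) at row(s): ",
         paste(utils::head(which(duplicated(key)), 10), collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write a per-centre results table
#' @param results Results data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_centre_results <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a per-trait scores table
#' @param scores Scores data frame from [score_traits()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run.  Defaults mirror the
#' recommended scoring parameters (`c = 3`, `q_hat = 0.05`,
#' `rho_hat = 0.5`), per-centre FDR families, and no sample-size
#' pre-filter; `impc_mode = TRUE` switches on the consortium convention of
#' at least 50 animals per sex per centre.
#'
#' @param fdr_scope `"per_centre"` or `"global"`.
#' @param c,q_hat,rho_hat,M Consensus parameters; see [consensus_params()].
#' @param min_per_sex Minimum animals per sex per centre x trait.
#' @param impc_mode Apply the 50-per-sex filter.
#' @param weighted_mean Sample-size-weighted mean effect for direction.
#' @param alpha Significance threshold for the all-agree baseline.
#' @param rounding Decimals for reported scores (`NULL` = full precision).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(fdr_scope = c("per_centre", "global"),
                            c = 3L, q_hat = 0.05, rho_hat = 0.5, M = NULL,
                            min_per_sex = 2L, impc_mode = FALSE,
                            weighted_mean = FALSE, alpha = 0.05,
                            rounding = NULL) {
  fdr_scope <- match.arg(fdr_scope)
  structure(list(fdr_scope = fdr_scope,
                 params = consensus_params(c = c, q_hat = q_hat,
                                           rho_hat = rho_hat, M = M),
                 min_per_sex = as.integer(min_per_sex),
                 impc_mode = isTRUE(impc_mode),
                 weighted_mean = isTRUE(weighted_mean),
                 alpha = alpha, rounding = rounding),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Keys mirror the arguments of [pipeline_config()]; absent keys keep
#' their defaults.
#'
#' @param path JSON file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("fdr_scope", "c", "q_hat", "rho_hat", "M", "min_per_sex",
               "impc_mode", "weighted_mean", "alpha", "rounding")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("read_pipeline_config: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

#' Run the full consensus pipeline
#'
#' Executes the whole chain on a measurement table: within-centre
#' standardisation and per-centre sex models ([centre_statistics()]),
#' FDR correction ([apply_fdr()]), per-trait consensus scoring and
#' classification ([score_traits()]) and, optionally, the two comparison
#' baselines ([compare_baselines()]).  A run summary with the count of
#' traits per decision class is logged at the end.
#'
#' @param measurements Measurement data frame (see [read_measurements()]).
#' @param config A [pipeline_config()].
#' @param baselines Also compute the comparison table (default `TRUE`).
#' @param output_dir If given, writes `centre_results.csv`, `scores.csv`
#'   and (with baselines) `comparison.csv` there.
#' @return List with `centre_results`, `scores` and `comparison` (the
#'   latter `NULL` when `baselines = FALSE`).
#' @export
run_pipeline <- function(measurements, config = pipeline_config(),
                         baselines = TRUE, output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.data.frame(measurements) || nrow(measurements) == 0L) {
    stop("run_pipeline: empty or invalid measurement table", call. = FALSE)
  }
  centre_results <- centre_statistics(measurements,
                                      min_per_sex = config$min_per_sex,
                                      impc_mode = config$impc_mode)
  centre_results <- apply_fdr(centre_results, scope = config$fdr_scope)

  params <- config$params
  if (is.null(params$M)) {
    params$M <- length(unique(measurements$centre_id))
  }
  scores <- score_traits(centre_results, params,
                         weighted_mean = config$weighted_mean,
                         rounding = config$rounding)
  comparison <- if (baselines) {
    compare_baselines(centre_results, params, alpha = config$alpha)
  } else NULL

  tab <- table(factor(scores$decision,
                      levels = c("CONSENSUS", "NO_CONSENSUS",
                                 "INSUFFICIENT_INFO", "INSUFFICIENT_CENTRES")))
  message(sprintf(
    "run_pipeline: %d trait(s) scored: %d consensus, %d no consensus, %d insufficient info, %d below centre minimum",
    nrow(scores), tab[["CONSENSUS"]], tab[["NO_CONSENSUS"]],
    tab[["INSUFFICIENT_INFO"]], tab[["INSUFFICIENT_CENTRES"]]))

  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    write_centre_results(centre_results,
                         file.path(output_dir, "centre_results.csv"))
    write_scores(scores, file.path(output_dir, "scores.csv"))
    if (!is.null(comparison)) {
      utils::write.csv(comparison, file.path(output_dir, "comparison.csv"),
                       row.names = FALSE)
    }
  }
  list(centre_results = centre_results, scores = scores,
       comparison = comparison)
}
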