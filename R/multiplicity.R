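#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate correction: on the sorted scale
#' `q_(i) = min_{j >= i} p_(j) * m / j`, clipped to 1 and returned in the
#' original order.  Delegates to [stats::p.adjust()] after validating the
#' input range.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, elementwise `>=` the input and monotone in
#'   it within the family.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop("bh_adjust: p-values must be numbers in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Set q-values on a per-centre results table
#'
#' Applies Benjamini-Hochberg correction within each multiple-testing
#' family.  The default family is a centre's own set of traits
#' (`scope = "per_centre"`): each centre corrects the tests it performed.
#' `scope = "global"` pools all centre x trait results into one family.
#'
#' @param results Per-centre results data frame with `p_value` set on every
#'   row (see [centre_statistics()]).
#' @param scope `"per_centre"` (default) or `"global"`.
#' @return The same data frame with `q_value` filled in.
#' @export
apply_fdr <- function(results, scope = c("per_centre", "global")) {
  scope <- match.arg(scope)
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0L) {
    warning("apply_fdr: empty results table, nothing to correct", call. = FALSE)
    return(results)
  }
  if (!"p_value" %in% names(results) || anyNA(results$p_value)) {
    stop("apply_fdr: every row must have a p_value", call. = FALSE)
  }
  if (scope == "global") {
    results$q_value <- bh_adjust(results$p_value)
  } else {
    for (cid in unique(results$centre_id)) {
      idx <- results$centre_id == cid
      results$q_value[idx] <- bh_adjust(results$p_value[idx])
    }
  }
  results
}
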