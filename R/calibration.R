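#' Population-based percentile cutoffs for risk groups
#'
#' Cutoffs are nearest-rank (type-1) empirical quantiles at the cumulative
#' requested proportions, so that on `n` distinct scores the achieved group
#' counts are exact integers. When `stratum_labels` is supplied the cutoffs
#' are computed separately per stratum (for example the 76-gene rule: the
#' lowest 30% of raw relapse scores in ER-positive and the lowest 22% in
#' ER-negative tumors form the good-prognosis group).
#'
#' @param scores numeric vector.
#' @param proportions requested group proportions, low- to high-risk,
#'   summing to 1.
#' @param stratum_labels optional character per sample.
#' @param type quantile algorithm (see [stats::quantile()]); the nearest
#'   rank default (type 1) makes achieved counts exact integers.
#' @return For unstratified input, a numeric vector of `length(proportions)
#'   - 1` cutoffs; stratified, a named list of such vectors per stratum.
#' @export
percentileCutoffs <- function(scores, proportions, stratum_labels = NULL,
                              type = 1) {
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must sum to 1")
  one <- function(x, context) {
    x <- x[!is.na(x)]
    if (length(unique(x)) < 2L)
      stop("all scores identical in context '", context,
           "': cannot place cutoffs")
    if (length(proportions) == 1L) return(numeric(0))
    probs <- cumsum(proportions)[-length(proportions)]
    as.numeric(quantile(x, probs = probs, type = type, names = FALSE))
  }
  if (is.null(stratum_labels)) return(one(scores, "all"))
  strata <- setdiff(unique(stratum_labels), NA)
  out <- lapply(strata, function(st)
    one(scores[!is.na(stratum_labels) & stratum_labels == st], st))
  names(out) <- strata
  out
}

#' Assign risk groups from cutoffs
#'
#' A score less than or equal to the first cutoff receives the first
#' (lowest-risk) label; ties exactly at a cutoff go to the lower-risk
#' group.
#'
#' @param scores numeric vector.
#' @param cutoffs ascending cutoff values (possibly empty for one group),
#'   or a named list per stratum.
#' @param labels group labels, low- to high-risk; `length(cutoffs) + 1`.
#' @param stratum_labels required when `cutoffs` is a per-stratum list.
#' @return factor of group labels (ordered low to high); `NA` score or
#'   unknown stratum yields `NA`.
#' @export
assignGroups <- function(scores, cutoffs, labels, stratum_labels = NULL) {
  if (is.list(cutoffs)) {
    if (is.null(stratum_labels))
      stop("per-stratum cutoffs need stratum labels")
    out <- factor(rep(NA_character_, length(scores)), levels = labels,
                  ordered = TRUE)
    for (st in names(cutoffs)) {
      idx <- which(!is.na(stratum_labels) & stratum_labels == st)
      if (length(idx))
        out[idx] <- assignGroups(scores[idx], cutoffs[[st]], labels)
    }
    return(out)
  }
  if (length(labels) != length(cutoffs) + 1L)
    stop("need length(cutoffs) + 1 labels")
  if (is.unsorted(cutoffs)) stop("cutoffs must be ascending")
  idx <- vapply(scores, function(s) {
    if (is.na(s)) return(NA_integer_)
    sum(s > cutoffs) + 1L  # ties at a cutoff fall to the lower-risk group
  }, integer(1L))
  factor(labels[idx], levels = labels, ordered = TRUE)
}

#' Assign population-calibrated risk groups for one signature
#'
#' Convenience wrapper: derives cutoffs from the signature's calibration
#' (globally, or per stratum when `by_stratum` proportions are declared)
#' and assigns groups.
#'
#' @param scores numeric vector.
#' @param sig [SignatureDefinition-class] with a `calibration` slot.
#' @param stratum_labels character per sample (required for per-stratum
#'   calibration).
#' @param type quantile algorithm, as in [percentileCutoffs()].
#' @return list with `groups` (factor) and `cutoffs`.
#' @export
calibrateRiskGroups <- function(scores, sig, stratum_labels = NULL,
                                type = 1) {
  cal <- sig@calibration
  if (!length(cal)) stop("signature '", sig@name, "' has no calibration")
  if (!is.null(cal$by_stratum)) {
    cuts <- list()
    for (st in names(cal$by_stratum)) {
      idx <- !is.na(stratum_labels) & stratum_labels == st
      cuts[[st]] <- percentileCutoffs(scores[idx], cal$by_stratum[[st]],
                                      type = type)
    }
    groups <- assignGroups(scores, cuts, cal$labels, stratum_labels)
  } else {
    cuts <- percentileCutoffs(scores, cal$proportions, type = type)
    groups <- assignGroups(scores, cuts, cal$labels)
  }
  list(groups = groups, cutoffs = cuts)
}

#' Standardize scores to unit standard deviation over a context
#'
#' Centers and scales so that the samples in the context (all samples by
#' default) have mean 0 and sample SD 1. Standardized hazard ratios are HRs
#' per one-SD increase of the score; the SD is computed over exactly the
#' samples entering the subsequent model fit.
#'
#' @param scores numeric vector.
#' @param context_mask logical mask of the samples defining the moments
#'   (default: all non-missing).
#' @return numeric vector (same length); values outside the context are
#'   standardized with the context's moments.
#' @export
standardizeScores <- function(scores, context_mask = NULL) {
  if (is.null(context_mask)) context_mask <- rep(TRUE, length(scores))
  x <- scores[context_mask & !is.na(scores)]
  if (length(x) < 2L) stop("need >= 2 context samples to standardize")
  s <- sd(x)
  if (s == 0) stop("zero standard deviation in context")
  (scores - mean(x)) / s
}
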