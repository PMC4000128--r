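#' Correlations of each sample with each class centroid
#'
#' Correlation is computed over the signature's matched centroid genes only,
#' pairwise-complete over missing entries. A sample/centroid pair sharing
#' fewer than 3 observed genes yields `NA`.
#'
#' @param expr genes x samples matrix (or [SignatureCohort-class]).
#' @param sig a centroid-archetype [SignatureDefinition-class].
#' @param method `"pearson"` or `"spearman"`; default taken from the
#'   signature (`score_method`/`classify_method`).
#' @param min_shared minimum shared observed genes per pair (default 3).
#' @param min_coverage passed to [mapSignature()].
#' @return samples x classes correlation matrix, entries in `[-1, 1]`.
#' @export
centroidCorrelations <- function(expr, sig, method = NULL, min_shared = 3L,
                                 min_coverage = 0.5) {
  if (methods::is(expr, "SignatureCohort")) expr <- exprs(expr)
  if (!ncol(sig@centroids)) stop("signature has no centroid matrix")
  if (is.null(method)) method <- sig@params$score_method
  mp <- mapSignature(sig, expr, min_coverage = min_coverage)
  genes <- intersect(rownames(sig@centroids), mp$matched)
  x <- expr[genes, , drop = FALSE]
  ctr <- sig@centroids[genes, , drop = FALSE]
  suppressWarnings(
    cc <- cor(x, ctr, use = "pairwise.complete.obs", method = method))
  shared <- crossprod(!is.na(x), !is.na(ctr))
  cc[shared < min_shared] <- NA_real_
  dimnames(cc) <- list(colnames(x), colnames(ctr))
  cc
}

#' Nearest-centroid subtype classification
#'
#' Assigns each sample the class with the highest centroid correlation.
#' Ties break deterministically to the first class in declared column
#' order; samples whose best correlation is missing are called
#' `"unknown"`. Margins below `ambiguous_margin` are flagged.
#'
#' @param correlation_matrix samples x classes matrix from
#'   [centroidCorrelations()].
#' @param ambiguous_margin calls with best-vs-second margin below this are
#'   flagged (default 1e-8).
#' @return character vector of calls with attributes `margin` (numeric) and
#'   `ambiguous` (logical).
#' @export
classifyNearestCentroid <- function(correlation_matrix,
                                    ambiguous_margin = 1e-8) {
  classes <- colnames(correlation_matrix)
  n <- nrow(correlation_matrix)
  calls <- rep("unknown", n)
  margin <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    r <- correlation_matrix[i, ]
    if (all(is.na(r))) next
    best <- which.max(r)  # first index on exact ties
    calls[i] <- classes[best]
    others <- r[-best]
    margin[i] <- if (all(is.na(others))) Inf else
      r[best] - max(others, na.rm = TRUE)
  }
  names(calls) <- rownames(correlation_matrix)
  attr(calls, "margin") <- margin
  attr(calls, "ambiguous") <- !is.na(margin) & margin < ambiguous_margin
  calls
}

#' Risk-of-relapse score as a linear combination of centroid correlations
#'
#' @param correlation_matrix samples x classes matrix.
#' @param coefficients one coefficient per class (matched by name when
#'   named, otherwise by position).
#' @return numeric risk score per sample.
#' @export
rorLinear <- function(correlation_matrix, coefficients) {
  k <- ncol(correlation_matrix)
  if (length(coefficients) != k)
    stop("need one ROR coefficient per class (", k, ")")
  if (!is.null(names(coefficients)) &&
      all(colnames(correlation_matrix) %in% names(coefficients)))
    coefficients <- coefficients[colnames(correlation_matrix)]
  drop(correlation_matrix %*% as.numeric(coefficients))
}

#' Risk score from correlation to a single reference centroid
#'
#' The oriented score is `risk_direction` times the correlation to the
#' reference (for example good-prognosis) centroid; with direction -1 a
#' sample identical to the good-prognosis profile gets the minimal score.
#'
#' @inheritParams centroidCorrelations
#' @return oriented risk score per sample.
#' @export
centroidRisk <- function(expr, sig, method = NULL, min_coverage = 0.5) {
  ref <- sig@params$reference_class
  cc <- centroidCorrelations(expr, sig, method = method,
                             min_coverage = min_coverage)
  sig@riskDirection * cc[, ref]
}

#' Weighted-sum risk score
#'
#' Score is the weighted sum of the signature genes' expression. For a
#' stratified definition (gene entries carrying a `stratum` label) each
#' sample is scored on its own stratum's gene set, so `stratum_labels` is
#' required; samples with a missing/unknown stratum get `NA`. Weights are
#' renormalized over the genes observed for each sample, so that missing
#' entries do not deflate the score.
#'
#' @param expr genes x samples matrix (or [SignatureCohort-class]).
#' @param sig a weighted_sum [SignatureDefinition-class].
#' @param stratum_labels character per sample (required when stratified).
#' @param min_coverage passed to [mapSignature()].
#' @return numeric risk score per sample.
#' @export
weightedSum <- function(expr, sig, stratum_labels = NULL,
                        min_coverage = 0.5) {
  if (methods::is(expr, "SignatureCohort")) expr <- exprs(expr)
  mp <- mapSignature(sig, expr, min_coverage = min_coverage)
  g <- sig@genes[sig@genes$gene_id %in% mp$matched, , drop = FALSE]
  strata <- if ("stratum" %in% names(g)) unique(as.character(g$stratum))
            else NA_character_
  stratified <- length(strata) > 1L || !all(is.na(strata))
  n <- ncol(expr)
  out <- rep(NA_real_, n)
  names(out) <- colnames(expr)
  score_set <- function(gs, cols) {
    x <- expr[gs$gene_id, cols, drop = FALSE]
    w <- as.numeric(gs$weight)
    obs <- !is.na(x)
    wsum <- colSums(w * x * obs, na.rm = TRUE)
    wobs <- colSums(abs(w) * obs)
    wtot <- sum(abs(w))
    s <- ifelse(wobs > 0, wsum * (wtot / wobs), ifelse(wtot == 0, 0, NA))
    s[wtot == 0] <- 0
    s
  }
  if (!stratified) {
    out[] <- score_set(g, seq_len(n))
  } else {
    if (is.null(stratum_labels))
      stop(sprintf("signature '%s' is stratified: stratum labels required",
                   sig@name))
    for (st in strata) {
      cols <- which(!is.na(stratum_labels) & stratum_labels == st)
      if (!length(cols)) next
      gs <- g[g$stratum == st, , drop = FALSE]
      if (!nrow(gs)) next
      out[cols] <- score_set(gs, cols)
    }
  }
  out
}

#' Difference-of-means risk score (genomic-grade-index family)
#'
#' Raw score is mean(up-set) minus mean(down-set) per sample. The raw
#' scores are then linearly rescaled so the cohort spans `[-1, +1]` around
#' the cohort midpoint, giving a platform-invariant scale; the applied
#' center/half-width is recorded in the result's attributes.
#'
#' @param expr genes x samples matrix (or [SignatureCohort-class]).
#' @param sig a difference_of_means [SignatureDefinition-class] (`group`
#'   column with `"up"`/`"down"`).
#' @param rescale rescale to the cohort reference range (default TRUE).
#' @param min_coverage passed to [mapSignature()].
#' @return numeric score per sample with attributes `raw`, `center`,
#'   `halfwidth`.
#' @export
differenceOfMeans <- function(expr, sig, rescale = TRUE,
                              min_coverage = 0.5) {
  if (methods::is(expr, "SignatureCohort")) expr <- exprs(expr)
  mp <- mapSignature(sig, expr, min_coverage = min_coverage)
  g <- sig@genes[sig@genes$gene_id %in% mp$matched, , drop = FALSE]
  up <- g$gene_id[g$group == "up"]
  down <- g$gene_id[g$group == "down"]
  if (!length(up) || !length(down))
    stop(sprintf("signature '%s': empty up- or down-set after mapping",
                 sig@name))
  raw <- colMeans(expr[up, , drop = FALSE], na.rm = TRUE) -
    colMeans(expr[down, , drop = FALSE], na.rm = TRUE)
  if (!rescale) return(raw)
  rng <- range(raw, na.rm = TRUE)
  center <- mean(rng)
  halfwidth <- diff(rng) / 2
  out <- if (halfwidth > 0) (raw - center) / halfwidth else raw - center
  attr(out, "raw") <- raw
  attr(out, "center") <- center
  attr(out, "halfwidth") <- halfwidth
  out
}

#' Grouped-threshold risk score (unscaled recurrence-score family)
#'
#' Per sample: (1) when reference genes are declared, the mean of the
#' reference genes is subtracted from every gene value; (2) each group's
#' value is the mean of its member genes; (3) group values are clipped to
#' declared bounds; (4) score = intercept + sum over groups of group weight
#' times clipped group value.
#'
#' @param expr genes x samples matrix (or [SignatureCohort-class]).
#' @param sig a grouped_threshold [SignatureDefinition-class].
#' @param min_coverage passed to [mapSignature()].
#' @return numeric risk score per sample.
#' @export
groupedThreshold <- function(expr, sig, min_coverage = 0.5) {
  if (methods::is(expr, "SignatureCohort")) expr <- exprs(expr)
  mp <- mapSignature(sig, expr, min_coverage = min_coverage)
  g <- sig@genes[sig@genes$gene_id %in% mp$matched, , drop = FALSE]
  ref_flag <- if ("reference" %in% names(g)) isTRUE_vec(g$reference)
              else rep(FALSE, nrow(g))
  had_refs <- "reference" %in% names(sig@genes) &&
    any(isTRUE_vec(sig@genes$reference))
  x <- expr[g$gene_id, , drop = FALSE]
  if (had_refs) {
    if (!any(ref_flag))
      stop(sprintf("signature '%s': no reference genes mapped", sig@name))
    ref_mean <- colMeans(x[ref_flag, , drop = FALSE], na.rm = TRUE)
    x <- sweep(x, 2L, ref_mean, "-")
  }
  weights <- sig@params$group_weights
  intercept <- if (is.null(sig@params$intercept)) 0 else sig@params$intercept
  clip <- sig@params$clip
  score <- rep(intercept, ncol(x))
  names(score) <- colnames(x)
  for (grp in names(weights)) {
    members <- g$gene_id[!ref_flag & g$group == grp]
    if (!length(members))
      stop(sprintf("signature '%s': group '%s' has no mapped genes",
                   sig@name, grp))
    gv <- colMeans(x[members, , drop = FALSE], na.rm = TRUE)
    if (!is.null(clip[[grp]])) {
      gv <- pmin(pmax(gv, clip[[grp]][1L]), clip[[grp]][2L])
    }
    score <- score + weights[[grp]] * gv
  }
  score
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

.score_one <- function(expr, sig, stratum_labels, min_coverage) {
  switch(sig@archetype,
    centroid_subtype = {
      cc_call <- centroidCorrelations(expr, sig,
                                      method = sig@params$classify_method,
                                      min_coverage = min_coverage)
      cc_score <- if (identical(sig@params$classify_method,
                                sig@params$score_method)) cc_call else
        centroidCorrelations(expr, sig, method = sig@params$score_method,
                             min_coverage = min_coverage)
      calls <- classifyNearestCentroid(cc_call)
      score <- rorLinear(cc_score, sig@params$ror_coefficients)
      list(score = sig@riskDirection * score, calls = calls,
           correlations = cc_score)
    },
    centroid_risk = list(score = centroidRisk(
      expr, sig, min_coverage = min_coverage)),
    weighted_sum = list(score = sig@riskDirection * weightedSum(
      expr, sig, stratum_labels = stratum_labels,
      min_coverage = min_coverage)),
    difference_of_means = {
      s <- differenceOfMeans(expr, sig, min_coverage = min_coverage)
      list(score = sig@riskDirection * as.numeric(s),
           metadata = list(center = attr(s, "center"),
                           halfwidth = attr(s, "halfwidth")))
    },
    grouped_threshold = list(score = sig@riskDirection * groupedThreshold(
      expr, sig, min_coverage = min_coverage)),
    stop("unknown archetype: ", sig@archetype))
}

#' Score every signature on a cohort
#'
#' Dispatches each [SignatureDefinition-class] to its archetype scorer,
#' orients all score columns to be increasing in risk (`risk_direction`
#' applied), and attaches subtype calls and centroid correlations for
#' centroid_subtype signatures. A signature failing (for example low
#' coverage) does not abort the others: its column is `NA` and its status
#' records the error.
#'
#' @param expr genes x samples matrix or [SignatureCohort-class].
#' @param signatures list of [SignatureDefinition-class] objects.
#' @param clinical clinical data.frame supplying `er_status` stratum labels
#'   for stratified signatures (taken from the cohort when `expr` is a
#'   [SignatureCohort-class]).
#' @param min_coverage coverage floor passed to [mapSignature()].
#' @return A [ScoreTable-class].
#' @export
scoreAll <- function(expr, signatures, clinical = NULL, min_coverage = 0.5) {
  if (methods::is(expr, "SignatureCohort")) {
    if (is.null(clinical)) clinical <- clinicalData(expr)
    expr <- exprs(expr)
  }
  if (is.null(names(signatures)))
    names(signatures) <- vapply(signatures, function(s) s@name, character(1L))
  stratum_labels <- NULL
  if (!is.null(clinical) && "er_status" %in% names(clinical)) {
    stratum_labels <- clinical$er_status[
      match(colnames(expr), clinical$sample_id)]
    stratum_labels[stratum_labels == "unknown"] <- NA
  }
  n <- ncol(expr)
  scores <- matrix(NA_real_, n, length(signatures),
                   dimnames = list(colnames(expr), names(signatures)))
  calls <- data.frame(row.names = colnames(expr))
  correlations <- list()
  status <- setNames(rep("ok", length(signatures)), names(signatures))
  metadata <- list()
  for (nm in names(signatures)) {
    res <- tryCatch(
      .score_one(expr, signatures[[nm]], stratum_labels, min_coverage),
      error = function(e) e)
    if (inherits(res, "error")) {
      status[nm] <- conditionMessage(res)
      next
    }
    scores[, nm] <- as.numeric(res$score)
    if (!is.null(res$calls)) calls[[nm]] <- as.character(res$calls)
    if (!is.null(res$correlations)) correlations[[nm]] <- res$correlations
    if (!is.null(res$metadata)) metadata[[nm]] <- res$metadata
  }
  methods::new("ScoreTable", scores = scores, calls = calls,
               correlations = correlations, status = status,
               metadata = metadata)
}
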