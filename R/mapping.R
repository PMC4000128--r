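#' Map a signature's genes onto an expression matrix
#'
#' Intersects the signature's gene list with the matrix rownames and reports
#' the annotation coverage fraction matched / total. Scoring requires
#' coverage at or above `min_coverage` (default 0.5); coverage between the
#' floor and 0.8 proceeds with a warning, reflecting that published
#' signatures are routinely applied at partial cross-platform coverage.
#'
#' @param sig a [SignatureDefinition-class].
#' @param expr genes x samples matrix (or [SignatureCohort-class]).
#' @param min_coverage hard floor on coverage fraction in `[0, 1]`.
#' @param warn_coverage warn when coverage is below this but above the floor.
#' @return list with `signature`, `matched`, `unmatched`,
#'   `coverage_fraction`.
#' @export
mapSignature <- function(sig, expr, min_coverage = 0.5,
                         warn_coverage = 0.8) {
  if (methods::is(expr, "SignatureCohort")) expr <- exprs(expr)
  universe <- rownames(expr)
  sig_genes <- unique(c(sig@genes$gene_id,
                        if (ncol(sig@centroids)) rownames(sig@centroids)))
  matched <- intersect(sig_genes, universe)
  unmatched <- setdiff(sig_genes, universe)
  coverage <- length(matched) / length(sig_genes)
  if (coverage < min_coverage)
    stop(sprintf(
      "signature '%s': coverage %.3f below minimum %.2f; unmatched genes: %s",
      sig@name, coverage, min_coverage,
      paste(utils::head(unmatched, 20), collapse = ", ")))
  if (coverage < warn_coverage)
    warning(sprintf("signature '%s': low annotation coverage %.1f%% (%d/%d)",
                    sig@name, 100 * coverage, length(matched),
                    length(sig_genes)))
  list(signature = sig@name, matched = matched, unmatched = unmatched,
       coverage_fraction = coverage)
}

#' Impute receptor status from a marker gene's expression
#'
#' Fits a two-component equal-variance Gaussian mixture to the marker
#' expression (for example ESR1 for ER status, ERBB2 for HER2) and calls a
#' sample positive when its posterior probability of belonging to the
#' higher-mean component exceeds 0.5. If the mixture degenerates (components
#' collapse, or the fit fails), the sample is split at the median instead
#' and the result is flagged.
#'
#' @param marker_values named numeric vector of marker expression (>= 20
#'   samples, not all identical).
#' @param seed integer seed; the fit is deterministic given data and seed.
#' @return list with `status` (character `"positive"`/`"negative"`),
#'   `posterior` (probability of the positive component), `fallback`
#'   (logical: median split used), `means` of the fitted components.
#' @importFrom mclust Mclust mclustBIC
#' @export
imputeReceptorStatus <- function(marker_values, seed = 1L) {
  x <- marker_values
  if (length(x) < 20L) stop("need at least 20 samples to fit the mixture")
  fallback <- FALSE
  post <- means <- NULL
  if (length(unique(x)) < 2L) {
    fallback <- TRUE
  } else {
    fit <- tryCatch({
      set.seed(seed)
      suppressWarnings(mclust::Mclust(x, G = 2, modelNames = "E",
                                      verbose = FALSE))
    }, error = function(e) NULL)
    if (is.null(fit) || is.null(fit$parameters)) {
      fallback <- TRUE
    } else {
      means <- fit$parameters$mean
      sds <- sqrt(fit$parameters$variance$sigmasq)
      sep <- abs(diff(means)) / max(sds, .Machine$double.eps)
      if (!is.finite(sep) || sep < 0.1) {
        fallback <- TRUE  # components collapsed onto each other
      } else {
        hi <- which.max(means)
        post <- fit$z[, hi]
      }
    }
  }
  if (fallback) {
    warning("degenerate mixture fit; falling back to median split")
    med <- median(x)
    post <- as.numeric(x > med)
    means <- c(med, med)
  }
  status <- ifelse(post > 0.5, "positive", "negative")
  names(status) <- names(x)
  list(status = status, posterior = post, fallback = fallback, means = means)
}
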