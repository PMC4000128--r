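#' Pairwise correlation matrix of signature risk scores
#'
#' Pairwise-complete: each pair of signatures is correlated over the
#' samples scored by both, so a signature failing coverage on some samples
#' does not erase the others. Pairs with fewer than `min_n` complete
#' samples are `NA`.
#'
#' @param score_table a [ScoreTable-class] or samples x signatures matrix.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param min_n minimum complete samples per pair (default 3).
#' @return list with `correlation` (symmetric, unit diagonal) and `n`
#'   (per-pair complete sample counts).
#' @export
scoreCorrelationMatrix <- function(score_table, method = "pearson",
                                   min_n = 3L) {
  x <- if (methods::is(score_table, "ScoreTable")) riskScores(score_table)
       else as.matrix(score_table)
  suppressWarnings(
    cc <- cor(x, use = "pairwise.complete.obs", method = method))
  nmat <- crossprod(!is.na(x))
  cc[nmat < min_n] <- NA_real_
  diag(cc)[diag(nmat) >= 1L] <- 1
  list(correlation = cc, n = nmat)
}

#' Confusion matrix between two subtype callers
#'
#' @param calls_a,calls_b character vectors of calls on the same samples.
#' @param class_order class vocabulary (row/column order).
#' @return square count matrix (rows = caller A, columns = caller B) with
#'   attribute `n_unknown`, the number of samples excluded because either
#'   caller returned `"unknown"`/`NA`.
#' @export
subtypeConfusion <- function(calls_a, calls_b, class_order) {
  if (length(calls_a) != length(calls_b))
    stop("call vectors must cover the same samples")
  a <- as.character(calls_a); b <- as.character(calls_b)
  unk <- is.na(a) | is.na(b) | a == "unknown" | b == "unknown"
  a <- a[!unk]; b <- b[!unk]
  bad <- setdiff(unique(c(a, b)), class_order)
  if (length(bad))
    stop("calls outside the class vocabulary: ", paste(bad, collapse = ", "))
  tab <- table(factor(a, levels = class_order),
               factor(b, levels = class_order))
  m <- unclass(as.matrix(tab))
  names(dimnames(m)) <- NULL
  attr(m, "n_unknown") <- sum(unk)
  m
}

#' Cohen's kappa from a confusion matrix
#'
#' kappa = (p_o - p_e) / (1 - p_e), with observed agreement p_o the
#' diagonal mass and chance agreement p_e the product of the margins; the
#' CI uses the standard asymptotic SE sqrt(p_o (1 - p_o)) / ((1 - p_e)
#' sqrt(n)).
#'
#' @param confusion square count matrix.
#' @param conf_level confidence level.
#' @return list with `kappa`, `se`, `lower`, `upper`, `p_observed`,
#'   `p_expected`, `n`.
#' @export
cohensKappa <- function(confusion, conf_level = 0.95) {
  m <- as.matrix(confusion)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square")
  n <- sum(m)
  if (n < 1) stop("empty confusion matrix")
  p <- m / n
  po <- sum(diag(p))
  pe <- sum(rowSums(p) * colSums(p))
  if (1 - pe < 1e-12)
    stop("degenerate margins: chance agreement is 1, kappa undefined")
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / n) / (1 - pe)
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(kappa = kappa, se = se, lower = kappa - z * se,
       upper = min(1, kappa + z * se), p_observed = po, p_expected = pe,
       n = n)
}

#' Cross-signature agreement report
#'
#' Bundles the pairwise score correlation matrix and, for every pair of
#' centroid_subtype signatures, the subtype confusion matrix with Cohen's
#' kappa.
#'
#' @param score_table a [ScoreTable-class].
#' @param method correlation method.
#' @return list with `correlation`, `n`, and `subtype_agreement` (named
#'   list per caller pair: `confusion`, `kappa`).
#' @export
agreementReport <- function(score_table, method = "pearson") {
  cm <- scoreCorrelationMatrix(score_table, method = method)
  calls <- subtypeCalls(score_table)
  sub <- list()
  if (ncol(calls) >= 2L) {
    callers <- names(calls)
    for (i in seq_len(length(callers) - 1L)) {
      for (j in seq(i + 1L, length(callers))) {
        a <- callers[i]; b <- callers[j]
        classes <- sort(unique(setdiff(
          c(calls[[a]], calls[[b]]), c(NA, "unknown"))))
        conf <- subtypeConfusion(calls[[a]], calls[[b]], classes)
        sub[[paste(a, b, sep = ".vs.")]] <-
          list(confusion = conf, kappa = cohensKappa(conf))
      }
    }
  }
  list(correlation = cm$correlation, n = cm$n, subtype_agreement = sub)
}
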