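#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats sd cor quantile median pchisq pnorm qnorm rnorm runif
#'   rexp rbinom complete.cases setNames integrate var
#' @importFrom utils read.delim write.table modifyList
NULL

.ARCHETYPES <- c("centroid_subtype", "centroid_risk", "weighted_sum",
                 "difference_of_means", "grouped_threshold")

#' SignatureCohort: expression plus clinical follow-up in one container
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with an `"exprs"`
#' assay of log2 expression (genes x samples) and clinical covariates in
#' `colData`: `time_years` (follow-up in years), `event` (1 = distant
#' metastasis observed), `er_status`/`her2_status`
#' (`positive`/`negative`/`unknown`), `size_cat` (`pT1`/`pT2`/`pT3-4`/
#' `unknown`), `node` (`positive`/`negative`/`unknown`), `grade`
#' (`1`/`2`/`3`/`unknown`), `cohort`, `systemic_treatment`.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("SignatureCohort", contains = "SummarizedExperiment")

.valid_clinical_levels <- list(
  er_status  = c("positive", "negative", "unknown"),
  her2_status = c("positive", "negative", "unknown"),
  size_cat   = c("pT1", "pT2", "pT3-4", "unknown"),
  node       = c("positive", "negative", "unknown"),
  grade      = c("1", "2", "3", "unknown"),
  systemic_treatment = c("yes", "no", "unknown")
)

setValidity("SignatureCohort", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    x <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(x)) msg <- c(msg, "'exprs' must be numeric")
    if (any(is.infinite(x))) msg <- c(msg, "'exprs' contains non-finite values")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  cd <- SummarizedExperiment::colData(object)
  if ("time_years" %in% names(cd)) {
    tt <- cd$time_years
    if (any(!is.na(tt) & tt < 0)) msg <- c(msg, "time_years must be >= 0")
  }
  if ("event" %in% names(cd)) {
    ev <- cd$event
    if (any(!is.na(ev) & !ev %in% c(0, 1)))
      msg <- c(msg, "event must be 0 or 1")
  }
  for (nm in intersect(names(.valid_clinical_levels), names(cd))) {
    bad <- setdiff(unique(as.character(cd[[nm]])),
                   c(.valid_clinical_levels[[nm]], NA))
    if (length(bad))
      msg <- c(msg, sprintf("invalid %s level(s): %s", nm,
                            paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SignatureCohort
#'
#' @param exprs numeric matrix, genes x samples, log2 scale; rownames = gene
#'   ids, colnames = sample ids.
#' @param clinical data.frame of survival records with a `sample_id` column
#'   matching `colnames(exprs)` (order-insensitive), or `NULL` for an
#'   expression-only cohort.
#' @return A [SignatureCohort-class] object.
#' @export
SignatureCohort <- function(exprs, clinical = NULL) {
  if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
    stop("'exprs' must carry gene ids as rownames and sample ids as colnames")
  if (is.null(clinical)) {
    cd <- S4Vectors::DataFrame(row.names = colnames(exprs))
  } else {
    if (!"sample_id" %in% names(clinical))
      stop("clinical table must have a 'sample_id' column")
    missing_ids <- setdiff(colnames(exprs), clinical$sample_id)
    if (length(missing_ids))
      stop("clinical table lacks samples: ",
           paste(utils::head(missing_ids, 5), collapse = ", "))
    clinical <- clinical[match(colnames(exprs), clinical$sample_id), ,
                         drop = FALSE]
    cd <- S4Vectors::DataFrame(clinical[setdiff(names(clinical), "sample_id")],
                               row.names = colnames(exprs))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs), colData = cd)
  methods::new("SignatureCohort", se)
}

#' SignatureDefinition: declarative description of one gene signature
#'
#' One of five scoring archetypes:
#' \describe{
#'   \item{centroid_subtype}{nearest-centroid subtype call over a genes x
#'     classes centroid matrix, plus a risk-of-relapse score as a linear
#'     combination of the centroid correlations (`ror_coefficients`).}
#'   \item{centroid_risk}{signed correlation to a single reference centroid
#'     (for example a good-prognosis profile with `risk_direction = -1`).}
#'   \item{weighted_sum}{weighted average of gene expression, optionally with
#'     separate gene sets per stratum (for example ER-positive vs negative).}
#'   \item{difference_of_means}{mean of an up-regulated set minus mean of a
#'     down-regulated set, linearly rescaled to a reference range.}
#'   \item{grouped_threshold}{reference-gene normalized group means, clipped
#'     to declared bounds, combined as intercept + sum of group weight times
#'     group value (unscaled recurrence-score family).}
#' }
#'
#' @slot name signature name.
#' @slot archetype one of the five archetypes above.
#' @slot genes data.frame with columns `gene_id` and, as the archetype needs
#'   them, `weight`, `group` (group label, or `"up"`/`"down"` for
#'   difference_of_means), `stratum`, `reference` (logical).
#' @slot centroids genes x classes numeric matrix (centroid archetypes).
#' @slot riskDirection +1 or -1; applied so higher oriented score = higher
#'   risk.
#' @slot calibration list with `labels` (low to high risk), `proportions`,
#'   and optionally `by_stratum` (named list of per-stratum proportions).
#' @slot params archetype extras: `ror_coefficients`, `reference_class`,
#'   `group_weights`, `clip` (list of c(low, high) per group), `intercept`,
#'   `classify_method`, `score_method`.
#' @export
setClass("SignatureDefinition",
  representation(name = "character", archetype = "character",
                 genes = "data.frame", centroids = "matrix",
                 riskDirection = "numeric", calibration = "list",
                 params = "list"),
  prototype(centroids = matrix(numeric(), 0, 0), riskDirection = 1,
            calibration = list(), params = list()))

setValidity("SignatureDefinition", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (length(object@archetype) != 1L || !object@archetype %in% .ARCHETYPES)
    msg <- c(msg, paste("archetype must be one of:",
                        paste(.ARCHETYPES, collapse = ", ")))
  g <- object@genes
  if (!"gene_id" %in% names(g)) msg <- c(msg, "genes needs a gene_id column")
  else {
    strat <- if ("stratum" %in% names(g)) as.character(g$stratum)
             else rep(NA_character_, nrow(g))
    if (anyDuplicated(paste(g$gene_id, strat)))
      msg <- c(msg, "gene entries must be unique within a stratum")
  }
  if (!object@riskDirection %in% c(-1, 1))
    msg <- c(msg, "riskDirection must be +1 or -1")
  a <- object@archetype
  if (length(a) == 1L && a %in% c("centroid_subtype", "centroid_risk")) {
    if (ncol(object@centroids) < 1L)
      msg <- c(msg, "centroid archetypes require a centroid matrix")
    if (is.null(colnames(object@centroids)) ||
        is.null(rownames(object@centroids)))
      msg <- c(msg, "centroids need gene rownames and class colnames")
  }
  if (length(a) == 1L && a == "centroid_subtype") {
    rc <- object@params$ror_coefficients
    if (!is.null(rc) && length(rc) != ncol(object@centroids))
      msg <- c(msg, "one ror coefficient per centroid class required")
  }
  if (length(a) == 1L && a == "centroid_risk") {
    ref <- object@params$reference_class
    if (is.null(ref) || !ref %in% colnames(object@centroids))
      msg <- c(msg, "reference_class must name a centroid column")
  }
  if (length(a) == 1L && a == "weighted_sum" && !"weight" %in% names(g))
    msg <- c(msg, "weighted_sum requires a weight column")
  if (length(a) == 1L && a == "difference_of_means") {
    if (!"group" %in% names(g) ||
        !all(c("up", "down") %in% unique(as.character(g$group))))
      msg <- c(msg, "difference_of_means requires non-empty up and down sets")
  }
  if (length(a) == 1L && a == "grouped_threshold") {
    if (!"group" %in% names(g))
      msg <- c(msg, "grouped_threshold requires a group column")
    gw <- object@params$group_weights
    if (is.null(gw) || is.null(names(gw)))
      msg <- c(msg, "grouped_threshold requires named group_weights")
    else {
      ref_flag <- if ("reference" %in% names(g)) g$reference else FALSE
      grps <- setdiff(unique(as.character(g$group[!ref_flag])), NA)
      if (!all(grps %in% names(gw)))
        msg <- c(msg, "every non-reference group needs a weight")
    }
  }
  cal <- object@calibration
  if (length(cal)) {
    chk <- function(p, where) {
      if (abs(sum(p) - 1) > 1e-9)
        sprintf("calibration proportions (%s) must sum to 1", where)
      else NULL
    }
    if (!is.null(cal$proportions)) {
      if (length(cal$labels) != length(cal$proportions))
        msg <- c(msg, "calibration labels/proportions length mismatch")
      msg <- c(msg, chk(cal$proportions, "global"))
    }
    for (st in names(cal$by_stratum)) {
      if (length(cal$labels) != length(cal$by_stratum[[st]]))
        msg <- c(msg, "calibration labels/proportions length mismatch")
      msg <- c(msg, chk(cal$by_stratum[[st]], st))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SignatureDefinition
#'
#' @param name signature name.
#' @param archetype scoring archetype (see [SignatureDefinition-class]).
#' @param genes data.frame with `gene_id` plus archetype columns.
#' @param centroids genes x classes matrix for centroid archetypes.
#' @param risk_direction +1 (default) or -1.
#' @param calibration risk-group calibration list (`labels`, `proportions`,
#'   optional `by_stratum`).
#' @param ... archetype extras stored in `params`: `ror_coefficients`,
#'   `reference_class`, `group_weights`, `clip`, `intercept`,
#'   `classify_method` (default `"spearman"`), `score_method`
#'   (default `"pearson"`).
#' @return A [SignatureDefinition-class].
#' @export
SignatureDefinition <- function(name, archetype, genes,
                                centroids = matrix(numeric(), 0, 0),
                                risk_direction = 1, calibration = list(),
                                ...) {
  params <- list(...)
  if (is.null(params$classify_method)) params$classify_method <- "spearman"
  if (is.null(params$score_method)) params$score_method <- "pearson"
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  genes$gene_id <- as.character(genes$gene_id)
  methods::new("SignatureDefinition", name = name, archetype = archetype,
               genes = genes, centroids = centroids,
               riskDirection = risk_direction, calibration = calibration,
               params = params)
}

#' ScoreTable: per-sample continuous risk scores
#'
#' @slot scores samples x signatures numeric matrix of oriented risk scores
#'   (higher = higher risk).
#' @slot calls data.frame of subtype calls (one column per centroid_subtype
#'   signature), `"unknown"` where no call could be made.
#' @slot correlations named list of samples x classes centroid-correlation
#'   matrices.
#' @slot status named character: `"ok"` or the failure message per signature.
#' @slot metadata list (for example the difference-of-means rescaling used).
#' @export
setClass("ScoreTable",
  representation(scores = "matrix", calls = "data.frame",
                 correlations = "list", status = "character",
                 metadata = "list"),
  prototype(calls = data.frame(), correlations = list(),
            status = character(), metadata = list()))

setValidity("ScoreTable", function(object) {
  msg <- character()
  if (is.null(rownames(object@scores)))
    msg <- c(msg, "scores must have sample ids as rownames")
  if (any(is.infinite(object@scores)))
    msg <- c(msg, "scores must be finite or NA")
  if (nrow(object@calls) && nrow(object@calls) != nrow(object@scores))
    msg <- c(msg, "calls rows must match score rows")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SignatureCohort", function(object) {
  cat("SignatureCohort:", nrow(object), "genes x", ncol(object), "samples\n")
  cd <- SummarizedExperiment::colData(object)
  if ("event" %in% names(cd))
    cat("  events:", sum(cd$event, na.rm = TRUE), "/",
        sum(!is.na(cd$event)), "with follow-up\n")
  if ("er_status" %in% names(cd))
    cat("  ER+:", sum(cd$er_status == "positive", na.rm = TRUE),
        " ER-:", sum(cd$er_status == "negative", na.rm = TRUE), "\n")
  invisible(NULL)
})

setMethod("show", "SignatureDefinition", function(object) {
  cat(sprintf("SignatureDefinition '%s' [%s]: %d genes",
              object@name, object@archetype, nrow(object@genes)))
  if (ncol(object@centroids))
    cat(",", ncol(object@centroids), "classes")
  cat(", risk direction", sprintf("%+d", object@riskDirection), "\n")
  invisible(NULL)
})

setMethod("show", "ScoreTable", function(object) {
  cat("ScoreTable:", nrow(object@scores), "samples x",
      ncol(object@scores), "signatures\n")
  ok <- sum(object@status == "ok")
  if (length(object@status))
    cat("  status: ", ok, "/", length(object@status), " scored\n", sep = "")
  if (ncol(object@calls))
    cat("  subtype calls:", paste(names(object@calls), collapse = ", "), "\n")
  invisible(NULL)
})
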