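#' Read a log2 expression matrix from TSV
#'
#' Expects genes in rows with the gene id in the first column and a header
#' row of sample ids. Duplicate gene rows (multiple probes mapping to the
#' same gene) are collapsed: by default the row with the highest variance
#' across samples is kept, preserving dynamic range; `collapse = "mean"`
#' averages instead.
#'
#' @param path TSV file path.
#' @param collapse `"max_variance"` (default) or `"mean"`.
#' @return numeric matrix, genes x samples.
#' @export
readExpression <- function(path, collapse = c("max_variance", "mean")) {
  collapse <- match.arg(collapse)
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("malformed expression header: need gene id column ",
                          "plus at least one sample column")
  gene_ids <- as.character(df[[1L]])
  sample_ids <- colnames(df)[-1L]
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicate sample ids: ", paste(unique(dup), collapse = ", "))
  for (j in seq_along(sample_ids)) {
    col <- df[[j + 1L]]
    if (is.character(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & !col %in% c("NA", ""))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                     col[bad[1L]], gene_ids[bad[1L]], sample_ids[j]))
      df[[j + 1L]] <- num
    }
  }
  x <- as.matrix(df[, -1L, drop = FALSE])
  rownames(x) <- gene_ids
  x <- collapseDuplicateGenes(x, collapse)
  if (any(is.infinite(x))) stop("expression values must be finite")
  x
}

#' Collapse duplicate gene rows of an expression matrix
#'
#' @param x numeric matrix with (possibly duplicated) gene-id rownames.
#' @param collapse `"max_variance"` keeps the most variable row per gene;
#'   `"mean"` averages rows per gene.
#' @return matrix with unique rownames, in first-appearance order.
#' @export
collapseDuplicateGenes <- function(x, collapse = c("max_variance", "mean")) {
  collapse <- match.arg(collapse)
  ids <- rownames(x)
  if (!anyDuplicated(ids)) return(x)
  keep_order <- unique(ids)
  if (collapse == "mean") {
    out <- rowsum(x, group = ids, reorder = FALSE) /
      as.vector(table(factor(ids, levels = unique(ids))))
  } else {
    v <- apply(x, 1L, function(r) {
      r <- r[!is.na(r)]
      if (length(r) < 2L) 0 else var(r)
    })
    keep <- vapply(split(seq_along(ids), factor(ids, levels = keep_order)),
                   function(i) i[which.max(v[i])], integer(1L))
    out <- x[keep, , drop = FALSE]
  }
  rownames(out) <- keep_order
  out
}

#' Write an expression matrix as TSV
#'
#' @param x genes x samples matrix.
#' @param path output path.
#' @export
writeExpression <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.CLINICAL_COLS <- c("sample_id", "time_years", "event", "er_status",
                    "her2_status", "size_cat", "node", "grade", "cohort",
                    "systemic_treatment")

#' Read a clinical follow-up table from TSV
#'
#' Columns are matched by name (`sample_id`, `time_years`, `event`,
#' `er_status`, `her2_status`, `size_cat`, `node`, `grade`, `cohort`,
#' `systemic_treatment`). Unknown categories must be encoded with the
#' sentinel given by `unknown` (default `"unknown"`; empty cells and `NA`
#' are also mapped to unknown). Unknowns are preserved, never dropped.
#'
#' @param path TSV file path.
#' @param unknown sentinel string for unknown categories.
#' @return data.frame of validated survival records.
#' @export
readClinical <- function(path, unknown = "unknown") {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"sample_id" %in% names(df)) stop("clinical table needs 'sample_id'")
  validateClinical(df, unknown = unknown)
}

#' Validate (and normalize) a clinical table
#'
#' @param df data.frame of survival records.
#' @param unknown sentinel for unknown categories.
#' @return the normalized data.frame.
#' @export
validateClinical <- function(df, unknown = "unknown") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in clinical table")
  if ("time_years" %in% names(df)) {
    df$time_years <- as.numeric(df$time_years)
    if (any(!is.na(df$time_years) & df$time_years < 0))
      stop("negative follow-up time")
  }
  if ("event" %in% names(df)) {
    df$event <- as.numeric(df$event)
    if (any(!is.na(df$event) & !df$event %in% c(0, 1)))
      stop("event indicator outside {0,1}")
  }
  for (nm in names(.valid_clinical_levels)) {
    if (!nm %in% names(df)) next
    v <- as.character(df[[nm]])
    v[is.na(v) | v == unknown] <- "unknown"
    levels_ok <- .valid_clinical_levels[[nm]]
    bad <- setdiff(unique(v), levels_ok)
    if (length(bad))
      stop(sprintf("invalid %s value(s): %s", nm, paste(bad, collapse = ", ")))
    df[[nm]] <- v
  }
  if ("cohort" %in% names(df)) df$cohort <- as.character(df$cohort)
  df
}

#' Write a clinical table as TSV
#' @param df clinical data.frame.
#' @param path output path.
#' @export
writeClinical <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature definition from JSON
#'
#' The JSON document mirrors [SignatureDefinition-class]: fields `name`,
#' `archetype`, `genes` (array of objects with `gene_id` and optional
#' `weight`, `group`, `stratum`, `reference`), optional `centroids`
#' (`classes`, `gene_ids`, `values` row-major genes x classes),
#' `ror_coefficients`, `reference_class`, `group_weights`, `clip`,
#' `intercept`, `risk_direction`, `calibration`, `classify_method`,
#' `score_method`. See `inst/extdata/signature-schema.json` for the schema.
#'
#' @param path JSON file path.
#' @return A [SignatureDefinition-class].
#' @export
readSignature <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (req in c("name", "archetype", "genes"))
    if (is.null(doc[[req]])) stop("signature JSON missing field: ", req)
  genes <- as.data.frame(doc$genes, stringsAsFactors = FALSE)
  centroids <- matrix(numeric(), 0, 0)
  if (!is.null(doc$centroids)) {
    cm <- doc$centroids
    vals <- cm$values
    if (!is.matrix(vals))  # row-major list of rows
      vals <- do.call(rbind, lapply(vals, as.numeric))
    centroids <- matrix(as.numeric(vals), nrow = length(cm$gene_ids),
                        ncol = length(cm$classes),
                        dimnames = list(cm$gene_ids, cm$classes))
  }
  cal <- if (is.null(doc$calibration)) list() else {
    cc <- doc$calibration
    list(labels = cc$labels, proportions = cc$proportions,
         by_stratum = if (is.null(cc$by_stratum)) NULL else
           lapply(cc$by_stratum, as.numeric))
  }
  extras <- list()
  for (nm in c("ror_coefficients", "reference_class", "group_weights",
               "intercept", "classify_method", "score_method")) {
    if (!is.null(doc[[nm]])) extras[[nm]] <- doc[[nm]]
  }
  if (!is.null(extras$ror_coefficients))
    extras$ror_coefficients <- unlist(extras$ror_coefficients)
  if (!is.null(extras$group_weights))
    extras$group_weights <- unlist(extras$group_weights)
  if (!is.null(doc$clip))
    extras$clip <- lapply(doc$clip, as.numeric)
  rd <- if (is.null(doc$risk_direction)) 1 else doc$risk_direction
  do.call(SignatureDefinition,
          c(list(name = doc$name, archetype = doc$archetype, genes = genes,
                 centroids = centroids, risk_direction = rd,
                 calibration = cal), extras))
}

#' Write a signature definition to JSON
#' @param sig a [SignatureDefinition-class].
#' @param path output path.
#' @export
writeSignature <- function(sig, path) {
  doc <- list(name = sig@name, archetype = sig@archetype, genes = sig@genes,
              risk_direction = sig@riskDirection)
  if (ncol(sig@centroids))
    doc$centroids <- list(classes = colnames(sig@centroids),
                          gene_ids = rownames(sig@centroids),
                          values = lapply(seq_len(nrow(sig@centroids)),
                                          function(i)
                                            unname(sig@centroids[i, ])))
  if (length(sig@calibration)) doc$calibration <- sig@calibration
  for (nm in c("ror_coefficients", "reference_class", "group_weights",
               "clip", "intercept", "classify_method", "score_method")) {
    v <- sig@params[[nm]]
    if (is.null(v)) next
    # named numeric vectors must serialize as JSON objects, not arrays
    if (nm %in% c("ror_coefficients", "group_weights")) v <- as.list(v)
    doc[[nm]] <- v
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read every signature JSON in a directory
#' @param dir directory containing `*.json` signature definitions.
#' @return named list of [SignatureDefinition-class] objects.
#' @export
readSignatureSet <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  files <- files[!grepl("schema", basename(files))]
  if (!length(files)) stop("no signature JSON files in ", dir)
  sigs <- lapply(files, readSignature)
  names(sigs) <- vapply(sigs, function(s) s@name, character(1L))
  sigs
}

#' Write a ScoreTable as TSV
#' @param st a [ScoreTable-class].
#' @param path output path.
#' @export
writeScoreTable <- function(st, path) {
  df <- data.frame(sample_id = rownames(st@scores), st@scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(st@calls)) {
    calls <- st@calls
    names(calls) <- paste0("subtype.", names(calls))
    df <- cbind(df, calls)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
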