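.stable_hash <- function(s) {
  # polynomial rolling hash over the UTF-8 bytes (mod 2^31 - 1, exact in
  # double arithmetic); stable run-metadata fingerprint
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.config_defaults <- list(
  analysis = list(intervals = c(0, 5, 10, Inf), strata = "er_status",
                  correlation_method = "pearson", ties = "efron",
                  ph_transform = "km", quantile_type = 1L,
                  min_coverage = 0.5, seed = 1L, bootstrap_B = 200L))

#' Validate a pipeline run configuration
#'
#' Accepts a YAML file path or a nested list with blocks `paths`
#' (`expression`, `clinical`, `signatures`, `output`) and `analysis`
#' (`intervals`, `strata`, `correlation_method`, `ties`, `ph_transform`,
#' `quantile_type`, `min_coverage`, `seed`, `bootstrap_B`). Defaults are
#' filled for all analysis options; unknown keys are rejected and every
#' violation is reported at once.
#'
#' @param config YAML path or list.
#' @return validated config list of class `"run_config"`.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- character()
  allowed_top <- c("paths", "analysis")
  extra <- setdiff(names(config), allowed_top)
  if (length(extra))
    errs <- c(errs, paste("unknown top-level key(s):",
                          paste(extra, collapse = ", ")))
  paths <- config$paths
  allowed_paths <- c("expression", "clinical", "signatures", "output")
  extra <- setdiff(names(paths), allowed_paths)
  if (length(extra))
    errs <- c(errs, paste("unknown paths key(s):",
                          paste(extra, collapse = ", ")))
  for (p in allowed_paths)
    if (is.null(paths[[p]]))
      errs <- c(errs, paste("missing required path:", p))
  an <- config$analysis
  allowed_an <- names(.config_defaults$analysis)
  extra <- setdiff(names(an), allowed_an)
  if (length(extra))
    errs <- c(errs, paste("unknown analysis key(s):",
                          paste(extra, collapse = ", ")))
  an <- modifyList(.config_defaults$analysis,
                   if (is.null(an)) list() else an)
  iv <- as.numeric(an$intervals)
  if (length(iv) < 2L || iv[1L] != 0 || is.unsorted(iv, strictly = TRUE))
    errs <- c(errs, "intervals must be strictly ascending from 0")
  if (!is.infinite(iv[length(iv)])) iv <- c(iv, Inf)
  an$intervals <- iv
  if (!an$correlation_method %in% c("pearson", "spearman"))
    errs <- c(errs, "correlation_method must be pearson or spearman")
  if (!an$ties %in% c("efron", "breslow"))
    errs <- c(errs, "ties must be efron or breslow")
  if (!an$ph_transform %in% c("km", "identity", "rank"))
    errs <- c(errs, "ph_transform must be km, identity or rank")
  if (!an$quantile_type %in% 1:9)
    errs <- c(errs, "quantile_type must be in 1..9")
  if (!is.numeric(an$min_coverage) || an$min_coverage < 0 ||
      an$min_coverage > 1)
    errs <- c(errs, "min_coverage must be in [0, 1]")
  if (!is.numeric(an$bootstrap_B) || an$bootstrap_B < 1)
    errs <- c(errs, "bootstrap_B must be >= 1")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  out <- list(paths = paths, analysis = an)
  class(out) <- "run_config"
  out
}

.intervals_as_list <- function(iv)
  lapply(seq_len(length(iv) - 1L), function(i) c(iv[i], iv[i + 1L]))

#' Run the full scoring-calibration-evaluation pipeline
#'
#' Reads expression, clinical and signature-definition inputs, scores all
#' signatures, assigns population-calibrated risk groups, computes
#' cross-signature agreement, and evaluates prognostic power: per-signature
#' C-index and PVE, standardized HRs per follow-up interval and ER
#' stratum with Schoenfeld PH diagnostics, multivariate Cox models with
#' size/node/grade, Kaplan-Meier curves per risk group and Aalen
#' cumulative-regression curves. All outputs are TSV/JSON in the output
#' directory, stamped with the config hash and seed. A signature that
#' fails (for example low coverage) is reported in the score status and
#' skipped downstream; a stage-level failure aborts with the stage name.
#'
#' @param config run configuration (path, list, or `"run_config"`).
#' @return invisibly, a list with the in-memory results (`scores`,
#'   `risk_groups`, `agreement`, `performance`, `interval_effects`,
#'   `ph_tests`, `multivariate`, `km_curves`, `aalen_curves`, `metadata`).
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validateConfig(config)
  an <- config$analysis
  outdir <- config$paths$output
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    log_lines <<- c(log_lines,
                    sprintf("[%s] stage %s done in %.2fs",
                            format(Sys.time(), "%H:%M:%S"), name,
                            timings[[name]]))
    res
  }
  set.seed(an$seed)

  inputs <- stage("read", {
    expr <- readExpression(config$paths$expression)
    clinical <- readClinical(config$paths$clinical)
    sigs <- readSignatureSet(config$paths$signatures)
    common <- intersect(colnames(expr), clinical$sample_id)
    list(cohort = SignatureCohort(
           expr[, common, drop = FALSE],
           clinical[clinical$sample_id %in% common, , drop = FALSE]),
         signatures = sigs)
  })
  cohort <- inputs$cohort
  clinical <- clinicalData(cohort)
  strata_var <- an$strata
  stratum_labels <- as.character(clinical[[strata_var]])
  stratum_labels[stratum_labels == "unknown"] <- NA

  st <- stage("score", suppressWarnings(
    scoreAll(cohort, inputs$signatures, min_coverage = an$min_coverage)))
  scores <- riskScores(st)
  ok_sigs <- names(which(scoreStatus(st) == "ok"))

  groups <- stage("calibrate", {
    out <- list(); cuts <- list()
    for (nm in ok_sigs) {
      sig <- inputs$signatures[[nm]]
      if (!length(sig@calibration)) next
      cal <- calibrateRiskGroups(scores[, nm], sig, stratum_labels,
                                 type = an$quantile_type)
      out[[nm]] <- cal$groups; cuts[[nm]] <- cal$cutoffs
    }
    list(groups = out, cutoffs = cuts)
  })

  agreement <- stage("agreement",
                     agreementReport(st, method = an$correlation_method))

  surv_ok <- !is.na(clinical$time_years) & !is.na(clinical$event)
  performance <- stage("performance", {
    rows <- list()
    for (nm in ok_sigs) {
      s <- scores[, nm]
      keep <- surv_ok & !is.na(s)
      z <- standardizeScores(s[keep])
      cx <- coxFit(z, clinical$time_years[keep], clinical$event[keep],
                   ties = an$ties)
      ci <- concordanceIndex(s[keep], clinical$time_years[keep],
                             clinical$event[keep])
      lr_p <- NA_real_
      if (!is.null(groups$groups[[nm]])) {
        gk <- groups$groups[[nm]][keep]
        if (length(unique(stats::na.omit(gk))) >= 2L)
          lr_p <- logrankTest(clinical$time_years[keep][!is.na(gk)],
                              clinical$event[keep][!is.na(gk)],
                              gk[!is.na(gk)])$p
      }
      rows[[nm]] <- data.frame(
        signature = nm, n = cx$n, n_event = cx$n_event,
        c_index = ci$c, c_lower = ci$lower, c_upper = ci$upper,
        pve_pct = 100 * pve(cx),
        hr_std = cx$coefficients$hr, hr_lower = cx$coefficients$lower,
        hr_upper = cx$coefficients$upper, p = cx$coefficients$p,
        logrank_p = lr_p, stringsAsFactors = FALSE)
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })

  ivs <- .intervals_as_list(an$intervals)
  interval_effects <- stage("interval_effects", {
    rows <- lapply(ok_sigs, function(nm) {
      tab <- intervalEffects(scores[, nm], clinical, intervals = ivs,
                             stratify_by = strata_var, ties = an$ties)
      cbind(signature = nm, tab, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  ph_tests <- stage("ph", {
    rows <- list()
    for (nm in ok_sigs) {
      for (stv in setdiff(sort(unique(stratum_labels)), NA)) {
        keep <- surv_ok & !is.na(scores[, nm]) &
          !is.na(stratum_labels) & stratum_labels == stv
        res <- tryCatch({
          z <- standardizeScores(scores[keep, nm])
          cx <- coxFit(z, clinical$time_years[keep], clinical$event[keep],
                       ties = an$ties)
          pt <- phTest(cx, transform = an$ph_transform)
          data.frame(signature = nm, stratum = stv, rho = pt$rho,
                     p = pt$p, transform = an$ph_transform,
                     stringsAsFactors = FALSE)
        }, error = function(e)
          data.frame(signature = nm, stratum = stv, rho = NA, p = NA,
                     transform = an$ph_transform, stringsAsFactors = FALSE))
        rows[[paste(nm, stv)]] <- res
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })

  multivariate <- stage("multivariate", {
    rows <- list()
    for (nm in ok_sigs) {
      for (stv in setdiff(sort(unique(stratum_labels)), NA)) {
        keep <- surv_ok & !is.na(scores[, nm]) &
          !is.na(stratum_labels) & stratum_labels == stv
        fits <- tryCatch(
          multivariateEffects(scores[keep, nm],
                              clinical[keep, , drop = FALSE],
                              ties = an$ties),
          error = function(e) NULL)
        if (is.null(fits)) next
        for (model in names(fits)) {
          ct <- fits[[model]]$coefficients
          rows[[paste(nm, stv, model)]] <- data.frame(
            signature = nm, stratum = stv, model = model, term = ct$term,
            hr = ct$hr, lower = ct$lower, upper = ct$upper, p = ct$p,
            n = fits[[model]]$n, n_event = fits[[model]]$n_event,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })

  km_curves <- stage("km", {
    rows <- list()
    for (nm in names(groups$groups)) {
      gk <- groups$groups[[nm]]
      for (lv in levels(gk)) {
        keep <- surv_ok & !is.na(gk) & gk == lv
        if (sum(keep) < 1L) next
        km <- kmEstimate(clinical$time_years[keep], clinical$event[keep])
        rows[[paste(nm, lv)]] <- cbind(signature = nm, group = lv, km,
                                       stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })

  aalen_curves <- stage("aalen", {
    rows <- list()
    for (nm in ok_sigs) {
      for (stv in setdiff(sort(unique(stratum_labels)), NA)) {
        keep <- surv_ok & !is.na(scores[, nm]) &
          !is.na(stratum_labels) & stratum_labels == stv
        res <- tryCatch({
          z <- standardizeScores(scores[keep, nm])
          aalenCumulative(z, clinical$time_years[keep],
                          clinical$event[keep])
        }, error = function(e) NULL)
        if (is.null(res)) next
        rows[[paste(nm, stv)]] <- data.frame(
          signature = nm, stratum = stv, time = res$time,
          estimate = res$estimate[, "covariate"],
          lower = res$lower[, "covariate"],
          upper = res$upper[, "covariate"], stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })

  metadata <- stage("write", {
    wt <- function(df, f) if (!is.null(df) && nrow(df))
      write.table(df, file.path(outdir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    writeScoreTable(st, file.path(outdir, "scores.tsv"))
    if (length(groups$groups)) {
      gdf <- data.frame(sample_id = rownames(scores),
                        lapply(groups$groups, as.character),
                        check.names = FALSE, stringsAsFactors = FALSE)
      wt(gdf, "risk_groups.tsv")
    }
    cm <- agreement$correlation
    wt(data.frame(signature = rownames(cm), cm, check.names = FALSE),
       "agreement_correlation.tsv")
    kap <- lapply(names(agreement$subtype_agreement), function(pair) {
      k <- agreement$subtype_agreement[[pair]]$kappa
      data.frame(pair = pair, kappa = k$kappa, lower = k$lower,
                 upper = k$upper, n = k$n)
    })
    if (length(kap)) wt(do.call(rbind, kap), "subtype_kappa.tsv")
    wt(performance, "performance.tsv")
    wt(interval_effects, "interval_effects.tsv")
    wt(ph_tests, "ph_tests.tsv")
    wt(multivariate, "multivariate.tsv")
    wt(km_curves, "km_curves.tsv")
    wt(aalen_curves, "aalen_curves.tsv")
    cfg_plain <- unclass(config)
    cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA)
    meta <- list(
      config = cfg_plain,
      config_hash = .stable_hash(as.character(cfg_json)),
      seed = an$seed,
      package_version = as.character(utils::packageVersion("sigsurv")),
      r_version = R.version.string,
      signature_status = as.list(scoreStatus(st)),
      cutoffs = groups$cutoffs, timings = timings)
    jsonlite::write_json(meta, file.path(outdir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    meta
  })
  writeLines(log_lines, file.path(outdir, "run.log"))

  invisible(list(scores = st, risk_groups = groups, agreement = agreement,
                 performance = performance,
                 interval_effects = interval_effects, ph_tests = ph_tests,
                 multivariate = multivariate, km_curves = km_curves,
                 aalen_curves = aalen_curves, metadata = metadata))
}
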