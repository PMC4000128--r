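#' @importFrom survival Surv coxph survfit survdiff strata coxph.control
NULL

#' Kaplan-Meier product-limit estimate
#'
#' @param times follow-up times (years).
#' @param events event indicators (1 = distant metastasis).
#' @param conf_level pointwise confidence level (log-log CI).
#' @return data.frame with `time`, `n_risk`, `n_event`, `surv`, `lower`,
#'   `upper`, one row per observed time.
#' @export
kmEstimate <- function(times, events, conf_level = 0.95) {
  if (!length(times)) stop("need at least one subject")
  fit <- survival::survfit(Surv(times, events) ~ 1, conf.type = "log-log",
                           conf.int = conf_level)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv, lower = fit$lower, upper = fit$upper)
}

#' Log-rank test across groups
#'
#' @param times follow-up times.
#' @param events event indicators.
#' @param groups group labels (>= 2 groups).
#' @return list with `statistic`, `df`, `p`.
#' @export
logrankTest <- function(times, events, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (sum(events) < 1L) stop("log-rank undefined without events")
  sd <- survival::survdiff(Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1L
  list(statistic = sd$chisq, df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Fit a Cox proportional-hazards model
#'
#' Partial-likelihood maximization via [survival::coxph()] with the
#' declared ties method (Efron default). Optional stratification gives each
#' stratum its own baseline hazard (used for cohort adjustment). Fitting a
#' [standardizeScores()]-transformed covariate yields standardized hazard
#' ratios (per one-SD increase).
#'
#' @param x covariate vector, matrix, or data.frame (factors allowed).
#' @param times follow-up times.
#' @param events event indicators.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param strata_labels optional stratification labels.
#' @param conf_level confidence level for the HR interval.
#' @return object of class `"CoxResult"`: list with `coefficients`
#'   (data.frame: term, beta, se, hr, lower, upper, p), `loglik`
#'   (`null`, `model`), `n`, `n_event`, `ties`, `times`, `events`, `fit`.
#' @export
coxFit <- function(x, times, events, ties = c("efron", "breslow"),
                   strata_labels = NULL, conf_level = 0.95) {
  ties <- match.arg(ties)
  if (is.null(dim(x))) x <- data.frame(x = x)
  x <- as.data.frame(x)
  keep <- complete.cases(x) & !is.na(times) & !is.na(events)
  if (!is.null(strata_labels)) keep <- keep & !is.na(strata_labels)
  x <- x[keep, , drop = FALSE]
  times <- times[keep]; events <- events[keep]
  if (sum(events) < 1L) stop("no events: Cox model undefined")
  for (j in seq_along(x)) {
    v <- x[[j]]
    if (is.numeric(v)) {
      if (any(!is.finite(v))) stop("non-finite covariate: ", names(x)[j])
      if (sd(v) == 0) stop("constant covariate: ", names(x)[j])
    } else if (length(unique(v)) < 2L) {
      stop("constant covariate: ", names(x)[j])
    }
  }
  dat <- cbind(x, .time = times, .event = events)
  rhs <- paste(sprintf("`%s`", names(x)), collapse = " + ")
  if (!is.null(strata_labels)) {
    dat$.stratum <- strata_labels[keep]
    rhs <- paste(rhs, "+ strata(.stratum)")
  }
  fml <- stats::as.formula(paste("Surv(.time, .event) ~", rhs))
  fit <- coxph(fml, data = dat, ties = ties)
  if (!is.null(fit$info) && !fit$info$converged)
    stop("Cox model failed to converge")
  beta <- stats::coef(fit)
  if (any(!is.finite(beta)) || any(abs(beta) > 15))
    stop("Cox model unstable (possible complete separation)")
  se <- sqrt(diag(fit$var))
  z <- qnorm(1 - (1 - conf_level) / 2)
  coef_tab <- data.frame(
    term = names(beta), beta = unname(beta), se = se,
    hr = exp(unname(beta)), lower = exp(unname(beta) - z * se),
    upper = exp(unname(beta) + z * se),
    p = 2 * pnorm(-abs(unname(beta) / se)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coef_tab,
                 loglik = list(null = fit$loglik[1L],
                               model = fit$loglik[2L]),
                 n = fit$n, n_event = fit$nevent, ties = ties,
                 times = times, events = events, fit = fit),
            class = "CoxResult")
}

#' @export
print.CoxResult <- function(x, ...) {
  cat(sprintf("Cox model (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_event))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Harrell's concordance index for censored survival
#'
#' A pair is usable when the order of failure is determinate under
#' censoring: the earlier time carries an event, or the times are tied with
#' exactly one event (the censored subject is known to fail later). C is
#' the fraction of usable pairs in which the failing-first subject has the
#' higher risk score; score ties count one half.
#'
#' @param scores risk scores (higher = higher predicted risk).
#' @param times follow-up times.
#' @param events event indicators.
#' @param ci_method `"asymptotic"` (normal SE over usable pairs) or
#'   `"bootstrap"`.
#' @param conf_level confidence level.
#' @param B bootstrap replicates (when `ci_method = "bootstrap"`).
#' @param seed bootstrap seed.
#' @return object of class `"ConcordanceResult"`: list with `c`, `se`,
#'   `lower`, `upper`, `n_pairs`, `concordant`, `discordant`, `tied_score`.
#' @export
concordanceIndex <- function(scores, times, events,
                             ci_method = c("asymptotic", "bootstrap"),
                             conf_level = 0.95, B = 200L, seed = 1L) {
  ci_method <- match.arg(ci_method)
  keep <- !is.na(scores) & !is.na(times) & !is.na(events)
  scores <- scores[keep]; times <- times[keep]; events <- events[keep]
  cnt <- .concordance_counts(scores, times, events)
  if (cnt$usable == 0L) stop("no usable pairs")
  cval <- (cnt$concordant + 0.5 * cnt$tied) / cnt$usable
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (ci_method == "asymptotic") {
    se <- sqrt(cval * (1 - cval) / cnt$usable)
  } else {
    set.seed(seed)
    n <- length(scores)
    cb <- replicate(B, {
      idx <- sample.int(n, n, replace = TRUE)
      k <- .concordance_counts(scores[idx], times[idx], events[idx])
      if (k$usable == 0L) NA_real_ else
        (k$concordant + 0.5 * k$tied) / k$usable
    })
    se <- sd(cb, na.rm = TRUE)
  }
  structure(list(c = cval, se = se,
                 lower = max(0, cval - z * se),
                 upper = min(1, cval + z * se),
                 n_pairs = cnt$usable, concordant = cnt$concordant,
                 discordant = cnt$discordant, tied_score = cnt$tied),
            class = "ConcordanceResult")
}

# vectorized pair counting over the upper triangle
.concordance_counts <- function(scores, times, events) {
  n <- length(scores)
  if (n < 2L) return(list(usable = 0L, concordant = 0, discordant = 0,
                          tied = 0))
  ti <- matrix(times, n, n); tj <- t(ti)
  ei <- matrix(events == 1, n, n); ej <- t(ei)
  si <- matrix(scores, n, n); sj <- t(si)
  ut <- upper.tri(ti)
  i_first <- (ti < tj & ei) | (ti == tj & ei & !ej)
  j_first <- (tj < ti & ej) | (ti == tj & ej & !ei)
  usable <- ut & (i_first | j_first)
  first_s <- ifelse(i_first, si, sj)
  other_s <- ifelse(i_first, sj, si)
  conc <- sum(usable & first_s > other_s)
  disc <- sum(usable & first_s < other_s)
  tied <- sum(usable & first_s == other_s)
  list(usable = sum(usable), concordant = conc, discordant = disc,
       tied = tied)
}

#' @export
print.ConcordanceResult <- function(x, ...) {
  cat(sprintf("C-index %.3f [%.3f, %.3f], %d usable pairs\n",
              x$c, x$lower, x$upper, x$n_pairs))
  invisible(x)
}

#' Proportion of variation explained by a survival predictor
#'
#' PVE = 1 - exp(-G/n) where G is the likelihood-ratio statistic of the
#' fitted model against the null and n the number of subjects.
#'
#' @param cox_result a `"CoxResult"` from [coxFit()].
#' @return fraction in `[0, 1)`.
#' @export
pve <- function(cox_result) {
  ll <- cox_result$loglik
  if (is.null(ll$null) || is.na(ll$null)) stop("missing null log-likelihood")
  G <- 2 * (ll$model - ll$null)
  1 - exp(-max(G, 0) / cox_result$n)
}

#' Proportional-hazards test on scaled Schoenfeld residuals
#'
#' Grambsch-Therneau diagnostic: the scaled Schoenfeld residuals of each
#' covariate are correlated with transformed event time; a non-zero slope
#' (rho) indicates a time-varying effect, with negative rho meaning the
#' effect declines over follow-up.
#'
#' @param cox_result a `"CoxResult"` from [coxFit()].
#' @param transform time transform: `"km"` (left-continuous 1 - KM at event
#'   times, default), `"identity"`, or `"rank"`.
#' @return data.frame with `term`, `rho`, `chisq`, `p` and the transform
#'   used (attribute `transform`).
#' @export
phTest <- function(cox_result, transform = c("km", "identity", "rank")) {
  transform <- match.arg(transform)
  fit <- cox_result$fit
  d <- cox_result$n_event
  if (d < 3L) stop("need >= 3 events for the PH test")
  sch <- stats::residuals(fit, type = "schoenfeld")
  if (is.null(dim(sch))) sch <- matrix(sch, ncol = 1L,
                                       dimnames = list(names(sch), NULL))
  etimes <- as.numeric(rownames(sch))
  ord <- order(etimes)
  sch <- sch[ord, , drop = FALSE]
  etimes <- etimes[ord]
  g <- switch(transform,
    identity = etimes,
    rank = rank(etimes),
    km = {
      km <- kmEstimate(cox_result$times, cox_result$events)
      # left-continuous KM: survival just before each event time
      surv_before <- vapply(etimes, function(t) {
        prior <- km$surv[km$time < t]
        if (length(prior)) prior[length(prior)] else 1
      }, numeric(1L))
      1 - surv_before
    })
  V <- fit$var
  scaled <- d * (sch %*% V)  # scaled Schoenfeld residuals (beta offsets drop
                             # out of correlation and centered test)
  xx <- g - mean(g)
  terms <- cox_result$coefficients$term
  out <- data.frame(term = terms, rho = NA_real_, chisq = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_along(terms)) {
    r <- scaled[, j]
    out$rho[j] <- suppressWarnings(cor(xx, r))
    # Grambsch-Therneau: T = d (sum xx sV)^2 / (V_jj sum xx^2); here
    # r = d * sV, so divide the squared sum by d once
    out$chisq[j] <- sum(xx * r)^2 / (d * V[j, j] * sum(xx^2))
    out$p[j] <- pchisq(out$chisq[j], 1L, lower.tail = FALSE)
  }
  attr(out, "transform") <- transform
  out
}

#' Restrict a survival dataset to one follow-up interval
#'
#' Subjects who failed or were lost before `lower` are excluded (not at
#' risk at interval start); subjects still at risk at `upper` are kept and
#' censored at `upper`; event or censoring inside `[lower, upper)` is kept
#' unchanged. Intervals are half-open, so an event exactly at `upper`
#' belongs to the next interval.
#'
#' @param times follow-up times.
#' @param events event indicators.
#' @param lower,upper interval bounds, `0 <= lower < upper` (`upper` may be
#'   `Inf`).
#' @return list with `times`, `events` (restricted) and `included`
#'   (logical over the input).
#' @export
restrictInterval <- function(times, events, lower, upper) {
  if (!(lower >= 0 && lower < upper)) stop("need 0 <= lower < upper")
  included <- !is.na(times) & times >= lower
  t2 <- times[included]
  e2 <- events[included]
  at_end <- t2 >= upper
  t2[at_end] <- upper
  e2[at_end] <- 0
  list(times = t2, events = e2, included = included)
}

.default_intervals <- list(c(0, 5), c(5, 10), c(10, Inf))

.interval_label <- function(iv) {
  if (is.infinite(iv[2L])) sprintf(">%g yr", iv[1L])
  else sprintf("%g-%g yr", iv[1L], iv[2L])
}

#' Standardized hazard ratios per follow-up interval and stratum
#'
#' For each (interval, stratum) cell: the survival data are restricted to
#' the interval with [restrictInterval()], the score is standardized over
#' exactly the restricted stratum sample, and a univariate Cox model is
#' fitted; the cell reports the number at risk at interval start, the
#' number of events in the interval, and the standardized HR with CI and
#' p-value. Cells that cannot be fitted (for example zero events) report
#' the reason instead of being dropped.
#'
#' @param score continuous risk score per sample (oriented, higher = risk).
#' @param clinical clinical data.frame (`time_years`, `event`, plus the
#'   stratification column).
#' @param intervals list of `c(lower, upper)` pairs, ascending and tiling
#'   `[0, Inf)` (default 0-5, 5-10, >10 years).
#' @param stratify_by clinical column to stratify on (default
#'   `"er_status"`), or `NULL` for a single stratum.
#' @param ties ties method for [coxFit()].
#' @return data.frame: `interval`, `stratum`, `n_risk`, `n_event`, `hr`,
#'   `lower`, `upper`, `p`, `note`.
#' @export
intervalEffects <- function(score, clinical, intervals = .default_intervals,
                            stratify_by = "er_status",
                            ties = "efron") {
  .check_intervals(intervals)
  if (is.null(stratify_by)) {
    strata_levels <- "all"
    stratum_of <- rep("all", nrow(clinical))
  } else {
    stratum_of <- as.character(clinical[[stratify_by]])
    strata_levels <- setdiff(sort(unique(stratum_of)), c(NA, "unknown"))
  }
  rows <- list()
  for (st in strata_levels) {
    in_st <- !is.na(stratum_of) & stratum_of == st &
      !is.na(clinical$time_years) & !is.na(clinical$event) & !is.na(score)
    tt <- clinical$time_years[in_st]
    ee <- clinical$event[in_st]
    ss <- score[in_st]
    for (iv in intervals) {
      r <- restrictInterval(tt, ee, iv[1L], iv[2L])
      n_risk <- sum(r$included)
      n_event <- sum(r$events)
      row <- data.frame(interval = .interval_label(iv), stratum = st,
                        n_risk = n_risk, n_event = n_event,
                        hr = NA_real_, lower = NA_real_, upper = NA_real_,
                        p = NA_real_, note = "", stringsAsFactors = FALSE)
      res <- tryCatch({
        z <- standardizeScores(ss[r$included])
        coxFit(z, r$times, r$events, ties = ties)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        row$note <- conditionMessage(res)
      } else {
        ct <- res$coefficients
        row$hr <- ct$hr; row$lower <- ct$lower; row$upper <- ct$upper
        row$p <- ct$p
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

.check_intervals <- function(intervals) {
  lo <- vapply(intervals, `[`, numeric(1L), 1L)
  up <- vapply(intervals, `[`, numeric(1L), 2L)
  if (any(lo >= up)) stop("each interval needs lower < upper")
  if (lo[1L] != 0 || !is.infinite(up[length(up)]) ||
      (length(lo) > 1L && any(up[-length(up)] != lo[-1L])))
    stop("intervals must be ascending and tile [0, Inf)")
  invisible(TRUE)
}

#' Aalen additive-hazards cumulative regression
#'
#' Least-squares increments of the additive hazard model at each event
#' time, accumulated into cumulative regression coefficients B(t) with
#' accumulated variance and pointwise CIs. A time-constant additive effect
#' appears as a straight line; a declining effect as an early rise that
#' flattens. Accumulation stops at the first event time with a singular
#' design (and records the truncation time).
#'
#' @param covariate numeric covariate per subject.
#' @param times follow-up times.
#' @param events event indicators.
#' @param conf_level pointwise confidence level.
#' @return object of class `"AalenResult"`: list with `time`, `estimate`
#'   (times x 2: `(Intercept)`, `covariate`), `se`, `lower`, `upper`,
#'   `truncated` (time or NA).
#' @export
aalenCumulative <- function(covariate, times, events, conf_level = 0.95) {
  keep <- !is.na(covariate) & !is.na(times) & !is.na(events)
  z <- covariate[keep]; tt <- times[keep]; ee <- events[keep]
  if (sum(ee) < 2L) stop("need >= 2 events")
  if (sd(z) == 0) stop("constant covariate")
  etimes <- sort(unique(tt[ee == 1]))
  ord <- order(tt)
  tt_s <- tt[ord]; z_s <- z[ord]
  # suffix sums give risk-set moments at each event time
  n <- length(tt_s)
  B <- matrix(0, 0, 2); Vd <- matrix(0, 0, 2); kept_times <- numeric(0)
  cumB <- c(0, 0); cumV <- c(0, 0)
  truncated <- NA_real_
  for (t_k in etimes) {
    at_risk <- which(tt_s >= t_k)
    m <- length(at_risk)
    zr <- z_s[at_risk]
    Sz <- sum(zr); Szz <- sum(zr^2)
    det <- m * Szz - Sz^2
    if (m < 2L || abs(det) < 1e-10 * max(1, m * Szz)) {
      truncated <- t_k
      break
    }
    Minv <- matrix(c(Szz, -Sz, -Sz, m), 2L, 2L) / det
    ev_idx <- which(tt == t_k & ee == 1)
    Xe <- rbind(1, z[ev_idx])            # 2 x (#events at t_k)
    incr <- Minv %*% rowSums(Xe)
    AXe <- Minv %*% Xe
    vincr <- rowSums(AXe^2)
    cumB <- cumB + as.numeric(incr)
    cumV <- cumV + vincr
    B <- rbind(B, cumB); Vd <- rbind(Vd, cumV)
    kept_times <- c(kept_times, t_k)
  }
  colnames(B) <- colnames(Vd) <- c("(Intercept)", "covariate")
  zq <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(Vd)
  structure(list(time = kept_times, estimate = B, se = se,
                 lower = B - zq * se, upper = B + zq * se,
                 truncated = truncated),
            class = "AalenResult")
}

#' @export
print.AalenResult <- function(x, ...) {
  cat(sprintf("Aalen cumulative regression: %d event times%s\n",
              length(x$time),
              if (is.na(x$truncated)) "" else
                sprintf(" (truncated at t = %.3g)", x$truncated)))
  invisible(x)
}

#' Multivariate Cox models combining a signature with clinical factors
#'
#' Fits the declared covariate sets: the standardized signature score
#' alone; with tumor size (ordered categories, pT1 reference); with
#' histological grade (grade 1 reference); and with size, node status
#' (negative reference) and grade together. Samples with unknown values in
#' a model's covariates are dropped from that model only; the score is
#' standardized over each model's fitted sample set.
#'
#' @param score continuous risk score per sample.
#' @param clinical clinical data.frame with `time_years`, `event`,
#'   `size_cat`, `node`, `grade`.
#' @param ties ties method for [coxFit()].
#' @param strata_labels optional stratification (for example cohort).
#' @return named list of `"CoxResult"` objects: `signature`,
#'   `signature_size`, `signature_grade`, `signature_size_node_grade`.
#' @export
multivariateEffects <- function(score, clinical, ties = "efron",
                                strata_labels = NULL) {
  enc <- data.frame(score = score)
  enc$size <- factor(clinical$size_cat, levels = c("pT1", "pT2", "pT3-4"))
  enc$node <- factor(clinical$node, levels = c("negative", "positive"))
  enc$grade <- factor(as.character(clinical$grade), levels = c("1", "2", "3"))
  bad <- setdiff(unique(stats::na.omit(as.character(clinical$size_cat))),
                 c(levels(enc$size), "unknown"))
  if (length(bad)) stop("unknown size category: ", paste(bad, collapse = ", "))
  model_sets <- list(
    signature = "score",
    signature_size = c("score", "size"),
    signature_grade = c("score", "grade"),
    signature_size_node_grade = c("score", "size", "node", "grade"))
  out <- list()
  for (nm in names(model_sets)) {
    vars <- model_sets[[nm]]
    sub <- enc[, vars, drop = FALSE]
    keep <- complete.cases(sub) & !is.na(clinical$time_years) &
      !is.na(clinical$event)
    sub <- sub[keep, , drop = FALSE]
    sub$score <- standardizeScores(sub$score)
    out[[nm]] <- coxFit(sub, clinical$time_years[keep],
                        clinical$event[keep], ties = ties,
                        strata_labels = if (is.null(strata_labels)) NULL
                                        else strata_labels[keep])
  }
  out
}
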