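.SUBTYPES <- c("lumA", "lumB", "her2e", "basal", "normal")
# relative proliferation of each subtype (luminal B / basal high, luminal A
# / normal low) -- drives the latent proliferation factor and the ROR
# coefficients of the synthetic centroid signatures
.PROLIF_LEVEL <- c(lumA = -1, lumB = 0.9, her2e = 0.7, basal = 1,
                   normal = -0.8)

#' Build a synthetic-cohort simulation configuration
#'
#' The defaults emulate the design of a pooled breast-cancer microarray
#' meta-cohort with distant-metastasis-free survival follow-up: 912
#' samples with 692 ER-positive (75.9%); five molecular subtypes with
#' ER-stratum-specific frequencies; nine signature score columns driven by
#' a shared latent proliferation factor (plus one hypoxia-like signature
#' driven by an independent stress factor); survival with a
#' piecewise-constant log-hazard effect of the latent risk factor -- strong
#' in the first five years of follow-up and null afterwards -- and
#' independent random plus administrative censoring at 15 years.
#'
#' @param n_samples cohort size.
#' @param er_positive_fraction fraction of ER-positive samples.
#' @param subtype_probs named list (`positive`, `negative`) of subtype
#'   frequencies over `lumA, lumB, her2e, basal, normal`.
#' @param prolif_alignment correlation strength between subtype identity
#'   and the proliferation factor.
#' @param loadings named proliferation-factor loading per signature
#'   (the hypoxia-like signature instead loads on the hypoxia factor).
#' @param specific_sd SD of the signature-specific latent factor.
#' @param gene_noise_sd per-gene measurement noise SD.
#' @param n_filler_genes unrelated noise genes appended to the matrix.
#' @param baseline_hazard named per-stratum baseline hazard (per year).
#' @param beta_schedule named list per ER stratum: `driver`
#'   (`"proliferation"` or `"hypoxia"`), `breaks` (ascending, from 0 to
#'   Inf) and `beta` (log-HR per unit of the standardized driver on each
#'   interval).
#' @param admin_censoring_years administrative censoring horizon.
#' @param random_censoring_rate exponential loss-to-follow-up rate.
#' @param grade_cutpoints,size_cutpoints quantile cut points on the
#'   proliferation factor generating histological grade (1/2/3) and tumor
#'   size (pT1/pT2/pT3-4), so grade and size mediate part of the
#'   signatures' effect.
#' @param node_positive_prob marginal probability of node positivity.
#' @param seed mandatory integer seed; all randomness flows from it via
#'   fixed per-component sub-streams.
#' @return validated config list of class `"sim_config"`.
#' @export
simulationConfig <- function(
    n_samples = 912L,
    er_positive_fraction = 692 / 912,
    subtype_probs = list(
      positive = c(lumA = 0.45, lumB = 0.33, her2e = 0.08, basal = 0.04,
                   normal = 0.10),
      negative = c(lumA = 0.05, lumB = 0.08, her2e = 0.30, basal = 0.45,
                   normal = 0.12)),
    prolif_alignment = 0.6,
    loadings = c(intrinsicLike = 0.8, pam50Like = 0.9, g70Like = 0.85,
                 g76Like = 0.85, ggiLike = 0.9, wrLike = 0.85,
                 hypoxiaLike = 0.9, rsLike = 0.85, epLike = 0.85),
    specific_sd = 0.45,
    gene_noise_sd = 0.5,
    n_filler_genes = 200L,
    baseline_hazard = c(positive = 0.035, negative = 0.065),
    beta_schedule = list(
      positive = list(driver = "proliferation", breaks = c(0, 5, Inf),
                      beta = c(log(2), 0)),
      negative = list(driver = "hypoxia", breaks = c(0, 5, Inf),
                      beta = c(log(1.5), 0))),
    admin_censoring_years = 15,
    random_censoring_rate = 0.06,
    grade_cutpoints = c(1 / 3, 2 / 3),
    size_cutpoints = c(0.5, 0.88),
    node_positive_prob = 0.45,
    seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  seed <- as.integer(seed)
  if (is.na(seed) || abs(seed) > 2^31 - 10) stop("seed out of integer range")
  cfg <- list(n_samples = as.integer(n_samples),
              er_positive_fraction = er_positive_fraction,
              subtype_probs = subtype_probs,
              prolif_alignment = prolif_alignment, loadings = loadings,
              specific_sd = specific_sd, gene_noise_sd = gene_noise_sd,
              n_filler_genes = as.integer(n_filler_genes),
              baseline_hazard = baseline_hazard,
              beta_schedule = beta_schedule,
              admin_censoring_years = admin_censoring_years,
              random_censoring_rate = random_censoring_rate,
              grade_cutpoints = grade_cutpoints,
              size_cutpoints = size_cutpoints,
              node_positive_prob = node_positive_prob, seed = seed)
  fr <- c(cfg$er_positive_fraction, unlist(subtype_probs))
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]")
  for (st in names(beta_schedule)) {
    sch <- beta_schedule[[st]]
    br <- sch$breaks
    if (br[1L] != 0 || !is.infinite(br[length(br)]) || is.unsorted(br))
      stop("beta schedule breaks must ascend from 0 to Inf")
    if (length(sch$beta) != length(br) - 1L)
      stop("need one beta per schedule interval")
    if (!sch$driver %in% c("proliferation", "hypoxia"))
      stop("schedule driver must be 'proliferation' or 'hypoxia'")
  }
  if (cfg$random_censoring_rate < 0) stop("censoring rate must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Piecewise-exponential survival times by inversion
#'
#' Hazard for subject i on schedule interval j is
#' `baseline * exp(beta[j] * z[i])`; times are drawn exactly by inverting
#' the piecewise-linear cumulative hazard at a unit-exponential deviate
#' (uses the current RNG state).
#'
#' @param z covariate vector (log-hazard scale, typically standardized).
#' @param baseline baseline hazard rate per year.
#' @param breaks ascending interval breaks from 0 to Inf.
#' @param betas log-HR per interval (`length(breaks) - 1`).
#' @return event times (no censoring applied).
#' @export
simulatePiecewiseExponential <- function(z, baseline, breaks, betas) {
  n <- length(z)
  e <- rexp(n)
  times <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    remaining <- e[i]
    for (j in seq_along(betas)) {
      lam <- baseline * exp(betas[j] * z[i])
      width <- breaks[j + 1L] - breaks[j]
      h <- lam * width
      if (!is.finite(h) || remaining < h || lam <= 0 && is.infinite(width)) {
        times[i] <- if (lam > 0) breaks[j] + remaining / lam else Inf
        break
      }
      remaining <- remaining - h
    }
    if (is.na(times[i])) times[i] <- Inf
  }
  times
}

#' Expected number of observed events under a simulation configuration
#'
#' Closed-form per-interval integration of the piecewise-exponential
#' failure density against the censoring survival (random exponential
#' censoring plus administrative cutoff), averaged over the standard-normal
#' driver by numerical quadrature. Used to sanity-check simulated cohorts.
#'
#' @param config a `"sim_config"` from [simulationConfig()].
#' @return expected count of observed (uncensored) events.
#' @export
expectedEventCount <- function(config) {
  cens <- config$random_censoring_rate
  Ta <- config$admin_censoring_years
  total <- 0
  n_pos <- round(config$n_samples * config$er_positive_fraction)
  n_by <- c(positive = n_pos, negative = config$n_samples - n_pos)
  for (st in names(config$beta_schedule)) {
    sch <- config$beta_schedule[[st]]
    lam0 <- config$baseline_hazard[[st]]
    p_event_given_z <- function(z) {
      vapply(z, function(zz) {
        surv <- 1  # P(T >= a, C >= a) at interval start
        p <- 0
        for (j in seq_along(sch$beta)) {
          a <- sch$breaks[j]; b <- min(sch$breaks[j + 1L], Ta)
          if (a >= Ta) break
          h <- lam0 * exp(sch$beta[j] * zz)
          tot <- h + cens
          width <- b - a
          seg <- if (tot > 0)
            surv * (h / tot) * (1 - exp(-tot * width)) else 0
          p <- p + seg
          surv <- surv * exp(-tot * width)
        }
        p
      }, numeric(1L))
    }
    pr <- integrate(function(z) p_event_given_z(z) * stats::dnorm(z),
                    -8, 8, subdivisions = 400L)$value
    total <- total + n_by[[st]] * pr
  }
  total
}

# deterministic synthetic signature set built from the config's latent
# structure; gene effects are drawn from the expression sub-stream before
# sample-level noise, so definitions are reproducible given the seed
.build_synthetic_signatures <- function(cfg) {
  gn <- function(sig, k) sprintf("%s_G%03d", sig, seq_len(k))
  sigs <- list()

  centroid_subtype_def <- function(name, n_genes, class_sd = 1,
                                   block_frac = 0.5) {
    genes <- gn(name, n_genes)
    block <- seq_len(round(n_genes * block_frac))
    C <- matrix(rnorm(n_genes * 5, sd = class_sd), n_genes, 5,
                dimnames = list(genes, .SUBTYPES))
    C[block, ] <- C[block, ] + rep(.PROLIF_LEVEL, each = length(block))
    ror <- 0.1 * .PROLIF_LEVEL
    SignatureDefinition(
      name = name, archetype = "centroid_subtype",
      genes = data.frame(gene_id = genes),
      centroids = C, ror_coefficients = ror,
      calibration = list(labels = c("low", "intermediate", "high"),
                         proportions = c(1, 1, 1) / 3),
      block = block)
  }
  sigs$intrinsicLike <- centroid_subtype_def("intrinsicLike", 40L)
  sigs$pam50Like <- centroid_subtype_def("pam50Like", 50L)

  centroid_risk_def <- function(name, n_genes) {
    genes <- gn(name, n_genes)
    good <- rnorm(n_genes)
    C <- cbind(good = good, poor = -good)
    rownames(C) <- genes
    SignatureDefinition(
      name = name, archetype = "centroid_risk",
      genes = data.frame(gene_id = genes), centroids = C,
      reference_class = "good", risk_direction = -1,
      calibration = list(labels = c("low", "high"),
                         proportions = c(0.5, 0.5)),
      profile = good)
  }
  sigs$g70Like <- centroid_risk_def("g70Like", 30L)
  sigs$wrLike <- centroid_risk_def("wrLike", 36L)

  # ER-stratified weighted sum: separate gene lists per ER stratum
  g76 <- rbind(
    data.frame(gene_id = gn("g76Like", 76L)[1:60],
               weight = rep(1 / 60, 60), stratum = "positive"),
    data.frame(gene_id = gn("g76Like", 76L)[61:76],
               weight = rep(1 / 16, 16), stratum = "negative"))
  sigs$g76Like <- SignatureDefinition(
    name = "g76Like", archetype = "weighted_sum", genes = g76,
    calibration = list(labels = c("good", "poor"),
                       by_stratum = list(positive = c(0.30, 0.70),
                                         negative = c(0.22, 0.78))))

  hyp_genes <- gn("hypoxiaLike", 30L)
  sigs$hypoxiaLike <- SignatureDefinition(
    name = "hypoxiaLike", archetype = "weighted_sum",
    genes = data.frame(gene_id = hyp_genes, weight = rep(1 / 30, 30)),
    calibration = list(labels = c("low", "high"),
                       proportions = c(0.5, 0.5)))

  ggi_genes <- gn("ggiLike", 40L)
  sigs$ggiLike <- SignatureDefinition(
    name = "ggiLike", archetype = "difference_of_means",
    genes = data.frame(gene_id = ggi_genes,
                       group = rep(c("up", "down"), each = 20L)),
    calibration = list(labels = c("low", "high"),
                       proportions = c(1 / 3, 2 / 3)))

  grouped_def <- function(name, groups, ref_n, weights, clip) {
    member <- unlist(mapply(function(g, k) rep(g, k), names(groups),
                            groups, SIMPLIFY = FALSE))
    ids <- gn(name, length(member) + ref_n)
    genes <- data.frame(
      gene_id = ids,
      group = c(member, rep("reference", ref_n)),
      reference = c(rep(FALSE, length(member)), rep(TRUE, ref_n)))
    SignatureDefinition(
      name = name, archetype = "grouped_threshold", genes = genes,
      group_weights = weights, clip = clip, intercept = 0,
      calibration = list(labels = c("low", "intermediate", "high"),
                         proportions = c(0.51, 0.22, 0.27)))
  }
  sigs$rsLike <- grouped_def(
    "rsLike", c(proliferation = 8L, invasion = 8L), ref_n = 5L,
    weights = c(proliferation = 1, invasion = 0.5),
    clip = list(proliferation = c(-4, 4), invasion = c(-4, 4)))
  sigs$epLike <- grouped_def(
    "epLike", c(proliferation = 5L, hormone = 3L), ref_n = 3L,
    weights = c(proliferation = 1, hormone = 0.75),
    clip = list(proliferation = c(-4, 4), hormone = c(-4, 4)))
  sigs
}

#' Simulate a synthetic breast-cancer cohort with ground truth
#'
#' Generates (1) a log2 expression matrix whose signature gene blocks are
#' driven by subtype centroids, a shared latent proliferation factor and a
#' signature-specific factor plus Gaussian noise (with filler genes and
#' bimodal ESR1/ERBB2 marker genes); (2) clinical follow-up where
#' distant-metastasis times follow a piecewise-exponential hazard whose
#' log-hazard adds the stratum's `beta(t)` times the standardized latent
#' driver, censored by the minimum of administrative and random censoring;
#' (3) the nine synthetic signature definitions; and (4) the full ground
#' truth (ER stratum, subtype, latent factors, schedules). Deterministic
#' given `config$seed`; each component draws from its own sub-stream.
#'
#' @param config a `"sim_config"` from [simulationConfig()].
#' @return list with `expression`, `clinical`, `signatures`, `truth`,
#'   `cohort` (a [SignatureCohort-class]).
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n <- cfg$n_samples
  ids <- sprintf("S%04d", seq_len(n))

  ## --- sample-level latent structure (sub-stream 1)
  set.seed(cfg$seed + 1L)
  n_pos <- round(n * cfg$er_positive_fraction)
  er <- c(rep("positive", n_pos), rep("negative", n - n_pos))
  subtype <- character(n)
  for (st in c("positive", "negative")) {
    idx <- which(er == st)
    subtype[idx] <- sample(.SUBTYPES, length(idx), replace = TRUE,
                           prob = cfg$subtype_probs[[st]])
  }
  a <- cfg$prolif_alignment
  prolif <- a * .PROLIF_LEVEL[subtype] + sqrt(1 - a^2) * rnorm(n)
  prolif <- as.numeric(scale(prolif))
  hypoxia <- rnorm(n)

  ## --- expression (sub-stream 2): signature gene blocks + markers + filler
  set.seed(cfg$seed + 2L)
  sigs <- .build_synthetic_signatures(cfg)
  spec_sd <- cfg$specific_sd
  noise_sd <- cfg$gene_noise_sd
  latent <- list()
  for (nm in names(sigs)) {
    l <- cfg$loadings[[nm]]
    shared <- if (nm == "hypoxiaLike") hypoxia else prolif
    latent[[nm]] <- l * shared + spec_sd * rnorm(n)
  }
  blocks <- list()
  for (nm in names(sigs)) {
    sig <- sigs[[nm]]
    Tn <- latent[[nm]]
    gene_ids <- unique(c(sig@genes$gene_id,
                         if (ncol(sig@centroids)) rownames(sig@centroids)))
    k <- length(gene_ids)
    noise <- matrix(rnorm(k * n, sd = noise_sd), k, n)
    x <- switch(sig@archetype,
      centroid_subtype = {
        C <- sig@centroids
        base <- C[, subtype, drop = FALSE]
        block <- sig@params$block
        base[block, ] <- base[block, ] + rep(0.5 * Tn, each = length(block))
        base + noise
      },
      centroid_risk = {
        profile <- sig@params$profile
        outer(profile, 1 - 0.8 * Tn) + noise
      },
      weighted_sum = {
        sweep(noise, 2L, Tn, "+")
      },
      difference_of_means = {
        sgn <- ifelse(sig@genes$group == "up", 1, -1)
        outer(sgn, Tn) + noise
      },
      grouped_threshold = {
        ref <- isTRUE_vec(sig@genes$reference)
        m <- matrix(10, k, n) + noise
        m[!ref, ] <- m[!ref, ] + rep(Tn, each = sum(!ref))
        m[ref, ] <- matrix(10, sum(ref), n) +
          matrix(rnorm(sum(ref) * n, sd = 0.1), sum(ref), n)
        m
      })
    rownames(x) <- gene_ids
    blocks[[nm]] <- x
  }
  esr1 <- ifelse(er == "positive", 2, -2) + rnorm(n, sd = 0.8)
  her2_true <- subtype == "her2e" | runif(n) < 0.08
  erbb2 <- ifelse(her2_true, 1.5, -1) + rnorm(n, sd = 0.7)
  filler <- matrix(rnorm(cfg$n_filler_genes * n), cfg$n_filler_genes, n,
                   dimnames = list(sprintf("FILLER_%04d",
                                           seq_len(cfg$n_filler_genes)),
                                   NULL))
  expr <- rbind(do.call(rbind, blocks),
                ESR1 = esr1, ERBB2 = erbb2, filler)
  colnames(expr) <- ids

  ## --- survival (sub-stream 3)
  set.seed(cfg$seed + 3L)
  true_time <- rep(NA_real_, n)
  driver <- rep(NA_real_, n)
  for (st in c("positive", "negative")) {
    idx <- which(er == st)
    sch <- cfg$beta_schedule[[st]]
    raw <- if (sch$driver == "proliferation") prolif[idx] else hypoxia[idx]
    z <- as.numeric(scale(raw))
    driver[idx] <- z
    true_time[idx] <- simulatePiecewiseExponential(
      z, cfg$baseline_hazard[[st]], sch$breaks, sch$beta)
  }

  ## --- censoring (sub-stream 4)
  set.seed(cfg$seed + 4L)
  cens <- rep(cfg$admin_censoring_years, n)
  if (cfg$random_censoring_rate > 0)
    cens <- pmin(cens, rexp(n, cfg$random_censoring_rate))
  time_obs <- pmin(true_time, cens)
  event <- as.numeric(true_time <= cens)

  ## --- clinical covariates from the proliferation factor (sub-stream 5)
  set.seed(cfg$seed + 5L)
  gq <- quantile(prolif, cfg$grade_cutpoints, type = 1)
  grade <- as.character(1L + findInterval(prolif, gq, left.open = TRUE))
  sq <- quantile(prolif, cfg$size_cutpoints, type = 1)
  size <- c("pT1", "pT2", "pT3-4")[1L + findInterval(prolif, sq,
                                                     left.open = TRUE)]
  node <- ifelse(runif(n) < cfg$node_positive_prob, "positive", "negative")
  cohort_lab <- sprintf("cohort%s", c("A", "B", "C")[
    1L + (seq_len(n) - 1L) %% 3L])
  treated <- ifelse(runif(n) < 0.55, "yes", "no")

  clinical <- data.frame(
    sample_id = ids, time_years = time_obs, event = event,
    er_status = er,
    her2_status = ifelse(her2_true, "positive", "negative"),
    size_cat = size, node = node, grade = grade, cohort = cohort_lab,
    systemic_treatment = treated, stringsAsFactors = FALSE)

  exp_events <- expectedEventCount(cfg)
  if (exp_events < 1)
    warning(sprintf("configuration expects ~%.2f events", exp_events))

  truth <- list(
    per_sample = data.frame(
      sample_id = ids, er_stratum = er, subtype = subtype,
      proliferation = prolif, hypoxia = hypoxia, driver = driver,
      true_event_time = true_time, stringsAsFactors = FALSE),
    beta_schedule = cfg$beta_schedule,
    latent_scores = as.data.frame(latent))

  list(expression = expr, clinical = clinical, signatures = sigs,
       truth = truth, cohort = SignatureCohort(expr, clinical))
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' @param config a `"sim_config"`.
#' @param dir output directory (created if needed): `expression.tsv`,
#'   `clinical.tsv`, `signatures/*.json`, `ground_truth.tsv` (never read
#'   by the analysis path).
#' @return the simulation list, invisibly.
#' @export
simulateCohortFiles <- function(config, dir) {
  sim <- simulateCohort(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "signatures"), showWarnings = FALSE)
  writeExpression(sim$expression, file.path(dir, "expression.tsv"))
  writeClinical(sim$clinical, file.path(dir, "clinical.tsv"))
  for (nm in names(sim$signatures))
    writeSignature(sim$signatures[[nm]],
                   file.path(dir, "signatures", paste0(nm, ".json")))
  write.table(sim$truth$per_sample, file.path(dir, "ground_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sim)
}
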