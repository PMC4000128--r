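# the five scoring archetypes and their dispatch

test_that("centroid correlations match direct correlation on a toy case", {
  genes <- c("g1", "g2", "g3", "g4")
  sig <- make_centroid_sig(genes, classes = c("k1", "k2"),
                           archetype = "centroid_risk")
  C <- sig@centroids
  # one sample equal to centroid k1, one equal to its negation (centered)
  neg <- -(C[, "k1"] - mean(C[, "k1"])) + mean(C[, "k1"])
  x <- make_expr(genes, c("same", "anti", "rand"),
                 cbind(C[, "k1"], neg, c(0.3, -1, 2, 0.5)))
  cc <- centroidCorrelations(x, sig, method = "pearson")
  expect_equal(cc["same", "k1"], 1.0)
  expect_equal(cc["anti", "k1"], -1.0)
  # independent oracle: plain cor() per pair
  for (s in colnames(x)) for (k in colnames(C))
    expect_equal(cc[s, k], cor(x[, s], C[, k]), tolerance = 1e-12)
})

test_that("pairs sharing fewer than 3 observed genes give NA", {
  genes <- sprintf("g%d", 1:4)
  sig <- make_centroid_sig(genes)
  x <- make_expr(genes, c("s1", "s2"))
  x[1:2, "s2"] <- NA
  cc <- centroidCorrelations(x, sig)
  expect_false(anyNA(cc["s1", ]))
  expect_true(all(is.na(cc["s2", ])))
})

test_that("nearest-centroid calls: argmax, tie rule, unknown propagation", {
  cm <- rbind(a = c(0.9, 0.1, 0.0, -0.2, -0.5),
              b = c(0.4, 0.7, 0.7, 0.1, 0.0),
              c = rep(NA_real_, 5))
  colnames(cm) <- paste0("k", 1:5)
  calls <- classifyNearestCentroid(cm)
  expect_equal(unname(calls["a"]), "k1")
  expect_equal(unname(calls["b"]), "k2")  # tie goes to first declared class
  expect_equal(unname(calls["c"]), "unknown")
  expect_true(attr(calls, "ambiguous")[2])
  expect_false(attr(calls, "ambiguous")[1])
})

test_that("ROR linear combination equals the hand dot product", {
  cm <- matrix(c(0.8, -0.1, 0.3, 0.05, -0.6), 1,
               dimnames = list("s1", paste0("k", 1:5)))
  coefs <- c(0.05, 0.1, -0.2, 0.1, -0.05)
  hand <- 0.05 * 0.8 + 0.1 * -0.1 + -0.2 * 0.3 + 0.1 * 0.05 + -0.05 * -0.6
  expect_equal(unname(rorLinear(cm, coefs)), hand)
  expect_equal(unname(rorLinear(cm, c(1, 0, 0, 0, 0))), 0.8)
  expect_equal(unname(rorLinear(cm, rep(0, 5))), 0)
  expect_error(rorLinear(cm, c(1, 2)), "one ROR coefficient per class")
})

test_that("centroid risk score is the oriented reference correlation", {
  genes <- sprintf("g%d", 1:6)
  sig <- make_centroid_sig(genes)  # reference "good", direction -1
  x <- make_expr(genes, sprintf("s%d", 1:5), seed = 8)
  cc <- centroidCorrelations(x, sig)
  expect_equal(centroidRisk(x, sig), -cc[, "good"])
  # sample identical to the good-prognosis centroid gets the minimum -1
  x2 <- make_expr(genes, "best", matrix(sig@centroids[, "good"]))
  expect_equal(unname(centroidRisk(x2, sig)), -1)
})

test_that("weighted sum matches hand arithmetic and renormalizes", {
  genes <- sprintf("g%d", 1:5)
  w <- c(0.2, -0.5, 1.0, 0.3, -0.1)
  sig <- make_weighted_sig(genes, w)
  vals <- matrix(c(1, 2, -1, 0.5, 4), 5, 1)
  x <- make_expr(genes, "s1", vals)
  expect_equal(unname(weightedSum(x, sig)), sum(w * vals))
  # single gene, weight 1
  x1 <- make_expr("g1", "s1", matrix(3.14))
  expect_equal(unname(weightedSum(x1, make_weighted_sig("g1", 1))), 3.14)
  # all weights zero
  expect_equal(unname(weightedSum(x, make_weighted_sig(genes, rep(0, 5)))), 0)
  # a missing gene: remaining weights scaled up to preserve total mass
  xm <- x; xm["g3", 1] <- NA
  obs <- c(1, 2, 4, 5)
  expect_equal(unname(weightedSum(xm, sig)),
               sum(w[obs] * vals[obs]) * sum(abs(w)) / sum(abs(w[obs])))
})

test_that("stratified weighted sum uses each sample's stratum gene set", {
  g <- data.frame(gene_id = c("a1", "a2", "b1"),
                  weight = c(0.5, 0.5, 1),
                  stratum = c("positive", "positive", "negative"))
  sig <- SignatureDefinition("strat", "weighted_sum", g)
  x <- make_expr(c("a1", "a2", "b1"), c("s1", "s2", "s3"),
                 matrix(c(2, 4, 9, 1, 3, 7, 0, 0, 5), 3))
  s <- weightedSum(x, sig, stratum_labels = c("positive", "negative", NA))
  expect_equal(unname(s), c(0.5 * 2 + 0.5 * 4, 7, NA))
  expect_error(weightedSum(x, sig), "stratum labels required")
})

test_that("difference of means: raw oracle and cohort rescaling", {
  set.seed(31)
  genes <- sprintf("g%d", 1:12)
  sig <- SignatureDefinition("ggi", "difference_of_means",
    data.frame(gene_id = genes, group = rep(c("up", "down"), each = 6)))
  x <- make_expr(genes, sprintf("s%d", 1:7), seed = 31)
  raw <- differenceOfMeans(x, sig, rescale = FALSE)
  brute <- apply(x, 2, function(v) mean(v[1:6]) - mean(v[7:12]))
  expect_equal(raw, brute, tolerance = 1e-12)
  scaled <- differenceOfMeans(x, sig)
  expect_equal(range(as.numeric(scaled)), c(-1, 1))
  # rescaling is a monotone linear map of raw
  expect_equal(cor(as.numeric(scaled), raw), 1)
  # constant vectors: up +1, down -1 gives raw difference 2
  x2 <- make_expr(genes, "s1", matrix(rep(c(1, -1), each = 6)))
  expect_equal(unname(differenceOfMeans(x2, sig, rescale = FALSE)), 2)
})

test_that("grouped threshold follows the declared evaluation steps", {
  # printed 6-gene toy: two groups plus reference genes, clipping on one
  genes <- c("p1", "p2", "q1", "q2", "r1", "r2")
  gdf <- data.frame(gene_id = genes,
                    group = c("prolif", "prolif", "inv", "inv",
                              "reference", "reference"),
                    reference = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  sig <- SignatureDefinition("rs", "grouped_threshold", gdf,
    group_weights = c(prolif = 2, inv = 0.5),
    clip = list(prolif = c(-1, 1)), intercept = 3)
  x <- make_expr(genes, "s1", matrix(c(14, 12, 10.5, 9.5, 10, 10)))
  # by hand: ref mean 10; prolif group (4+2)/2 = 3 clipped to 1;
  # inv group (0.5 - 0.5)/2 = 0; score = 3 + 2*1 + 0.5*0 = 5
  expect_equal(unname(groupedThreshold(x, sig)), 5)
  # all genes at the reference mean: score = intercept
  x0 <- make_expr(genes, "s1", matrix(rep(10, 6)))
  expect_equal(unname(groupedThreshold(x0, sig)), 3)
  # unmapped group is a named error
  xsub <- make_expr(c("p1", "p2", "r1", "r2"), "s1",
                    matrix(c(1, 2, 0, 0)))
  expect_error(suppressWarnings(groupedThreshold(xsub, sig)), "inv")
})

test_that("grouped threshold without clipping/reference reduces to a
           weighted sum reparameterization", {
  set.seed(77)
  genes <- sprintf("g%d", 1:9)
  gdf <- data.frame(gene_id = genes,
                    group = rep(c("a", "b", "c"), each = 3))
  wts <- c(a = 1.5, b = -0.75, c = 0.25)
  sig <- SignatureDefinition("gt", "grouped_threshold", gdf,
                             group_weights = wts, intercept = 0)
  wsig <- make_weighted_sig(genes, rep(wts / 3, each = 3))
  x <- make_expr(genes, sprintf("s%d", 1:20), seed = 77)
  expect_equal(groupedThreshold(x, sig), weightedSum(x, wsig),
               tolerance = 1e-12)
})

test_that("correlation scorers are invariant to per-sample affine maps", {
  genes <- sprintf("g%d", 1:10)
  sig <- make_centroid_sig(genes, classes = c("a", "b", "c"),
                           archetype = "centroid_subtype",
                           ror = c(a = 0.1, b = -0.3, c = 0.2))
  x <- make_expr(genes, sprintf("s%d", 1:15), seed = 4)
  a <- runif(15, 0.5, 3); b <- rnorm(15)
  xt <- sweep(sweep(x, 2, a, "*"), 2, b, "+")
  for (m in c("pearson", "spearman")) {
    expect_equal(centroidCorrelations(xt, sig, method = m),
                 centroidCorrelations(x, sig, method = m),
                 tolerance = 1e-10)
  }
})

test_that("noise-free centroid copies classify perfectly and degrade
           with noise on average", {
  genes <- sprintf("g%d", 1:20)
  sig <- make_centroid_sig(genes, classes = paste0("k", 1:5),
                           archetype = "centroid_subtype",
                           ror = setNames(rep(0.1, 5), paste0("k", 1:5)))
  set.seed(55)
  truth <- sample(paste0("k", 1:5), 60, replace = TRUE)
  clean <- sig@centroids[, truth]
  colnames(clean) <- sprintf("s%d", 1:60)
  calls <- classifyNearestCentroid(
    centroidCorrelations(clean, sig, method = "spearman"))
  expect_identical(as.character(calls), truth)
  acc <- vapply(c(0.5, 4), function(sd_noise) {
    accs <- vapply(1:10, function(r) {
      noisy <- clean + matrix(rnorm(length(clean), sd = sd_noise),
                              nrow(clean))
      mean(classifyNearestCentroid(
        centroidCorrelations(noisy, sig, method = "spearman")) == truth)
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  expect_gt(acc[1], acc[2])
})

test_that("scoreAll dispatch equals direct scorer calls and respects
           orientation", {
  sim <- simulateCohort(simulationConfig(n_samples = 120, seed = 21))
  st <- suppressWarnings(scoreAll(sim$cohort, sim$signatures))
  sc <- riskScores(st)
  expect_true(all(scoreStatus(st) == "ok"))
  expect_false(anyNA(sc))
  expect_equal(ncol(sc), 9L)
  # dispatch equality for two archetypes
  expr <- sim$expression
  expect_equal(sc[, "g70Like"],
               centroidRisk(expr, sim$signatures$g70Like))
  expect_equal(unname(sc[, "hypoxiaLike"]),
               unname(weightedSum(expr, sim$signatures$hypoxiaLike)))
  # negating risk_direction negates the oriented column
  flipped <- sim$signatures$hypoxiaLike
  flipped@riskDirection <- -1
  st2 <- suppressWarnings(
    scoreAll(sim$cohort, list(hypoxiaLike = flipped)))
  expect_equal(riskScores(st2)[, 1], -sc[, "hypoxiaLike"])
  # subtype calls and correlations attached for centroid_subtype
  expect_true("pam50Like" %in% names(subtypeCalls(st)))
  expect_true("pam50Like" %in% names(centroidCorrelationMatrices(st)))
})

test_that("a failing signature yields status, not an aborted table", {
  sim <- simulateCohort(simulationConfig(n_samples = 60, seed = 22))
  bogus <- make_weighted_sig(sprintf("nonexistent%d", 1:10), rep(1, 10),
                             name = "bogus")
  st <- suppressWarnings(scoreAll(
    sim$cohort, list(bogus = bogus, ok = sim$signatures$hypoxiaLike)))
  expect_match(scoreStatus(st)["bogus"], "coverage")
  expect_equal(unname(scoreStatus(st)["ok"]), "ok")
  expect_true(all(is.na(riskScores(st)[, "bogus"])))
  expect_false(anyNA(riskScores(st)[, "ok"]))
})
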