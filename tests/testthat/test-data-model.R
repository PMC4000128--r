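# readers, validation, duplicate-probe collapse, signature mapping, and
# receptor-status imputation

test_that("expression round-trip preserves values, ids and order", {
  x <- make_expr(c("g1", "g2", "g3"), c("s1", "s2"),
                 matrix(c(1.5, -2.25, 0, 3.125, NA, 7), 3, 2))
  f <- tempfile(fileext = ".tsv")
  writeExpression(x, f)
  y <- readExpression(f)
  expect_identical(dim(y), c(3L, 2L))
  expect_identical(rownames(y), rownames(x))
  expect_identical(colnames(y), colnames(x))
  expect_equal(y, x)
})

test_that("duplicate gene rows collapse by max variance or mean", {
  x <- rbind(c(1, 2, 3), c(10, 20, 30), c(5, 5, 5))
  rownames(x) <- c("gA", "gA", "gB")
  colnames(x) <- c("s1", "s2", "s3")
  f <- tempfile(fileext = ".tsv")
  writeExpression(x, f)
  # rule applied by hand: row 2 has the larger variance
  mv <- readExpression(f, collapse = "max_variance")
  expect_equal(mv["gA", ], c(s1 = 10, s2 = 20, s3 = 30))
  mn <- readExpression(f, collapse = "mean")
  expect_equal(mn["gA", ], c(s1 = 5.5, s2 = 11, s3 = 16.5))
  expect_identical(rownames(mv), c("gA", "gB"))
})

test_that("malformed expression input is rejected with context", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts1", "g1\t1\t2"), f)
  expect_error(readExpression(f), "duplicate sample ids")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\tzap"), f)
  expect_error(readExpression(f), "zap.*g1.*s2")
})

test_that("clinical reader validates and preserves unknowns", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(paste("sample_id", "time_years", "event", "er_status",
                     "grade", sep = "\t"),
               "s1\t4.2\t1\tpositive\t2",
               "s2\t0.5\t0\tunknown\t"), f)
  cl <- readClinical(f)
  expect_equal(cl$time_years, c(4.2, 0.5))
  expect_equal(cl$grade, c("2", "unknown"))
  expect_equal(cl$er_status, c("positive", "unknown"))
  writeLines(c("sample_id\ttime_years\tevent", "s1\t-1\t1"), f)
  expect_error(readClinical(f), "negative")
  writeLines(c("sample_id\ttime_years\tevent", "s1\t1\t2"), f)
  expect_error(readClinical(f), "event")
})

test_that("SignatureCohort enforces its invariants", {
  x <- make_expr(c("g1", "g2"), c("s1", "s2"))
  cl <- data.frame(sample_id = c("s1", "s2"), time_years = c(1, 2),
                   event = c(0, 1))
  sc <- SignatureCohort(x, cl)
  expect_s4_class(sc, "SignatureCohort")
  expect_equal(exprs(sc), x)
  expect_equal(clinicalData(sc)$time_years, c(1, 2))
  bad <- cl; bad$time_years[1] <- -2
  expect_error(SignatureCohort(x, bad), "time_years")
  bad <- cl; bad$event[2] <- 3
  expect_error(SignatureCohort(x, bad), "event")
})

test_that("signature JSON round-trip preserves every component", {
  genes <- sprintf("g%02d", 1:8)
  sig <- make_centroid_sig(genes, classes = c("a", "b", "c"),
                           archetype = "centroid_subtype",
                           ror = c(a = 0.05, b = -0.2, c = 0.1))
  sig@calibration <- list(labels = c("low", "high"),
                          proportions = c(0.4, 0.6))
  f <- tempfile(fileext = ".json")
  writeSignature(sig, f)
  s2 <- readSignature(f)
  expect_equal(s2@centroids, sig@centroids)
  expect_equal(s2@params$ror_coefficients, sig@params$ror_coefficients)
  expect_equal(s2@calibration$proportions, sig@calibration$proportions)
  expect_equal(s2@genes$gene_id, sig@genes$gene_id)
})

test_that("map coverage equals the exact set-intersection ratio", {
  x <- make_expr(sprintf("g%d", 1:10), c("s1", "s2"))
  sig <- make_weighted_sig(sprintf("g%d", 1:10), rep(1, 10))
  expect_equal(mapSignature(sig, x)$coverage_fraction, 1.0)
  # the 46-of-70 situation: coverage 0.657, accepted with a warning
  sig70 <- make_weighted_sig(sprintf("h%d", 1:70), rep(1, 70))
  x70 <- make_expr(sprintf("h%d", 1:46), c("s1", "s2"))
  expect_warning(mp <- mapSignature(sig70, x70), "coverage")
  expect_equal(mp$coverage_fraction, 46 / 70, tolerance = 1e-12)
  expect_equal(round(mp$coverage_fraction, 3), 0.657)
  # nothing matched: hard error listing unmatched genes
  xnone <- make_expr(c("zz1", "zz2"), c("s1", "s2"))
  expect_error(mapSignature(sig, xnone), "coverage.*below")

  # property: random gene universes
  set.seed(42)
  for (rep in 1:20) {
    univ <- sample(sprintf("u%03d", 1:300), 120)
    picked <- sample(sprintf("u%03d", 1:300), 40)
    xx <- make_expr(univ, "s1")
    sg <- make_weighted_sig(picked, rep(1, 40))
    expected <- length(intersect(picked, univ)) / 40
    if (expected < 0.5) {
      expect_error(mapSignature(sg, xx))
    } else {
      mp <- suppressWarnings(mapSignature(sg, xx))
      expect_equal(mp$coverage_fraction, expected)
      expect_equal(sort(mp$unmatched), sort(setdiff(picked, univ)))
    }
  }
})

test_that("receptor imputation recovers a clear bimodal mixture", {
  set.seed(9)
  truth <- rep(c("negative", "positive"), each = 250)
  x <- c(rnorm(250, -2, 0.5), rnorm(250, 2, 0.5))
  res <- imputeReceptorStatus(x, seed = 3)
  expect_false(res$fallback)
  expect_gte(mean(res$status == truth), 0.95)
  # invariance to positive affine transforms of the marker
  res2 <- imputeReceptorStatus(3.7 * x + 11, seed = 3)
  expect_identical(res$status, res2$status)
})

test_that("receptor imputation: separable small case and degenerate fall" ,{
  set.seed(2)
  x <- c(rnorm(10, -4, 0.2), rnorm(10, 4, 0.2))
  res <- imputeReceptorStatus(x, seed = 1)
  expect_identical(unname(res$status),
                   rep(c("negative", "positive"), each = 10))
  expect_warning(res <- imputeReceptorStatus(rep(1, 25)), "median")
  expect_true(res$fallback)
  expect_error(imputeReceptorStatus(rnorm(10)), "20 samples")
})
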