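# Kaplan-Meier, log-rank, Cox, concordance, PVE, PH diagnostics,
# interval restriction, Aalen additive regression, multivariate models

test_that("product-limit estimate matches the closed form", {
  km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # mixed censoring, hand-checkable
  tt <- c(1, 2, 2, 3, 4); ee <- c(1, 0, 1, 1, 0)
  km <- kmEstimate(tt, ee)
  expect_equal(km$surv[km$n_event > 0],
               km_oracle(tt, ee, at = c(1, 2, 3)))
  # all censored
  expect_true(all(kmEstimate(c(1, 5, 9), c(0, 0, 0))$surv == 1))
  # single subject with an event
  expect_equal(kmEstimate(3, 1)$surv, 0)
})

test_that("log-rank behaves on identical, separated and permuted groups", {
  set.seed(5)
  t1 <- rexp(200, 1); t2 <- rexp(200, 5)
  same <- logrankTest(c(t1, t1), rep(1, 400), rep(c("a", "b"), each = 200))
  expect_equal(same$statistic, 0, tolerance = 1e-9)
  expect_equal(same$p, 1, tolerance = 1e-9)
  sep <- logrankTest(c(t1, t2), rep(1, 400), rep(c("a", "b"), each = 200))
  expect_lt(sep$p, 0.001)
  g3 <- rep(c("a", "b", "c"), length.out = 400)
  s1 <- logrankTest(c(t1, t2), rep(1, 400), g3)
  s2 <- logrankTest(c(t1, t2), rep(1, 400),
                    c(c = "b", a = "c", b = "a")[g3])
  expect_equal(s1$statistic, s2$statistic)
  expect_error(logrankTest(t1, rep(0, 200), rep(c("a", "b"), 100)),
               "without events")
})

test_that("Cox fit recovers a known log-hazard ratio", {
  d <- sim_exp_surv(2000, beta = log(2), baseline = 0.3,
                    censor_rate = 0.1, seed = 42)
  expect_gt(mean(d$event), 0.6)
  cx <- coxFit(d$z, d$time, d$event)
  expect_equal(cx$coefficients$beta, log(2), tolerance = 0.1)
  expect_true(cx$coefficients$lower < 2 && 2 < cx$coefficients$upper)
})

test_that("Cox fit under the null and with duplicated subjects", {
  d <- sim_exp_surv(5000, beta = 0, baseline = 0.2, censor_rate = 0.05,
                    seed = 7)
  cx <- coxFit(d$z, d$time, d$event)
  expect_gte(cx$coefficients$hr, 0.93)
  expect_lte(cx$coefficients$hr, 1.07)
  # doubling every subject leaves the Breslow estimate unchanged
  d2 <- sim_exp_surv(300, beta = log(1.5), baseline = 0.3, seed = 8)
  b1 <- coxFit(d2$z, d2$time, d2$event, ties = "breslow")
  b2 <- coxFit(rep(d2$z, 2), rep(d2$time, 2), rep(d2$event, 2),
               ties = "breslow")
  expect_equal(b1$coefficients$beta, b2$coefficients$beta,
               tolerance = 1e-6)
  expect_error(coxFit(rep(1, 10), rexp(10), rep(1, 10)), "constant")
  expect_error(coxFit(rnorm(10), rexp(10), rep(0, 10)), "no events")
})

test_that("concordance equals brute-force enumeration and the survival
           package on censored data", {
  set.seed(12)
  n <- 60
  sc <- round(rnorm(n), 1)  # induce score ties
  tt <- round(rexp(n, 0.5), 1)  # induce time ties
  ee <- rbinom(n, 1, 0.7)
  ci <- concordanceIndex(sc, tt, ee)
  expect_equal(ci$c, cindex_oracle(sc, tt, ee))
  # independent implementation: survival::concordance (reverse for risk)
  sv <- survival::concordance(survival::Surv(tt, ee) ~ sc, reverse = TRUE)
  expect_equal(ci$c, unname(sv$concordance), tolerance = 1e-12)
  # perfect ranking / anti-ranking without censoring
  t0 <- 1:10
  expect_equal(concordanceIndex(10:1, t0, rep(1, 10))$c, 1.0)
  expect_equal(concordanceIndex(1:10, t0, rep(1, 10))$c, 0.0)
  expect_error(concordanceIndex(1:3, c(1, 1, 1), c(0, 0, 0)), "usable")
})

test_that("bootstrap concordance CI is seeded and sane", {
  set.seed(3)
  d <- sim_exp_surv(120, beta = log(2), baseline = 0.4, seed = 3)
  b1 <- concordanceIndex(d$z, d$time, d$event, ci_method = "bootstrap",
                         B = 50, seed = 10)
  b2 <- concordanceIndex(d$z, d$time, d$event, ci_method = "bootstrap",
                         B = 50, seed = 10)
  expect_identical(b1$lower, b2$lower)
  expect_true(b1$lower < b1$c && b1$c < b1$upper)
})

test_that("PVE is zero under the null fit and increases with effect", {
  d <- sim_exp_surv(1000, beta = 1, baseline = 0.3, seed = 17)
  strong <- coxFit(d$z, d$time, d$event)
  set.seed(18)
  weak <- coxFit(rnorm(1000), d$time, d$event)
  expect_gt(pve(strong), 10 * pve(weak))
  expect_lt(pve(weak), 0.01)
  expect_true(pve(strong) >= 0 && pve(strong) < 1)
})

test_that("PH test flags a decaying effect with negative rho and flips
           sign for a growing effect", {
  set.seed(91)
  z <- rnorm(600)
  # effect log(2) before t = 1, none after: hazard declines with time
  decay <- simulatePiecewiseExponential(z, 0.5, c(0, 1, Inf), c(log(2), 0))
  admin <- pmin(decay, 4)
  cx <- coxFit(z, admin, as.numeric(decay <= 4))
  ph <- phTest(cx)
  expect_lt(ph$rho, 0)
  expect_lt(ph$p, 0.05)
  # time-reversed pattern: no effect early, strong late
  grow <- simulatePiecewiseExponential(z, 0.5, c(0, 1, Inf), c(0, log(2)))
  cx2 <- coxFit(z, pmin(grow, 4), as.numeric(grow <= 4))
  ph2 <- phTest(cx2)
  expect_gt(ph2$rho, 0)
  expect_true(all(abs(c(ph$rho, ph2$rho)) <= 1))
})

test_that("interval restriction implements the exclusion and censoring
           rules", {
  # event at 7 seen from [0,5): kept, censored at 5
  r <- restrictInterval(7, 1, 0, 5)
  expect_equal(r$times, 5); expect_equal(r$events, 0)
  # event at 4 seen from [5,10): excluded
  r <- restrictInterval(4, 1, 5, 10)
  expect_false(r$included)
  # event at 3 inside [0,5): kept as-is
  r <- restrictInterval(3, 1, 0, 5)
  expect_equal(r$times, 3); expect_equal(r$events, 1)
  # censored before the interval start: excluded
  r <- restrictInterval(4.5, 0, 5, 10)
  expect_false(r$included)
  # boundary: event exactly at the upper bound belongs to the next interval
  r1 <- restrictInterval(5, 1, 0, 5)
  r2 <- restrictInterval(5, 1, 5, 10)
  expect_equal(r1$events, 0)
  expect_equal(r2$events, 1)
  expect_error(restrictInterval(1, 1, 5, 5), "lower < upper")
})

test_that("tiling intervals partition the events exactly once", {
  set.seed(33)
  tt <- rexp(500, 0.2); ee <- rbinom(500, 1, 0.6)
  ivs <- list(c(0, 2), c(2, 7), c(7, Inf))
  counted <- numeric(500)
  for (iv in ivs) {
    r <- restrictInterval(tt, ee, iv[1], iv[2])
    idx <- which(r$included)[r$events == 1]
    counted[idx] <- counted[idx] + 1
  }
  expect_equal(counted, as.numeric(ee))
})

test_that("interval effects recover a piecewise-constant hazard ratio and
           report structural columns", {
  set.seed(44)
  n <- 1500
  z <- as.numeric(scale(rnorm(n)))
  t_true <- simulatePiecewiseExponential(z, 0.06, c(0, 5, Inf), c(log(2), 0))
  cens <- pmin(rexp(n, 0.04), 12)
  clin <- data.frame(sample_id = sprintf("s%d", 1:n),
                     time_years = pmin(t_true, cens),
                     event = as.numeric(t_true <= cens),
                     er_status = "positive", stringsAsFactors = FALSE)
  tab <- intervalEffects(z, clin,
                         intervals = list(c(0, 5), c(5, 12), c(12, Inf)))
  expect_equal(nrow(tab), 3L)
  expect_true(all(diff(tab$n_risk) <= 0))
  expect_true(all(tab$n_event <= tab$n_risk))
  expect_gt(tab$hr[1], 1.5)
  expect_true(tab$lower[2] < 1.25 & tab$hr[2] < 1.4)
  # a cell without events reports a reason, not silence
  clin0 <- clin; clin0$event <- 0; clin0$event[clin0$time_years < 5] <- 1
  clin0$time_years <- pmin(clin0$time_years, 6)
  tab0 <- intervalEffects(clin0$event * 0 + z, clin0,
                          intervals = list(c(0, 5), c(5, 6), c(6, Inf)))
  expect_true(any(nzchar(tab0$note)))
})

test_that("Aalen cumulative regression: linearity in the covariate and
           agreement with the survival package", {
  set.seed(26)
  n <- 400
  z <- runif(n)
  haz <- 0.2 + 0.3 * z
  tt <- rexp(n, haz)
  ee <- as.numeric(tt <= 3); tt <- pmin(tt, 3)
  tt <- tt + seq(0, 1e-6, length.out = n)  # break ties for the comparison
  a1 <- aalenCumulative(z, tt, ee)
  # covariate rescaled by c scales the cumulative estimate by 1/c
  a2 <- aalenCumulative(2 * z, tt, ee)
  expect_equal(a2$estimate[, "covariate"],
               a1$estimate[, "covariate"] / 2, tolerance = 1e-9)
  # independent implementation: survival::aareg on the same data
  ar <- survival::aareg(survival::Surv(tt, ee) ~ z)
  ours_at <- a1$estimate[, "covariate"]
  theirs <- cumsum(ar$coefficient[, "z"])
  k <- min(length(ours_at), length(theirs))
  expect_equal(unname(ours_at[1:k]), unname(theirs[1:k]),
               tolerance = 1e-8)
  expect_error(aalenCumulative(rep(1, 50), rexp(50), rep(1, 50)),
               "constant")
})

test_that("Aalen estimator truncates on a singular design", {
  # once the risk set shrinks to one subject the design is singular
  z <- c(0, 0, 1, 1)
  a <- aalenCumulative(z, c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_false(is.na(a$truncated))
  expect_lt(length(a$time), 4)
})

test_that("multivariate models: encoding, mediation attenuation and
           independence", {
  set.seed(61)
  n <- 1200
  latent <- rnorm(n)
  score <- latent + rnorm(n, sd = 0.3)
  grade <- cut(latent, quantile(latent, c(0, 1 / 3, 2 / 3, 1)),
               labels = c("1", "2", "3"), include.lowest = TRUE)
  t_true <- rexp(n, 0.1 * exp(log(2) * latent))  # grade's driver is latent
  cens <- pmin(rexp(n, 0.05), 15)
  clin <- data.frame(
    sample_id = sprintf("s%d", 1:n),
    time_years = pmin(t_true, cens), event = as.numeric(t_true <= cens),
    size_cat = sample(c("pT1", "pT2", "pT3-4"), n, TRUE),
    node = sample(c("positive", "negative"), n, TRUE),
    grade = as.character(grade), stringsAsFactors = FALSE)
  fits <- multivariateEffects(score, clin)
  expect_named(fits, c("signature", "signature_size", "signature_grade",
                       "signature_size_node_grade"))
  hr_alone <- fits$signature$coefficients$hr[1]
  hr_grade <- subset(fits$signature_grade$coefficients,
                     term == "score")$hr
  # grade mediates part of the score effect: adjusted HR attenuates
  expect_lt(hr_grade, hr_alone)
  # independent covariates leave the score effect essentially unchanged
  hr_size <- subset(fits$signature_size$coefficients,
                    term == "score")$hr
  expect_equal(hr_size, hr_alone, tolerance = 0.05)
  # reference levels: pT1 / grade 1 / node negative never appear as terms
  terms <- fits$signature_size_node_grade$coefficients$term
  expect_false(any(grepl("pT1|grade1|negative", terms)))
  clin$size_cat[1] <- "pT9"
  expect_error(multivariateEffects(score, clin), "unknown size")
})

test_that("cohort adjustment by stratified baselines changes no more than
           the baseline", {
  d <- sim_exp_surv(800, beta = log(1.8), baseline = 0.25, seed = 66)
  cohort <- rep(c("A", "B"), 400)
  plain <- coxFit(d$z, d$time, d$event)
  strat <- coxFit(d$z, d$time, d$event, strata_labels = cohort)
  expect_equal(strat$coefficients$beta, plain$coefficients$beta,
               tolerance = 0.1)
  expect_equal(strat$n, plain$n)
})
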