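# Small in-code fixtures shared across test files.

make_expr <- function(genes, samples, values = NULL, seed = 1) {
  if (is.null(values)) {
    set.seed(seed)
    values <- matrix(rnorm(length(genes) * length(samples)),
                     length(genes), length(samples))
  }
  dimnames(values) <- list(genes, samples)
  values
}

# two-class centroid signature over `genes`; centroids fixed by seed
make_centroid_sig <- function(genes, classes = c("good", "poor"),
                              archetype = "centroid_risk", seed = 5,
                              ror = NULL) {
  set.seed(seed)
  C <- matrix(rnorm(length(genes) * length(classes)), length(genes),
              length(classes), dimnames = list(genes, classes))
  args <- list(name = "toyCentroid", archetype = archetype,
               genes = data.frame(gene_id = genes), centroids = C)
  if (archetype == "centroid_risk") {
    args$reference_class <- classes[1]
    args$risk_direction <- -1
  } else {
    args$ror_coefficients <- if (is.null(ror))
      setNames(seq_along(classes) / 10, classes) else ror
  }
  do.call(SignatureDefinition, args)
}

make_weighted_sig <- function(genes, weights, name = "toyWeighted") {
  SignatureDefinition(name = name, archetype = "weighted_sum",
                      genes = data.frame(gene_id = genes, weight = weights))
}

# exponential survival with a multiplicative covariate effect
sim_exp_surv <- function(n, beta, baseline = 0.1, censor_rate = 0.05,
                         admin = Inf, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  times <- rexp(n, baseline * exp(beta * z))
  cens <- pmin(if (censor_rate > 0) rexp(n, censor_rate) else Inf, admin)
  list(z = z, time = pmin(times, cens), event = as.numeric(times <= cens))
}

# independent brute-force Harrell C oracle: explicit double loop over pairs
cindex_oracle <- function(scores, times, events) {
  n <- length(scores)
  conc <- disc <- tied <- usable <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      first <- 0L
      if (times[i] < times[j] && events[i] == 1) first <- i
      else if (times[j] < times[i] && events[j] == 1) first <- j
      else if (times[i] == times[j] && events[i] + events[j] == 1)
        first <- if (events[i] == 1) i else j
      if (first == 0L) next
      other <- if (first == i) j else i
      usable <- usable + 1
      if (scores[first] > scores[other]) conc <- conc + 1
      else if (scores[first] < scores[other]) disc <- disc + 1
      else tied <- tied + 1
    }
  }
  if (usable == 0) return(NA_real_)
  (conc + 0.5 * tied) / usable
}

# closed-form product-limit oracle over unique event times
km_oracle <- function(times, events, at) {
  ts <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(at))
  for (k in seq_along(at)) {
    s <- 1
    for (t in ts[ts <= at[k]]) {
      d <- sum(times == t & events == 1)
      r <- sum(times >= t)
      s <- s * (1 - d / r)
    }
    out[k] <- s
  }
  out
}
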