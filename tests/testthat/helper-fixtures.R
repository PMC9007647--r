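# Shared fixtures and independent oracles. Cohorts are memoized so that
# several test files can reuse the same generated data without re-paying the
# simulation cost.

.fixtureCache <- new.env(parent = emptyenv())

cachedCohort <- function(seed, ...) {
  args <- list(...)
  key <- paste0("cohort_", seed, "_",
                paste(names(args), unlist(args), sep = "=", collapse = "_"))
  if (!exists(key, .fixtureCache))
    assign(key, generateCohort(cohortConfig(seed = seed, ...)), .fixtureCache)
  get(key, .fixtureCache)
}

cachedScores <- function(seed, ...) {
  key <- paste0("scores_", seed)
  if (!exists(key, .fixtureCache))
    assign(key, scoreSamples(cachedCohort(seed, ...)), .fixtureCache)
  get(key, .fixtureCache)
}

# Independent ssGSEA oracle: literal O(N^2) evaluation of the two partial
# ECDF sums over ranked positions (distinct expression values assumed).
oracleSsgsea <- function(x, setGenes, alpha) {
  genes <- names(x)
  ordGenes <- genes[order(x, decreasing = TRUE)]
  N <- length(x)
  rankOf <- stats::setNames(seq_len(N), ordGenes)
  v <- stats::setNames((N - rankOf + 1)^alpha, ordGenes)
  inS <- ordGenes %in% setGenes
  denomIn <- sum(v[setGenes])
  denomOut <- N - length(setGenes)
  es <- 0
  for (i in seq_len(N)) {
    pin <- sum(v[ordGenes[seq_len(i)][inS[seq_len(i)]]]) / denomIn
    pout <- sum(!inS[seq_len(i)]) / denomOut
    es <- es + pin - pout
  }
  es
}

# Brute-force Harrell's C by exhaustive pair enumeration.
oracleConcordance <- function(risk, time, event) {
  n <- length(risk)
  num <- den <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # usable if the smaller time is an event
    ti <- time[i]; tj <- time[j]; ei <- event[i]; ej <- event[j]
    if (ti == tj && ei == 1 && ej == 1) next   # tied event times unusable
    if (ti < tj && ei == 0) next
    if (tj < ti && ej == 0) next
    if (ti == tj && (ei == 0 || ej == 0)) next
    first <- if (ti < tj || (ti == tj && ei == 1)) i else j
    other <- if (first == i) j else i
    den <- den + 1
    if (risk[first] > risk[other]) num <- num + 1
    else if (risk[first] == risk[other]) num <- num + 0.5
  }
  num / den
}

# Exhaustive cutpoint oracle using survdiff as an independent log-rank
# implementation; smallest threshold wins ties.
oracleCutpoint <- function(marker, time, event, minprop = 0.1) {
  n <- length(marker)
  vals <- sort(unique(marker))
  cand <- vals[-length(vals)]
  minSize <- ceiling(minprop * n)
  best <- NULL
  for (c in cand) {
    g <- marker <= c
    if (sum(g) < minSize || sum(!g) < minSize) next
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ g)
    z <- sqrt(sd_$chisq) * sign(sd_$obs[2] - sd_$exp[2])
    if (is.null(best) || abs(z) > abs(best$z) + 1e-12)
      best <- list(threshold = c, z = z)
  }
  best
}

# Simplex grid-search deconvolution oracle for two cell types summing to <= 1.
oracleDeconv2 <- function(beta, R, step = 0.01) {
  grid <- expand.grid(f1 = seq(0, 1, step), f2 = seq(0, 1, step))
  grid <- grid[grid$f1 + grid$f2 <= 1, ]
  sse <- apply(grid, 1, function(f) sum((beta - R %*% as.numeric(f))^2))
  as.numeric(grid[which.min(sse), ])
}

# Small deterministic survival fixture used across survival tests.
survFixture <- function(n = 40, seed = 42, censor = TRUE) {
  set.seed(seed)
  tm <- rexp(n, 0.02)
  if (censor) {
    cs <- runif(n, 0, 100)
    list(time = pmin(tm, cs), event = as.integer(tm <= cs),
         marker = rnorm(n))
  } else list(time = tm, event = rep(1L, n), marker = rnorm(n))
}

adjRandIndex <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(comb2(tab))
  sumI <- sum(comb2(rowSums(tab)))
  sumJ <- sum(comb2(colSums(tab)))
  nC2 <- comb2(sum(tab))
  expected <- sumI * sumJ / nC2
  (sumIJ - expected) / ((sumI + sumJ) / 2 - expected)
}
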