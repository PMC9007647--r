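test_that("Kaplan-Meier estimate matches product-limit hand computations", {
  km1 <- kmEstimate(5, 1)
  expect_equal(km1$surv, 0)
  expect_warning(km0 <- kmEstimate(c(2, 4, 6), c(0, 0, 0)), "no events")
  expect_true(all(km0$surv == 1))
  km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # nonincreasing, drops only at event times
  fx <- survFixture(60, seed = 5)
  kmf <- kmEstimate(fx$time, fx$event)
  expect_true(all(diff(kmf$surv) <= 1e-12))
  expect_true(all(kmf$surv[kmf$nEvent == 0] ==
                  c(1, kmf$surv)[which(kmf$nEvent == 0)]))
})

test_that("log-rank test is zero on duplicated groups and matches hand tables", {
  fx <- survFixture(30, seed = 8)
  res <- logrankTest(rep(c("a", "b"), each = 30), rep(fx$time, 2),
                     rep(fx$event, 2))
  expect_equal(res$statistic, 0, tolerance = 1e-10)
  expect_true(res$p >= 0 && res$p <= 1)
  # 6-subject worked example: A events at 1,3,5; B events at 2,4,6
  time <- c(1, 3, 5, 2, 4, 6); event <- rep(1, 6)
  grp <- rep(c("A", "B"), each = 3)
  # hand-tabulated hypergeometric O-E and variance per risk set
  E <- 3 / 6 + 2 / 5 + 2 / 4 + 1 / 3 + 1 / 2 + 0
  V <- (3 / 6) * (3 / 6) * 1 + (2 / 5) * (3 / 5) + (2 / 4) * (2 / 4) +
    (1 / 3) * (2 / 3) + (1 / 2) * (1 / 2) + 0
  chi2Hand <- (3 - E)^2 / V
  res6 <- logrankTest(grp, time, event)
  expect_equal(res6$statistic, chi2Hand, tolerance = 1e-10)
  expect_equal(res6$df, 1L)
  # invariant to permutation of subject order
  ord <- c(4, 2, 6, 1, 5, 3)
  expect_equal(logrankTest(grp[ord], time[ord], event[ord])$statistic,
               res6$statistic)
  expect_error(logrankTest(rep("a", 6), time, event), ">= 2 groups")
})

test_that("optimal cutpoint equals the exhaustive-search argmax", {
  for (s in 1:10) {
    fx <- survFixture(n = 35, seed = s)
    got <- optimalCutpoint(fx$marker, fx$time, fx$event)
    want <- oracleCutpoint(fx$marker, fx$time, fx$event)
    expect_equal(got$threshold, want$threshold)
    expect_equal(abs(got$statistic), abs(want$z), tolerance = 1e-8)
  }
})

test_that("cutpoint respects minprop and separates a bimodal marker", {
  set.seed(12)
  marker <- rep(c(0, 1), each = 15)
  time <- c(rexp(15, 1), rexp(15, 0.01) + 5)
  event <- c(rep(1, 15), rep(0, 15))
  res <- optimalCutpoint(marker, time, event)
  expect_true(res$threshold >= 0 && res$threshold < 1)
  fx <- survFixture(20, seed = 3)
  res20 <- optimalCutpoint(fx$marker, fx$time, fx$event, minprop = 0.1)
  expect_gte(res20$nLow, 2)
  expect_gte(res20$nHigh, 2)
  expect_error(optimalCutpoint(rep(1, 20), fx$time, fx$event), "distinct")
})

test_that("Cox fit matches a brute-force partial-likelihood grid search", {
  time <- c(2, 5, 7, 9, 12, 15)
  event <- c(1, 1, 0, 1, 1, 1)
  z <- c(1, 0, 1, 0, 1, 0)
  fit <- coxFit(data.frame(z = z), time, event)
  # explicit partial likelihood (no ties): product over event times of
  # exp(b z_i) / sum over risk set of exp(b z_j)
  logpl <- function(b) {
    s <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      s <- s + b * z[i] - log(sum(exp(b * z[risk])))
    }
    s
  }
  grid <- seq(-4, 4, 1e-4)
  bHat <- grid[which.max(vapply(grid, logpl, numeric(1)))]
  expect_lt(abs(fit$coefficients$beta - bHat), 1e-4)
  # negating the covariate negates beta exactly
  fitNeg <- coxFit(data.frame(z = -z), time, event)
  expect_equal(fitNeg$coefficients$beta, -fit$coefficients$beta,
               tolerance = 1e-10)
  expect_true(fit$coefficients$lower95 <= fit$coefficients$HR &
              fit$coefficients$HR <= fit$coefficients$upper95)
  expect_warning(coxFit(data.frame(z = z, const = 1), time, event),
                 "constant")
})

test_that("null Cox coefficients have near-nominal CI coverage", {
  cover <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 120
    g <- rep(0:1, each = n / 2)
    tm <- rexp(n, 0.05); cs <- runif(n, 0, 60)
    fit <- coxFit(data.frame(g = g), pmin(tm, cs), as.integer(tm <= cs))
    fit$coefficients$lower95 <= 1 && 1 <= fit$coefficients$upper95
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("concordance index equals exhaustive pair enumeration", {
  # perfect concordance / all ties
  tmE <- 10:1
  expect_equal(concordanceIndex(1:10, tmE, rep(1, 10)), 1)
  expect_equal(concordanceIndex(rep(1, 10), tmE, rep(1, 10)), 0.5)
  for (s in 1:5) {
    fx <- survFixture(n = sample(8:20, 1), seed = 100 + s)
    expect_equal(concordanceIndex(fx$marker, fx$time, fx$event),
                 oracleConcordance(fx$marker, fx$time, fx$event))
  }
})

test_that("time-dependent AUC reduces to Mann-Whitney without censoring", {
  set.seed(44)
  n <- 80
  time <- rexp(n, 0.05)
  event <- rep(1L, n)
  marker <- -time + rnorm(n, 0, 5)
  t0 <- median(time)
  auc <- timeDependentAuc(marker, time, event, t0)
  cases <- marker[time <= t0]; ctrls <- marker[time > t0]
  mw <- mean(outer(cases, ctrls, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(unname(auc), mw)
  # perfect ranking
  aucP <- timeDependentAuc(-time, time, event, t0)
  expect_equal(unname(aucP), 1)
  expect_error(timeDependentAuc(marker, time, event, max(time) + 1),
               "beyond")
})

test_that("an uninformative marker gives AUC near 0.5 under censoring", {
  set.seed(45)
  aucs <- vapply(1:10, function(s) {
    n <- 400
    tm <- rexp(n, 0.05); cs <- runif(n, 0, 60)
    unname(timeDependentAuc(rnorm(n), pmin(tm, cs), as.integer(tm <= cs), 15))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("decision-curve net benefit follows its closed forms", {
  set.seed(46)
  outcome <- rbinom(200, 1, 0.3)
  prob <- runif(200)
  dc <- decisionCurve(prob, outcome, c(0.1, 0.2, 0.5))
  expect_true(all(dc$treatNone == 0))
  prev <- mean(outcome)
  expect_equal(dc$treatAll[2], prev - (1 - prev) * 0.25)
  dcPerfect <- decisionCurve(outcome, outcome, c(0.1, 0.5, 0.9))
  expect_equal(dcPerfect$netBenefit, rep(prev, 3))
  expect_error(decisionCurve(prob, outcome, 1), "strictly")
})

test_that("maximal-selection corrected p behaves like a p-value", {
  expect_equal(maxstatP(0), 1)
  b <- seq(0.5, 5, 0.5)
  p <- vapply(b, maxstatP, numeric(1))
  expect_true(all(diff(p) <= 0))
  expect_true(all(diff(p[b >= 1.5]) < 0))
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(maxstatP(4), 0.01)
})

test_that("prognostic screen handles empty input and records failures", {
  empty <- data.frame(probe = character(), gene = character())
  clin <- data.frame(OS_time = rexp(30, 0.05) + 0.1, OS_event = rbinom(30, 1, 0.7),
                     age = rnorm(30, 65), gender = sample(c("m", "f"), 30, TRUE),
                     stage = sample(c("I", "II"), 30, TRUE),
                     row.names = paste0("s", 1:30))
  ex <- matrix(rnorm(30), 1, 30, dimnames = list("g1", paste0("s", 1:30)))
  me <- matrix(runif(30), 1, 30, dimnames = list("p1", paste0("s", 1:30)))
  res <- prognosticScreen(empty, ex, me, clin)
  expect_equal(nrow(res$markers), 0L)
  # a constant marker cannot be cut: error recorded, screen not aborted
  exBad <- rbind(ex, gflat = rep(1, 30))
  pairs <- data.frame(probe = c("p1", "p1"), gene = c("g1", "gflat"))
  res2 <- prognosticScreen(pairs, exBad, me, clin)
  expect_equal(nrow(res2$markers), 3L)
  bad <- res2$markers[res2$markers$id == "gflat", ]
  expect_false(bad$significant)
  expect_match(bad$error, "distinct")
})
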