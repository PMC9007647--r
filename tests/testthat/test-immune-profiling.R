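test_that("ssGSEA matches hand-enumerated step sums on 4 genes", {
  x <- c(g1 = 9, g2 = 7, g3 = 4, g4 = 2)
  expect_equal(ssgseaScore(x, c("g1", "g2"), alpha = 0), 2.0)   # 0.5+1+0.5+0
  expect_equal(ssgseaScore(x, c("g3", "g4"), alpha = 0), -2.0)  # symmetry
  y <- c(g1 = 100, g2 = 7.5, g3 = 0.1, g4 = -3)                 # same ranks
  expect_equal(ssgseaScore(y, c("g1", "g2"), alpha = 0),
               ssgseaScore(x, c("g1", "g2"), alpha = 0))
})

test_that("ssGSEA equals the brute-force ECDF oracle on random cases", {
  set.seed(101)
  for (rep_ in 1:20) {
    N <- sample(5:40, 1)
    x <- stats::setNames(rnorm(N), paste0("g", seq_len(N)))
    S <- sample(names(x), sample(seq_len(N - 1), 1))
    for (alpha in c(0, 0.25, 1)) {
      expect_equal(ssgseaScore(x, S, alpha), oracleSsgsea(x, S, alpha),
                   tolerance = 1e-12)
    }
  }
})

test_that("ssGSEA input validation and matrix scoring agree", {
  x <- c(a = 3, b = 2, c = 1)
  expect_error(ssgseaScore(x, character(0)), "empty")
  expect_error(ssgseaScore(x, c("a", "b", "c")), "proper subset")
  expect_error(ssgseaScore(x, c("a", "zz"), missing = "fail"), "absent")
  expect_equal(ssgseaScore(x, c("a", "zz"), missing = "drop"),
               ssgseaScore(x, "a"))
  m <- cbind(s1 = c(a = 3, b = 2, c = 1, d = 0), s2 = c(4, 1, 3, 2))
  es <- ssgseaMatrix(m, list(S1 = c("a", "b"), S2 = "d"), alpha = 0.25)
  expect_equal(es["S1", "s1"], ssgseaScore(m[, 1], c("a", "b"), 0.25))
  expect_equal(es["S2", "s2"], ssgseaScore(m[, 2], "d", 0.25))
})

test_that("IMpS is the exact sum of the seven IMaS values", {
  expect_equal(computeImps(rep(1, 7)), 7)
  expect_equal(computeImps(rep(0, 7)), 0)
  expect_equal(computeImps(c(2, -1, 0.5, -0.5, 1, 1, -1)), 2.0)
  expect_error(computeImps(rep(1, 6)), "7")
  expect_error(computeImps(c(rep(1, 6), NA)), "finite")
  sc <- cachedScores(1)
  imas <- S4Vectors::metadata(sc)$imas
  expect_equal(unname(sc$IMpS), unname(rowSums(imas)))
})

test_that("IMaS applies the +1/-1 category weights to standardized scores", {
  co <- cachedCohort(1)
  panel <- cohortTruth(co)$panel
  imas <- computeImas(exprMatrix(co), panel)
  es <- ssgseaMatrix(exprMatrix(co), panelSets(panel))
  esZ <- t(apply(es, 1, function(z) (z - mean(z)) / sd(z)))
  cats <- panelCategories(panel)
  for (cat_ in c("coinhibitors", "effectors")) {
    unsigned <- colMeans(esZ[names(cats)[cats == cat_], , drop = FALSE])
    w <- defaultPanelSigns()[cat_]
    expect_equal(unname(imas[, cat_]), unname(w * unsigned))
  }
  # a zero unsigned score stays zero after weighting
  expect_equal(computeCyt(0, 0, offset = 0), 0)
})

test_that("CYT is the geometric mean of GZMA and PRF1", {
  expect_equal(computeCyt(5, 5, offset = 0), 5)
  expect_equal(computeCyt(4, 9, offset = 0), 6)
  expect_equal(computeCyt(0, 100, offset = 1), sqrt(101))
  expect_error(computeCyt(-1, 5), "non-negative")
})

test_that("average methylation is a mean over retained probes", {
  expect_equal(averageMethylation(c(0.1, 0.2, 0.9)), 0.4)
  expect_equal(averageMethylation(rep(0.5, 10)), 0.5)
  v <- runif(20)
  expect_equal(averageMethylation(v), averageMethylation(rev(v)))
  expect_equal(averageMethylation(c(0.2, NA, 0.4)), 0.3)
  expect_error(averageMethylation(c(NA_real_, NA_real_)), "missing")
  expect_error(averageMethylation(c(0.5, 1.2)), "outside")
})

test_that("clustering recovers separable blobs and canonical label order", {
  set.seed(7)
  centers <- rbind(rep(2, 7), rep(0, 7), rep(-2, 7))
  imas <- centers[rep(1:3, each = 30), ] + matrix(rnorm(90 * 7, 0, 0.2), 90)
  rownames(imas) <- paste0("s", 1:90)
  lab <- clusterImmunophenotypes(imas)
  expect_equal(adjRandIndex(rep(1:3, each = 30), lab), 1)
  means <- tapply(rowSums(imas), lab, mean)
  expect_gt(means[["C2"]], means[["C1"]])
  expect_gt(means[["C1"]], means[["C3"]])
  expect_error(clusterImmunophenotypes(imas[1:2, ]), "fewer samples")
  expect_error(clusterImmunophenotypes(matrix(1, 10, 7)), "degenerate")
})

test_that("deconvolution recovers exact and noisy mixtures on the simplex", {
  set.seed(11)
  R <- cbind(immune = runif(30, 0.05, 0.95), epithelial = runif(30, 0.05, 0.95))
  rownames(R) <- paste0("cg", 1:30)
  expect_equal(unname(deconvolveFractions(R[, 1], R)), c(1, 0),
               tolerance = 1e-6)
  mix <- 0.5 * R[, 1] + 0.5 * R[, 2]
  expect_equal(unname(deconvolveFractions(mix, R)), c(0.5, 0.5),
               tolerance = 1e-6)
  for (rep_ in 1:5) {
    fTrue <- c(runif(1, 0.1, 0.6), runif(1, 0.1, 0.35))
    noisy <- pmin(pmax(as.numeric(R %*% fTrue) + rnorm(30, 0, 0.02), 0), 1)
    names(noisy) <- rownames(R)
    f <- deconvolveFractions(noisy, R)
    grid <- oracleDeconv2(noisy, R)
    expect_lt(max(abs(f - fTrue)), 0.05)
    expect_lt(max(abs(f - grid)), 0.02)   # agrees with the grid oracle
    expect_true(all(f >= -1e-9) && sum(f) <= 1 + 1e-6)
  }
  expect_error(deconvolveFractions(R[, 1], cbind(R[, 1], R[, 1])),
               "rank-deficient")
})

test_that("score table carries coherent per-sample summaries", {
  sc <- cachedScores(1)
  co <- cachedCohort(1)
  expect_true(all(sc$averageBeta >= 0 & sc$averageBeta <= 1))
  expect_equal(unname(sc$averageBeta), unname(colMeans(betaMatrix(co))))
  expect_equal(unname(sc$CYT),
               unname(computeCyt(2^exprMatrix(co)["GZMA", ],
                                 2^exprMatrix(co)["PRF1", ])))
  expect_true(all(levels(sc$cluster) == c("C1", "C2", "C3")))
  expect_false(anyNA(sc$cluster))
})
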