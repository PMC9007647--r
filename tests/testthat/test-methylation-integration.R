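test_that("differential expression is calibrated on null data", {
  set.seed(21)
  mat <- matrix(rnorm(2000 * 40), 2000, 40,
                dimnames = list(paste0("g", 1:2000), paste0("s", 1:40)))
  de <- differentialExpression(mat, paste0("s", 1:20), paste0("s", 21:40))
  expect_lt(abs(mean(de$p < 0.05) - 0.05), 0.02)
  expect_true(all(de$adjP >= de$p))
})

test_that("swapping groups negates logFC and keeps p", {
  set.seed(22)
  mat <- matrix(rnorm(50 * 12), 50, 12,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  a <- paste0("s", 1:6); b <- paste0("s", 7:12)
  d1 <- differentialExpression(mat, a, b)
  d2 <- differentialExpression(mat, b, a)
  expect_equal(d1$logFC, -d2$logFC)
  expect_equal(d1$p, d2$p)
  expect_error(differentialExpression(mat, a, a), "overlap")
  expect_error(differentialExpression(mat, a[1:2], b), ">= 3")
})

test_that("a planted expression difference is flagged with the right logFC", {
  hit <- sapply(1:10, function(s) {
    set.seed(s)
    mat <- rbind(target = c(rnorm(20, 6, 0.5), rnorm(20, 4, 0.5)),
                 matrix(rnorm(99 * 40, 5, 0.5), 99))
    rownames(mat)[-1] <- paste0("null", 1:99)
    colnames(mat) <- paste0("s", 1:40)
    de <- differentialExpression(mat, paste0("s", 1:20), paste0("s", 21:40))
    c(de["target", "isDEG"], abs(de["target", "logFC"] - 2) < 0.35)
  })
  expect_true(all(hit))
})

test_that("differential methylation handles degenerate probes and uses adjusted p", {
  set.seed(23)
  n <- 300
  beta <- rbind(planted = c(runif(150, 0.55, 0.75), runif(150, 0.35, 0.55)),
                flat = rep(0.4, n),
                matrix(runif(50 * n, 0.2, 0.8), 50))
  rownames(beta)[-(1:2)] <- paste0("bg", 1:50)
  colnames(beta) <- paste0("s", 1:n)
  dm <- differentialMethylation(beta, paste0("s", 1:150), paste0("s", 151:300))
  expect_true(dm["planted", "isDMP"])
  expect_equal(dm["planted", "direction"], "up")
  expect_equal(dm["flat", "p"], 1)
  expect_false(dm["flat", "isDMP"])
  # BH adjusted p is monotone nondecreasing in raw-p rank order
  ord <- order(dm$p)
  expect_true(all(diff(dm$adjP[ord]) >= -1e-12))
  # the DMP rule uses adjusted p: construct a probe significant raw but not adj
  expect_true(all(dm$isDMP == (dm$adjP < 0.05 & abs(dm$deltaBeta) > 0)))
})

test_that("mDEG overlap equals a brute-force cross-join on a small fixture", {
  deg <- data.frame(feature = paste0("g", 1:5), logFC = c(2, -1, 1, 0.5, -2),
                    stat = 1, p = c(0.01, 0.2, 0.01, 0.01, 0.04),
                    adjP = 0.05, direction = "up",
                    isDEG = c(TRUE, FALSE, TRUE, TRUE, TRUE),
                    row.names = paste0("g", 1:5))
  dmp <- data.frame(feature = paste0("p", 1:4), deltaBeta = c(0.2, 0.1, -0.1, 0.3),
                    stat = 1, p = 0.01, adjP = c(0.01, 0.01, 0.2, 0.01),
                    direction = "up", isDMP = c(TRUE, TRUE, FALSE, TRUE),
                    row.names = paste0("p", 1:4))
  ann <- data.frame(gene = c("g1", "g1;g3", "g4", "g2"),
                    gene_region = "Body", cgi_relation = "Island",
                    chromosome = "chr1", row.names = paste0("p", 1:4))
  ov <- overlapMdegs(deg, dmp, ann)
  # brute force: p1->g1; p2->g1,g3 (both DEG -> 2 records); p3 not DMP;
  # p4 -> g2 not DEG
  expect_equal(nrow(ov), 3L)
  expect_setequal(paste(ov$probe, ov$gene),
                  c("p1 g1", "p2 g1", "p2 g3"))
  degNone <- transform(deg, isDEG = FALSE)
  expect_equal(nrow(overlapMdegs(degNone, dmp, ann)), 0L)
})

test_that("Spearman screen matches the hand rank computation", {
  s <- spearmanScreen(1:5, c(2, 1, 4, 3, 5))
  expect_equal(s$r, 0.8)        # 1 - 6*4/120, d^2 = (1,1,1,1,0)
  expect_equal(spearmanScreen(1:10, exp(1:10))$r, 1)
  expect_equal(spearmanScreen(1:10, -(1:10))$r, -1)
  expect_error(spearmanScreen(1:10, rep(1, 10)), "zero variance")
  expect_error(spearmanScreen(1:3, 1:3), ">= 5")
  expect_error(spearmanScreen(1:5, c(1, 2, NA, 4, 5)), "non-finite")
})

test_that("regulation class follows the sign of the co-trend", {
  expect_equal(classifyRegulation(c(-0.8, 0.8, 0)),
               c("trans", "cis", "undetermined"))
  expect_equal(classifyRegulation(0.3, pPG = 0.2, strict = TRUE),
               "undetermined")
  # invariance to monotone transforms of either variable
  set.seed(31)
  x <- runif(30); y <- -2 * x + rnorm(30, 0, 0.1)
  r1 <- spearmanScreen(x, y)$r
  r2 <- spearmanScreen(exp(3 * x), y^3)$r
  expect_equal(classifyRegulation(r1), classifyRegulation(r2))
  expect_equal(r1, r2)
})

test_that("mIMg gates require all three screens to pass", {
  set.seed(32)
  n <- 60
  samp <- paste0("s", 1:n)
  imps <- stats::setNames(rnorm(n), samp)
  # probe1/gene1 strongly coupled to IMpS and each other; pair2 weak
  b1 <- plogis(-1.2 * imps + rnorm(n, 0, 0.3))
  g1 <- 2 * imps + rnorm(n, 0, 0.3)
  b2 <- runif(n); g2 <- 0.2 * imps + rnorm(n)
  expression <- rbind(g1 = g1, g2 = g2); colnames(expression) <- samp
  methylation <- rbind(p1 = b1, p2 = b2); colnames(methylation) <- samp
  pairs <- data.frame(probe = c("p1", "p2"), gene = c("g1", "g2"),
                      isMDEG = TRUE)
  out <- selectMimg(pairs, imps, expression, methylation)
  expect_true(out$isMIMg[1])
  expect_false(out$isMIMg[2])
  expect_equal(out$regulationClass[1], "trans")
  expect_true(all(abs(c(out$rPG, out$rPI, out$rGI)) <= 1))
  # mIMg implies mDEG
  pairs$isMDEG <- c(FALSE, FALSE)
  out2 <- selectMimg(pairs, imps, expression, methylation)
  expect_false(any(out2$isMIMg))
  expect_error(selectMimg(pairs, imps[-1], expression, methylation),
               "match")
})

test_that("cohort intersection behaves as set intersection", {
  p <- data.frame(probe = c("p1", "p2", "p3"), gene = c("g1", "g2", "g3"),
                  isMDEG = TRUE, rPG = c(-0.8, 0.7, -0.6), pPG = 0.01,
                  rPI = 0.8, pPI = 0.01, rGI = 0.8, pGI = 0.01,
                  regulationClass = c("trans", "cis", "trans"),
                  isMIMg = c(TRUE, TRUE, TRUE))
  expect_equal(intersectCohorts(list(p, p, p))[, c("probe", "gene")],
               p[, c("probe", "gene")])
  empty <- p[0, ]
  expect_equal(nrow(intersectCohorts(list(p, empty))), 0L)
  q <- p; q$isMIMg <- c(TRUE, FALSE, FALSE)
  r <- p[c(1, 3), ]; r$isMIMg <- c(TRUE, FALSE)
  shared <- intersectCohorts(list(p, q, r))
  expect_equal(nrow(shared), 1L)
  expect_equal(shared$probe, "p1")
  expect_error(intersectCohorts(list(p)), ">= 2")
})

test_that("2x2 enrichment chi-squared matches the closed forms", {
  pairs <- data.frame(
    probe = paste0("p", 1:80),
    regulationClass = rep(c("trans", "cis"), each = 40))
  # [[30,10],[10,30]]: 30 of 40 trans in promoter, 10 of 40 cis in promoter
  reg <- c(rep("TSS200", 30), rep("Body", 10), rep("TSS1500", 10),
           rep("Body", 30))
  ann <- data.frame(gene = "g", gene_region = reg, cgi_relation = "Island",
                    chromosome = "chr1", row.names = paste0("p", 1:80))
  resY <- regionEnrichmentTest(pairs, ann, "promoter")
  expect_equal(resY$statistic, 18.05, tolerance = 1e-10)  # 80*760^2/2560000
  resN <- regionEnrichmentTest(pairs, ann, "promoter", correct = FALSE)
  expect_equal(resN$statistic, 20, tolerance = 1e-10)
  expect_equal(unname(resY$table[1, ]), c(30, 10))
  # balanced table -> statistic 0
  regB <- rep(c("TSS200", "Body"), 40)
  annB <- ann; annB$gene_region <- regB
  expect_equal(regionEnrichmentTest(pairs, annB, "promoter")$statistic, 0)
  # empty margin errors
  annE <- ann; annE$gene_region <- "Body"
  expect_error(regionEnrichmentTest(pairs, annE, "promoter"), "empty margin")
})
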