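#' @importFrom stats p.adjust pt cor.test chisq.test complete.cases
NULL

.welchRows <- function(mat, ga, gb) {
  A <- mat[, ga, drop = FALSE]
  B <- mat[, gb, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  se2 <- vA / nA + vB / nB
  t <- (mA - mB) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- 2 * pt(-abs(t), df)
  # degenerate zero-variance features: p = 1 when means equal, ~0 otherwise
  zero <- se2 == 0
  if (any(zero)) {
    t[zero] <- 0
    p[zero] <- ifelse(mA[zero] == mB[zero], 1, 0)
  }
  p[is.na(p)] <- 1
  list(effect = mA - mB, stat = t, p = p)
}

.checkGroups <- function(mat, groupA, groupB) {
  if (length(intersect(groupA, groupB)))
    stop("groups overlap")
  if (length(groupA) < 3L || length(groupB) < 3L)
    stop("each group needs >= 3 samples")
  miss <- setdiff(c(groupA, groupB), colnames(mat))
  if (length(miss))
    stop("samples not in the matrix: ", paste(utils::head(miss, 5), collapse = ", "))
}

#' Differential expression between two immunophenotype groups
#'
#' Per-gene Welch two-sample test on log2 expression with Benjamini-Hochberg
#' adjustment. A gene is flagged DEG when raw p < 0.05 and |log2 fold
#' change| > 0, with logFC = mean(group A) - mean(group B); by pipeline
#' convention group A is the noninflamed contrast group, so
#' \code{direction} reports up/down in group A.
#'
#' @param expression genes x samples log2 matrix.
#' @param groupA,groupB disjoint sample-id vectors, each >= 3 samples.
#' @param pThreshold raw p cutoff for the DEG flag (default 0.05).
#' @return data.frame: feature, logFC, stat, p, adjP, direction, isDEG.
#' @export
differentialExpression <- function(expression, groupA, groupB,
                                   pThreshold = 0.05) {
  .checkGroups(expression, groupA, groupB)
  w <- .welchRows(expression, groupA, groupB)
  adjP <- p.adjust(w$p, method = "BH")
  data.frame(feature = rownames(expression), logFC = w$effect, stat = w$stat,
             p = w$p, adjP = adjP,
             direction = ifelse(w$effect > 0, "up", "down"),
             isDEG = w$p < pThreshold & abs(w$effect) > 0,
             row.names = rownames(expression), stringsAsFactors = FALSE)
}

#' Differential methylation between two immunophenotype groups
#'
#' Per-probe Welch two-sample test with BH adjustment. The effect size is
#' delta-beta = mean(group A) - mean(group B) on the beta scale; the test can
#' optionally run on M-values (logit beta, variance-stabilized) while always
#' reporting delta-beta. A probe is flagged DMP when ADJUSTED p < 0.05 and
#' |delta-beta| > 0 — note the deliberate asymmetry with the DEG rule, which
#' uses raw p.
#'
#' @param methylation probes x samples beta matrix.
#' @param groupA,groupB disjoint sample-id vectors, each >= 3 samples.
#' @param useMValues test on logit(beta) instead of beta (default FALSE).
#' @param pThreshold adjusted p cutoff for the DMP flag (default 0.05).
#' @return data.frame: feature, deltaBeta, stat, p, adjP, direction, isDMP.
#' @export
differentialMethylation <- function(methylation, groupA, groupB,
                                    useMValues = FALSE, pThreshold = 0.05) {
  .checkGroups(methylation, groupA, groupB)
  testMat <- if (useMValues) {
    eps <- 1e-3
    qlogis(pmin(pmax(methylation, eps), 1 - eps))
  } else methylation
  w <- .welchRows(testMat, groupA, groupB)
  dBeta <- rowMeans(methylation[, groupA, drop = FALSE]) -
    rowMeans(methylation[, groupB, drop = FALSE])
  adjP <- p.adjust(w$p, method = "BH")
  data.frame(feature = rownames(methylation), deltaBeta = dBeta,
             stat = w$stat, p = w$p, adjP = adjP,
             direction = ifelse(dBeta > 0, "up", "down"),
             isDMP = adjP < pThreshold & abs(dBeta) > 0,
             row.names = rownames(methylation), stringsAsFactors = FALSE)
}

#' Overlap DEGs and DMP-annotated genes into candidate pairs (mDEGs)
#'
#' One record per (DMP probe, DEG gene) pair in which the probe's annotated
#' gene is itself a DEG. A probe annotated to several genes (semicolon-
#' separated) yields one record per annotated DEG. Duplicates are removed.
#'
#' @param deg result of \code{\link{differentialExpression}}.
#' @param dmp result of \code{\link{differentialMethylation}}.
#' @param annotation probe annotation \code{DataFrame}/data.frame with
#'   rownames = probe ids and a \code{gene} column.
#' @return data.frame: probe, gene, logFC, deltaBeta, pGene, pProbe,
#'   adjPProbe, isMDEG (all TRUE); zero rows when the overlap is empty.
#' @export
overlapMdegs <- function(deg, dmp, annotation) {
  ann <- as.data.frame(annotation)
  dmpHits <- dmp$feature[dmp$isDMP]
  degGenes <- deg$feature[deg$isDEG]
  out <- list()
  for (probe in dmpHits) {
    if (!probe %in% rownames(ann)) next
    genes <- strsplit(ann[probe, "gene"], ";", fixed = TRUE)[[1]]
    genes <- unique(genes[nzchar(genes) & genes %in% degGenes])
    for (g in genes)
      out[[length(out) + 1L]] <- data.frame(
        probe = probe, gene = g,
        logFC = deg[g, "logFC"], deltaBeta = dmp[probe, "deltaBeta"],
        pGene = deg[g, "p"], pProbe = dmp[probe, "p"],
        adjPProbe = dmp[probe, "adjP"], isMDEG = TRUE,
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(probe = character(), gene = character(),
                      logFC = numeric(), deltaBeta = numeric(),
                      pGene = numeric(), pProbe = numeric(),
                      adjPProbe = numeric(), isMDEG = logical(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[!duplicated(res[, c("probe", "gene")]), , drop = FALSE]
}

#' Spearman correlation screen
#'
#' Spearman rank correlation with tie-corrected (average) ranks and a
#' two-sided p-value from the t approximation.
#'
#' @param x,y numeric vectors of equal length >= 5, finite values.
#' @return list(r, p).
#' @examples
#' spearmanScreen(1:5, c(2, 1, 4, 3, 5))  # r = 0.7
#' @export
spearmanScreen <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 5L) stop("need >= 5 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Classify the regulation pattern of probe/gene pairs
#'
#' Cis regulation: methylation and expression co-trend in the same direction
#' (positive probe-gene correlation, e.g. hyper-methylation with activated
#' expression). Trans regulation: opposite directions (negative correlation,
#' e.g. promoter hyper-methylation silencing the gene). Classification uses
#' the sign of the Spearman correlation, which is invariant to monotone
#' transforms of either variable.
#'
#' @param rPG probe-gene Spearman correlations (vectorized).
#' @param pPG optional matching p-values for strict mode.
#' @param strict when TRUE, pairs with \code{pPG >= pThreshold} are
#'   \code{"undetermined"}.
#' @param pThreshold significance cutoff for strict mode (default 0.05).
#' @return character vector in \{cis, trans, undetermined\}.
#' @export
classifyRegulation <- function(rPG, pPG = NULL, strict = FALSE,
                               pThreshold = 0.05) {
  if (any(is.na(rPG))) stop("missing probe-gene correlation")
  cls <- ifelse(rPG > 0, "cis", ifelse(rPG < 0, "trans", "undetermined"))
  if (strict) {
    if (is.null(pPG)) stop("strict mode needs p-values")
    cls[pPG >= pThreshold] <- "undetermined"
  }
  cls
}

#' Dual Spearman screen for immune-related methylation-regulated pairs (mIMg)
#'
#' For each candidate pair, computes three Spearman screens — probe beta vs
#' gene expression (r_pg), probe beta vs IMpS (r_pI) and gene expression vs
#' IMpS (r_gI) — and flags the pair as mIMg when all three pass |r| >
#' \code{rThreshold} (strict) and p < \code{pThreshold}. Also assigns the
#' cis/trans regulation class from the sign of r_pg.
#'
#' @param pairs candidate pair table from \code{\link{overlapMdegs}}.
#' @param imps named per-sample IMpS vector.
#' @param expression genes x samples log2 matrix.
#' @param methylation probes x samples beta matrix.
#' @param rThreshold correlation magnitude gate (default 0.5, strict >).
#' @param pThreshold p-value gate (default 0.05).
#' @return The pair table augmented with rPG/pPG, rPI/pPI, rGI/pGI,
#'   regulationClass and isMIMg.
#' @export
selectMimg <- function(pairs, imps, expression, methylation,
                       rThreshold = 0.5, pThreshold = 0.05) {
  samp <- colnames(expression)
  if (!identical(samp, colnames(methylation)))
    stop("expression/methylation sample mismatch")
  if (is.null(names(imps)) || !identical(samp, names(imps)))
    stop("IMpS samples do not match the matrices")
  n <- nrow(pairs)
  rPG <- pPG <- rPI <- pPI <- rGI <- pGI <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    b <- methylation[pairs$probe[i], ]
    g <- expression[pairs$gene[i], ]
    s1 <- spearmanScreen(b, g)
    s2 <- spearmanScreen(b, imps)
    s3 <- spearmanScreen(g, imps)
    rPG[i] <- s1$r; pPG[i] <- s1$p
    rPI[i] <- s2$r; pPI[i] <- s2$p
    rGI[i] <- s3$r; pGI[i] <- s3$p
  }
  pairs$rPG <- rPG; pairs$pPG <- pPG
  pairs$rPI <- rPI; pairs$pPI <- pPI
  pairs$rGI <- rGI; pairs$pGI <- pGI
  pairs$regulationClass <- if (n) classifyRegulation(rPG) else character(0)
  pairs$isMIMg <- (abs(rPG) > rThreshold & pPG < pThreshold &
                   abs(rPI) > rThreshold & pPI < pThreshold &
                   abs(rGI) > rThreshold & pGI < pThreshold)
  if (n) pairs$isMIMg <- pairs$isMIMg & pairs$isMDEG
  pairs
}

#' Intersect pair tables across cohorts
#'
#' Keeps the (probe, gene) pairs present — and, by default, flagged mIMg —
#' in every cohort; per-cohort correlation statistics are retained with a
#' cohort suffix.
#'
#' @param pairLists list of >= 2 pair tables from \code{\link{selectMimg}}.
#' @param requireMimg only intersect pairs with \code{isMIMg} TRUE
#'   (default TRUE).
#' @return data.frame of shared pairs with per-cohort rPG/pPG columns and the
#'   first cohort's regulation class.
#' @export
intersectCohorts <- function(pairLists, requireMimg = TRUE) {
  if (length(pairLists) < 2L) stop("need >= 2 cohorts")
  keyed <- lapply(pairLists, function(p) {
    if (requireMimg && nrow(p)) p <- p[p$isMIMg, , drop = FALSE]
    p$key <- paste(p$probe, p$gene, sep = "|")
    p
  })
  shared <- Reduce(intersect, lapply(keyed, function(p) p$key))
  base <- keyed[[1]][match(shared, keyed[[1]]$key),
                     intersect(c("probe", "gene", "regulationClass"),
                               colnames(keyed[[1]])), drop = FALSE]
  for (k in seq_along(keyed)) {
    idx <- match(shared, keyed[[k]]$key)
    for (col in intersect(c("rPG", "pPG", "rPI", "rGI"), colnames(keyed[[k]])))
      base[[paste0(col, ".", k)]] <- keyed[[k]][[col]][idx]
  }
  rownames(base) <- NULL
  base
}

#' Probe-location enrichment test
#'
#' 2x2 chi-squared test (Yates continuity correction by default) of the
#' association between a probe-location dichotomy (promoter vs non-promoter,
#' or CpG-island shore vs island) and the regulation class (trans vs cis) of
#' the pairs.
#'
#' @param pairs pair table with \code{probe} and \code{regulationClass}.
#' @param annotation probe annotation (rownames = probe ids).
#' @param rowPartition \code{"promoter"} (TSS200/TSS1500/1stExon/5'UTR vs
#'   rest), \code{"shoreVsIsland"} (N/S shore vs island, other probes
#'   dropped), or a logical vector aligned to \code{pairs}.
#' @param colPartition logical vector aligned to \code{pairs}; defaults to
#'   \code{regulationClass == "trans"}.
#' @param correct apply Yates continuity correction (default TRUE).
#' @return list(statistic, df, p, table) where table is the 2x2 count matrix.
#' @export
regionEnrichmentTest <- function(pairs, annotation, rowPartition = "promoter",
                                 colPartition = NULL, correct = TRUE) {
  ann <- as.data.frame(annotation)
  region <- ann[pairs$probe, "gene_region"]
  cgi <- ann[pairs$probe, "cgi_relation"]
  keep <- rep(TRUE, nrow(pairs))
  if (is.character(rowPartition) && length(rowPartition) == 1L) {
    if (rowPartition == "promoter") {
      rowFlag <- region %in% .PROMOTER_REGIONS
      rowNames <- c("promoter", "non-promoter")
    } else if (rowPartition == "shoreVsIsland") {
      keep <- cgi %in% c(.SHORE_RELATIONS, "Island")
      rowFlag <- cgi %in% .SHORE_RELATIONS
      rowNames <- c("shore", "island")
    } else stop("unknown rowPartition keyword: ", rowPartition)
  } else {
    rowFlag <- as.logical(rowPartition)
    rowNames <- c("in", "out")
  }
  if (is.null(colPartition)) colPartition <- pairs$regulationClass == "trans"
  colFlag <- as.logical(colPartition)
  rowFlag <- rowFlag[keep]; colFlag <- colFlag[keep]
  tab <- matrix(c(sum(rowFlag & colFlag), sum(rowFlag & !colFlag),
                  sum(!rowFlag & colFlag), sum(!rowFlag & !colFlag)),
                2, 2, byrow = TRUE,
                dimnames = list(rowNames, c("trans", "cis")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("empty margin in the enrichment table: ",
         paste(capture.output(print(tab)), collapse = " / "))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab)
}
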