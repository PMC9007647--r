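#' @importFrom stats dist hclust cutree
NULL

.ssgseaOne <- function(x, setIdx, alpha) {
  N <- length(x)
  ord <- order(x, decreasing = TRUE)
  r <- rank(-x, ties.method = "average")
  v <- (N - r + 1)^alpha
  inS <- logical(N)
  inS[setIdx] <- TRUE
  inOrd <- inS[ord]
  pin <- cumsum(v[ord] * inOrd) / sum(v[setIdx])
  pout <- cumsum(!inOrd) / (N - length(setIdx))
  sum(pin - pout)
}

#' Single-sample gene-set enrichment score
#'
#' Rank-based enrichment of a gene set within one sample's expression
#' profile. Genes are ranked by decreasing expression (average ranks for
#' ties); with rank weight \eqn{v_i = (N - rank_i + 1)^\alpha}, the score is
#' the sum over all ranked positions of the difference between the weighted
#' in-set ECDF and the unweighted out-of-set ECDF. With \code{alpha = 0} the
#' score depends on expression only through ranks and is invariant to any
#' strictly monotone transformation.
#'
#' @param expr named numeric vector of one sample's per-gene expression.
#' @param geneSet character vector of gene ids; must be a non-empty proper
#'   subset of the measured genes.
#' @param alpha rank-weight exponent, >= 0 (default 0.25).
#' @param missing what to do with set genes absent from \code{expr}:
#'   \code{"drop"} (default) or \code{"fail"}.
#' @return The enrichment score (finite scalar).
#' @examples
#' x <- c(a = 4, b = 3, c = 2, d = 1)
#' ssgseaScore(x, c("a", "b"), alpha = 0)   # 2
#' @export
ssgseaScore <- function(expr, geneSet, alpha = 0.25,
                        missing = c("drop", "fail")) {
  missing <- match.arg(missing)
  stopifnot(alpha >= 0, !anyDuplicated(geneSet))
  if (is.null(names(expr))) stop("expr must be a named vector")
  absent <- setdiff(geneSet, names(expr))
  if (length(absent)) {
    if (missing == "fail")
      stop("genes absent from the expression profile: ",
           paste(utils::head(absent, 5), collapse = ", "))
    geneSet <- setdiff(geneSet, absent)
  }
  if (length(geneSet) == 0L) stop("empty gene set")
  if (length(geneSet) >= length(expr))
    stop("gene set must be a proper subset of the measured genes")
  setIdx <- match(geneSet, names(expr))
  .ssgseaOne(as.numeric(expr), setIdx, alpha)
}

#' ssGSEA scores for many sets over a whole matrix
#'
#' @param expression genes x samples matrix (log2 scale).
#' @param sets named list of gene-id vectors.
#' @inheritParams ssgseaScore
#' @return sets x samples matrix of enrichment scores.
#' @export
ssgseaMatrix <- function(expression, sets, alpha = 0.25,
                         missing = c("drop", "fail")) {
  missing <- match.arg(missing)
  genes <- rownames(expression)
  idx <- lapply(sets, function(s) {
    absent <- setdiff(s, genes)
    if (length(absent) && missing == "fail")
      stop("genes absent from the expression matrix: ",
           paste(utils::head(absent, 5), collapse = ", "))
    i <- match(setdiff(s, absent), genes)
    if (length(i) == 0L) stop("empty gene set after dropping missing genes")
    if (length(i) >= length(genes))
      stop("gene set must be a proper subset of the measured genes")
    i
  })
  out <- matrix(NA_real_, length(sets), ncol(expression),
                dimnames = list(names(sets), colnames(expression)))
  for (j in seq_len(ncol(expression))) {
    x <- expression[, j]
    N <- length(x)
    ord <- order(x, decreasing = TRUE)
    r <- rank(-x, ties.method = "average")
    v <- (N - r + 1)^alpha
    for (k in seq_along(idx)) {
      inS <- logical(N)
      inS[idx[[k]]] <- TRUE
      inOrd <- inS[ord]
      pin <- cumsum(v[ord] * inOrd) / sum(v[idx[[k]]])
      pout <- cumsum(!inOrd) / (N - length(idx[[k]]))
      out[k, j] <- sum(pin - pout)
    }
  }
  out
}

#' Immune activity scores (IMaS)
#'
#' Scores every gene set of the panel by ssGSEA, optionally z-standardizes
#' each set's scores across samples (default; makes sets of different sizes
#' commensurable for clustering), averages sets within each of the 7 feature
#' categories, and applies the category sign weight (+1 for
#' effectors/Th1/MHC/co-stimulators, -1 for suppressors/Th2/co-inhibitors).
#'
#' @param expression genes x samples matrix (log2 scale).
#' @param panel an \linkS4class{ImmunePanel}.
#' @param alpha ssGSEA rank-weight exponent.
#' @param standardize z-standardize per-set scores across samples before
#'   sign-weighting (default TRUE; set FALSE for raw-score mode).
#' @param missing missing-gene policy passed to \code{\link{ssgseaMatrix}}.
#' @return samples x 7 matrix of signed IMaS values, columns in canonical
#'   category order.
#' @export
computeImas <- function(expression, panel, alpha = 0.25, standardize = TRUE,
                        missing = c("drop", "fail")) {
  stopifnot(is(panel, "ImmunePanel"))
  validObject(panel)
  es <- ssgseaMatrix(expression, panelSets(panel), alpha = alpha,
                     missing = missing)
  if (standardize) {
    es <- t(apply(es, 1, function(z) {
      s <- sd(z)
      if (s == 0) rep(0, length(z)) else (z - mean(z)) / s
    }))
  }
  cats <- panelCategories(panel)
  signs <- panelSigns(panel)
  imas <- sapply(.PANEL_CATEGORIES, function(cat_) {
    rows <- which(cats[rownames(es)] == cat_)
    signs[cat_] * colMeans(es[rows, , drop = FALSE])
  })
  rownames(imas) <- colnames(expression)
  imas
}

#' Immunophenotype score (IMpS)
#'
#' The sum of the seven signed immune activity scores of a sample.
#'
#' @param imas either a length-7 numeric vector (one sample) or a samples x 7
#'   matrix from \code{\link{computeImas}}.
#' @return A scalar, or a named per-sample vector for matrix input.
#' @examples
#' computeImps(c(2, -1, 0.5, -0.5, 1, 1, -1))  # 2
#' @export
computeImps <- function(imas) {
  if (is.matrix(imas) || is.data.frame(imas)) {
    imas <- as.matrix(imas)
    if (ncol(imas) != 7L) stop("expected 7 IMaS features, got ", ncol(imas))
    if (any(!is.finite(imas))) stop("non-finite IMaS value")
    return(rowSums(imas))
  }
  if (length(imas) != 7L) stop("expected 7 IMaS values, got ", length(imas))
  if (any(!is.finite(imas))) stop("non-finite IMaS value")
  sum(imas)
}

#' Cytolytic activity (CYT)
#'
#' Geometric mean of granzyme A (GZMA) and perforin (PRF1) linear-scale
#' expression, with a pseudocount to guard zeros.
#'
#' @param gzma,prf1 non-negative linear-scale expression values (vectors of
#'   equal length are accepted).
#' @param offset pseudocount >= 0 added to both genes (default 1).
#' @return sqrt((gzma + offset) * (prf1 + offset)).
#' @examples
#' computeCyt(4, 9, offset = 0)  # 6
#' @export
computeCyt <- function(gzma, prf1, offset = 1) {
  if (any(gzma < 0, na.rm = TRUE) || any(prf1 < 0, na.rm = TRUE))
    stop("expression values must be non-negative (linear scale)")
  if (offset < 0) stop("offset must be >= 0")
  sqrt((gzma + offset) * (prf1 + offset))
}

#' Per-sample average methylation
#'
#' Arithmetic mean beta value over retained probes; missing values are
#' dropped per sample.
#'
#' @param beta numeric vector of one sample's beta values, or a probes x
#'   samples matrix (column means returned).
#' @return Mean beta in [0, 1] (per sample for matrix input).
#' @export
averageMethylation <- function(beta) {
  if (is.matrix(beta)) {
    if (any(beta < 0 | beta > 1, na.rm = TRUE))
      stop("beta values outside [0, 1]")
    out <- colMeans(beta, na.rm = TRUE)
    if (any(!is.finite(out))) stop("sample with all beta values missing")
    return(out)
  }
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) stop("beta values outside [0, 1]")
  beta <- beta[!is.na(beta)]
  if (length(beta) == 0L) stop("all beta values missing")
  mean(beta)
}

#' Cluster samples into three canonical immunophenotypes
#'
#' Agglomerative hierarchical clustering of the samples x 7 IMaS matrix
#' (Euclidean distance, Ward linkage by default), cut at \code{k} groups and
#' renamed canonically by mean IMpS: C2 = highest (immunologically hot),
#' C3 = lowest (cold), C1 = intermediate. The canonical renaming makes the
#' labels deterministic regardless of dendrogram order.
#'
#' @param imas samples x 7 IMaS matrix.
#' @param k number of clusters (default 3; canonical names require k = 3).
#' @param distance distance measure for \code{\link[stats]{dist}}.
#' @param linkage agglomeration method for \code{\link[stats]{hclust}}
#'   (default \code{"ward.D2"}).
#' @return Factor of cluster labels (levels C1, C2, C3 for k = 3), named by
#'   sample.
#' @export
clusterImmunophenotypes <- function(imas, k = 3L, distance = "euclidean",
                                    linkage = "ward.D2") {
  imas <- as.matrix(imas)
  if (nrow(imas) < k) stop("fewer samples than clusters")
  if (all(apply(imas, 2, function(z) length(unique(z)) == 1L)))
    stop("degenerate input: all samples identical")
  hc <- hclust(dist(imas, method = distance), method = linkage)
  raw <- cutree(hc, k = k)
  imps <- rowSums(imas)
  means <- tapply(imps, raw, mean)
  ord <- order(means, decreasing = TRUE)   # highest first
  if (k == 3L) {
    canon <- c("C2", "C1", "C3")           # hot, medium, cold
    map <- stats::setNames(canon, names(means)[ord])
    lab <- factor(map[as.character(raw)], levels = c("C1", "C2", "C3"))
  } else {
    map <- stats::setNames(paste0("C", seq_len(k)), names(means)[ord])
    lab <- factor(map[as.character(raw)], levels = paste0("C", seq_len(k)))
  }
  names(lab) <- rownames(imas)
  lab
}

#' Reference-based cell-fraction deconvolution
#'
#' Estimates cell-type fractions from a sample's methylation profile by
#' constrained least squares: minimize ||beta - R f||^2 subject to f >= 0 and
#' sum(f) <= 1, where R is the marker-probe x cell-type reference matrix.
#' The simplex constraint is imposed through a heavily penalty-weighted
#' slack variable on top of a non-negative least-squares solve.
#'
#' @param beta named beta vector for one sample, or a probes x samples matrix
#'   (deconvolved per column); only probes present in the reference are used,
#'   complete cases only.
#' @param reference marker-probe x cell-type matrix of reference beta values
#'   (>= 2 cell types, full column rank).
#' @return Named fraction vector per cell type (matrix input: cell types x
#'   samples), lying in the simplex \{f >= 0, sum f <= 1\}.
#' @export
deconvolveFractions <- function(beta, reference) {
  reference <- as.matrix(reference)
  if (ncol(reference) < 2L) stop("reference needs >= 2 cell types")
  if (qr(reference)$rank < ncol(reference))
    stop("rank-deficient reference profile matrix")
  if (is.matrix(beta)) {
    out <- apply(beta, 2, deconvolveFractions, reference = reference)
    rownames(out) <- colnames(reference)
    return(out)
  }
  if (!is.null(names(beta)) && !is.null(rownames(reference))) {
    common <- intersect(rownames(reference), names(beta))
    if (length(common) < ncol(reference))
      stop("fewer marker probes than cell types")
    beta <- beta[common]
    R <- reference[common, , drop = FALSE]
  } else {
    if (length(beta) != nrow(reference))
      stop("beta length does not match the reference")
    R <- reference
  }
  keep <- stats::complete.cases(beta)
  beta <- beta[keep]
  R <- R[keep, , drop = FALSE]
  if (nrow(R) < ncol(R)) stop("fewer marker probes than cell types")
  solveMu <- function(mu) {
    A <- rbind(cbind(R, 0), mu * rep(1, ncol(R) + 1))
    pracma::lsqnonneg(A, c(beta, mu))$x
  }
  # retry with a softer penalty if the active-set solver stalls numerically
  f <- NULL
  for (mu in 1e3 * max(1, max(abs(R))) / c(1, 10, 100)) {
    f <- tryCatch(solveMu(mu), error = function(e) NULL)
    if (!is.null(f)) break
  }
  if (is.null(f)) stop("non-negative least-squares solver failed to converge")
  stats::setNames(f[seq_len(ncol(R))], colnames(R))
}

#' Per-sample immune score table
#'
#' Runs the whole scoring stage on a cohort: ssGSEA per gene set, signed IMaS
#' per feature category, IMpS, CYT (from GZMA/PRF1 on the linear scale),
#' average methylation, and the canonical immunophenotype cluster label.
#'
#' @param cohort a \linkS4class{MethylImmuneCohort}.
#' @param panel an \linkS4class{ImmunePanel}; defaults to the cohort's own
#'   panel for synthetic cohorts.
#' @param alpha,standardize ssGSEA/IMaS options (see \code{\link{computeImas}}).
#' @param cytOffset pseudocount for CYT (default 1).
#' @param cluster compute the cluster labels (default TRUE).
#' @param linkage,distance clustering options.
#' @return \code{DataFrame} keyed by sample with columns \code{ES_<set>},
#'   \code{IMaS_<category>}, \code{IMpS}, \code{CYT}, \code{averageBeta} and
#'   \code{cluster}; the IMaS matrix is attached as metadata column
#'   attribute \code{"imas"}.
#' @export
scoreSamples <- function(cohort, panel = NULL, alpha = 0.25,
                         standardize = TRUE, cytOffset = 1, cluster = TRUE,
                         linkage = "ward.D2", distance = "euclidean") {
  stopifnot(is(cohort, "MethylImmuneCohort"))
  if (is.null(panel)) panel <- cohortTruth(cohort)$panel
  if (is.null(panel)) stop("no panel supplied and the cohort carries none")
  expr <- exprMatrix(cohort)
  es <- ssgseaMatrix(expr, panelSets(panel), alpha = alpha)
  imas <- computeImas(expr, panel, alpha = alpha, standardize = standardize)
  imps <- computeImps(imas)
  cyt <- if (all(c("GZMA", "PRF1") %in% rownames(expr))) {
    computeCyt(2^expr["GZMA", ], 2^expr["PRF1", ], offset = cytOffset)
  } else {
    warning("GZMA/PRF1 not in the expression matrix; CYT set to NA")
    rep(NA_real_, ncol(expr))
  }
  avgBeta <- averageMethylation(betaMatrix(cohort))
  lab <- if (cluster)
    clusterImmunophenotypes(imas, distance = distance, linkage = linkage)
  else factor(rep(NA_character_, ncol(expr)))
  out <- S4Vectors::DataFrame(t(es), imas, IMpS = imps, CYT = cyt,
                              averageBeta = avgBeta, cluster = lab,
                              row.names = colnames(expr))
  colnames(out)[seq_len(nrow(es))] <- paste0("ES_", rownames(es))
  colnames(out)[nrow(es) + seq_len(7)] <- paste0("IMaS_", .PANEL_CATEGORIES)
  S4Vectors::metadata(out)$imas <- imas
  out
}
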