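#' @importFrom stats rnorm runif rexp plogis qlogis rbinom sd uniroot
NULL

# Internal wiring constants of the generator. probeCoupling/geneCoupling tie
# planted probes and genes to the latent immune axis so the planted pairs are
# genuinely immune-related (correlated with IMpS downstream); negAmplitude
# attenuates and negCatNoiseFrac blurs the response of negative immune
# factors, so that IMpS (4 positive - 3 sign-flipped negative categories)
# remains a faithful readout of the latent axis instead of cancelling;
# plantedScale is the SD (log2 units) of the planted-gene signal;
# globalBetaDrift (logit units per SD of immune activity) plants the global
# hyper-methylation trend of inflamed tumors into the background probes.
.GEN <- list(probeCoupling = 0.8, geneCoupling = 0.78, negAmplitude = 0.45,
             negCatNoiseFrac = 0.12, plantedScale = 1.5,
             globalBetaDrift = 0.15, nMarkerProbes = 60L, markerNoise = 0.02)

.panelSetDesign <- function() {
  c(aCD4T = "effectors", aCD8T = "effectors", CD4Tem = "effectors",
    CD8Tem = "effectors", Treg = "suppressors", MDSC = "suppressors",
    Th1 = "Th1", Th2 = "Th2", MHC = "MHC", CoStim = "costimulators",
    CoInhib = "coinhibitors")
}

# Deterministic cluster sizes by largest remainder, then a random permutation
# of the assignment order; guarantees no cluster is degenerate.
.assignClusters <- function(n, props) {
  base <- floor(n * props)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * props - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1L
  }
  labels <- rep(c("hot", "medium", "cold"), times = base)
  factor(sample(labels), levels = c("hot", "medium", "cold"))
}

# Spearman target -> Pearson correlation under a Gaussian copula.
.pearsonForSpearman <- function(rs) 2 * sin(pi * rs / 6)

#' Generate a synthetic matched expression/methylation cohort
#'
#' Builds a cohort with the statistical structure the downstream analysis
#' assumes, plus full ground truth: three latent immunophenotype clusters
#' (hot/medium/cold) driving co-expressed immune gene sets, planted
#' methylation-regulated probe/gene pairs (trans: beta high when immune
#' activity is low and anti-correlated with expression; cis: positively
#' coupled), promoter-biased probe annotation, deconvolution marker probes
#' mixed from two stored reference methylomes (immune-like and
#' epithelial-like) with immune weight increasing from cold to hot, and
#' exponential survival whose log-hazard is linear in the standardized
#' expression of the planted hazard genes, with independent uniform
#' censoring calibrated to the configured rate.
#'
#' Beta values are inverse-logit transforms of Gaussian latent values
#' (logit-normal), so they lie in [0, 1] without truncation.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return A \linkS4class{MethylImmuneCohort} whose \code{cohortTruth} list
#'   holds \code{clusterLabels}, \code{pairs}, \code{logHazards},
#'   \code{cellFractions}, \code{referenceProfiles}, \code{immuneActivity}
#'   and the \code{panel} (an \linkS4class{ImmunePanel}).
#' @examples
#' cohort <- generateCohort(cohortConfig(nSamples = 60, nBackgroundGenes = 100,
#'                                       nPlantedPairs = 10, seed = 3))
#' cohort
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  set.seed(config@seed)
  n <- config@nSamples
  e <- config@effectSizeExpr
  samples <- sprintf("S%04d", seq_len(n))

  cl <- .assignClusters(n, config@clusterProportions)
  names(cl) <- samples
  # latent immune activity: hot +e/2, medium 0, cold -e/2
  a <- c(hot = e / 2, medium = 0, cold = -e / 2)[as.character(cl)]
  aStd <- as.numeric(scale(a))
  if (any(!is.finite(aStd))) aStd <- rep(0, n)

  ## ---- immune panel and immune gene expression ----
  setDesign <- .panelSetDesign()
  nPerSet <- config@nImmuneGenesPerSet
  geneCounter <- 0L
  sets <- list()
  immuneGenes <- character()
  for (s in names(setDesign)) {
    g <- sprintf("G%06d", geneCounter + seq_len(nPerSet))
    geneCounter <- geneCounter + nPerSet
    sets[[s]] <- g
    immuneGenes <- c(immuneGenes, g)
  }
  panel <- immunePanel(sets, setDesign)

  nImm <- length(immuneGenes)
  baselineImm <- rnorm(nImm, 6, 1)
  # medium-cluster heterogeneity: per-sample, per-category random effects
  het <- matrix(0, n, length(.PANEL_CATEGORIES),
                dimnames = list(samples, .PANEL_CATEGORIES))
  medIdx <- which(cl == "medium")
  het[medIdx, ] <- rnorm(length(medIdx) * ncol(het), 0, e / 6)
  # negative categories respond to the axis with smaller amplitude and extra
  # category-level noise (suppressive programs track inflammation loosely)
  negNoise <- matrix(0, n, length(.PANEL_CATEGORIES),
                     dimnames = list(samples, .PANEL_CATEGORIES))
  negCats <- names(which(panelSigns(panel) < 0))
  negNoise[, negCats] <- rnorm(n * length(negCats), 0,
                               .GEN$negCatNoiseFrac * e)
  exprImm <- matrix(0, nImm, n, dimnames = list(immuneGenes, samples))
  row0 <- 0L
  for (s in names(setDesign)) {
    cat_ <- setDesign[[s]]
    amp <- if (panelSigns(panel)[cat_] > 0) 1 else .GEN$negAmplitude
    idx <- row0 + seq_len(nPerSet)
    shift <- amp * (a + het[, cat_]) + negNoise[, cat_]
    exprImm[idx, ] <- baselineImm[idx] +
      matrix(shift, nPerSet, n, byrow = TRUE) +
      matrix(rnorm(nPerSet * n, 0, config@noiseSd), nPerSet, n)
    row0 <- row0 + nPerSet
  }

  # cytolytic effector genes for CYT, tracking immune activity
  exprCyt <- matrix(5 + rep(a, each = 2) + rnorm(2 * n, 0, config@noiseSd),
                    2, n, dimnames = list(c("GZMA", "PRF1"), samples))

  ## ---- background genes and probes ----
  nBg <- config@nBackgroundGenes
  bgGenes <- sprintf("G%06d", geneCounter + seq_len(nBg))
  geneCounter <- geneCounter + nBg
  exprBg <- matrix(rnorm(nBg, 6, 1.2) + rnorm(nBg * n, 0, config@noiseSd),
                   nBg, n, dimnames = list(bgGenes, samples))
  bgProbes <- sprintf("cgS%06d", seq_len(nBg))
  # global methylation drift: inflamed (high immune activity) samples are
  # globally hyper-methylated, mirrored across all background probes
  betaBg <- plogis(matrix(rnorm(nBg, 0, 1), nBg, n) +
                   matrix(.GEN$globalBetaDrift * aStd, nBg, n, byrow = TRUE) +
                   matrix(rnorm(nBg * n, 0, 0.5), nBg, n))
  dimnames(betaBg) <- list(bgProbes, samples)

  ## ---- planted methylation-regulated immune pairs ----
  nP <- config@nPlantedPairs
  nTrans <- round(config@transFraction * nP)
  classes <- rep(c("trans", "cis"), c(nTrans, nP - nTrans))
  plantedGenes <- sprintf("G%06d", geneCounter + seq_len(nP))
  plantedProbes <- sprintf("cgS%06d", nBg + seq_len(nP))
  # three-way correlation design per planted pair: the probe latent x and the
  # gene latent y carry target correlations corr(x, a) = +/-kp (probe vs
  # immune axis), corr(y, a) = kg and corr(x, y) = +/-rhoP (the configured
  # Spearman coupling on the Pearson scale of a Gaussian copula); trans pairs
  # flip the probe's sign (beta high when immune activity is low) and the
  # probe-gene coupling
  kp <- .GEN$probeCoupling
  kg <- .GEN$geneCoupling
  rhoP <- .pearsonForSpearman(config@couplingStrength)
  sx <- sqrt(1 - kp^2)
  t1 <- (rhoP - kp * kg) / sx
  t2sq <- 1 - kg^2 - t1^2
  if (t2sq < 0) {          # extreme coupling: collapse onto the feasible edge
    t2 <- 0
    norm <- sqrt(kg^2 + t1^2)
    kgEff <- kg / norm; t1 <- t1 / norm
  } else {
    t2 <- sqrt(t2sq); kgEff <- kg
  }
  # logit-scale slope reproducing the requested hot-vs-cold beta separation
  dA <- if (any(cl == "hot") && any(cl == "cold"))
    mean(aStd[cl == "hot"]) - mean(aStd[cl == "cold"]) else 0
  lam <- if (dA > 0)
    2 * qlogis(0.5 + min(config@effectSizeBeta, 0.98) / 2) / (kp * dA)
  else 1
  exprP <- matrix(0, max(nP, 1L), n)
  betaP <- matrix(0, max(nP, 1L), n)
  if (nP > 0) {
    for (j in seq_len(nP)) {
      sgn <- if (classes[j] == "trans") -1 else 1   # probe beta vs immune axis
      e1 <- rnorm(n); e2 <- rnorm(n)
      x <- sgn * kp * aStd + sx * e1
      y <- kgEff * aStd + sgn * t1 * e1 + t2 * e2
      mu0 <- rnorm(1, 0, 0.7)
      betaP[j, ] <- plogis(mu0 + lam * x)
      exprP[j, ] <- rnorm(1, 6, 1) + .GEN$plantedScale * y
    }
    dimnames(exprP) <- list(plantedGenes, samples)
    dimnames(betaP) <- list(plantedProbes, samples)
  }

  ## ---- deconvolution marker probes: mixture of two reference methylomes ----
  nM <- .GEN$nMarkerProbes
  markerProbes <- sprintf("cgS9%05d", seq_len(nM))
  refImm <- runif(nM, 0.05, 0.95)
  refEpi <- pmin(pmax(refImm + sample(c(-1, 1), nM, TRUE) * runif(nM, 0.3, 0.6),
                      0.02), 0.98)
  reference <- cbind(immune = refImm, epithelial = refEpi)
  rownames(reference) <- markerProbes
  fImm <- c(hot = 0.45, medium = 0.30, cold = 0.15)[as.character(cl)] +
    runif(n, -0.08, 0.08)
  fImm <- pmin(pmax(fImm, 0.02), 0.95)
  fractions <- cbind(immune = fImm, epithelial = 1 - fImm)
  rownames(fractions) <- samples
  betaM <- reference %*% t(fractions) +
    matrix(rnorm(nM * n, 0, .GEN$markerNoise * config@noiseSd), nM, n)
  betaM <- pmin(pmax(betaM, 0), 1)
  dimnames(betaM) <- list(markerProbes, samples)

  ## ---- assemble matrices ----
  expression <- rbind(exprImm, exprCyt, exprBg,
                      if (nP > 0) exprP else NULL)
  methylation <- rbind(betaBg, if (nP > 0) betaP else NULL, betaM)

  ## ---- probe annotation ----
  .drawRegion <- function(k, pPromoter) {
    isProm <- rbinom(k, 1, pPromoter) == 1
    out <- character(k)
    out[isProm] <- sample(.PROMOTER_REGIONS, sum(isProm), TRUE)
    out[!isProm] <- sample(c("Body", "3'UTR", "IGR"), sum(!isProm), TRUE,
                           prob = c(0.7, 0.15, 0.15))
    out
  }
  .drawCgi <- function(k, probs) sample(.CGI_VOCAB, k, TRUE, prob = probs)
  annBg <- data.frame(
    gene = bgGenes,
    gene_region = .drawRegion(nBg, 0.5),
    cgi_relation = .drawCgi(nBg, c(0.3, 0.15, 0.15, 0.1, 0.1, 0.2)),
    chromosome = paste0("chr", sample(1:22, nBg, TRUE)),
    row.names = bgProbes, stringsAsFactors = FALSE)
  annP <- if (nP > 0) {
    pProm <- ifelse(classes == "trans", config@promoterEnrichmentTrans,
                    config@promoterEnrichmentCis)
    reg <- vapply(pProm, function(p) .drawRegion(1L, p), character(1))
    cgi <- character(nP)
    isTrans <- classes == "trans"
    cgi[isTrans] <- .drawCgi(sum(isTrans), c(0.25, 0.25, 0.25, 0.05, 0.05, 0.15))
    cgi[!isTrans] <- .drawCgi(sum(!isTrans), c(0.5, 0.125, 0.125, 0.05, 0.05, 0.15))
    data.frame(gene = plantedGenes, gene_region = reg, cgi_relation = cgi,
               chromosome = paste0("chr", sample(1:22, nP, TRUE)),
               row.names = plantedProbes, stringsAsFactors = FALSE)
  } else NULL
  annM <- data.frame(
    gene = "", gene_region = .drawRegion(nM, 0.5),
    cgi_relation = .drawCgi(nM, c(0.3, 0.15, 0.15, 0.1, 0.1, 0.2)),
    chromosome = paste0("chr", sample(1:22, nM, TRUE)),
    row.names = markerProbes, stringsAsFactors = FALSE)
  annotation <- rbind(annBg, annP, annM)

  ## ---- survival and clinical covariates ----
  h <- config@hazardCoefficients
  lp <- rep(0, n)
  logHazards <- numeric(0)
  if (nP > 0 && length(h) > 0) {
    nh <- min(length(h), nP)
    hz <- h[seq_len(nh)]
    names(hz) <- plantedGenes[seq_len(nh)]
    z <- scale(t(exprP[seq_len(nh), , drop = FALSE]))
    lp <- as.numeric(z %*% hz)
    logHazards <- hz
  }
  rate <- config@baselineHazard * exp(lp)
  tEvent <- rexp(n, rate)
  if (config@censoringRate > 0) {
    f <- function(cmax) mean(pmin(tEvent / cmax, 1)) - config@censoringRate
    cmax <- uniroot(f, c(1e-6, 1e8), tol = 1e-8)$root
    tCens <- runif(n, 0, cmax)
    osTime <- pmin(tEvent, tCens)
    osEvent <- as.integer(tEvent <= tCens)
  } else {
    osTime <- tEvent
    osEvent <- rep(1L, n)
  }
  clinical <- data.frame(
    OS_time = pmax(osTime, 1e-3),
    OS_event = osEvent,
    age = round(pmin(pmax(rnorm(n, 65, 10), 30), 90)),
    gender = sample(c("male", "female"), n, TRUE),
    stage = sample(c("I", "II", "III", "IV"), n, TRUE,
                   prob = c(0.45, 0.25, 0.2, 0.1)),
    EGFR_status = sample(c("mut", "wt"), n, TRUE, prob = c(0.15, 0.85)),
    ICI_response = ifelse(rbinom(n, 1, plogis(aStd - 0.5)) == 1,
                          "responder", "nonresponder"),
    row.names = samples, stringsAsFactors = FALSE)

  truth <- list(
    clusterLabels = cl,
    pairs = if (nP > 0)
      data.frame(probe = plantedProbes, gene = plantedGenes,
                 regulation_class = classes, is_immune_related = TRUE,
                 stringsAsFactors = FALSE)
    else data.frame(probe = character(), gene = character(),
                    regulation_class = character(),
                    is_immune_related = logical()),
    logHazards = logHazards,
    cellFractions = fractions,
    referenceProfiles = reference,
    immuneActivity = stats::setNames(aStd, samples),
    panel = panel)

  methylImmuneCohort(expression, methylation, annotation, clinical, truth)
}

#' Ground-truth table of planted probe/gene pairs
#'
#' @param cohort a synthetic \linkS4class{MethylImmuneCohort}.
#' @return data.frame with columns \code{probe}, \code{gene},
#'   \code{regulation_class} (cis/trans) and \code{is_immune_related};
#'   exhaustive and duplicate-free.
#' @export
truthPairTable <- function(cohort) {
  stopifnot(is(cohort, "MethylImmuneCohort"))
  tr <- cohortTruth(cohort)
  if (is.null(tr$pairs))
    stop("cohort carries no ground truth (not a synthetic cohort)")
  tr$pairs
}
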