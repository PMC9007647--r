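#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.REGION_VOCAB <- c("TSS200", "TSS1500", "1stExon", "5'UTR", "Body", "3'UTR", "IGR")
.CGI_VOCAB <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")
.PROMOTER_REGIONS <- c("TSS200", "TSS1500", "1stExon", "5'UTR")
.SHORE_RELATIONS <- c("N_Shore", "S_Shore")
.PANEL_CATEGORIES <- c("effectors", "suppressors", "Th1", "Th2", "MHC",
                       "costimulators", "coinhibitors")

#' Configuration of a synthetic methylation-immune cohort
#'
#' Holds every tunable of the synthetic-cohort generator: cohort size, latent
#' immunophenotype cluster proportions, feature-space dimensions, the number of
#' planted methylation-regulated immune pairs and their cis/trans split, effect
#' sizes on the expression (log2) and methylation (beta) scales, the target
#' absolute Spearman coupling of planted probe/gene pairs, survival-model
#' coefficients and censoring, and the promoter-annotation probabilities that
#' drive probe-location enrichment.
#'
#' @slot nSamples number of samples.
#' @slot clusterProportions length-3 numeric, proportions of the hot, medium
#'   and cold immunophenotype clusters; must sum to 1.
#' @slot nBackgroundGenes number of unstructured background genes (each with
#'   one unlinked background probe).
#' @slot nImmuneGenesPerSet genes per immune gene set (11 sets across the 7
#'   feature categories).
#' @slot nPlantedPairs number of planted methylation-regulated immune
#'   probe/gene pairs.
#' @slot transFraction share of planted pairs with trans (negative) coupling.
#' @slot effectSizeExpr hot-vs-cold separation of immune gene means, log2 units.
#' @slot effectSizeBeta hot-vs-cold separation of planted probe means, beta units.
#' @slot couplingStrength target absolute Spearman correlation of planted
#'   probe/gene pairs, in (0, 1].
#' @slot noiseSd residual SD of expression noise (log2 units); also scales the
#'   deconvolution marker noise (0.02 * noiseSd on the beta scale).
#' @slot hazardCoefficients per-gene log-hazard weights applied to the
#'   standardized expression of the first \code{length(hazardCoefficients)}
#'   planted genes.
#' @slot censoringRate target probability that a subject is censored.
#' @slot promoterEnrichmentTrans probability a planted trans probe is annotated
#'   to a promoter region (TSS200/TSS1500/1stExon/5'UTR).
#' @slot promoterEnrichmentCis same for planted cis probes.
#' @slot baselineHazard rate of the exponential baseline survival model
#'   (per month).
#' @slot seed integer seed; identical config + seed gives identical cohorts.
#' @exportClass CohortConfig
setClass("CohortConfig", representation(
  nSamples = "integer",
  clusterProportions = "numeric",
  nBackgroundGenes = "integer",
  nImmuneGenesPerSet = "integer",
  nPlantedPairs = "integer",
  transFraction = "numeric",
  effectSizeExpr = "numeric",
  effectSizeBeta = "numeric",
  couplingStrength = "numeric",
  noiseSd = "numeric",
  hazardCoefficients = "numeric",
  censoringRate = "numeric",
  promoterEnrichmentTrans = "numeric",
  promoterEnrichmentCis = "numeric",
  baselineHazard = "numeric",
  seed = "integer"
))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (length(object@clusterProportions) != 3L)
    msg <- c(msg, "clusterProportions must have length 3")
  else if (abs(sum(object@clusterProportions) - 1) > 1e-12)
    msg <- c(msg, "clusterProportions must sum to 1")
  if (any(object@clusterProportions < 0))
    msg <- c(msg, "clusterProportions must be non-negative")
  for (f in c("nSamples", "nBackgroundGenes", "nImmuneGenesPerSet"))
    if (slot(object, f) < 1L) msg <- c(msg, paste(f, "must be positive"))
  if (object@nPlantedPairs < 0L)
    msg <- c(msg, "nPlantedPairs must be non-negative")
  if (object@nPlantedPairs > object@nBackgroundGenes)
    msg <- c(msg, "nPlantedPairs exceeds the available background gene pool")
  if (object@transFraction < 0 || object@transFraction > 1)
    msg <- c(msg, "transFraction must lie in [0, 1]")
  if (object@couplingStrength <= 0 || object@couplingStrength > 1)
    msg <- c(msg, "couplingStrength must lie in (0, 1]")
  if (object@censoringRate < 0 || object@censoringRate >= 1)
    msg <- c(msg, "censoringRate must lie in [0, 1)")
  for (f in c("promoterEnrichmentTrans", "promoterEnrichmentCis"))
    if (slot(object, f) < 0 || slot(object, f) > 1)
      msg <- c(msg, paste(f, "must lie in [0, 1]"))
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (object@baselineHazard <= 0) msg <- c(msg, "baselineHazard must be positive")
  if (length(msg)) msg else TRUE
})

#' Create a synthetic cohort configuration
#'
#' Defaults describe a mid-sized tumor cohort: 300 samples in three roughly
#' balanced immunophenotype clusters, 2000 background genes, 11 immune gene
#' sets of 15 genes, 40 planted methylation-regulated pairs of which 70% are
#' trans, a 1.5 log2-unit immune expression contrast, a 0.25 beta-unit
#' methylation contrast, Spearman coupling 0.8, exponential survival with
#' median ~36 months and 30% uniform censoring.
#'
#' @param nSamples,clusterProportions,nBackgroundGenes,nImmuneGenesPerSet
#'   cohort dimensions; see \linkS4class{CohortConfig}.
#' @param nPlantedPairs,transFraction,couplingStrength planted pair design.
#' @param effectSizeExpr,effectSizeBeta,noiseSd effect and noise scales.
#' @param hazardCoefficients,censoringRate,baselineHazard survival model.
#' @param promoterEnrichmentTrans,promoterEnrichmentCis annotation design.
#' @param seed integer seed.
#' @return A validated \linkS4class{CohortConfig}.
#' @examples
#' cfg <- cohortConfig(nSamples = 60, nBackgroundGenes = 100, seed = 7)
#' @export
cohortConfig <- function(nSamples = 300L,
                         clusterProportions = c(0.30, 0.35, 0.35),
                         nBackgroundGenes = 2000L,
                         nImmuneGenesPerSet = 30L,
                         nPlantedPairs = 40L,
                         transFraction = 0.7,
                         effectSizeExpr = 1.5,
                         effectSizeBeta = 0.25,
                         couplingStrength = 0.8,
                         noiseSd = 1,
                         hazardCoefficients = 0.7,
                         censoringRate = 0.3,
                         promoterEnrichmentTrans = 0.8,
                         promoterEnrichmentCis = 0.4,
                         baselineHazard = log(2) / 36,
                         seed = 1L) {
  new("CohortConfig",
      nSamples = as.integer(nSamples),
      clusterProportions = as.numeric(clusterProportions),
      nBackgroundGenes = as.integer(nBackgroundGenes),
      nImmuneGenesPerSet = as.integer(nImmuneGenesPerSet),
      nPlantedPairs = as.integer(nPlantedPairs),
      transFraction = as.numeric(transFraction),
      effectSizeExpr = as.numeric(effectSizeExpr),
      effectSizeBeta = as.numeric(effectSizeBeta),
      couplingStrength = as.numeric(couplingStrength),
      noiseSd = as.numeric(noiseSd),
      hazardCoefficients = as.numeric(hazardCoefficients),
      censoringRate = as.numeric(censoringRate),
      promoterEnrichmentTrans = as.numeric(promoterEnrichmentTrans),
      promoterEnrichmentCis = as.numeric(promoterEnrichmentCis),
      baselineHazard = as.numeric(baselineHazard),
      seed = as.integer(seed))
}

#' Signed immune feature panel
#'
#' Seven immune feature categories, each holding one or more gene sets and a
#' sign weight: effectors (aCD4+T, aCD8+T, CD4+Tem, CD8+Tem), Th1, MHC
#' molecules and co-stimulators are positive immune factors (+1); suppressors
#' (Treg, MDSC), Th2 and co-inhibitors are negative immune factors (-1). The
#' signed per-category mean of ssGSEA scores is the immune activity score
#' (IMaS).
#'
#' @slot sets named list of character vectors: gene set name -> gene ids.
#' @slot categories named character: gene set name -> one of the 7 categories.
#' @slot signs named numeric: category -> +1 or -1.
#' @exportClass ImmunePanel
setClass("ImmunePanel", representation(
  sets = "list",
  categories = "character",
  signs = "numeric"
))

setValidity("ImmunePanel", function(object) {
  msg <- character()
  if (!setequal(names(object@signs), .PANEL_CATEGORIES))
    msg <- c(msg, "signs must name exactly the 7 immune feature categories")
  if (!all(object@signs %in% c(-1, 1)))
    msg <- c(msg, "sign weights must be +1 or -1")
  expected <- defaultPanelSigns()
  if (setequal(names(object@signs), .PANEL_CATEGORIES) &&
      !identical(object@signs[.PANEL_CATEGORIES], expected))
    msg <- c(msg, "sign convention must be +1 for effectors/Th1/MHC/costimulators and -1 for suppressors/Th2/coinhibitors")
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "gene sets must have unique names")
  if (!setequal(names(object@categories), names(object@sets)))
    msg <- c(msg, "categories must map every gene set")
  if (!all(object@categories %in% .PANEL_CATEGORIES))
    msg <- c(msg, "category labels outside the 7-category vocabulary")
  if (!setequal(unique(object@categories), .PANEL_CATEGORIES))
    msg <- c(msg, "every category must hold at least one gene set")
  if (any(lengths(object@sets) == 0L))
    msg <- c(msg, "every gene set must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Default sign weights of the seven immune feature categories
#'
#' @return Named numeric of +1/-1 weights in canonical category order.
#' @export
defaultPanelSigns <- function() {
  c(effectors = 1, suppressors = -1, Th1 = 1, Th2 = -1, MHC = 1,
    costimulators = 1, coinhibitors = -1)
}

#' Construct an immune feature panel
#'
#' @param sets named list of gene-id character vectors.
#' @param categories named character mapping each set name to a category.
#' @param signs named numeric category sign weights; defaults to the standard
#'   +1/-1 convention.
#' @return A validated \linkS4class{ImmunePanel}.
#' @export
immunePanel <- function(sets, categories, signs = defaultPanelSigns()) {
  new("ImmunePanel", sets = sets,
      categories = categories[names(sets)],
      signs = stats::setNames(as.numeric(signs[.PANEL_CATEGORIES]),
                              .PANEL_CATEGORIES))
}

#' Matched expression/methylation cohort
#'
#' Container for one cohort: a genes-by-samples log2 expression matrix, a
#' probes-by-samples methylation beta matrix, a probe annotation table
#' (gene, gene region, CpG-island relation, chromosome), a clinical table
#' (OS time/event, age, gender, stage, optional strata columns), and — for
#' synthetic cohorts — a ground-truth list.
#'
#' @slot expression numeric matrix, genes x samples, log2 scale.
#' @slot methylation numeric matrix, probes x samples, beta values in [0, 1].
#' @slot annotation \code{DataFrame} with rownames = probe ids and columns
#'   \code{gene}, \code{gene_region}, \code{cgi_relation}, \code{chromosome}.
#' @slot clinical \code{DataFrame} with rownames = sample ids and columns
#'   \code{OS_time}, \code{OS_event}, \code{age}, \code{gender}, \code{stage}
#'   (plus optional columns).
#' @slot truth list of ground-truth objects (empty for real cohorts).
#' @exportClass MethylImmuneCohort
setClass("MethylImmuneCohort", representation(
  expression = "matrix",
  methylation = "matrix",
  annotation = "DataFrame",
  clinical = "DataFrame",
  truth = "list"
))

setValidity("MethylImmuneCohort", function(object) {
  msg <- character()
  sx <- colnames(object@expression)
  sm <- colnames(object@methylation)
  sc <- rownames(object@clinical)
  if (is.null(sx) || is.null(sm))
    msg <- c(msg, "expression and methylation must carry sample column names")
  else {
    if (!identical(sx, sm))
      msg <- c(msg, "expression and methylation sample ids differ")
    if (nrow(object@clinical) > 0L && !identical(sx, sc))
      msg <- c(msg, "clinical sample ids differ from the matrices")
  }
  if (anyDuplicated(sx)) msg <- c(msg, "duplicate sample ids")
  if (anyDuplicated(rownames(object@expression)))
    msg <- c(msg, "duplicate gene ids")
  if (anyDuplicated(rownames(object@methylation)))
    msg <- c(msg, "duplicate probe ids")
  b <- object@methylation
  if (length(b) && any(b < 0 | b > 1, na.rm = TRUE))
    msg <- c(msg, "beta values outside [0, 1]")
  if (nrow(object@annotation) > 0L) {
    if (!identical(rownames(object@annotation), rownames(object@methylation)))
      msg <- c(msg, "annotation rows must match methylation probes")
    need <- c("gene", "gene_region", "cgi_relation", "chromosome")
    if (!all(need %in% colnames(object@annotation)))
      msg <- c(msg, "annotation lacks required columns")
    else {
      if (!all(object@annotation$gene_region %in% .REGION_VOCAB))
        msg <- c(msg, "gene_region outside the closed vocabulary")
      if (!all(object@annotation$cgi_relation %in% .CGI_VOCAB))
        msg <- c(msg, "cgi_relation outside the closed vocabulary")
    }
  }
  if (nrow(object@clinical) > 0L) {
    need <- c("OS_time", "OS_event")
    if (!all(need %in% colnames(object@clinical)))
      msg <- c(msg, "clinical lacks OS_time/OS_event")
    else {
      if (any(object@clinical$OS_time <= 0, na.rm = TRUE))
        msg <- c(msg, "OS_time must be positive")
      if (!all(object@clinical$OS_event %in% c(0, 1)))
        msg <- c(msg, "OS_event must be 0/1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a matched cohort object
#'
#' @param expression genes x samples numeric matrix (log2 scale).
#' @param methylation probes x samples numeric matrix (beta values).
#' @param annotation probe annotation \code{DataFrame} or data.frame.
#' @param clinical clinical \code{DataFrame} or data.frame.
#' @param truth optional ground-truth list (synthetic cohorts).
#' @return A validated \linkS4class{MethylImmuneCohort}.
#' @export
methylImmuneCohort <- function(expression, methylation,
                               annotation = S4Vectors::DataFrame(),
                               clinical = S4Vectors::DataFrame(),
                               truth = list()) {
  new("MethylImmuneCohort",
      expression = as.matrix(expression),
      methylation = as.matrix(methylation),
      annotation = as(annotation, "DataFrame"),
      clinical = as(clinical, "DataFrame"),
      truth = truth)
}

#' Pipeline run report
#'
#' Result of \code{\link{runPipeline}}: the per-sample score table, the pair
#' tables at each stage of the filter funnel (candidate mDEG pairs, then
#' mIMg), the probe-location enrichment tests, the prognostic screen, the
#' stage counts and a provenance block.
#'
#' @slot scores per-sample score \code{DataFrame} (ssGSEA, IMaS, IMpS, CYT,
#'   average beta, cluster label).
#' @slot imas samples x 7 IMaS matrix used for clustering.
#' @slot deg,dmp differential expression/methylation tables.
#' @slot mdeg candidate probe/gene pair table (DEG-and-DMP overlap).
#' @slot mimg pair table with Spearman screens, regulation class and mIMg flag.
#' @slot enrichment list of probe-location enrichment test results.
#' @slot screen prognostic screen table (may have zero rows).
#' @slot counts named integer funnel counts.
#' @slot provenance list: configuration, seed, package version.
#' @exportClass MimgReport
setClass("MimgReport", representation(
  scores = "DataFrame",
  imas = "matrix",
  deg = "data.frame",
  dmp = "data.frame",
  mdeg = "data.frame",
  mimg = "data.frame",
  enrichment = "list",
  screen = "data.frame",
  counts = "integer",
  provenance = "list"
))

setValidity("MimgReport", function(object) {
  cnt <- object@counts
  need <- c("mdegPairs", "mimgPairs")
  if (all(need %in% names(cnt)) && cnt[["mimgPairs"]] > cnt[["mdegPairs"]])
    return("filter funnel counts must be non-increasing (mimg > mdeg)")
  TRUE
})
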