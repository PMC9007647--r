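#' Run the full integrative analysis on one cohort
#'
#' Orchestrates the whole funnel: immune scoring (ssGSEA, IMaS, IMpS, CYT,
#' average beta), canonical three-cluster immunophenotyping, differential
#' expression and methylation between the configured contrast clusters
#' (default C3, the noninflamed cluster, vs C2, the inflamed cluster),
#' DEG/DMP overlap into candidate pairs, the dual Spearman mIMg screen with
#' cis/trans classification, probe-location enrichment tests (promoter vs
#' non-promoter and CGI shore vs island, against trans vs cis), and the
#' prognostic screen of the mIMg markers. Identical input + seed gives an
#' identical report; cluster labels are canonicalized by mean IMpS, not by
#' dendrogram order.
#'
#' @param cohort a \linkS4class{MethylImmuneCohort}.
#' @param panel an \linkS4class{ImmunePanel} (defaults to a synthetic
#'   cohort's own panel).
#' @param alpha ssGSEA exponent.
#' @param standardize z-standardize per-set ssGSEA scores (default TRUE).
#' @param contrast length-2 cluster labels: group A then group B of the
#'   differential analysis (default \code{c("C3", "C2")}).
#' @param rThreshold,pThreshold mIMg screen gates.
#' @param minprop cutpoint search constraint for the prognostic screen.
#' @param screen run the prognostic screen (default TRUE; needs clinical
#'   data).
#' @param selectionAdjust see \code{\link{prognosticScreen}}.
#' @param seed optional integer seed fixed at the start of the run.
#' @param outputDir optional directory; when given, the score table, pair
#'   tables and screen are written as TSV plus a JSON summary.
#' @return A \linkS4class{MimgReport}.
#' @export
runPipeline <- function(cohort, panel = NULL, alpha = 0.25,
                        standardize = TRUE, contrast = c("C3", "C2"),
                        rThreshold = 0.5, pThreshold = 0.05, minprop = 0.1,
                        screen = TRUE, selectionAdjust = TRUE, seed = NULL,
                        outputDir = NULL) {
  stopifnot(is(cohort, "MethylImmuneCohort"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(panel)) panel <- cohortTruth(cohort)$panel
  if (is.null(panel)) stop("stage scoring: no immune panel available")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  scores <- stage("scoring", scoreSamples(cohort, panel, alpha = alpha,
                                          standardize = standardize))
  imas <- S4Vectors::metadata(scores)$imas
  lab <- scores$cluster
  groupA <- rownames(scores)[lab == contrast[1]]
  groupB <- rownames(scores)[lab == contrast[2]]
  deg <- stage("differential expression",
               differentialExpression(exprMatrix(cohort), groupA, groupB))
  dmp <- stage("differential methylation",
               differentialMethylation(betaMatrix(cohort), groupA, groupB))
  mdeg <- stage("mDEG overlap",
                overlapMdegs(deg, dmp, probeAnnotation(cohort)))
  imps <- setNames(scores$IMpS, rownames(scores))
  mimg <- stage("mIMg selection",
                selectMimg(mdeg, imps, exprMatrix(cohort),
                           betaMatrix(cohort), rThreshold = rThreshold,
                           pThreshold = pThreshold))
  hits <- mimg[mimg$isMIMg, , drop = FALSE]

  enrichment <- list()
  if (nrow(hits) >= 4L && length(unique(hits$regulationClass)) >= 2L) {
    enrichment$promoter <- tryCatch(
      regionEnrichmentTest(hits, probeAnnotation(cohort), "promoter"),
      error = function(e) NULL)
    enrichment$shore <- tryCatch(
      regionEnrichmentTest(hits, probeAnnotation(cohort), "shoreVsIsland"),
      error = function(e) NULL)
  }

  screenRes <- list(markers = data.frame(), pairs = hits)
  if (screen && nrow(clinicalData(cohort)) > 0L && nrow(hits) > 0L)
    screenRes <- stage("prognostic screen",
                       prognosticScreen(hits, exprMatrix(cohort),
                                        betaMatrix(cohort),
                                        clinicalData(cohort),
                                        minprop = minprop,
                                        pThreshold = pThreshold,
                                        selectionAdjust = selectionAdjust))

  counts <- c(genes = nrow(exprMatrix(cohort)),
              probes = nrow(betaMatrix(cohort)),
              deg = sum(deg$isDEG), dmp = sum(dmp$isDMP),
              mdegPairs = nrow(mdeg), mimgPairs = nrow(hits),
              prognosticPairs = sum(screenRes$pairs$pairSignificant %||% FALSE))
  report <- new("MimgReport", scores = scores, imas = imas, deg = deg,
                dmp = dmp, mdeg = mdeg, mimg = mimg,
                enrichment = enrichment, screen = screenRes$markers,
                counts = as.integer(setNames(counts, names(counts))),
                provenance = list(
                  contrast = contrast, alpha = alpha,
                  rThreshold = rThreshold, pThreshold = pThreshold,
                  minprop = minprop, seed = seed,
                  package = as.character(utils::packageVersion("epiImmune")),
                  timestampFree = TRUE))
  names(report@counts) <- names(counts)
  if (!is.null(outputDir)) .writeReport(report, outputDir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.writeReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sc <- as.data.frame(report@scores)
  sc <- cbind(sample_id = rownames(sc), sc)
  data.table::fwrite(sc, file.path(dir, "scores.tsv"), sep = "\t")
  data.table::fwrite(report@mdeg, file.path(dir, "pairs_mdeg.tsv"), sep = "\t")
  data.table::fwrite(report@mimg, file.path(dir, "pairs_mimg.tsv"), sep = "\t")
  if (nrow(report@screen))
    data.table::fwrite(report@screen, file.path(dir, "prognostic_screen.tsv"),
                       sep = "\t")
  summ <- list(counts = as.list(setNames(as.integer(report@counts),
                                         names(report@counts))),
               enrichment = lapply(report@enrichment, function(e)
                 if (is.null(e)) NULL
                 else list(statistic = e$statistic, df = e$df, p = e$p)),
               provenance = report@provenance)
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Run the pipeline on several cohorts and intersect the mIMg sets
#'
#' Applies \code{\link{runPipeline}} per cohort (each clustered and screened
#' independently, with labels canonicalized per cohort by IMpS ordering) and
#' intersects the per-cohort mIMg pairs.
#'
#' @param cohorts list of \linkS4class{MethylImmuneCohort} objects.
#' @param ... arguments forwarded to \code{\link{runPipeline}}.
#' @return list(reports = per-cohort \linkS4class{MimgReport} list,
#'   intersected = shared mIMg pair table).
#' @export
runPipelineMulti <- function(cohorts, ...) {
  if (length(cohorts) < 2L) stop("need >= 2 cohorts")
  reports <- lapply(cohorts, runPipeline, ...)
  intersected <- intersectCohorts(lapply(reports, function(r) r@mimg))
  list(reports = reports, intersected = intersected)
}

#' Run the pipeline from a YAML configuration file
#'
#' The YAML lists per-cohort input paths (\code{expression},
#' \code{methylation}, \code{annotation}, \code{clinical}, \code{geneSets},
#' optional \code{panelSigns}), optional \code{thresholds} (\code{r},
#' \code{p}, \code{minprop}, \code{alpha}), a \code{contrast}, a
#' \code{seed} and an \code{outputDir}. With several cohorts the mIMg sets
#' are intersected.
#'
#' @param configPath YAML file path.
#' @return A \linkS4class{MimgReport} (single cohort) or the
#'   \code{\link{runPipelineMulti}} list.
#' @export
runPipelineConfig <- function(configPath) {
  cfg <- yaml::read_yaml(configPath)
  if (is.null(cfg$cohorts)) stop("config must list cohorts")
  loadOne <- function(co) {
    for (f in c("expression", "methylation", "annotation", "clinical",
                "geneSets"))
      if (!is.null(co[[f]]) && !file.exists(co[[f]]))
        stop("missing input file: ", co[[f]])
    cohort <- methylImmuneCohort(
      expression = readMatrix(co$expression),
      methylation = readMatrix(co$methylation, betaRange = "reject"),
      annotation = readAnnotation(co$annotation),
      clinical = readClinical(co$clinical))
    panel <- if (!is.null(co$panelSigns))
      readPanel(co$geneSets, co$panelSigns)
    else readPanel(co$geneSets)
    list(cohort = cohort, panel = panel)
  }
  th <- cfg$thresholds %||% list()
  args <- list(alpha = th$alpha %||% 0.25,
               rThreshold = th$r %||% 0.5,
               pThreshold = th$p %||% 0.05,
               minprop = th$minprop %||% 0.1,
               contrast = unlist(cfg$contrast %||% c("C3", "C2")),
               seed = cfg$seed,
               outputDir = cfg$outputDir)
  loaded <- lapply(cfg$cohorts, loadOne)
  if (length(loaded) == 1L)
    do.call(runPipeline, c(list(cohort = loaded[[1]]$cohort,
                                panel = loaded[[1]]$panel), args))
  else {
    args$outputDir <- NULL
    reports <- lapply(loaded, function(l)
      do.call(runPipeline, c(list(cohort = l$cohort, panel = l$panel), args)))
    list(reports = reports,
         intersected = intersectCohorts(lapply(reports, function(r) r@mimg)))
  }
}
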