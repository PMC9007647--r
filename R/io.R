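#' @importFrom data.table fread fwrite
NULL

#' Read / write a feature-by-sample matrix
#'
#' TSV dialect: UTF-8, first column = feature id, header = sample ids.
#' Round-trip stable to full precision.
#'
#' @param path file path.
#' @param betaRange validate values against [0, 1]: \code{"none"} (default),
#'   \code{"reject"} (error on out-of-range) or \code{"clamp"}.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
readMatrix <- function(path, betaRange = c("none", "reject", "clamp")) {
  betaRange <- match.arg(betaRange)
  dt <- fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature ids in ", path, ": ",
         paste(head(unique(ids[duplicated(ids)]), 3), collapse = ", "))
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in ", path)
  rownames(m) <- ids
  if (betaRange != "none" && any(m < 0 | m > 1, na.rm = TRUE)) {
    if (betaRange == "reject") stop("beta values outside [0, 1] in ", path)
    m <- pmin(pmax(m, 0), 1)
  }
  m
}

#' @rdname readMatrix
#' @param mat matrix to write.
#' @param idColumn name of the feature-id column (default "feature_id").
#' @export
writeMatrix <- function(mat, path, idColumn = "feature_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- idColumn
  fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then the gene ids, tab-separated.
#'
#' @param path file path.
#' @return \code{readGmt}: named list of gene-id vectors (descriptions kept
#'   as the \code{"descriptions"} attribute).
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in ", path)
  attr(sets, "descriptions") <- vapply(parts, `[`, character(1), 2L)
  sets
}

#' @rdname readGmt
#' @param sets named list of gene-id vectors.
#' @param descriptions optional per-set description strings.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe annotation table
#'
#' Expects manifest-style columns \code{probe_id}, \code{gene},
#' \code{gene_region}, \code{cgi_relation}, \code{chromosome}; region and
#' CGI labels must come from the closed vocabularies.
#'
#' @param path TSV path.
#' @return data.frame with rownames = probe ids.
#' @export
readAnnotation <- function(path) {
  df <- fread(path, sep = "\t", header = TRUE, data.table = FALSE,
              colClasses = "character")
  need <- c("probe_id", "gene", "gene_region", "cgi_relation", "chromosome")
  if (!all(need %in% colnames(df)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe ids in ", path)
  bad <- setdiff(unique(df$gene_region), .REGION_VOCAB)
  if (length(bad)) stop("unknown gene_region labels: ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$cgi_relation), .CGI_VOCAB)
  if (length(bad)) stop("unknown cgi_relation labels: ",
                        paste(bad, collapse = ", "))
  rownames(df) <- df$probe_id
  df[, setdiff(colnames(df), "probe_id"), drop = FALSE]
}

#' Read a clinical table
#'
#' Expects a \code{sample_id} column plus \code{OS_time} (> 0),
#' \code{OS_event} (0/1) and any covariate columns; duplicate sample ids are
#' a hard error naming the offender.
#'
#' @param path TSV path.
#' @return data.frame with rownames = sample ids.
#' @export
readClinical <- function(path) {
  df <- fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!"sample_id" %in% colnames(df))
    stop("clinical table must have a sample_id column")
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop("duplicated sample id(s): ", paste(head(dup, 5), collapse = ", "))
  if (!all(c("OS_time", "OS_event") %in% colnames(df)))
    stop("clinical table must have OS_time and OS_event")
  if (any(df$OS_time <= 0, na.rm = TRUE)) stop("OS_time must be positive")
  if (!all(df$OS_event %in% c(0, 1))) stop("OS_event must be 0/1")
  rownames(df) <- df$sample_id
  df[, setdiff(colnames(df), "sample_id"), drop = FALSE]
}

#' Read / write an immune panel
#'
#' The GMT set names follow the convention \code{<category>.<setName>}; the
#' sign map is a JSON object category -> +1/-1 (a default asset ships with
#' the package under \code{extdata/panel_signs.json}).
#'
#' @param gmtPath GMT file of gene sets.
#' @param signsPath JSON sign map; defaults to the shipped asset.
#' @return An \linkS4class{ImmunePanel}.
#' @export
readPanel <- function(gmtPath, signsPath = system.file(
                        "extdata", "panel_signs.json", package = "epiImmune")) {
  sets <- readGmt(gmtPath)
  signs <- unlist(jsonlite::read_json(signsPath))
  parts <- strsplit(names(sets), ".", fixed = TRUE)
  cats <- vapply(parts, `[`, character(1), 1L)
  short <- vapply(parts, function(p) paste(p[-1], collapse = "."), character(1))
  names(sets) <- short
  attr(sets, "descriptions") <- NULL
  immunePanel(sets, setNames(cats, short), signs[.PANEL_CATEGORIES])
}

#' @rdname readPanel
#' @param panel an \linkS4class{ImmunePanel}.
#' @param path output GMT path.
#' @export
writePanel <- function(panel, path) {
  sets <- panelSets(panel)
  cats <- panelCategories(panel)
  named <- setNames(sets, paste(cats[names(sets)], names(sets), sep = "."))
  writeGmt(named, path, descriptions = unname(cats[names(sets)]))
  invisible(path)
}

#' Write a cohort to a directory of pipeline-ready files
#'
#' Writes expression.tsv, methylation.tsv, annotation.tsv, clinical.tsv and
#' panel.gmt (when the cohort carries a panel) in the formats the pipeline
#' reads, so a generated cohort is a drop-in input. The ground truth of a
#' synthetic cohort is written to a separate truth.json sidecar that the
#' pipeline itself never reads.
#'
#' @param cohort a \linkS4class{MethylImmuneCohort}.
#' @param dir output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             methylation = file.path(dir, "methylation.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             clinical = file.path(dir, "clinical.tsv"))
  writeMatrix(exprMatrix(cohort), paths["expression"], "gene_id")
  writeMatrix(betaMatrix(cohort), paths["methylation"], "probe_id")
  ann <- as.data.frame(probeAnnotation(cohort))
  ann <- cbind(probe_id = rownames(ann), ann)
  fwrite(ann, paths["annotation"], sep = "\t", quote = FALSE)
  clin <- as.data.frame(clinicalData(cohort))
  clin <- cbind(sample_id = rownames(clin), clin)
  fwrite(clin, paths["clinical"], sep = "\t", quote = FALSE)
  tr <- cohortTruth(cohort)
  if (!is.null(tr$panel)) {
    paths["panel"] <- file.path(dir, "panel.gmt")
    writePanel(tr$panel, paths["panel"])
  }
  if (length(tr)) {
    paths["truth"] <- file.path(dir, "truth.json")
    side <- list(
      clusterLabels = as.list(setNames(as.character(tr$clusterLabels),
                                       names(tr$clusterLabels))),
      pairs = tr$pairs,
      logHazards = as.list(tr$logHazards),
      cellFractions = as.data.frame(tr$cellFractions),
      referenceProfiles = as.data.frame(tr$referenceProfiles))
    jsonlite::write_json(side, paths["truth"], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

#' Read a cohort from a directory written by \code{writeCohort}
#'
#' @param dir directory containing expression.tsv, methylation.tsv,
#'   annotation.tsv and clinical.tsv.
#' @param betaPolicy out-of-range beta handling, see \code{\link{readMatrix}}.
#' @return A \linkS4class{MethylImmuneCohort} (without ground truth).
#' @export
readCohort <- function(dir, betaPolicy = c("reject", "clamp")) {
  betaPolicy <- match.arg(betaPolicy)
  methylImmuneCohort(
    expression = readMatrix(file.path(dir, "expression.tsv")),
    methylation = readMatrix(file.path(dir, "methylation.tsv"),
                             betaRange = betaPolicy),
    annotation = readAnnotation(file.path(dir, "annotation.tsv")),
    clinical = readClinical(file.path(dir, "clinical.tsv")))
}
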