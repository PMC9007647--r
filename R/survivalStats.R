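#' @importFrom survival Surv survfit survdiff coxph concordance
#' @importFrom stats pchisq pnorm dnorm qlogis setNames coef
#' @importFrom utils head capture.output
NULL

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function: right-continuous,
#' non-increasing, S(0) = 1, dropping only at event times.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @return data.frame with columns time, nRisk, nEvent, nCensor, surv.
#' @export
kmEstimate <- function(time, event) {
  stopifnot(length(time) == length(event), all(time > 0),
            all(event %in% c(0, 1)))
  if (sum(event) == 0) warning("no events: survival curve is flat at 1")
  sf <- survfit(Surv(time, event) ~ 1)
  data.frame(time = sf$time, nRisk = sf$n.risk, nEvent = sf$n.event,
             nCensor = sf$n.censor, surv = sf$surv)
}

#' Log-rank test between groups
#'
#' @param groups group labels (>= 2 groups).
#' @param time,event survival columns.
#' @return list(statistic, df, p).
#' @export
logrankTest <- function(groups, time, event) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) stop("need >= 2 groups")
  sd_ <- survdiff(Surv(time, event) ~ groups)
  df <- length(sd_$n) - 1L
  list(statistic = unname(sd_$chisq), df = df,
       p = pchisq(sd_$chisq, df, lower.tail = FALSE))
}

# Precomputed risk-set structure for repeated two-group log-rank statistics
# on the same survival data (the cutpoint scan evaluates hundreds of splits).
.logrankEngine <- function(time, event) {
  ord <- order(time)
  ts <- time[ord]; es <- event[ord]
  n <- length(ts)
  ut <- unique(ts)
  block <- match(ts, ut)                    # distinct-time block per subject
  first <- match(seq_along(ut), block)      # first sorted index per block
  d <- as.numeric(rowsum(es, block))        # events per block
  atRisk <- n - first + 1                   # subjects with time >= ut[b]
  keep <- d > 0                             # only event times contribute
  list(ord = ord, block = block, first = first, d = d, atRisk = atRisk,
       keep = keep, es = es, n = n)
}

.logrankZengine <- function(eng, g) {
  gs <- as.numeric(g[eng$ord])
  cum <- rev(cumsum(rev(gs)))
  n1 <- cum[eng$first]                      # group-1 subjects at risk
  d1 <- as.numeric(rowsum(gs * eng$es, eng$block))
  k <- eng$keep
  d <- eng$d[k]; n1 <- n1[k]; nt <- eng$atRisk[k]; d1 <- d1[k]
  if (length(d) == 0L) return(0)
  O <- sum(d1)
  E <- sum(d * n1 / nt)
  ok <- nt > 1
  V <- sum((d * (n1 / nt) * (1 - n1 / nt) * (nt - d) / (nt - 1))[ok])
  if (V <= 0) return(0)
  (O - E) / sqrt(V)
}

# Standardized two-group log-rank statistic Z = (O1 - E1)/sqrt(V) for the
# subjects with g == TRUE, computed over distinct event times.
.logrankZ <- function(g, time, event) {
  .logrankZengine(.logrankEngine(time, event), g)
}

#' Optimal survival cutpoint by the maximally selected log-rank statistic
#'
#' Scans every admissible split of a continuous marker (low group: marker <=
#' threshold) leaving at least \code{ceiling(minprop * n)} subjects on each
#' side, computes the standardized two-group log-rank statistic, and returns
#' the split maximizing its absolute value. Ties are broken deterministically
#' towards the smallest threshold.
#'
#' @param marker per-sample marker values (>= 2 distinct values).
#' @param time,event survival columns.
#' @param minprop minimum fraction of samples per side (default 0.1).
#' @return list(threshold, statistic, nLow, nHigh, minprop) of class
#'   \code{"cutpointResult"}.
#' @export
optimalCutpoint <- function(marker, time, event, minprop = 0.1) {
  stopifnot(length(marker) == length(time), length(time) == length(event))
  n <- length(marker)
  vals <- sort(unique(marker))
  if (length(vals) < 2L) stop("marker has fewer than 2 distinct values")
  minSize <- ceiling(minprop * n)
  cand <- vals[-length(vals)]
  nLow <- vapply(cand, function(c) sum(marker <= c), integer(1))
  ok <- nLow >= minSize & (n - nLow) >= minSize
  if (!any(ok))
    stop("no admissible split: increase n or decrease minprop")
  cand <- cand[ok]
  eng <- .logrankEngine(time, event)
  z <- vapply(cand, function(c) .logrankZengine(eng, marker <= c),
              numeric(1))
  best <- which.max(abs(z))   # first max -> smallest threshold
  res <- list(threshold = cand[best], statistic = z[best],
              nLow = sum(marker <= cand[best]),
              nHigh = sum(marker > cand[best]), minprop = minprop)
  class(res) <- "cutpointResult"
  res
}

#' Selection-corrected p-value for a maximally selected log-rank statistic
#'
#' Improved-Bonferroni approximation to the null distribution of the maximum
#' absolute standardized log-rank statistic over all splits within the
#' quantile range [minprop, 1 - minprop]:
#' p = 4*phi(b)/b + phi(b)*(b - 1/b)*log((e2(1-e1))/(e1(1-e2))),
#' clamped to [0, 1]. Without this correction, testing a marker at its own
#' optimal cutpoint is strongly anti-conservative.
#'
#' @param b observed maximum absolute standardized statistic.
#' @param minprop minimum group proportion used in the search (default 0.1).
#' @return Approximate two-sided p-value.
#' @export
maxstatP <- function(b, minprop = 0.1) {
  b <- abs(b)
  e1 <- minprop; e2 <- 1 - minprop
  # the approximation is only sensible for b > 1 (the b - 1/b factor flips
  # sign below); smaller statistics are never significant
  if (b <= 1) return(1)
  p <- 4 * dnorm(b) / b +
    dnorm(b) * (b - 1 / b) * log((e2 * (1 - e1)) / (e1 * (1 - e2)))
  min(max(p, 2 * pnorm(-b)), 1)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling by default; constant
#' covariates are dropped with a warning. Wald confidence intervals.
#'
#' @param covariates data.frame of design columns.
#' @param time,event survival columns.
#' @param ties "efron" (default) or "breslow".
#' @return list of class \code{"coxFitResult"}: \code{coefficients}
#'   (term, beta, HR, lower95, upper95, p), \code{logLik}, \code{ties},
#'   \code{model} (the underlying \code{coxph} object).
#' @export
coxFit <- function(covariates, time, event, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  const <- vapply(covariates, function(z) length(unique(z)) <= 1L, logical(1))
  if (any(const)) {
    warning("dropping constant covariates: ",
            paste(names(covariates)[const], collapse = ", "))
    covariates <- covariates[, !const, drop = FALSE]
  }
  if (ncol(covariates) == 0L) stop("no usable covariates")
  if (sum(event) < ncol(covariates))
    stop("fewer events than covariates")
  df <- cbind(covariates, .time = time, .event = event)
  fit <- coxph(Surv(.time, .event) ~ ., data = df, ties = ties)
  if (any(is.na(coef(fit))))
    stop("Cox fit failed (singular design or separation)")
  sm <- summary(fit)
  co <- data.frame(term = rownames(sm$coefficients),
                   beta = sm$coefficients[, "coef"],
                   HR = sm$coefficients[, "exp(coef)"],
                   lower95 = sm$conf.int[, "lower .95"],
                   upper95 = sm$conf.int[, "upper .95"],
                   p = sm$coefficients[, "Pr(>|z|)"],
                   row.names = NULL, stringsAsFactors = FALSE)
  res <- list(coefficients = co, logLik = fit$loglik[2], ties = ties,
              model = fit)
  class(res) <- "coxFitResult"
  res
}

#' Harrell's concordance index
#'
#' Probability that, of a usable pair, the subject with the higher risk score
#' fails earlier (higher risk = worse outcome); risk ties count 0.5.
#'
#' @param risk per-sample risk scores.
#' @param time,event survival columns.
#' @return C in [0, 1].
#' @export
concordanceIndex <- function(risk, time, event) {
  if (length(unique(time[event == 1])) == 0L &&
      sum(event) == 0L) stop("no usable pairs (no events)")
  cf <- concordance(Surv(time, event) ~ risk, reverse = TRUE)
  if (sum(unlist(cf$count[c("concordant", "discordant", "tied.x")])) == 0)
    stop("no usable pairs")
  unname(cf$concordance)
}

.kmEval <- function(tms, srv, t, leftLimit = FALSE) {
  idx <- if (leftLimit) sum(tms < t) else sum(tms <= t)
  if (idx == 0L) 1 else srv[idx]
}

#' Time-dependent AUC with IPCW
#'
#' Cumulative/dynamic AUC at fixed horizons: cases are subjects with an
#' observed event at or before the horizon, controls those still under
#' observation past it. Inverse-probability-of-censoring weights come from
#' the Kaplan-Meier estimate of the censoring distribution (cases weighted by
#' 1/G(T-), controls by 1/G(t)). With no censoring before the horizon this
#' reduces to the empirical binary-outcome AUC (Mann-Whitney statistic).
#'
#' @param marker per-sample marker (higher = higher risk).
#' @param time,event survival columns.
#' @param horizons evaluation times, each within the observed follow-up.
#' @return Named numeric vector of AUC(t) per horizon.
#' @export
timeDependentAuc <- function(marker, time, event, horizons) {
  stopifnot(length(marker) == length(time))
  if (any(horizons > max(time)))
    stop("horizon beyond the last observed time")
  cens <- survfit(Surv(time, 1 - event) ~ 1)
  out <- setNames(numeric(length(horizons)), paste0("t=", horizons))
  for (k in seq_along(horizons)) {
    t0 <- horizons[k]
    isCase <- time <= t0 & event == 1
    isCtrl <- time > t0
    if (!any(isCase) || !any(isCtrl)) {
      warning("no cases or no controls at horizon ", t0)
      out[k] <- NA_real_
      next
    }
    wCase <- 1 / vapply(time[isCase], function(ti)
      .kmEval(cens$time, cens$surv, ti, leftLimit = TRUE), numeric(1))
    gT <- .kmEval(cens$time, cens$surv, t0)
    mC <- marker[isCase]; mK <- marker[isCtrl]
    cmp <- outer(mC, mK, function(a, b) (a > b) + 0.5 * (a == b))
    out[k] <- sum(wCase * rowSums(cmp)) / (sum(wCase) * length(mK))
  }
  out
}

#' Decision-curve net benefit
#'
#' Net benefit of acting on predicted probabilities at each threshold
#' probability pt: NB(pt) = TP/n - (FP/n) * pt/(1-pt), with the treat-all
#' policy prevalence - (1-prevalence) * pt/(1-pt) and treat-none = 0 as
#' references.
#'
#' @param predictedProb predicted event probabilities in [0, 1].
#' @param outcome observed 0/1 outcomes.
#' @param thresholds threshold probabilities, all in (0, 1).
#' @return data.frame: threshold, netBenefit, treatAll, treatNone.
#' @export
decisionCurve <- function(predictedProb, outcome, thresholds) {
  stopifnot(all(predictedProb >= 0 & predictedProb <= 1),
            all(outcome %in% c(0, 1)))
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly in (0, 1)")
  n <- length(outcome)
  prev <- mean(outcome)
  nb <- vapply(thresholds, function(pt) {
    pos <- predictedProb >= pt
    sum(pos & outcome == 1) / n - sum(pos & outcome == 0) / n * pt / (1 - pt)
  }, numeric(1))
  data.frame(threshold = thresholds, netBenefit = nb,
             treatAll = prev - (1 - prev) * thresholds / (1 - thresholds),
             treatNone = 0)
}

.encodeStage <- function(stage, encoding) {
  lev <- c("I", "II", "III", "IV")
  f <- factor(as.character(stage), levels = lev)
  if (any(is.na(f) & !is.na(stage)))
    f <- factor(as.character(stage))
  if (encoding == "ordinal") as.integer(f) else f
}

#' Prognostic screen of mIMg probes and genes
#'
#' For each marker (the methylation beta of every probe and the expression of
#' every gene in the pair list): find the optimal survival cutpoint, enter
#' the resulting two-level factor (reference = low marker) into a Cox model
#' adjusted for the requested clinical covariates, and flag the marker
#' prognostic when the adjusted Cox p-value is below \code{pThreshold} and —
#' by default — the selection-corrected p-value of the maximally selected
#' statistic is too (\code{selectionAdjust}; without it the screen is
#' anti-conservative because the cutpoint is chosen to maximize group
#' separation). Pairs where BOTH the probe and the gene are prognostic form
#' the headline set. Component failures are recorded per marker without
#' aborting the screen. Mutation-status or other strata are supported via
#' \code{subset}.
#'
#' @param pairs pair table with \code{probe} and \code{gene} columns
#'   (typically the mIMg set).
#' @param expression,methylation cohort matrices.
#' @param clinical clinical table (rownames = sample ids) with OS_time,
#'   OS_event and the adjuster columns.
#' @param adjusters clinical covariates entered alongside the marker
#'   (default age, gender, stage).
#' @param minprop minimum group fraction for the cutpoint search.
#' @param pThreshold significance level (default 0.05).
#' @param selectionAdjust also require the maximal-selection corrected
#'   p < pThreshold (default TRUE).
#' @param stageEncoding "ordinal" (I<II<III<IV as 1..4, default) or "dummy".
#' @param subset optional sample ids restricting the screen (e.g. a mutation
#'   stratum).
#' @return list with \code{markers} (per-marker table: id, type, threshold,
#'   statistic, selectionP, HR, lower95, upper95, coxP, significant, error)
#'   and \code{pairs} (pair table with pairSignificant flag).
#' @export
prognosticScreen <- function(pairs, expression, methylation, clinical,
                             adjusters = c("age", "gender", "stage"),
                             minprop = 0.1, pThreshold = 0.05,
                             selectionAdjust = TRUE,
                             stageEncoding = c("ordinal", "dummy"),
                             subset = NULL) {
  stageEncoding <- match.arg(stageEncoding)
  clinical <- as.data.frame(clinical)
  samp <- rownames(clinical)
  if (!is.null(subset)) samp <- intersect(samp, subset)
  samp <- samp[complete.cases(clinical[samp, c("OS_time", "OS_event",
                                               adjusters), drop = FALSE])]
  cl <- clinical[samp, , drop = FALSE]
  markers <- unique(rbind(
    if (nrow(pairs)) data.frame(id = pairs$gene, type = "gene",
                                stringsAsFactors = FALSE),
    if (nrow(pairs)) data.frame(id = pairs$probe, type = "probe",
                                stringsAsFactors = FALSE)))
  empty <- data.frame(id = character(), type = character(),
                      threshold = numeric(), statistic = numeric(),
                      selectionP = numeric(), HR = numeric(),
                      lower95 = numeric(), upper95 = numeric(),
                      coxP = numeric(), significant = logical(),
                      error = character(), stringsAsFactors = FALSE)
  if (is.null(markers) || nrow(markers) == 0L)
    return(list(markers = empty, pairs = cbind(pairs,
                pairSignificant = logical(nrow(pairs)))))
  adj <- cl[, adjusters, drop = FALSE]
  if ("stage" %in% colnames(adj))
    adj$stage <- .encodeStage(adj$stage, stageEncoding)
  rows <- lapply(seq_len(nrow(markers)), function(i) {
    id <- markers$id[i]
    tryCatch({
      vals <- if (markers$type[i] == "gene") expression[id, samp]
              else methylation[id, samp]
      if (anyNA(vals)) stop("missing marker values")
      cut <- optimalCutpoint(vals, cl$OS_time, cl$OS_event, minprop = minprop)
      grp <- factor(ifelse(vals > cut$threshold, "high", "low"),
                    levels = c("low", "high"))
      cov <- cbind(data.frame(marker = grp), adj)
      fit <- coxFit(cov, cl$OS_time, cl$OS_event)
      mrow <- fit$coefficients[grepl("^marker", fit$coefficients$term), ]
      selP <- maxstatP(cut$statistic, minprop)
      sig <- mrow$p < pThreshold && (!selectionAdjust || selP < pThreshold)
      data.frame(id = id, type = markers$type[i],
                 threshold = cut$threshold, statistic = cut$statistic,
                 selectionP = selP, HR = mrow$HR, lower95 = mrow$lower95,
                 upper95 = mrow$upper95, coxP = mrow$p, significant = sig,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(id = id, type = markers$type[i], threshold = NA_real_,
                 statistic = NA_real_, selectionP = NA_real_, HR = NA_real_,
                 lower95 = NA_real_, upper95 = NA_real_, coxP = NA_real_,
                 significant = FALSE, error = conditionMessage(e),
                 stringsAsFactors = FALSE))
  })
  mk <- do.call(rbind, rows)
  sigOf <- function(id, type) {
    j <- which(mk$id == id & mk$type == type)
    length(j) == 1L && isTRUE(mk$significant[j])
  }
  pairs$pairSignificant <- vapply(seq_len(nrow(pairs)), function(i)
    sigOf(pairs$gene[i], "gene") && sigOf(pairs$probe[i], "probe"),
    logical(1))
  list(markers = mk, pairs = pairs)
}
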