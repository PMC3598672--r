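## Append a provenance record to a count/expression container.
.addStep <- function(x, step, params = list()) {
  metadata(x)$provenance <- c(metadata(x)$provenance,
                              list(list(step = step, params = params)))
  x
}

.endoIdx <- function(x) which(probeClass(x) == "endogenous")

#' Probe-level background correction
#'
#' Subtracts a user-supplied per-probe correction from the raw counts of the
#' listed probes; corrected values that fall below zero are set to 1. Probes
#' without a listed correction are unchanged. Probe-specific correction
#' values are an input table (default empty) because they are
#' platform-lot-specific and must be supplied by the user.
#'
#' @param x a \linkS4class{MiRCountSet}.
#' @param corrections named non-negative numeric vector, probe id to
#'   correction value; may be empty.
#' @return corrected \linkS4class{MiRCountSet}.
#' @export
probeBackgroundCorrect <- function(x, corrections = numeric(0)) {
  stopifnot(is(x, "MiRCountSet"))
  if (length(corrections)) {
    if (is.null(names(corrections)) || any(corrections < 0))
      stop("'corrections' must be a named, non-negative vector")
    unknown <- setdiff(names(corrections), rownames(x))
    if (length(unknown))
      stop("correction listed for unknown probe(s): ",
           paste(unknown, collapse = ", "))
    cts <- counts(x)
    sub <- cts[names(corrections), , drop = FALSE] - corrections
    sub[sub < 0] <- 1
    cts[names(corrections), ] <- sub
    SummarizedExperiment::assay(x, "counts") <- cts
  }
  .addStep(x, "probe_background_correct",
           list(n_corrected = length(corrections)))
}

#' Positive spike-in control normalisation
#'
#' Scales every sample by (cross-sample arithmetic mean of positive-control
#' sums) / (that sample's positive-control sum), absorbing differences in
#' assay efficiency. After scaling, positive sums agree across samples to
#' 1e-9 relative.
#'
#' @param x a \linkS4class{MiRCountSet} with at least one positive-control
#'   probe.
#' @return scaled \linkS4class{MiRCountSet}; the factors are recorded in the
#'   provenance and surface in the \linkS4class{QCReport}.
#' @export
positiveControlNormalize <- function(x) {
  stopifnot(is(x, "MiRCountSet"))
  pos <- which(probeClass(x) == "pos")
  if (!length(pos)) stop("no positive-control probes present")
  sums <- colSums(counts(x)[pos, , drop = FALSE])
  zero <- which(sums <= 0)
  if (length(zero))
    stop("zero positive-control sum in sample(s): ",
         paste(colnames(x)[zero], collapse = ", "))
  factors <- mean(sums) / sums
  SummarizedExperiment::assay(x, "counts") <-
    sweep(counts(x), 2L, factors, `*`)
  .addStep(x, "positive_control_normalize", list(factors = factors))
}

#' Negative-control background thresholding and detection
#'
#' For each sample the background threshold is the mean plus two standard
#' deviations (n-1 denominator) of its eight (or however many) negative
#' controls. The threshold is subtracted from every endogenous count of that
#' sample; the detected set consists of the probes whose subtracted count is
#' non-negative in \emph{every} sample, and all other endogenous probes are
#' removed. With \code{subtract = FALSE} the threshold is used for detection
#' only and the counts are left unsubtracted.
#'
#' @param x a \linkS4class{MiRCountSet} with at least two negative controls.
#' @param subtract keep the background-subtracted counts (default) or use
#'   the threshold for detection only.
#' @return \linkS4class{MiRCountSet} restricted to detected endogenous
#'   probes (control probes are retained); \code{detectedProbes()} returns
#'   the detected ids.
#' @export
negativeBackgroundThreshold <- function(x, subtract = TRUE) {
  stopifnot(is(x, "MiRCountSet"))
  neg <- which(probeClass(x) == "neg")
  if (length(neg) < 2L)
    stop("at least two negative-control probes are required (sd undefined)")
  cts <- counts(x)
  thr <- apply(cts[neg, , drop = FALSE], 2L,
               function(v) mean(v) + 2 * sd(v))
  endo <- .endoIdx(x)
  subMat <- sweep(cts[endo, , drop = FALSE], 2L, thr, `-`)
  detected <- rownames(subMat)[apply(subMat >= 0, 1L, all)]
  if (subtract)
    cts[endo, ] <- pmax(subMat, 0)
  SummarizedExperiment::assay(x, "counts") <- cts
  keep <- probeClass(x) != "endogenous" | rownames(x) %in% detected
  out <- x[keep, ]
  metadata(out)$detected <- detected
  .addStep(out, "negative_background_threshold",
           list(threshold = thr, subtract = subtract,
                n_detected = length(detected)))
}

#' Content normalisation to the detected set
#'
#' Scales each sample so that its total count over the detected endogenous
#' probes equals the cross-sample arithmetic mean of those totals, making
#' every sample carry the same total miRNA code count. Control probes do not
#' contribute to the scaling sum.
#'
#' @param x a \linkS4class{MiRCountSet} whose endogenous probes are the
#'   detected set (i.e. after \code{\link{negativeBackgroundThreshold}}).
#' @return scaled \linkS4class{MiRCountSet}.
#' @export
contentNormalize <- function(x) {
  stopifnot(is(x, "MiRCountSet"))
  endo <- .endoIdx(x)
  if (!length(endo)) stop("no endogenous probes to normalise to")
  totals <- colSums(counts(x)[endo, , drop = FALSE])
  zero <- which(totals <= 0)
  if (length(zero))
    stop("zero detected-set total in sample(s): ",
         paste(colnames(x)[zero], collapse = ", "))
  factors <- mean(totals) / totals
  SummarizedExperiment::assay(x, "counts") <-
    sweep(counts(x), 2L, factors, `*`)
  .addStep(x, "content_normalize", list(factors = factors))
}

#' Minimum-count abundance filter
#'
#' Retains endogenous probes whose normalised counts stay at or above the
#' threshold. The default convention requires the \emph{minimum} across
#' samples to reach the threshold; \code{stat = "mean"} is the selectable
#' alternative reading.
#'
#' @param x a \linkS4class{MiRCountSet}.
#' @param threshold minimum code count (default 100, must be > 0).
#' @param stat per-probe summary compared against the threshold.
#' @return filtered \linkS4class{MiRCountSet} (warns if no probe survives).
#' @export
filterMinCount <- function(x, threshold = 100, stat = c("min", "mean")) {
  stopifnot(is(x, "MiRCountSet"))
  if (threshold <= 0) stop("'threshold' must be > 0")
  stat <- match.arg(stat)
  endo <- .endoIdx(x)
  vals <- counts(x)[endo, , drop = FALSE]
  s <- if (stat == "min") apply(vals, 1L, min) else rowMeans(vals)
  keepIds <- rownames(vals)[s >= threshold]
  if (!length(keepIds))
    warning("no endogenous probe passes the minimum-count filter")
  keep <- probeClass(x) != "endogenous" | rownames(x) %in% keepIds
  out <- x[keep, ]
  metadata(out)$detected <- metadata(x)$detected
  .addStep(out, "filter_min_count",
           list(threshold = threshold, stat = stat,
                n_retained = length(keepIds)))
}

#' Log2 transformation
#'
#' Floors counts at one (consistent with setting negative corrected counts
#' to 1) and takes log2, yielding the expression matrix used by the
#' differential-expression and deconvolution stages. Only endogenous probes
#' are carried forward.
#'
#' @param x a \linkS4class{MiRCountSet}.
#' @return A \linkS4class{MiRExpressionSet}.
#' @export
log2Transform <- function(x) {
  stopifnot(is(x, "MiRCountSet"))
  endo <- .endoIdx(x)
  vals <- log2(pmax(counts(x)[endo, , drop = FALSE], 1))
  prov <- c(metadata(x)$provenance,
            list(list(step = "log2_transform", params = list(floor = 1))))
  MiRExpressionSet(vals, colData = colData(x)[, , drop = FALSE],
                   provenance = prov)
}

#' Run the full preprocessing ladder
#'
#' Applies, in order: probe background correction, positive-control
#' normalisation, negative-control background thresholding with all-samples
#' detection, content normalisation to the detected set, minimum-count
#' filtering, and log2 transformation; and assembles a
#' \linkS4class{QCReport} of the probe attrition and per-sample factors.
#'
#' @param raw a raw \linkS4class{MiRCountSet}.
#' @param corrections per-probe background corrections (default none).
#' @param minCount minimum-count threshold (default 100).
#' @param minStat filter convention, \code{"min"} or \code{"mean"}.
#' @param subtractBackground keep background-subtracted counts (default) or
#'   threshold for detection only.
#' @return list with elements \code{expr} (\linkS4class{MiRExpressionSet})
#'   and \code{qc} (\linkS4class{QCReport}).
#' @export
runPreprocess <- function(raw, corrections = numeric(0), minCount = 100,
                          minStat = "min", subtractBackground = TRUE) {
  stopifnot(is(raw, "MiRCountSet"))
  nEndo <- function(x) length(.endoIdx(x))
  steps <- data.frame(step = "raw", probes = nEndo(raw))
  x <- probeBackgroundCorrect(raw, corrections)
  steps <- rbind(steps, data.frame(step = "probe_background_correct",
                                   probes = nEndo(x)))
  x <- positiveControlNormalize(x)
  posFactors <- metadata(x)$provenance[[length(metadata(x)$provenance)]]$params$factors
  steps <- rbind(steps, data.frame(step = "positive_control_normalize",
                                   probes = nEndo(x)))
  x <- negativeBackgroundThreshold(x, subtract = subtractBackground)
  thr <- metadata(x)$provenance[[length(metadata(x)$provenance)]]$params$threshold
  steps <- rbind(steps, data.frame(step = "negative_background_threshold",
                                   probes = nEndo(x)))
  x <- contentNormalize(x)
  contentFactors <- metadata(x)$provenance[[length(metadata(x)$provenance)]]$params$factors
  steps <- rbind(steps, data.frame(step = "content_normalize",
                                   probes = nEndo(x)))
  x <- filterMinCount(x, threshold = minCount, stat = minStat)
  steps <- rbind(steps, data.frame(step = "filter_min_count",
                                   probes = nEndo(x)))
  expr <- log2Transform(x)
  steps <- rbind(steps, data.frame(step = "log2_transform",
                                   probes = nrow(expr)))
  qc <- new("QCReport", steps = steps, posFactors = posFactors,
            contentFactors = contentFactors, detectionThreshold = thr)
  validObject(qc)
  list(expr = expr, qc = qc)
}

#' Serialise a QC report
#'
#' @param qc a \linkS4class{QCReport}.
#' @param path output path; extension \code{.json} writes JSON, anything
#'   else a human-readable text rendering.
#' @return invisibly, \code{path}.
#' @export
writeQCReport <- function(qc, path) {
  stopifnot(is(qc, "QCReport"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(steps = qc@steps,
           pos_factors = as.list(qc@posFactors),
           content_factors = as.list(qc@contentFactors),
           detection_threshold = as.list(qc@detectionThreshold)),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    writeLines(utils::capture.output(show(qc)), path)
  }
  invisible(path)
}
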