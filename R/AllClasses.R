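#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- rowData
#'   rowData<- colData colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.PROBE_CLASSES <- c("endogenous", "pos", "neg", "hk")

#' MiRCountSet: probe x sample digital counts with probe-class annotation
#'
#' A \linkS4class{SummarizedExperiment} subclass holding an nCounter-style
#' count table. The single assay \code{"counts"} carries non-negative counts
#' (raw counts are integers; normalised intermediates may be real valued).
#' \code{rowData} carries a \code{probe_class} factor over
#' \code{endogenous}, \code{pos} (spike-in positive controls), \code{neg}
#' (negative controls) and \code{hk} (housekeeping mRNAs). Preprocessing
#' steps append their parameters to \code{metadata()$provenance}.
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @export
setClass("MiRCountSet", contains = "SummarizedExperiment")

setValidity("MiRCountSet", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (anyNA(cts)) msg <- c(msg, "counts contain missing values")
    else if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
  }
  if (!"probe_class" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain 'probe_class'")
  else {
    pc <- as.character(rowData(object)$probe_class)
    unknown <- setdiff(unique(pc), .PROBE_CLASSES)
    if (length(unknown))
      msg <- c(msg, paste0("unknown probe class: ",
                           paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a MiRCountSet
#'
#' @param counts numeric matrix, probes x samples, non-negative, with
#'   rownames (probe ids) and colnames (sample ids).
#' @param probeClass character vector, one of \code{"endogenous"},
#'   \code{"pos"}, \code{"neg"}, \code{"hk"} per probe.
#' @param colData optional \code{DataFrame} of per-sample annotation
#'   (e.g. \code{group}, \code{subject}).
#' @return A \linkS4class{MiRCountSet}.
#' @export
MiRCountSet <- function(counts, probeClass, colData = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    stop("'counts' must have probe ids as rownames")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (length(probeClass) != nrow(counts))
    stop("'probeClass' must have one entry per probe")
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(row.names = colnames(counts))
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(probe_class = as.character(probeClass),
                                   row.names = rownames(counts)),
    colData = colData)
  obj <- new("MiRCountSet", se)
  metadata(obj)$provenance <- list()
  validObject(obj)
  obj
}

#' MiRExpressionSet: log2-scale expression of detected, retained probes
#'
#' Holds the assay \code{"log2expr"} for the endogenous probes surviving
#' detection and minimum-count filtering, plus the ordered provenance of the
#' preprocessing steps that produced it in \code{metadata()$provenance}.
#'
#' @export
setClass("MiRExpressionSet", contains = "SummarizedExperiment")

setValidity("MiRExpressionSet", function(object) {
  msg <- character()
  if (!"log2expr" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'log2expr' is required")
  else if (!all(is.finite(SummarizedExperiment::assay(object, "log2expr"))))
    msg <- c(msg, "log2 expression must be finite")
  if (length(msg)) msg else TRUE
})

#' @param log2expr numeric matrix of log2 expression values.
#' @param colData optional per-sample annotation.
#' @param provenance list of applied step records.
#' @rdname MiRExpressionSet-class
#' @export
MiRExpressionSet <- function(log2expr, colData = NULL, provenance = list()) {
  log2expr <- as.matrix(log2expr)
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(row.names = colnames(log2expr))
  se <- SummarizedExperiment(assays = list(log2expr = log2expr),
                             colData = colData)
  obj <- new("MiRExpressionSet", se)
  metadata(obj)$provenance <- provenance
  validObject(obj)
  obj
}

#' CellFractions: sample x cell-type proportion matrix
#'
#' Rows are samples, columns cell types; each row sums to one (checked to
#' 1e-6) and entries are non-negative. \code{source} records whether the
#' fractions are raw leukocyte differentials or a grouped scheme (e.g.
#' granulocytes / PBMC).
#'
#' @slot fractions numeric matrix of proportions on the 0-1 scale.
#' @slot source character, free-text origin tag.
#' @export
setClass("CellFractions",
         representation(fractions = "matrix", source = "character"))

setValidity("CellFractions", function(object) {
  f <- object@fractions
  msg <- character()
  if (is.null(colnames(f))) msg <- c(msg, "cell types must be named")
  if (anyNA(f)) msg <- c(msg, "fractions contain missing values")
  else {
    if (any(f < 0)) msg <- c(msg, "fractions must be non-negative")
    if (any(abs(rowSums(f) - 1) > 1e-6))
      msg <- c(msg, "each row must sum to 1 (within 1e-6)")
  }
  if (length(msg)) msg else TRUE
})

#' @param fractions numeric matrix (samples x cell types); rows are
#'   renormalised to sum to one.
#' @param source origin tag.
#' @rdname CellFractions-class
#' @export
CellFractions <- function(fractions, source = "raw") {
  fractions <- as.matrix(fractions)
  if (any(fractions < 0, na.rm = TRUE))
    stop("cell fractions must be non-negative")
  rs <- rowSums(fractions)
  if (any(!is.finite(rs)) || any(rs <= 0))
    stop("each sample must have a positive fraction total")
  fractions <- fractions / rs
  if (is.null(rownames(fractions)))
    rownames(fractions) <- paste0("S", seq_len(nrow(fractions)))
  new("CellFractions", fractions = fractions, source = source)
}

#' QCReport: probe attrition and scale factors along the preprocessing ladder
#'
#' @slot steps data.frame with columns \code{step} and \code{probes}, the
#'   number of endogenous probes retained after each step (non-increasing).
#' @slot posFactors per-sample positive-control scale factors.
#' @slot contentFactors per-sample content-normalisation scale factors.
#' @slot detectionThreshold per-sample negative-control background threshold
#'   (mean + 2 sd of the negative controls).
#' @export
setClass("QCReport",
         representation(steps = "data.frame", posFactors = "numeric",
                        contentFactors = "numeric",
                        detectionThreshold = "numeric"))

setValidity("QCReport", function(object) {
  p <- object@steps$probes
  if (length(p) > 1L && any(diff(p) > 0))
    "retained probe counts must be non-increasing across steps"
  else TRUE
})

#' CellRegressionFit: zero-intercept regression of expression on fractions
#'
#' Per-group least squares of an expression vector onto the cell-fraction
#' matrix through the origin, so each coefficient is the expression
#' attributable to one cell type at fraction one.
#'
#' @slot group group label the fit belongs to.
#' @slot coefficients named per-cell-type coefficients.
#' @slot se per-cell-type standard errors.
#' @slot n number of samples in the group.
#' @slot df residual degrees of freedom (n - K).
#' @slot sigma residual standard deviation.
#' @slot residuals residual vector.
#' @export
setClass("CellRegressionFit",
         representation(group = "character", coefficients = "numeric",
                        se = "numeric", n = "integer", df = "integer",
                        sigma = "numeric", residuals = "numeric"))

#' DEFit: per-probe two-group fits prior to variance moderation
#'
#' @slot coefficients per-probe log2 fold change (level 2 minus level 1).
#' @slot stdevUnscaled per-probe unscaled coefficient standard deviation
#'   (standard error divided by the residual sd).
#' @slot sigma per-probe residual standard deviation.
#' @slot df per-probe residual degrees of freedom.
#' @slot labels the two group levels, in contrast order.
#' @slot robust whether robust (Huber IRLS) fitting was used.
#' @slot fallback probe ids where the robust fit fell back to ordinary
#'   least squares.
#' @export
setClass("DEFit",
         representation(coefficients = "numeric", stdevUnscaled = "numeric",
                        sigma = "numeric", df = "numeric",
                        labels = "character", robust = "logical",
                        fallback = "character"))

#' SimulatedCohort: synthetic blood miRNA study with known ground truth
#'
#' @slot counts \linkS4class{MiRCountSet} including control probes.
#' @slot fractions true \linkS4class{CellFractions}.
#' @slot metadata data.frame with \code{sample}, \code{group}
#'   (HC / pre / post) and \code{subject} (pre/post pairing).
#' @slot truth list: \code{cellMeans} (probe x cell type x group),
#'   \code{expected} expected endogenous counts, \code{libsize} factors.
#' @slot config the generating \code{simConfig} list.
#' @slot seed integer master seed.
#' @export
setClass("SimulatedCohort",
         representation(counts = "MiRCountSet", fractions = "CellFractions",
                        metadata = "data.frame", truth = "list",
                        config = "list", seed = "integer"))

setValidity("SimulatedCohort", function(object) {
  md <- object@metadata
  msg <- character()
  pre <- md$subject[md$group == "pre"]
  post <- md$subject[md$group == "post"]
  if (!setequal(pre, post) || anyDuplicated(pre) || anyDuplicated(post))
    msg <- c(msg, "each asthmatic subject must contribute exactly one pre and one post sample")
  if (length(msg)) msg else TRUE
})
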