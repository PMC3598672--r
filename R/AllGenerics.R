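#' Accessors for bloodmiR classes
#'
#' \code{probeClass} returns the per-probe class annotation;
#' \code{counts} the count assay; \code{log2expr} the log2 expression assay;
#' \code{fractions} the sample x cell-type proportion matrix;
#' \code{cellTypes} its column names; \code{provenance} the ordered list of
#' applied preprocessing steps; \code{detectedProbes} the ids of probes above
#' background in every sample.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("probeClass", function(x) standardGeneric("probeClass"))

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("log2expr", function(x) standardGeneric("log2expr"))

#' @rdname accessors
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))

#' @rdname accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("detectedProbes", function(x) standardGeneric("detectedProbes"))

#' @rdname accessors
#' @export
setMethod("probeClass", "MiRCountSet",
          function(x) as.character(rowData(x)$probe_class))

#' @rdname accessors
#' @export
setMethod("counts", "MiRCountSet",
          function(x) SummarizedExperiment::assay(x, "counts"))

#' @rdname accessors
#' @export
setMethod("log2expr", "MiRExpressionSet",
          function(x) SummarizedExperiment::assay(x, "log2expr"))

#' @rdname accessors
#' @export
setMethod("fractions", "CellFractions", function(x) x@fractions)

#' @rdname accessors
#' @export
setMethod("cellTypes", "CellFractions", function(x) colnames(x@fractions))

#' @rdname accessors
#' @export
setMethod("provenance", "MiRCountSet",
          function(x) metadata(x)$provenance)

#' @rdname accessors
#' @export
setMethod("provenance", "MiRExpressionSet",
          function(x) metadata(x)$provenance)

#' @rdname accessors
#' @export
setMethod("detectedProbes", "MiRCountSet",
          function(x) metadata(x)$detected)

setMethod("show", "MiRCountSet", function(object) {
  pc <- table(factor(probeClass(object), levels = .PROBE_CLASSES))
  cat("MiRCountSet:", nrow(object), "probes x", ncol(object), "samples\n")
  cat("  probe classes:",
      paste(sprintf("%s=%d", names(pc), pc), collapse = ", "), "\n")
  steps <- vapply(provenance(object), `[[`, "", "step")
  if (length(steps))
    cat("  provenance:", paste(steps, collapse = " -> "), "\n")
})

setMethod("show", "MiRExpressionSet", function(object) {
  cat("MiRExpressionSet:", nrow(object), "probes x", ncol(object),
      "samples (log2 scale)\n")
  steps <- vapply(provenance(object), `[[`, "", "step")
  if (length(steps))
    cat("  provenance:", paste(steps, collapse = " -> "), "\n")
})

setMethod("show", "CellFractions", function(object) {
  f <- fractions(object)
  cat("CellFractions:", nrow(f), "samples x", ncol(f),
      "cell types [", object@source, "]\n")
  cat("  cell types:", paste(colnames(f), collapse = ", "), "\n")
  cat("  column means:",
      paste(sprintf("%.3f", colMeans(f)), collapse = ", "), "\n")
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport\n")
  for (i in seq_len(nrow(object@steps)))
    cat(sprintf("  %-28s %d probes\n", object@steps$step[i],
                object@steps$probes[i]))
  cat("  positive-control factors: ",
      paste(sprintf("%.3f", object@posFactors), collapse = ", "), "\n",
      sep = "")
  cat("  content factors:          ",
      paste(sprintf("%.3f", object@contentFactors), collapse = ", "), "\n",
      sep = "")
})

setMethod("show", "CellRegressionFit", function(object) {
  cat("CellRegressionFit [group ", object@group, ", n=", object@n,
      ", df=", object@df, "]\n", sep = "")
  print(round(rbind(coef = object@coefficients, se = object@se), 4))
})

setMethod("show", "SimulatedCohort", function(object) {
  md <- object@metadata
  cat("SimulatedCohort:", nrow(md), "samples (",
      sum(md$group == "HC"), "HC,", sum(md$group == "pre"), "pre,",
      sum(md$group == "post"), "post ), seed", object@seed, "\n")
  show(object@counts)
})
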