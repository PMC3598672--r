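#' Collapse technical qPCR replicates
#'
#' Averages the replicate wells of every (sample, assay) pair and censors
#' measurements whose collapsed mean Ct exceeds 35 cycles, the detection
#' limit of the assay. Censoring is applied to the collapsed mean, not per
#' well, because it is the measurement that is below detection. A missing
#' replicate (fewer wells than the modal replicate count) is tolerated with
#' a warning.
#'
#' @param ctTable data.frame with columns sample, assay, class, replicate,
#'   ct (as from \code{\link{readCtTable}} or
#'   \code{\link{simulateCtTable}}).
#' @param ctLimit detection limit in cycles (default 35).
#' @return data.frame: sample, assay, class, n_wells, mean_ct, censored.
#' @export
collapseReplicates <- function(ctTable, ctLimit = 35) {
  req <- c("sample", "assay", "class", "replicate", "ct")
  if (!all(req %in% colnames(ctTable)))
    stop("Ct table must have columns: ", paste(req, collapse = ", "))
  if (any(ctTable$ct <= 0)) stop("Ct values must be positive")
  key <- interaction(ctTable$sample, ctTable$assay, drop = TRUE)
  agg <- do.call(rbind, lapply(split(ctTable, key), function(d) {
    data.frame(sample = d$sample[1L], assay = d$assay[1L],
               class = d$class[1L], n_wells = nrow(d),
               mean_ct = mean(d$ct), stringsAsFactors = FALSE)
  }))
  if (length(unique(agg$n_wells)) > 1L)
    warning("unequal replicate counts across (sample, assay) pairs")
  agg$censored <- agg$mean_ct > ctLimit
  rownames(agg) <- NULL
  agg[order(agg$sample, agg$assay), ]
}

#' Delta-Ct relative quantification
#'
#' For each sample, subtracts the mean Ct of the reference small-RNA assays
#' from the target's collapsed Ct: \eqn{\Delta Ct = Ct_{target} -
#' mean(Ct_{refs})}; relative expression is \eqn{2^{-\Delta Ct}}. Samples
#' with any censored reference are excluded (with a message naming them);
#' censored targets keep their flag and carry no \eqn{\Delta Ct}.
#'
#' @param collapsed output of \code{\link{collapseReplicates}}.
#' @param references names of the reference assays (default RNU44, RNU6B).
#' @return data.frame: sample, assay, mean_ct, censored, delta_ct,
#'   rel_expr; target rows only.
#' @export
deltaCt <- function(collapsed, references = c("RNU44", "RNU6B")) {
  miss <- setdiff(references, unique(collapsed$assay))
  if (length(miss))
    stop("reference assay(s) absent: ", paste(miss, collapse = ", "))
  out <- list()
  for (s in unique(collapsed$sample)) {
    d <- collapsed[collapsed$sample == s, ]
    refs <- d[d$assay %in% references, ]
    targets <- d[!d$assay %in% references, ]
    if (nrow(refs) < length(references)) {
      message("sample ", s, " excluded: missing reference assay")
      next
    }
    if (any(refs$censored)) {
      message("sample ", s, " excluded: censored reference assay (",
              paste(refs$assay[refs$censored], collapse = ", "), ")")
      next
    }
    refMean <- mean(refs$mean_ct)
    dct <- ifelse(targets$censored, NA_real_, targets$mean_ct - refMean)
    out[[s]] <- data.frame(sample = s, assay = targets$assay,
                           mean_ct = targets$mean_ct,
                           censored = targets$censored,
                           delta_ct = dct, rel_expr = 2^(-dct),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cell-specific regression of qPCR relative expression
#'
#' Feeds the delta-Ct results into the same zero-intercept cell-regression
#' and permutation machinery used for the count-based expression: the
#' normalised relative expression (\eqn{2^{-\Delta Ct}} by default, or
#' \eqn{\Delta Ct} itself with \code{value = "delta"}) of one target assay
#' is regressed onto the cell fractions of each group and the per-cell-type
#' contrast is referenced to a permutation null. Censored samples are
#' dropped.
#'
#' @param deltaResults output of \code{\link{deltaCt}}.
#' @param fractions \linkS4class{CellFractions} whose rows cover the
#'   samples.
#' @param labels named two-level group vector (names = sample ids) or a
#'   vector aligned with the fraction rows.
#' @param assay target assay (default: the single target present).
#' @param value regress \code{"relative"} expression or the \code{"delta"}
#'   Ct itself.
#' @param B,seed permutation parameters.
#' @return as \code{\link{permutationTest}}.
#' @export
qpcrCellRegression <- function(deltaResults, fractions, labels,
                               assay = NULL,
                               value = c("relative", "delta"),
                               B = 1000L, seed = 1L) {
  value <- match.arg(value)
  if (is.null(assay)) {
    assay <- unique(deltaResults$assay)
    if (length(assay) != 1L)
      stop("multiple targets present; supply 'assay'")
  }
  d <- deltaResults[deltaResults$assay == assay & !deltaResults$censored, ]
  if (!nrow(d)) stop("no uncensored measurements for assay ", assay)
  X <- if (is(fractions, "CellFractions")) fractions(fractions)
       else as.matrix(fractions)
  if (is.null(rownames(X)))
    stop("fraction rows must be named by sample")
  miss <- setdiff(d$sample, rownames(X))
  if (length(miss))
    stop("no fractions for sample(s): ", paste(miss, collapse = ", "))
  lab <- if (!is.null(names(labels))) labels[d$sample]
         else stats::setNames(labels, rownames(X))[d$sample]
  y <- if (value == "relative") d$rel_expr else d$delta_ct
  permutationTest(y, X[d$sample, , drop = FALSE], lab, B = B, seed = seed)
}
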