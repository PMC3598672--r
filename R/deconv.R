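#' Collapse leukocyte differentials into cell-population fractions
#'
#' The default scheme mirrors the small-cohort grouping used for
#' whole-blood deconvolution: neutrophils, eosinophils and basophils are
#' added into a granulocyte population, lymphocytes and monocytes into a
#' PBMC population. Rows are renormalised to sum to one (printed
#' differentials need not close to 100\%). The identity scheme keeps the
#' five classes.
#'
#' @param differentials matrix or data.frame (samples x leukocyte classes)
#'   of percentages; a \code{sample} column is used for row names if
#'   present.
#' @param scheme named list mapping population name to the class columns it
#'   sums, or \code{"identity"} to keep every class.
#' @return A \linkS4class{CellFractions} on the 0-1 scale.
#' @export
groupCellFractions <- function(differentials,
                               scheme = list(
                                 granulocytes = c("neutrophils",
                                                  "eosinophils",
                                                  "basophils"),
                                 PBMC = c("lymphocytes", "monocytes"))) {
  df <- as.data.frame(differentials)
  rn <- if ("sample" %in% colnames(df)) df$sample else rownames(df)
  df <- df[, setdiff(colnames(df), "sample"), drop = FALSE]
  if (identical(scheme, "identity"))
    scheme <- as.list(stats::setNames(colnames(df), colnames(df)))
  miss <- setdiff(unlist(scheme), colnames(df))
  if (length(miss))
    stop("missing leukocyte class column(s): ", paste(miss, collapse = ", "))
  if (any(as.matrix(df[, unlist(scheme)]) < 0))
    stop("leukocyte percentages must be non-negative")
  m <- vapply(scheme,
              function(cols) rowSums(df[, cols, drop = FALSE]),
              numeric(nrow(df)))
  if (nrow(df) == 1L) m <- matrix(m, nrow = 1L,
                                  dimnames = list(NULL, names(scheme)))
  rownames(m) <- rn
  CellFractions(m, source = "grouped")
}

## Zero-intercept least squares core; returns NULL on rank deficiency.
.fitOriginCore <- function(y, X) {
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  beta <- drop(backsolve(R, forwardsolve(t(R), crossprod(X, y))))
  res <- drop(y - X %*% beta)
  df <- length(y) - ncol(X)
  sigma2 <- if (df > 0) sum(res^2) / df else NA_real_
  inv <- chol2inv(R)
  list(beta = beta, se = sqrt(diag(inv) * sigma2), res = res,
       sigma = sqrt(sigma2), df = df)
}

#' Zero-intercept regression of expression onto cell fractions
#'
#' Least squares through the origin of one group's expression values on its
#' cell-fraction matrix: \eqn{\hat\beta = (X^\top X)^{-1} X^\top y}. The
#' zero intercept encodes the mixture assumption that zero cell frequency
#' contributes zero expression, so \eqn{\hat\beta_k} is the mean expression
#' attributable to cell type k (per unit fraction; divide by 100 for the
#' per-percentage-point reading). Standard errors use the residual variance
#' on \eqn{n - K} degrees of freedom.
#'
#' @param expr numeric expression vector for the group's samples.
#' @param fractions \linkS4class{CellFractions} (or matrix) for the same
#'   samples.
#' @param group group label stored in the fit.
#' @return A \linkS4class{CellRegressionFit}.
#' @export
fitCellRegression <- function(expr, fractions, group = "g") {
  X <- if (is(fractions, "CellFractions")) fractions(fractions)
       else as.matrix(fractions)
  y <- as.numeric(expr)
  if (length(y) != nrow(X))
    stop("'expr' must have one value per fraction row")
  K <- ncol(X)
  if (length(y) < K + 1L)
    warning("fewer than K + 1 samples; standard errors are unreliable")
  fit <- .fitOriginCore(y, X)
  if (is.null(fit))
    stop("cell-fraction matrix is rank deficient; consider merging cell types")
  new("CellRegressionFit", group = as.character(group),
      coefficients = stats::setNames(fit$beta, colnames(X)),
      se = stats::setNames(fit$se, colnames(X)),
      n = length(y), df = as.integer(fit$df), sigma = fit$sigma,
      residuals = fit$res)
}

## Vectorised statistic core used by the permutation loop. A relative
## tolerance absorbs float noise from exact-fit degeneracies (e.g. constant
## expression), where coefficients and SEs are both zero up to rounding.
.cssamT <- function(b1, se1, n1, b2, se2, n2) {
  pooled <- sqrt((n1 * se1^2 + n2 * se2^2) / (n1 + n2))
  tol <- 1e-12 * (1 + pmax(abs(b1), abs(b2)))
  degenerate <- !is.na(pooled) & pooled <= tol
  t <- ifelse(!degenerate, (b2 - b1) / pooled,
              ifelse(abs(b2 - b1) <= tol, 0, sign(b2 - b1) * Inf))
  list(t = t, pooled = pooled)
}

#' Between-group cell-specific contrast statistic
#'
#' Wald-like contrast of the per-group cell-type coefficients,
#' \deqn{t_{k21} = (\hat\beta_{k2} - \hat\beta_{k1}) / se(\hat\beta_{k21}),}
#' with the sample-size-weighted pooled standard error
#' \deqn{se(\hat\beta_{k21}) = \sqrt{(n_1 se(\hat\beta_{k1})^2 +
#'   n_2 se(\hat\beta_{k2})^2) / (n_1 + n_2)}.}
#' The statistic is exactly antisymmetric under group exchange. A zero
#' pooled SE yields t = 0 for equal coefficients and signed infinity (with
#' a warning) otherwise.
#'
#' @param fit1,fit2 \linkS4class{CellRegressionFit} for groups 1 and 2.
#' @param cellType cell type(s) to contrast; default all shared ones.
#' @return data.frame: cell_type, beta1, se1, beta2, se2, pooled_se, t.
#' @export
cssamStatistic <- function(fit1, fit2, cellType = NULL) {
  stopifnot(is(fit1, "CellRegressionFit"), is(fit2, "CellRegressionFit"))
  if (is.null(cellType))
    cellType <- intersect(names(fit1@coefficients),
                          names(fit2@coefficients))
  miss <- setdiff(cellType, intersect(names(fit1@coefficients),
                                      names(fit2@coefficients)))
  if (length(miss))
    stop("cell type(s) absent from both fits: ",
         paste(miss, collapse = ", "))
  b1 <- fit1@coefficients[cellType]; se1 <- fit1@se[cellType]
  b2 <- fit2@coefficients[cellType]; se2 <- fit2@se[cellType]
  st <- .cssamT(b1, se1, fit1@n, b2, se2, fit2@n)
  if (any(is.infinite(st$t)))
    warning("zero pooled standard error with unequal coefficients; ",
            "statistic is signed infinity")
  data.frame(cell_type = cellType, beta1 = unname(b1), se1 = unname(se1),
             beta2 = unname(b2), se2 = unname(se2),
             pooled_se = unname(st$pooled), t = unname(st$t),
             row.names = NULL, stringsAsFactors = FALSE)
}

## One relabelled statistic vector; NULL when a group fit is rank deficient.
.permStat <- function(y, X, lab2mask) {
  f1 <- .fitOriginCore(y[!lab2mask], X[!lab2mask, , drop = FALSE])
  f2 <- .fitOriginCore(y[lab2mask], X[lab2mask, , drop = FALSE])
  if (is.null(f1) || is.null(f2)) return(NULL)
  .cssamT(f1$beta, f1$se, sum(!lab2mask), f2$beta, f2$se, sum(lab2mask))$t
}

#' Permutation test of cell-specific expression differences
#'
#' Computes the observed contrast statistic per cell type, then rebuilds its
#' empirical null by reshuffling the two group labels across samples B times
#' (each sample's expression/fraction pair travels intact, the only
#' exchangeable reading of the null). The two-sided empirical p-value uses
#' the add-one convention
#' \deqn{p = (1 + \#\{|t_{perm}| \ge |t_{obs}|\}) / (B + 1),}
#' so the smallest attainable p is \eqn{1/(B+1)}. Permutations whose group
#' fits are rank deficient are redrawn (and counted in
#' \code{attr(, "resampled")}).
#'
#' @param expr numeric expression vector over the samples of both groups.
#' @param fractions \linkS4class{CellFractions} (or matrix) for the same
#'   samples.
#' @param labels two-level factor; level order defines the contrast
#'   (group 2 minus group 1).
#' @param B number of permutations (default 1000).
#' @param seed integer seed.
#' @return data.frame (one row per cell type): cell_type, beta1, se1,
#'   beta2, se2, pooled_se, t, p_perm, B, seed.
#' @export
permutationTest <- function(expr, fractions, labels, B = 1000L, seed = 1L) {
  X <- if (is(fractions, "CellFractions")) fractions(fractions)
       else as.matrix(fractions)
  y <- as.numeric(expr)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two label levels are required")
  if (length(y) != nrow(X) || length(labels) != length(y))
    stop("expression, fractions and labels must align")
  if (B < 1L) stop("'B' must be >= 1")
  seed <- .assertScalarSeed(seed)
  lab2 <- labels == levels(labels)[2L]
  f1 <- fitCellRegression(y[!lab2], X[!lab2, , drop = FALSE],
                          group = levels(labels)[1L])
  f2 <- fitCellRegression(y[lab2], X[lab2, , drop = FALSE],
                          group = levels(labels)[2L])
  obs <- cssamStatistic(f1, f2)
  K <- nrow(obs)
  tperm <- matrix(NA_real_, B, K)
  resampled <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        tb <- .permStat(y, X, sample(lab2))
        if (!is.null(tb)) break
        resampled <- resampled + 1L
        if (resampled > 100L * B)
          stop("permutation fits persistently rank deficient")
      }
      tperm[b, ] <- tb
    }
  })
  p <- vapply(seq_len(K), function(k) {
    (1 + sum(abs(tperm[, k]) >= abs(obs$t[k]))) / (B + 1)
  }, numeric(1L))
  out <- cbind(obs, p_perm = p, B = B, seed = seed)
  attr(out, "tperm") <- tperm
  attr(out, "resampled") <- resampled
  if (resampled > 0L)
    message(resampled, " rank-deficient permutation(s) redrawn")
  out
}

#' Cell-specific contrast over a set of probes
#'
#' Runs \code{\link{permutationTest}} for each requested probe of an
#' expression matrix, returning a long, bar-plot-ready table of per-group
#' coefficients, contrast statistics and permutation p-values. Probe-level
#' seeds are derived deterministically from \code{seed}.
#'
#' @param expr \linkS4class{MiRExpressionSet} or log2 matrix.
#' @param fractions \linkS4class{CellFractions} for the contrasted samples.
#' @param labels two-level factor over those samples.
#' @param probes probe ids (must exist in \code{expr}).
#' @param B permutations per probe.
#' @param seed integer master seed.
#' @param coefScale \code{"unit"} reports coefficients per unit fraction;
#'   \code{"percent"} divides coefficients and SEs by 100, the
#'   per-percentage-point reading (the contrast statistic is invariant).
#' @return data.frame: probe, cell_type, beta1, se1, beta2, se2, pooled_se,
#'   t, p_perm, B, seed.
#' @export
deconvolveContrast <- function(expr, fractions, labels, probes, B = 1000L,
                               seed = 1L, coefScale = c("unit", "percent")) {
  coefScale <- match.arg(coefScale)
  E <- if (is(expr, "MiRExpressionSet")) log2expr(expr) else as.matrix(expr)
  miss <- setdiff(probes, rownames(E))
  if (length(miss))
    stop("probe(s) not in expression matrix: ", paste(miss, collapse = ", "))
  res <- lapply(seq_along(probes), function(i) {
    out <- permutationTest(E[probes[i], ], fractions, labels, B = B,
                           seed = .deriveSeed(seed, i))
    cbind(probe = probes[i], as.data.frame(out))
  })
  out <- do.call(rbind, res)
  if (coefScale == "percent") {
    sc <- c("beta1", "se1", "beta2", "se2", "pooled_se")
    out[sc] <- out[sc] / 100
  }
  rownames(out) <- NULL
  out
}
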