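## Vectorised ordinary two-group fit: pooled-variance difference of means.
.fitOrdinary <- function(E, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(E[, idx1, drop = FALSE])
  m2 <- rowMeans(E[, idx2, drop = FALSE])
  ss <- rowSums((E[, idx1, drop = FALSE] - m1)^2) +
        rowSums((E[, idx2, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2L
  list(coef = m2 - m1, sigma = sqrt(ss / df),
       su = rep(sqrt(1 / n1 + 1 / n2), nrow(E)), df = rep(df, nrow(E)))
}

## Huber IRLS fit of one probe on [1, group2 indicator]; falls back to
## ordinary least squares (signalled by NULL) when the robust fit cannot be
## computed (e.g. zero residual scale).
.fitHuberProbe <- function(y, g2, k = 1.345, maxit = 50L, acc = 1e-8) {
  X <- cbind(1, as.numeric(g2))
  fit <- tryCatch(
    MASS::rlm(X, y, psi = MASS::psi.huber, k = k, maxit = maxit, acc = acc),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit) || !isTRUE(fit$converged) || !is.finite(fit$s) ||
      fit$s <= 0)
    return(NULL)
  w <- fit$w
  XtWX <- crossprod(X * w, X)
  inv <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(inv)) return(NULL)
  list(coef = unname(fit$coefficients[2L]), sigma = fit$s,
       su = sqrt(inv[2L, 2L]))
}

#' Per-probe two-group linear fits
#'
#' Fits, for every probe, the difference in mean log2 expression between the
#' second and first label level. The default robust path uses iteratively
#' reweighted least squares with Huber weights (tuning constant 1.345, at
#' most 50 iterations, convergence tolerance 1e-8); probes where the robust
#' fit fails (for example constant expression, which leaves the residual
#' scale undefined) fall back to the ordinary fit with a warning. The
#' ordinary path is the pooled-variance two-sample estimate.
#'
#' @param expr a \linkS4class{MiRExpressionSet} or log2 matrix
#'   (probes x samples).
#' @param labels two-level factor (or character) over the samples; the
#'   coefficient is level 2 minus level 1.
#' @param robust use Huber IRLS (default) or ordinary least squares.
#' @return A \linkS4class{DEFit}.
#' @export
fitTwoGroup <- function(expr, labels, robust = TRUE) {
  E <- if (is(expr, "MiRExpressionSet")) log2expr(expr) else as.matrix(expr)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L)
    stop("exactly two label levels are required")
  if (length(labels) != ncol(E))
    stop("'labels' must have one entry per sample")
  idx1 <- which(labels == levels(labels)[1L])
  idx2 <- which(labels == levels(labels)[2L])
  if (length(idx1) < 2L || length(idx2) < 2L)
    stop("each group needs at least two samples")
  ord <- .fitOrdinary(E, idx1, idx2)
  fallback <- character()
  if (robust) {
    g2 <- labels == levels(labels)[2L]
    for (p in seq_len(nrow(E))) {
      rf <- .fitHuberProbe(E[p, ], g2)
      if (is.null(rf)) {
        fallback <- c(fallback, rownames(E)[p])
      } else {
        ord$coef[p] <- rf$coef
        ord$sigma[p] <- rf$sigma
        ord$su[p] <- rf$su
      }
    }
    if (length(fallback))
      warning(length(fallback),
              " probe(s) fell back to the ordinary fit: ",
              paste(utils::head(fallback, 5L), collapse = ", "),
              if (length(fallback) > 5L) ", ...")
  }
  names(ord$coef) <- if (!is.null(rownames(E))) rownames(E)
                     else paste0("probe", seq_len(nrow(E)))
  new("DEFit", coefficients = ord$coef, stdevUnscaled = unname(ord$su),
      sigma = unname(ord$sigma), df = as.numeric(ord$df),
      labels = levels(labels), robust = robust, fallback = fallback)
}

## Moment-matching fit of a scaled inverse chi-square prior to the residual
## variances: log s^2 is matched to its theoretical mean and variance under
## the hierarchical model, and the trigamma equation is inverted for the
## prior df. No positive solution means the variances are consistent with a
## single common value, i.e. infinite prior df.
.fitVariancePrior <- function(s2, df) {
  ok <- df > 0 & s2 > 0
  if (!any(ok))
    stop("all residual variances are zero or without df; ",
         "use the ordinary t-statistic instead")
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(df[ok] / 2))
  ## no positive solution: variances consistent with a common value, whose
  ## natural estimate (equal df) is the arithmetic mean
  if (is.na(evar) || evar <= 0)
    return(list(d0 = Inf, s02 = mean(s2[ok])))
  y <- .trigammaInverse(evar)
  list(d0 = 2 * y, s02 = exp(emean + digamma(y) - log(y)))
}

#' Empirical-Bayes variance moderation and moderated t-statistics
#'
#' Shrinks each probe's residual variance toward an ensemble prior estimated
#' by moment matching on the log residual variances (digamma/trigamma
#' inversion). The posterior variance is
#' \deqn{\tilde s^2 = (d_0 s_0^2 + df\, s^2) / (d_0 + df),}
#' the moderated t is the coefficient over its posterior standard error, and
#' p-values use a t distribution on \eqn{df + d_0} degrees of freedom.
#' \code{priorDf = 0} recovers the ordinary t exactly; \code{priorDf = Inf}
#' pools every variance to \eqn{s_0^2}.
#'
#' @param fit a \linkS4class{DEFit} over at least 10 probes.
#' @param priorDf optional override of the prior degrees of freedom
#'   \eqn{d_0} (\code{NULL} estimates it).
#' @param priorVar optional override of the prior variance \eqn{s_0^2}.
#' @return data.frame (one row per probe): logFC, t, p, df.total, sigma,
#'   posterior sd; the estimated \code{priorDf} and \code{priorVar} are
#'   attached as attributes.
#' @export
ebayesModerate <- function(fit, priorDf = NULL, priorVar = NULL) {
  stopifnot(is(fit, "DEFit"))
  m <- length(fit@coefficients)
  if (is.null(priorDf) && m < 10L)
    stop("hyperparameter estimation needs at least 10 probes")
  s2 <- fit@sigma^2
  if (!is.null(priorDf) && priorDf == 0) {
    d0 <- 0; s02 <- NA_real_
    post <- s2
  } else {
    if (is.null(priorDf) || is.null(priorVar)) {
      prior <- .fitVariancePrior(s2, fit@df)
    } else prior <- list(d0 = priorDf, s02 = priorVar)
    d0 <- if (is.null(priorDf)) prior$d0 else priorDf
    s02 <- if (is.null(priorVar)) prior$s02 else priorVar
    post <- if (is.infinite(d0)) rep(s02, m)
            else (d0 * s02 + fit@df * s2) / (d0 + fit@df)
  }
  denom <- fit@stdevUnscaled * sqrt(post)
  t <- ifelse(denom > 0, fit@coefficients / denom, 0)
  ## total df capped at the pooled ensemble df: shrinkage cannot carry more
  ## information than the whole ensemble of residual variances
  dfTotal <- pmin(fit@df + d0, sum(fit@df))
  p <- 2 * pt(-abs(t), df = dfTotal)
  out <- data.frame(probe = names(fit@coefficients),
                    logFC = unname(fit@coefficients), t = t, p = p,
                    df.total = dfTotal, sigma = fit@sigma,
                    s.post = sqrt(post),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "priorDf") <- d0
  attr(out, "priorVar") <- s02
  attr(out, "labels") <- fit@labels
  out
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjusted q-values (via \code{stats::p.adjust}) with significance
#' flags at the configured FDR, 1\% by default.
#'
#' @param p p-values in [0, 1].
#' @param fdr FDR threshold for the flags.
#' @return data.frame with columns p, q, flag (in input order).
#' @export
benjaminiHochberg <- function(p, fdr = 0.01) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  q <- p.adjust(p, method = "BH")
  data.frame(p = p, q = q, flag = q <= fdr)
}

#' Full two-group differential-expression table
#'
#' Convenience wrapper: robust (or ordinary) fits, empirical-Bayes
#' moderation, and BH q-values with flags at the configured FDR.
#'
#' @inheritParams fitTwoGroup
#' @inheritParams benjaminiHochberg
#' @param priorDf optional prior df override (see
#'   \code{\link{ebayesModerate}}).
#' @return data.frame: probe, logFC, t, p, q, flag.
#' @export
deTable <- function(expr, labels, fdr = 0.01, robust = TRUE,
                    priorDf = NULL) {
  fit <- fitTwoGroup(expr, labels, robust = robust)
  res <- ebayesModerate(fit, priorDf = priorDf)
  bh <- benjaminiHochberg(res$p, fdr = fdr)
  out <- data.frame(probe = res$probe, logFC = res$logFC, t = res$t,
                    p = res$p, q = bh$q, flag = bh$flag,
                    stringsAsFactors = FALSE)
  attr(out, "priorDf") <- attr(res, "priorDf")
  attr(out, "priorVar") <- attr(res, "priorVar")
  attr(out, "labels") <- attr(res, "labels")
  attr(out, "fdr") <- fdr
  out
}

#' Volcano-plot table
#'
#' One plotting-ready row per probe: log2 fold change, -log10 p and the
#' significance flag. The FDR cut is expressed as the p-value of the last
#' rejected hypothesis and attached as \code{attr(, "pThreshold")}
#' (\code{NA} when nothing is rejected).
#'
#' @param result a \code{\link{deTable}} data.frame.
#' @return data.frame with columns probe, logFC, negLog10P, flag.
#' @export
volcanoTable <- function(result) {
  stopifnot(all(c("probe", "logFC", "p", "flag") %in% colnames(result)))
  out <- data.frame(probe = result$probe, logFC = result$logFC,
                    negLog10P = -log10(result$p), flag = result$flag,
                    stringsAsFactors = FALSE)
  attr(out, "pThreshold") <-
    if (any(result$flag)) max(result$p[result$flag]) else NA_real_
  out
}
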