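#' Allergen-induced shift in methacholine PC20
#'
#' Ratio of pre- to post-challenge PC20 (a ratio above one means greater
#' airway hyperresponsiveness after challenge). Vectorised; a missing (ND)
#' value on either side yields \code{NA}. Display values are rounded to two
#' significant figures; the raw ratio is what downstream computation uses.
#'
#' @param pc20Pre,pc20Post PC20 values in mg/ml (> 0 where present).
#' @return data.frame with columns shift (raw) and display.
#' @export
allergenShift <- function(pc20Pre, pc20Post) {
  if (length(pc20Pre) != length(pc20Post))
    stop("'pc20Pre' and 'pc20Post' must align")
  if (any(stats::na.omit(c(pc20Pre, pc20Post)) <= 0))
    stop("PC20 values must be positive")
  shift <- pc20Pre / pc20Post
  data.frame(shift = shift, display = signif(shift, 2))
}

#' Geometric mean
#'
#' \eqn{\exp(\mathrm{mean}(\ln x))}; missing values (ND) are excluded
#' before averaging.
#'
#' @param x positive values.
#' @return the geometric mean.
#' @export
geometricMean <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

#' Mean and standard error
#'
#' SE = sd / sqrt(n). The default \code{"population"} convention uses the
#' n-denominator standard deviation, which reproduces the printed summary
#' rows of the worked example's demographics table; the usual n-1
#' convention is selectable.
#'
#' @param x numeric values (NA dropped; n >= 2 required).
#' @param convention \code{"population"} (n) or \code{"sample"} (n-1).
#' @return named vector c(mean, se).
#' @export
meanSE <- function(x, convention = c("population", "sample")) {
  convention <- match.arg(convention)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) stop("at least two values are required")
  v <- var(x)
  if (convention == "population") v <- v * (n - 1) / n
  c(mean = mean(x), se = sqrt(v / n))
}

#' One-way analysis of variance across groups
#'
#' F-test p-value from \code{stats::aov}; with two groups this equals the
#' two-sided equal-variance t-test. Values flagged at p < 0.05 by
#' convention.
#'
#' @param values numeric outcome.
#' @param labels group labels (>= 2 groups, each n >= 2).
#' @return list with p, significant, and the aov fit.
#' @export
compareGroupsAnova <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("at least two groups are required")
  if (any(table(labels) < 2L)) stop("every group needs at least two values")
  if (length(values) != length(labels))
    stop("'values' and 'labels' must align")
  fit <- aov(values ~ labels)
  p <- anova(fit)[["Pr(>F)"]][1L]
  list(p = p, significant = p < 0.05, fit = fit)
}

#' Cohort demographics and challenge-response summary
#'
#' Reproduces the derived quantities of the demographics table: per-group
#' mean +/- SE of age, geometric mean pre- and post-challenge PC20, the
#' per-subject allergen-induced shift (pre PC20 / post PC20), and its mean
#' +/- SE. Shifts are defined only where both PC20 values are present.
#'
#' @param subjects data.frame as from \code{\link{readSubjectTable}}.
#' @param seConvention SE convention passed to \code{\link{meanSE}}.
#' @return list: age (per-group mean/se), pc20 (geometric means), shifts
#'   (per-subject data.frame), shiftSummary (mean/se).
#' @export
cohortSummary <- function(subjects, seConvention = "population") {
  stopifnot(all(c("group", "age", "pc20_pre", "pc20_post") %in%
                colnames(subjects)))
  age <- lapply(split(subjects$age, subjects$group), meanSE,
                convention = seConvention)
  asthma <- subjects[subjects$group != "HC", ]
  sh <- allergenShift(asthma$pc20_pre, asthma$pc20_post)
  shifts <- data.frame(subject = asthma$subject, sh,
                       stringsAsFactors = FALSE)
  list(age = age,
       pc20 = c(pre = geometricMean(asthma$pc20_pre),
                post = geometricMean(asthma$pc20_post)),
       shifts = shifts,
       shiftSummary = meanSE(sh$shift, convention = seConvention))
}
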