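#' Configuration of an end-to-end pipeline run
#'
#' @param seed master seed; all stochastic stages (simulation, permutation
#'   nulls, qPCR noise) derive their streams from it.
#' @param simulation a \code{\link{simConfig}}; \code{NULL} builds the
#'   default cohort with a seed derived from \code{seed}. An explicitly
#'   supplied config keeps its own seed.
#' @param contrasts list of length-2 character vectors of group labels;
#'   each is fitted as an independent two-group model, level 2 minus
#'   level 1.
#' @param fdr BH false discovery rate for the differential flags.
#' @param B permutations for the deconvolution null.
#' @param minCount,corrections,minStat preprocessing parameters (see
#'   \code{\link{runPreprocess}}).
#' @param deconvProbes probes to deconvolve; \code{NULL} uses the
#'   cross-contrast intersection of significant probes (or, if empty, the
#'   top probe of the first contrast).
#' @param outDir output directory.
#' @return validated list of class \code{"RunConfig"}.
#' @export
runConfig <- function(seed, simulation = NULL,
                      contrasts = list(c("HC", "pre"), c("pre", "post")),
                      fdr = 0.01, B = 1000L, minCount = 100,
                      corrections = numeric(0), minStat = "min",
                      deconvProbes = NULL, outDir = tempfile("bloodmiR_run")) {
  seed <- .assertScalarSeed(seed)
  if (is.null(simulation))
    simulation <- simConfig(seed = .deriveSeed(seed, 1L))
  stopifnot(inherits(simulation, "SimulationConfig"))
  groups <- dimnames(simulation$cellMeans)[[3L]]
  for (ct in contrasts) {
    if (length(ct) != 2L || !all(ct %in% groups))
      stop("each contrast must name two of: ", paste(groups, collapse = ", "))
  }
  if (fdr <= 0 || fdr >= 1) stop("'fdr' must lie in (0, 1)")
  structure(list(seed = seed, simulation = simulation,
                 contrasts = contrasts, fdr = fdr, B = as.integer(B),
                 minCount = minCount, corrections = corrections,
                 minStat = minStat, deconvProbes = deconvProbes,
                 outDir = outDir),
            class = "RunConfig")
}

.stage <- function(name, fingerprint, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed (input: ", fingerprint,
         "): ", conditionMessage(e), call. = FALSE)
  })
}

.contrastTag <- function(ct) paste0(ct[1L], "_vs_", ct[2L])

#' Run the full analysis pipeline
#'
#' Simulate (or accept) a cohort, run the preprocessing ladder, fit the
#' configured two-group contrasts with moderated statistics and BH flags,
#' intersect the significant probe sets across contrasts, deconvolve the
#' selected probes per contrast against a permutation null, run the qPCR
#' delta-Ct validation arm on the first deconvolved probe, summarise the
#' bundled cohort demographics, and write every table as canonical CSV plus
#' a JSON provenance manifest. Two runs with identical config and seed
#' produce byte-identical outputs.
#'
#' @param config a \code{\link{runConfig}}.
#' @param cohort optional pre-built \linkS4class{SimulatedCohort} (skips
#'   simulation).
#' @return invisibly, a results bundle: cohort, expr, qc, de (per
#'   contrast), intersection, deconv (per contrast), qpcr, cohortSummary,
#'   paths.
#' @export
runPipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if (is.null(cohort))
    cohort <- .stage("simulate", "config", simulateCohort(config$simulation))
  fp <- sprintf("%d probes x %d samples", nrow(cohort@counts),
                ncol(cohort@counts))

  pp <- .stage("preprocess", fp,
               runPreprocess(cohort@counts, corrections = config$corrections,
                             minCount = config$minCount,
                             minStat = config$minStat))
  expr <- pp$expr
  paths["qc_json"] <- file.path(config$outDir, "qc.json")
  paths["qc_txt"] <- file.path(config$outDir, "qc.txt")
  writeQCReport(pp$qc, paths["qc_json"])
  writeQCReport(pp$qc, paths["qc_txt"])

  md <- cohort@metadata
  de <- list()
  for (ct in config$contrasts) {
    tag <- .contrastTag(ct)
    sel <- md$sample[md$group %in% ct]
    labels <- factor(md$group[md$group %in% ct], levels = ct)
    tab <- .stage(paste0("de_", tag), fp,
                  deTable(log2expr(expr)[, sel, drop = FALSE], labels,
                          fdr = config$fdr))
    de[[tag]] <- tab
    paths[paste0("de_", tag)] <-
      file.path(config$outDir, paste0("de_", tag, ".csv"))
    .writeCanonicalCsv(tab, paths[paste0("de_", tag)])
  }

  sigSets <- lapply(de, function(t) t$probe[t$flag])
  common <- Reduce(intersect, sigSets)
  inter <- data.frame(probe = common, stringsAsFactors = FALSE)
  for (tag in names(de)) {
    m <- match(common, de[[tag]]$probe)
    inter[[paste0("logFC_", tag)]] <- de[[tag]]$logFC[m]
    inter[[paste0("t_", tag)]] <- de[[tag]]$t[m]
    inter[[paste0("q_", tag)]] <- de[[tag]]$q[m]
  }
  paths["intersection"] <- file.path(config$outDir, "intersection.csv")
  .writeCanonicalCsv(inter, paths["intersection"])

  probes <- config$deconvProbes
  if (is.null(probes)) {
    probes <- if (length(common)) common
              else de[[1L]]$probe[which.max(abs(de[[1L]]$t))]
  }
  deconv <- list()
  for (i in seq_along(config$contrasts)) {
    ct <- config$contrasts[[i]]
    tag <- .contrastTag(ct)
    sel <- md$sample[md$group %in% ct]
    labels <- factor(md$group[md$group %in% ct], levels = ct)
    fr <- CellFractions(fractions(cohort@fractions)[sel, , drop = FALSE],
                        source = cohort@fractions@source)
    dtab <- .stage(paste0("deconvolve_", tag), fp,
                   deconvolveContrast(log2expr(expr)[, sel, drop = FALSE],
                                      fr, labels, probes,
                                      B = config$B,
                                      seed = .deriveSeed(config$seed,
                                                         100L + i)))
    dtab <- dtab[, setdiff(colnames(dtab), "seed")]
    deconv[[tag]] <- dtab
    paths[paste0("deconv_", tag)] <-
      file.path(config$outDir, paste0("deconv_", tag, ".csv"))
    .writeCanonicalCsv(dtab, paths[paste0("deconv_", tag)])
  }

  qprobe <- probes[1L]
  ctTab <- .stage("qpcr_simulate", qprobe,
                  simulateCtTable(cohort, probe = qprobe,
                                  assay = qprobe,
                                  seed = .deriveSeed(config$seed, 200L)))
  dct <- deltaCt(collapseReplicates(ctTab))
  ct1 <- config$contrasts[[1L]]
  sel <- md$sample[md$group %in% ct1]
  qdeconv <- .stage("qpcr_deconvolve", qprobe, {
    d <- dct[dct$sample %in% sel, ]
    qpcrCellRegression(d,
                       CellFractions(fractions(cohort@fractions)[sel, ,
                                                                 drop = FALSE]),
                       stats::setNames(md$group, md$sample)[sel],
                       B = config$B,
                       seed = .deriveSeed(config$seed, 300L))
  })
  paths["qpcr"] <- file.path(config$outDir, "qpcr.csv")
  .writeCanonicalCsv(dct, paths["qpcr"])
  paths["qpcr_deconv"] <- file.path(config$outDir, "qpcr_deconv.csv")
  .writeCanonicalCsv(as.data.frame(qdeconv), paths["qpcr_deconv"])

  subj <- exampleSubjects()
  cs <- cohortSummary(subj)
  csFlat <- data.frame(
    quantity = c(paste0("age_mean_", names(cs$age)),
                 paste0("age_se_", names(cs$age)),
                 "pc20_geomean_pre", "pc20_geomean_post",
                 "shift_mean", "shift_se"),
    value = c(vapply(cs$age, `[[`, 0, "mean"),
              vapply(cs$age, `[[`, 0, "se"),
              cs$pc20["pre"], cs$pc20["post"],
              cs$shiftSummary["mean"], cs$shiftSummary["se"]))
  paths["cohort_summary"] <- file.path(config$outDir, "cohort_summary.csv")
  .writeCanonicalCsv(csFlat, paths["cohort_summary"])

  manifest <- list(
    package = paste0("bloodmiR ",
                     as.character(packageVersion("bloodmiR"))),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    contrasts = vapply(config$contrasts, .contrastTag, ""),
    fdr = config$fdr, B = config$B, min_count = config$minCount,
    simulation_seed = config$simulation$seed,
    n_samples = ncol(cohort@counts),
    n_probes_raw = sum(probeClass(cohort@counts) == "endogenous"),
    n_probes_retained = nrow(expr),
    deconv_probes = probes,
    files = basename(unname(paths)))
  paths["manifest"] <- file.path(config$outDir, "manifest.json")
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, expr = expr, qc = pp$qc, de = de,
                 intersection = inter, deconv = deconv, qpcr = dct,
                 qpcrDeconv = qdeconv, cohortSummary = cs, paths = paths))
}
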