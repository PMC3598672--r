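#' Simulation configuration for a synthetic whole-blood miRNA cohort
#'
#' Assembles and validates the parameters of the cohort generator. The
#' defaults describe a small allergen-challenge study: four unpaired healthy
#' controls plus seven asthmatic subjects sampled immediately before and two
#' hours after challenge, a codeset of 734 endogenous probes with six
#' positive spike-in controls on a geometric 0.125--128 fM ladder, eight
#' negative controls and five housekeeping mRNAs, and two modelled cell
#' populations (granulocytes and PBMCs) whose Dirichlet fraction
#' distribution is anchored to printed whole-blood leukocyte differentials.
#'
#' Endogenous counts are negative-binomial draws around a cell-fraction
#' mixture: the expected count of probe p in sample s of group g is
#' \deqn{libsize_s \sum_k f_{sk}\, cellMeans[p, k, g].}
#'
#' @param nHC number of healthy-control samples.
#' @param nAsthma number of asthmatic subjects; each contributes one paired
#'   pre- and post-challenge sample.
#' @param nProbes number of endogenous probes.
#' @param cellTypeNames cell-type names (length K >= 2).
#' @param dirichletAlpha named list of per-group Dirichlet concentration
#'   vectors (groups HC, pre, post); \code{NULL} uses the leukocyte
#'   differential anchored defaults.
#' @param cellMeans probe x cell-type x group array of true mean expression
#'   on the linear count scale; \code{NULL} builds defaults from the seed.
#' @param dispersion negative-binomial dispersion (>= 0; 0 gives Poisson).
#' @param libsizeSdlog log-normal sd of the per-sample library-size factors.
#' @param libsizeFactors optional explicit per-sample factors (> 0).
#' @param posControlLadder six strictly increasing spike-in concentrations
#'   (fM).
#' @param posControlScale expected counts per fM for the positive controls.
#' @param negControlMean,negControlSd background count parameters; negative
#'   controls are rounded, zero-floored normal draws.
#' @param hkMeans named expected counts of the housekeeping mRNAs.
#' @param seed integer master seed.
#' @return A validated list of class \code{"SimulationConfig"}.
#' @export
simConfig <- function(nHC = 4L, nAsthma = 7L, nProbes = 734L,
                      cellTypeNames = c("granulocytes", "PBMC"),
                      dirichletAlpha = NULL, cellMeans = NULL,
                      dispersion = 0.1, libsizeSdlog = 0.15,
                      libsizeFactors = NULL,
                      posControlLadder = c(0.125, 0.5, 2, 8, 32, 128),
                      posControlScale = 240,
                      negControlMean = 10, negControlSd = 4,
                      hkMeans = c(ACTB = 2000, B2M = 1600, GAPDH = 1200,
                                  RPL19 = 900, RPLP0 = 700),
                      seed = 1L) {
  nHC <- as.integer(nHC); nAsthma <- as.integer(nAsthma)
  if (nHC < 0L || nAsthma < 0L)
    stop("sample counts must be non-negative")
  if (nHC < 1L && nAsthma < 1L)
    stop("at least one of 'nHC' and 'nAsthma' must be positive")
  K <- length(cellTypeNames)
  if (K < 2L) stop("at least two cell types are required")
  if (is.null(dirichletAlpha))
    dirichletAlpha <- defaultDirichletAlpha(cellTypeNames)
  for (g in names(dirichletAlpha)) {
    a <- dirichletAlpha[[g]]
    if (length(a) != K) stop("dirichletAlpha[['", g, "']] must have length K")
    bad <- which(!(a > 0))
    if (length(bad))
      stop(sprintf("dirichletAlpha[['%s']] entry %d (%s) must be strictly positive",
                   g, bad[1L], format(a[bad[1L]])))
  }
  if (dispersion < 0) stop("'dispersion' must be >= 0")
  if (length(posControlLadder) != 6L || any(diff(posControlLadder) <= 0))
    stop("'posControlLadder' must be 6 strictly increasing concentrations")
  if (negControlSd < 0 || negControlMean < 0)
    stop("negative-control background parameters must be non-negative")
  if (!is.null(libsizeFactors) && any(libsizeFactors <= 0))
    stop("'libsizeFactors' must be strictly positive")
  seed <- .assertScalarSeed(seed)
  if (is.null(cellMeans))
    cellMeans <- defaultCellMeans(nProbes, cellTypeNames,
                                  seed = .deriveSeed(seed, 11L))
  dm <- dim(cellMeans)
  if (length(dm) != 3L || dm[1L] != nProbes || dm[2L] != K)
    stop("'cellMeans' must be an nProbes x K x group array")
  if (is.null(dimnames(cellMeans)[[3L]]))
    stop("'cellMeans' must name its group slices")
  structure(list(nHC = nHC, nAsthma = nAsthma, nProbes = as.integer(nProbes),
                 cellTypeNames = cellTypeNames,
                 dirichletAlpha = dirichletAlpha, cellMeans = cellMeans,
                 dispersion = dispersion, libsizeSdlog = libsizeSdlog,
                 libsizeFactors = libsizeFactors,
                 posControlLadder = posControlLadder,
                 posControlScale = posControlScale,
                 negControlMean = negControlMean, negControlSd = negControlSd,
                 hkMeans = hkMeans, seed = seed),
            class = "SimulationConfig")
}

#' Default per-group Dirichlet concentrations from leukocyte differentials
#'
#' Group mean proportions are the printed whole-blood differentials collapsed
#' to the granulocyte (neutrophils + eosinophils + basophils) and PBMC
#' (lymphocytes + monocytes) populations, renormalised; the total
#' concentration of 20 gives the between-subject spread implied by the
#' printed standard errors (cell-fraction sd around 10 percentage points).
#'
#' @param cellTypeNames cell-type names; for the default two populations the
#'   anchored values are returned, otherwise a symmetric concentration.
#' @param concentration total Dirichlet concentration.
#' @return named list of per-group concentration vectors.
#' @export
defaultDirichletAlpha <- function(cellTypeNames = c("granulocytes", "PBMC"),
                                  concentration = 20) {
  if (identical(cellTypeNames, c("granulocytes", "PBMC"))) {
    diffs <- exampleDifferentials()
    gran <- diffs$neutrophils + diffs$eosinophils + diffs$basophils
    pbmc <- diffs$lymphocytes + diffs$monocytes
    p <- cbind(granulocytes = gran, PBMC = pbmc) / (gran + pbmc)
    out <- lapply(seq_len(nrow(p)), function(i) {
      a <- p[i, ] * concentration
      names(a) <- cellTypeNames
      a
    })
    names(out) <- diffs$group
    out
  } else {
    a <- rep(concentration / length(cellTypeNames), length(cellTypeNames))
    names(a) <- cellTypeNames
    list(HC = a, pre = a, post = a)
  }
}

#' Default true cell-specific mean expression
#'
#' Per-probe base abundance is log-normal (median 30 counts, log sd 1.8) so
#' that, against a background of roughly 18 counts, a minority of probes pass
#' detection and fewer still the minimum-count filter, mirroring the steep
#' probe attrition typical of whole-blood miRNA codesets. Cell types modulate
#' the base by independent log-normal factors (log sd 0.5). All groups share
#' the same means (a global null); use \code{\link{spikeCellMeans}} to inject
#' group or cell-type effects.
#'
#' @param nProbes number of endogenous probes.
#' @param cellTypeNames cell-type names.
#' @param groups group names.
#' @param baseMeanlog,baseSdlog log-normal parameters of the per-probe base.
#' @param cellSdlog log sd of the per-cell-type modulation.
#' @param seed integer seed.
#' @return probe x cell type x group array.
#' @export
defaultCellMeans <- function(nProbes, cellTypeNames = c("granulocytes", "PBMC"),
                             groups = c("HC", "pre", "post"),
                             baseMeanlog = log(30), baseSdlog = 1.8,
                             cellSdlog = 0.5, seed = 1L) {
  withr::with_seed(.assertScalarSeed(seed), {
    base <- exp(rnorm(nProbes, baseMeanlog, baseSdlog))
    mod <- matrix(exp(rnorm(nProbes * length(cellTypeNames), 0, cellSdlog)),
                  nrow = nProbes)
    m <- base * mod
  })
  probes <- sprintf("miR-%04d", seq_len(nProbes))
  arr <- array(rep(m, length(groups)),
               dim = c(nProbes, length(cellTypeNames), length(groups)),
               dimnames = list(probes, cellTypeNames, groups))
  arr
}

#' Inject a group/cell-type effect into a cell-means array
#'
#' Multiplies the mean expression of one probe by \code{2^log2fc} in the
#' given groups, either in all cell types or only in the named ones. Used to
#' create known differential or cell-specific signal for recovery tests.
#'
#' @param cellMeans probe x cell type x group array.
#' @param probe probe id or index.
#' @param log2fc log2 fold change to apply.
#' @param groups group slice names to modify.
#' @param cellTypes cell types to modify (default all).
#' @return the modified array.
#' @export
spikeCellMeans <- function(cellMeans, probe, log2fc, groups,
                           cellTypes = NULL) {
  if (is.null(cellTypes)) cellTypes <- dimnames(cellMeans)[[2L]]
  cellMeans[probe, cellTypes, groups] <-
    cellMeans[probe, cellTypes, groups] * 2^log2fc
  cellMeans
}

#' Simulate sample cell fractions from a Dirichlet distribution
#'
#' @param nSamples number of samples.
#' @param alpha strictly positive concentration vector (length K >= 2).
#' @param seed integer seed.
#' @param sampleNames optional row names.
#' @return A \linkS4class{CellFractions}; each row sums to one.
#' @export
simulateCellFractions <- function(nSamples, alpha, seed = 1L,
                                  sampleNames = NULL) {
  seed <- .assertScalarSeed(seed)
  f <- withr::with_seed(seed, .rdirichlet(nSamples, alpha))
  colnames(f) <- if (!is.null(names(alpha))) names(alpha)
                 else paste0("cell", seq_along(alpha))
  rownames(f) <- if (!is.null(sampleNames)) sampleNames
                 else paste0("S", seq_len(nSamples))
  CellFractions(f, source = "simulated")
}

## Expected endogenous counts under the mixture model.
.expectedEndogenous <- function(cellMeans, fracMat, groupLabels, libsize) {
  nP <- dim(cellMeans)[1L]
  E <- matrix(NA_real_, nP, nrow(fracMat),
              dimnames = list(dimnames(cellMeans)[[1L]], rownames(fracMat)))
  for (g in unique(groupLabels)) {
    sel <- which(groupLabels == g)
    E[, sel] <- cellMeans[, , g, drop = TRUE] %*% t(fracMat[sel, , drop = FALSE])
  }
  sweep(E, 2L, libsize, `*`)
}

#' Simulate an nCounter-style count table
#'
#' Draws endogenous counts from a negative binomial (Poisson when
#' \code{dispersion = 0}) around the cell-fraction mixture expectation,
#' positive-control counts proportional to the spike-in ladder, negative
#' controls from the configured background distribution, and housekeeping
#' counts around their configured means.
#'
#' @param config a \code{\link{simConfig}}.
#' @param fractions a \linkS4class{CellFractions} (rows align with
#'   \code{groupLabels}).
#' @param groupLabels character group per sample; every group must have a
#'   slice in \code{config$cellMeans}.
#' @param libsize optional per-sample library-size factors; defaults to
#'   log-normal draws controlled by \code{config$libsizeSdlog}.
#' @param seed integer seed (defaults to the config seed).
#' @return A \linkS4class{MiRCountSet} whose \code{metadata()$expected}
#'   holds the endogenous expectation matrix and \code{metadata()$libsize}
#'   the factors used.
#' @export
simulateCounts <- function(config, fractions, groupLabels, libsize = NULL,
                           seed = config$seed) {
  stopifnot(inherits(config, "SimulationConfig"))
  fracMat <- fractions(fractions)
  n <- nrow(fracMat)
  if (length(groupLabels) != n)
    stop("'groupLabels' must align with the fraction rows")
  missing <- setdiff(unique(groupLabels), dimnames(config$cellMeans)[[3L]])
  if (length(missing))
    stop("cellMeans has no slice for group(s): ",
         paste(missing, collapse = ", "))
  if (!identical(colnames(fracMat), config$cellTypeNames))
    stop("fraction cell types must match the configured cell types")
  seed <- .assertScalarSeed(seed)
  withr::with_seed(seed, {
    if (is.null(libsize)) {
      libsize <- if (!is.null(config$libsizeFactors)) config$libsizeFactors
                 else exp(rnorm(n, 0, config$libsizeSdlog))
    }
    if (length(libsize) != n) stop("'libsize' must have one factor per sample")
    E <- .expectedEndogenous(config$cellMeans, fracMat, groupLabels, libsize)
    endo <- matrix(
      if (config$dispersion == 0) rpois(length(E), lambda = E)
      else rnbinom(length(E), mu = E, size = 1 / config$dispersion),
      nrow = nrow(E), dimnames = dimnames(E))
    posMu <- outer(config$posControlLadder * config$posControlScale, libsize)
    pos <- matrix(rpois(length(posMu), posMu), nrow = 6L,
                  dimnames = list(sprintf("POS_%s(%g)", LETTERS[1:6],
                                          config$posControlLadder),
                                  colnames(E)))
    neg <- matrix(round(pmax(rnorm(8L * n, config$negControlMean,
                                   config$negControlSd), 0)),
                  nrow = 8L,
                  dimnames = list(sprintf("NEG_%s", LETTERS[1:8]),
                                  colnames(E)))
    hkMu <- outer(config$hkMeans, libsize)
    hk <- matrix(rpois(length(hkMu), hkMu), nrow = length(config$hkMeans),
                 dimnames = list(names(config$hkMeans), colnames(E)))
  })
  cts <- rbind(endo, pos, neg, hk)
  obj <- MiRCountSet(cts,
                     probeClass = rep(c("endogenous", "pos", "neg", "hk"),
                                      c(nrow(endo), 6L, 8L, nrow(hk))),
                     colData = S4Vectors::DataFrame(group = groupLabels,
                                                    row.names = colnames(cts)))
  metadata(obj)$expected <- E
  metadata(obj)$libsize <- libsize
  obj
}

#' Simulate a full cohort with known ground truth
#'
#' Healthy controls are unpaired; each asthmatic subject contributes exactly
#' one pre- and one post-challenge sample (pairing encoded by subject id).
#' Fractions, library sizes and counts are all reproducible from the config
#' seed.
#'
#' @param config a \code{\link{simConfig}}.
#' @return A \linkS4class{SimulatedCohort}.
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  groups <- c(rep("HC", config$nHC),
              rep(c("pre", "post"), config$nAsthma))
  subjects <- c(sprintf("HC%d", seq_len(config$nHC)),
                rep(sprintf("A%d", seq_len(config$nAsthma)), each = 2L))
  samples <- ifelse(groups == "HC", subjects, paste0(subjects, "_", groups))
  fracMat <- matrix(NA_real_, length(samples), length(config$cellTypeNames),
                    dimnames = list(samples, config$cellTypeNames))
  for (g in unique(groups)) {
    sel <- which(groups == g)
    fg <- simulateCellFractions(length(sel), config$dirichletAlpha[[g]],
                                seed = .deriveSeed(config$seed,
                                                   match(g, c("HC", "pre", "post"))),
                                sampleNames = samples[sel])
    fracMat[sel, ] <- fractions(fg)
  }
  fr <- CellFractions(fracMat, source = "simulated")
  cts <- simulateCounts(config, fr, groups,
                        seed = .deriveSeed(config$seed, 7L))
  md <- data.frame(sample = samples, group = groups, subject = subjects,
                   stringsAsFactors = FALSE)
  new("SimulatedCohort", counts = cts, fractions = fr, metadata = md,
      truth = list(cellMeans = config$cellMeans,
                   expected = metadata(cts)$expected,
                   libsize = metadata(cts)$libsize),
      config = unclass(config), seed = config$seed)
}

#' Simulate an RT-qPCR Ct table for one target miRNA
#'
#' Each well's Ct falls by one cycle per doubling of the underlying
#' abundance: \code{Ct = ctIntercept - log2(abundance) + noise}. Reference
#' small-RNA assays sit at fixed characteristic Cts. Abundances below
#' \code{2^(ctIntercept - 35)} therefore emit Ct values above the
#' detection limit of 35 cycles.
#'
#' @param cohort a \linkS4class{SimulatedCohort}; per-sample target
#'   abundance defaults to the true expected count of \code{probe}.
#' @param probe endogenous probe id used as the qPCR target (defaults to
#'   the first probe).
#' @param assay assay name recorded in the table.
#' @param abundance optional named per-sample abundance override.
#' @param references named characteristic Cts of the reference assays.
#' @param duplicateSd technical sd of a single well (cycles).
#' @param nReplicates wells per (sample, assay).
#' @param ctIntercept Ct of one abundance unit.
#' @param seed integer seed.
#' @return data.frame with columns sample, assay, class, replicate, ct.
#' @export
simulateCtTable <- function(cohort = NULL, probe = NULL, assay = "miR-192",
                            abundance = NULL,
                            references = c(RNU44 = 24.5, RNU6B = 26.5),
                            duplicateSd = 0.15, nReplicates = 2L,
                            ctIntercept = 38, seed = 1L) {
  if (is.null(names(references)) || length(references) < 1L)
    stop("reference assays must be named")
  if (duplicateSd < 0) stop("'duplicateSd' must be >= 0")
  if (is.null(abundance)) {
    stopifnot(is(cohort, "SimulatedCohort"))
    ## biological mixture abundance: the library-size factor is a property
    ## of the counting assay, not of the RNA re-measured by qPCR
    E <- cohort@truth$expected
    if (is.null(probe)) probe <- rownames(E)[1L]
    abundance <- E[probe, ] / cohort@truth$libsize
  }
  if (any(abundance <= 0)) stop("abundances must be strictly positive")
  samples <- names(abundance)
  assays <- c(assay, names(references))
  classes <- c("target", rep("reference", length(references)))
  baseCt <- c(ctIntercept - log2(abundance))
  rows <- expand.grid(replicate = seq_len(nReplicates), sample = samples,
                      assay = assays, stringsAsFactors = FALSE)
  rows$class <- classes[match(rows$assay, assays)]
  mu <- ifelse(rows$class == "target", baseCt[rows$sample],
               references[rows$assay])
  ct <- withr::with_seed(.assertScalarSeed(seed),
                         rnorm(nrow(rows), mu, duplicateSd))
  data.frame(sample = rows$sample, assay = rows$assay, class = rows$class,
             replicate = rows$replicate, ct = ct, stringsAsFactors = FALSE)
}

#' Write a simulated cohort as plain-text artifacts
#'
#' Emits \code{counts.csv} (probe_id, probe_class, one column per sample),
#' \code{fractions.csv}, \code{metadata.csv}, optionally \code{ct.csv}, and
#' a \code{manifest.yaml} recording the scalar configuration and seed. The
#' manifest flags every distributional choice as a synthetic stand-in. All
#' numeric output uses a canonical format, so a fixed seed fixes every byte.
#'
#' @param cohort a \linkS4class{SimulatedCohort}.
#' @param dir output directory (created if needed).
#' @param ct optional Ct table from \code{\link{simulateCtTable}}.
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir, ct = NULL) {
  stopifnot(is(cohort, "SimulatedCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cts <- counts(cohort@counts)
  countsDf <- data.frame(probe_id = rownames(cts),
                         probe_class = probeClass(cohort@counts),
                         cts, check.names = FALSE)
  fr <- fractions(cohort@fractions)
  fracDf <- data.frame(sample = rownames(fr), fr, check.names = FALSE)
  paths <- c(counts = file.path(dir, "counts.csv"),
             fractions = file.path(dir, "fractions.csv"),
             metadata = file.path(dir, "metadata.csv"),
             manifest = file.path(dir, "manifest.yaml"))
  .writeCanonicalCsv(countsDf, paths["counts"])
  .writeCanonicalCsv(fracDf, paths["fractions"])
  .writeCanonicalCsv(cohort@metadata, paths["metadata"])
  if (!is.null(ct)) {
    paths <- c(paths, ct = file.path(dir, "ct.csv"))
    .writeCanonicalCsv(ct, paths["ct"])
  }
  cfg <- cohort@config
  manifest <- list(
    generator = paste0("bloodmiR ", as.character(packageVersion("bloodmiR"))),
    seed = cohort@seed,
    note = paste("All generator distributions (negative-binomial mixture",
                 "counts, Dirichlet fractions, normal background, Ct noise)",
                 "are synthetic stand-ins with known ground truth, not",
                 "fitted to any real assay."),
    config = list(nHC = cfg$nHC, nAsthma = cfg$nAsthma,
                  nProbes = cfg$nProbes,
                  cellTypes = cfg$cellTypeNames,
                  dirichletAlpha = lapply(cfg$dirichletAlpha, as.list),
                  dispersion = cfg$dispersion,
                  libsizeSdlog = cfg$libsizeSdlog,
                  posControlLadder = cfg$posControlLadder,
                  posControlScale = cfg$posControlScale,
                  negControlMean = cfg$negControlMean,
                  negControlSd = cfg$negControlSd,
                  hkMeans = as.list(cfg$hkMeans)))
  writeLines(yaml::as.yaml(manifest), paths["manifest"])
  invisible(paths)
}
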