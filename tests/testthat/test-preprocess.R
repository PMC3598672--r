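test_that("count tables round-trip through both text dialects", {
  cfg <- simConfig(nProbes = 30, seed = 101,
                   cellMeans = defaultCellMeans(30, seed = 5))
  coh <- simulateCohort(cfg)
  d <- withr::local_tempdir()
  writeCohort(coh, d)
  rt <- readCountTable(file.path(d, "counts.csv"))
  expect_equal(unname(counts(rt)), unname(counts(coh@counts)))
  expect_identical(probeClass(rt), probeClass(coh@counts))
  expect_identical(rownames(rt), rownames(coh@counts))

  ## rcc-like sectioned dialect wraps the same payload
  rcc <- file.path(d, "counts.rcc")
  writeLines(c("<Header>", "version,1", "</Header>", "<Code_Summary>",
               readLines(file.path(d, "counts.csv")), "</Code_Summary>"),
             rcc)
  rt2 <- readCountTable(rcc, dialect = "rcc")
  expect_equal(counts(rt2), counts(rt))
})

test_that("count parsing enforces the raw-count contract", {
  d <- withr::local_tempdir()
  f <- file.path(d, "bad.csv")
  writeLines(c("probe_id,probe_class,S1", "p1,endogenous,5",
               "p1,endogenous,6"), f)
  expect_error(readCountTable(f), "duplicate probe")
  writeLines(c("probe_id,probe_class,S1", "p1,endogenous,-3"), f)
  expect_error(readCountTable(f), "negative count")
  writeLines(c("probe_id,probe_class,S1", "p1,mystery,3"), f)
  expect_error(readCountTable(f), "unknown probe class 'mystery' at row 1")
})

test_that("a full codeset layout parses into its class tallies", {
  cfg <- simConfig(seed = 103)   # 734 endogenous + 6 pos + 8 neg + 5 hk
  coh <- simulateCohort(cfg)
  d <- withr::local_tempdir()
  writeCohort(coh, d)
  rt <- readCountTable(file.path(d, "counts.csv"))
  tally <- table(probeClass(rt))
  expect_equal(unname(tally["endogenous"]), 734L)
  expect_equal(unname(tally["pos"]), 6L)
  expect_equal(unname(tally["neg"]), 8L)
  expect_equal(unname(tally["hk"]), 5L)
})

test_that("probe-level background correction floors negatives at 1", {
  endo <- matrix(c(50, 5, 30, 50, 5, 30), 3, 2,
                 dimnames = list(c("pA", "pB", "pC"), c("S1", "S2")))
  x <- toyCountSet(endo)
  out <- probeBackgroundCorrect(x, c(pA = 10, pB = 10))
  expect_equal(unname(counts(out)["pA", ]), c(40, 40))   # 50 - 10
  expect_equal(unname(counts(out)["pB", ]), c(1, 1))     # 5 - 10 -> floored
  expect_equal(unname(counts(out)["pC", ]), c(30, 30))   # unlisted unchanged
  expect_equal(counts(probeBackgroundCorrect(x)), counts(x))
  expect_error(probeBackgroundCorrect(x, c(nope = 1)), "unknown probe")
})

test_that("positive-control normalisation equalises spike-in sums to the mean target", {
  endo <- matrix(c(10, 20), 1, 2, dimnames = list("pA", c("S1", "S2")))
  pos <- matrix(c(60, 40, 120, 80), 2, 2,
                dimnames = list(c("POS_A", "POS_B"), c("S1", "S2")))
  x <- toyCountSet(endo, pos = pos)   # positive sums 100 and 200
  out <- positiveControlNormalize(x)
  prov <- provenance(out)[[length(provenance(out))]]
  expect_equal(unname(prov$params$factors), c(1.5, 0.75))
  sums <- colSums(counts(out)[probeClass(out) == "pos", ])
  expect_equal(unname(sums), c(150, 150))
  expect_lt(abs(sums[1] - sums[2]) / sums[1], 1e-9)

  ## equal sums in -> identity
  posEq <- matrix(50, 2, 2, dimnames = list(c("POS_A", "POS_B"),
                                            c("S1", "S2")))
  xEq <- toyCountSet(endo, pos = posEq)
  expect_equal(counts(positiveControlNormalize(xEq)), counts(xEq))

  posZero <- matrix(c(0, 0, 10, 10), 2, 2,
                    dimnames = list(c("POS_A", "POS_B"), c("S1", "S2")))
  expect_error(positiveControlNormalize(toyCountSet(endo, pos = posZero)),
               "S1")
})

test_that("negative-control thresholding subtracts mean + 2 sd and applies the all-samples detection rule", {
  ## negatives 1..8: mean 4.5, sd sqrt(6) => threshold 9.39898...
  neg <- matrix(rep(1:8, 2), 8, 2,
                dimnames = list(paste0("NEG_", LETTERS[1:8]), c("S1", "S2")))
  thr <- 4.5 + 2 * sqrt(6)
  endo <- matrix(c(10, 10, 9, 10, 20, 20), 3, 2, byrow = TRUE,
                 dimnames = list(c("pA", "pB", "pC"), c("S1", "S2")))
  x <- toyCountSet(endo, neg = neg)
  out <- negativeBackgroundThreshold(x)
  expect_equal(unname(counts(out)["pA", 1]), 10 - thr, tolerance = 1e-12)
  expect_equal(detectedProbes(out), c("pA", "pC"))
  expect_false("pB" %in% rownames(out))  # negative in one sample => dropped

  ## all-zero negatives: threshold 0, counts unchanged, everything detected
  negZ <- matrix(0, 8, 2, dimnames = dimnames(neg))
  outZ <- negativeBackgroundThreshold(toyCountSet(endo, neg = negZ))
  expect_equal(counts(outZ)[c("pA", "pB", "pC"), ], endo)
  expect_equal(detectedProbes(outZ), c("pA", "pB", "pC"))

  one <- toyCountSet(endo, neg = negZ[1, , drop = FALSE])
  expect_error(negativeBackgroundThreshold(one), "two negative")
})

test_that("content normalisation equalises detected-set totals and ignores controls", {
  endo <- matrix(c(600, 400, 1800, 1200), 2, 2,
                 dimnames = list(c("pA", "pB"), c("S1", "S2")))
  pos <- matrix(c(10, 10, 999, 999), 2, 2,
                dimnames = list(c("POS_A", "POS_B"), c("S1", "S2")))
  x <- toyCountSet(endo, pos = pos)     # endo totals 1000 and 3000
  out <- contentNormalize(x)
  tot <- colSums(counts(out)[probeClass(out) == "endogenous", ])
  expect_equal(unname(tot), c(2000, 2000))
  ## controls excluded from the scaling sum: same factors whatever pos holds
  out2 <- contentNormalize(toyCountSet(endo))
  expect_equal(counts(out2)[c("pA", "pB"), ], counts(out)[c("pA", "pB"), ])

  ## idempotence of both ratio normalisations
  again <- contentNormalize(out)
  expect_equal(counts(again), counts(out), tolerance = 1e-9)
  pn <- positiveControlNormalize(x)
  expect_equal(counts(positiveControlNormalize(pn)), counts(pn),
               tolerance = 1e-9)
})

test_that("minimum-count filter honours the >= convention and matches a brute-force scan", {
  endo <- matrix(c(100, 100, 100,
                   99.9, 500, 500,
                   150, 101, 120,
                   20, 20, 20,
                   1000, 1000, 99), 5, 3, byrow = TRUE,
                 dimnames = list(paste0("p", 1:5), c("S1", "S2", "S3")))
  x <- toyCountSet(endo)
  out <- filterMinCount(x, threshold = 100)
  keepOracle <- rownames(endo)[apply(endo, 1, function(r) all(r >= 100))]
  expect_identical(rownames(out)[probeClass(out) == "endogenous"], keepOracle)
  expect_true("p1" %in% rownames(out))  # boundary: min exactly 100 retained

  outMean <- filterMinCount(x, threshold = 100, stat = "mean")
  keepMean <- rownames(endo)[rowMeans(endo) >= 100]
  expect_identical(rownames(outMean)[probeClass(outMean) == "endogenous"],
                   keepMean)

  expect_warning(filterMinCount(x, threshold = 1e9), "no endogenous probe")
  expect_error(filterMinCount(x, threshold = 0), "> 0")
})

test_that("log2 transform floors at one and is monotone", {
  endo <- matrix(c(1024, 0, 0.5, 7), 4, 1,
                 dimnames = list(paste0("p", 1:4), "S1"))
  ex <- log2Transform(toyCountSet(endo))
  expect_equal(unname(log2expr(ex)[, 1]), c(10, 0, 0, log2(7)))
  x <- sort(runif(50, 0, 2000))
  v <- log2(pmax(x, 1))
  expect_true(all(diff(v) >= 0))
})

test_that("the preprocessing ladder composes in order with a faithful QC report", {
  cfg <- simConfig(nProbes = 120, seed = 107,
                   cellMeans = defaultCellMeans(120, seed = 6))
  coh <- simulateCohort(cfg)
  pp <- runPreprocess(coh@counts)
  steps <- pp$qc@steps
  expect_identical(steps$step,
                   c("raw", "probe_background_correct",
                     "positive_control_normalize",
                     "negative_background_threshold", "content_normalize",
                     "filter_min_count", "log2_transform"))
  expect_true(all(diff(steps$probes) <= 0))

  ## QC attrition equals an independent recomputation of the ladder
  raw <- counts(coh@counts)
  pc <- probeClass(coh@counts)
  posSum <- colSums(raw[pc == "pos", ])
  scaled <- sweep(raw, 2, mean(posSum) / posSum, `*`)
  thr <- apply(scaled[pc == "neg", ], 2, function(v) mean(v) + 2 * sd(v))
  sub <- sweep(scaled[pc == "endogenous", ], 2, thr, `-`)
  detected <- rownames(sub)[apply(sub >= 0, 1, all)]
  ## detected count and retained count surface in the report
  expect_equal(steps$probes[steps$step == "negative_background_threshold"],
               length(detected))
  expect_equal(steps$probes[steps$step == "log2_transform"], nrow(pp$expr))

  ## identity config: no corrections, uniform controls => output is log2 of
  ## the content-normalised input
  endo <- matrix(c(200, 300, 120, 500, 150, 800), 3, 2,
                 dimnames = list(paste0("p", 1:3), c("S1", "S2")))
  x <- toyCountSet(endo)   # equal pos sums, zero negatives
  ppI <- runPreprocess(x, minCount = 1)
  tots <- colSums(endo)
  manual <- log2(pmax(sweep(endo, 2, mean(tots) / tots, `*`), 1))
  expect_equal(unname(log2expr(ppI$expr)), unname(manual), tolerance = 1e-12)

  ## serialised QC report
  jf <- file.path(withr::local_tempdir(), "qc.json")
  writeQCReport(pp$qc, jf)
  parsed <- jsonlite::read_json(jf)
  expect_equal(length(parsed$steps), 7)
})

test_that("per-sample rescaling of raw counts only shifts log2 expression by a common constant", {
  cfg <- simConfig(nProbes = 80, seed = 109,
                   cellMeans = defaultCellMeans(80, seed = 7))
  coh <- simulateCohort(cfg)
  raw <- coh@counts
  pp1 <- runPreprocess(raw)

  scaled <- counts(raw)
  scaled[, 3] <- scaled[, 3] * 3
  raw2 <- MiRCountSet(scaled, probeClass = probeClass(raw))
  pp2 <- runPreprocess(raw2)
  expect_identical(rownames(pp2$expr), rownames(pp1$expr))
  dlt <- log2expr(pp2$expr) - log2expr(pp1$expr)
  expect_lt(max(abs(dlt - dlt[1, 1])), 1e-9)
})
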