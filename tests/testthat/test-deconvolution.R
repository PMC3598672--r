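test_that("leukocyte differentials collapse into granulocyte/PBMC fractions", {
  diffs <- exampleDifferentials()
  hc <- diffs[diffs$group == "HC", ]
  ## printed means: granulocytes 56.4+2.1+5.6 = 64.1, PBMC 29.6+4.5 = 34.1
  gran <- hc$neutrophils + hc$eosinophils + hc$basophils
  pbmc <- hc$lymphocytes + hc$monocytes
  expect_equal(gran, 64.1)
  expect_equal(pbmc, 34.1)
  fr <- groupCellFractions(hc[, c("neutrophils", "lymphocytes", "monocytes",
                                  "eosinophils", "basophils")])
  expect_equal(unname(fractions(fr)[1, ]),
               c(64.1, 34.1) / 98.2, tolerance = 1e-12)

  ## a row closing to 100 is proportionally unchanged
  row <- data.frame(neutrophils = 60, lymphocytes = 30, monocytes = 5,
                    eosinophils = 3, basophils = 2)
  fr2 <- groupCellFractions(row)
  expect_equal(unname(fractions(fr2)[1, ]), c(65, 35) / 100)

  ## identity scheme keeps the five classes, renormalised
  fr3 <- groupCellFractions(row, scheme = "identity")
  expect_equal(unname(fractions(fr3)[1, ]), c(60, 30, 5, 3, 2) / 100)

  expect_error(groupCellFractions(row[, -1]), "missing leukocyte class")
  rowNeg <- row; rowNeg$basophils <- -1
  expect_error(groupCellFractions(rowNeg), "non-negative")
})

test_that("zero-intercept cell regression matches the normal equations", {
  ## pure samples: coefficients are the pure-sample means
  X <- rbind(diag(2), diag(2))
  colnames(X) <- c("granulocytes", "PBMC")
  rownames(X) <- paste0("s", 1:4)
  y <- c(4, 10, 6, 12)
  fit <- fitCellRegression(y, X)
  expect_equal(unname(fit@coefficients), c(5, 11), tolerance = 1e-12)

  ## constant expression with simplex rows: exact solution beta = c
  set.seed(23)
  Xs <- fractions(simulateCellFractions(6, c(granulocytes = 4, PBMC = 2),
                                        seed = 3))
  fitC <- fitCellRegression(rep(7.5, 6), Xs)
  expect_equal(unname(fitC@coefficients), c(7.5, 7.5), tolerance = 1e-10)
  expect_equal(unname(fitC@se), c(0, 0), tolerance = 1e-10)

  ## hand-chosen 4-sample instance against the explicit normal equations
  Xh <- matrix(c(0.7, 0.3, 0.5, 0.5, 0.8, 0.2, 0.4, 0.6), 4, 2,
               byrow = TRUE, dimnames = list(paste0("s", 1:4),
                                             c("granulocytes", "PBMC")))
  yh <- c(5.1, 6.0, 4.7, 6.6)
  fh <- fitCellRegression(yh, Xh)
  oh <- oracleOriginFit(yh, Xh)
  expect_equal(unname(fh@coefficients), oh$beta, tolerance = 1e-12)
  expect_equal(unname(fh@se), oh$se, tolerance = 1e-12)

  ## property: random instances agree with the oracle to 1e-10
  set.seed(29)
  for (i in 1:25) {
    K <- sample(2:3, 1); n <- sample(6:20, 1)
    X <- matrix(abs(rnorm(n * K)) + 0.05, n, K,
                dimnames = list(NULL, paste0("c", 1:K)))
    X <- X / rowSums(X)
    y <- rnorm(n, 6, 2)
    f <- fitCellRegression(y, X)
    o <- oracleOriginFit(y, X)
    expect_lt(max(abs(f@coefficients - o$beta)), 1e-10)
    expect_lt(max(abs(f@se - o$se)), 1e-10)
  }

  Xr <- cbind(a = c(0.5, 0.5, 0.5), b = c(0.5, 0.5, 0.5))
  expect_error(fitCellRegression(1:3, Xr), "merging")
  expect_warning(fitCellRegression(1:2, Xh[1:2, ]), "fewer than K \\+ 1")
})

test_that("the pooled-SE contrast statistic evaluates its formula and is antisymmetric", {
  mk <- function(b, se, n, g) new("CellRegressionFit", group = g,
                                  coefficients = b, se = se,
                                  n = as.integer(n),
                                  df = as.integer(n - length(b)),
                                  sigma = 1, residuals = numeric(n))
  ct <- c(granulocytes = 0, PBMC = 0)
  f1 <- mk(c(granulocytes = 1, PBMC = 1), c(granulocytes = 0.5, PBMC = 0.5),
           4, "HC")
  f2 <- mk(c(granulocytes = 1, PBMC = 2), c(granulocytes = 0.5, PBMC = 0.5),
           7, "pre")
  st <- cssamStatistic(f1, f2)
  ## pooled se = sqrt((4 * 0.25 + 7 * 0.25) / 11) = 0.5; t = (2-1)/0.5 = 2
  expect_equal(st$pooled_se, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(st$t[st$cell_type == "PBMC"], 2, tolerance = 1e-12)
  expect_equal(st$t[st$cell_type == "granulocytes"], 0)

  rev <- cssamStatistic(f2, f1)
  expect_equal(rev$t, -st$t, tolerance = 1e-15)       # exact antisymmetry
  expect_equal(rev$pooled_se, st$pooled_se)

  ## zero pooled SE: equal coefficients -> 0; unequal -> signed infinity
  f3 <- mk(c(granulocytes = 1, PBMC = 3), c(granulocytes = 0, PBMC = 0),
           5, "a")
  f4 <- mk(c(granulocytes = 1, PBMC = 5), c(granulocytes = 0, PBMC = 0),
           5, "b")
  expect_warning(st0 <- cssamStatistic(f3, f4), "signed infinity")
  expect_equal(st0$t[st0$cell_type == "granulocytes"], 0)
  expect_equal(st0$t[st0$cell_type == "PBMC"], Inf)
})

test_that("permutation p-values honour their conventions", {
  sim <- simulateDeconvInstance(5, 6, effect = 0, seed = 31)

  ## constant expression: every statistic ties at zero, p = 1
  resC <- permutationTest(rep(4, 11), sim$X, sim$labels, B = 99, seed = 1)
  expect_equal(resC$p_perm, c(1, 1))

  ## p is bounded below by 1/(B+1) and reproducible under the seed
  res1 <- permutationTest(sim$y, sim$X, sim$labels, B = 200, seed = 5)
  res2 <- permutationTest(sim$y, sim$X, sim$labels, B = 200, seed = 5)
  expect_identical(res1$p_perm, res2$p_perm)
  expect_true(all(res1$p_perm >= 1 / 201 & res1$p_perm <= 1))

  ## invariance to cell-type column order
  resSwap <- permutationTest(sim$y, sim$X[, c(2, 1)], sim$labels,
                             B = 200, seed = 5)
  expect_equal(resSwap$p_perm[match(res1$cell_type, resSwap$cell_type)],
               res1$p_perm)

  expect_error(permutationTest(sim$y, sim$X, rep("a", 11), B = 10),
               "two label levels")
})

test_that("coefficients shift by c under y + c and the statistic is invariant", {
  sim <- simulateDeconvInstance(6, 7, effect = 1, seed = 37)
  r0 <- permutationTest(sim$y, sim$X, sim$labels, B = 150, seed = 9)
  r1 <- permutationTest(sim$y + 3, sim$X, sim$labels, B = 150, seed = 9)
  expect_equal(r1$beta1, r0$beta1 + 3, tolerance = 1e-9)
  expect_equal(r1$beta2, r0$beta2 + 3, tolerance = 1e-9)
  expect_equal(r1$t, r0$t, tolerance = 1e-9)
  expect_equal(r1$p_perm, r0$p_perm)
})

test_that("coefficients recover the truth as noise vanishes and are unbiased", {
  ## zero noise: exact recovery
  sim <- simulateDeconvInstance(8, 8, effect = 2, sigma = 0, seed = 41)
  f2 <- fitCellRegression(sim$y[9:16], sim$X[9:16, ])
  expect_lt(max(abs(f2@coefficients - sim$beta2)), 1e-6)

  ## zero-effect replicates: mean coefficient error within 3 MC SEs of 0
  set.seed(43)
  errs <- t(sapply(1:100, function(r) {
    s <- simulateDeconvInstance(7, 7, effect = 0, seed = 1000 + r)
    fitCellRegression(s$y, s$X)@coefficients - s$beta1
  }))
  mcse <- apply(errs, 2, sd) / sqrt(nrow(errs))
  expect_true(all(abs(colMeans(errs)) < 3 * mcse))
})

test_that("a strong PBMC-only effect is attributed to PBMCs, not granulocytes", {
  ## effect 16 residual sds, n = 4 vs 7: PBMC p is usually significant and
  ## granulocyte p rarely is
  nrep <- 20
  p <- matrix(NA_real_, nrep, 2)
  for (r in seq_len(nrep)) {
    sim <- simulateDeconvInstance(4, 7, effect = 16 * 0.5, seed = 5000 + r)
    res <- permutationTest(sim$y, sim$X, sim$labels, B = 500,
                           seed = 6000 + r)
    p[r, ] <- res$p_perm[match(c("granulocytes", "PBMC"), res$cell_type)]
  }
  expect_gte(mean(p[, 2] <= 0.05), 0.5)
  expect_gte(mean(p[, 1] > 0.05), 0.8)
  expect_lt(median(p[, 2]), median(p[, 1]))
})

test_that("contrast tables cover every probe x cell type", {
  sim <- simulateDeconvInstance(5, 6, effect = 1, seed = 47)
  E <- rbind(`miR-a` = sim$y, `miR-b` = sim$y + rnorm(11, 0, 0.1))
  tab <- deconvolveContrast(E, sim$X, sim$labels, probes = "miR-a", B = 50,
                            seed = 3)
  expect_equal(nrow(tab), 2)   # single probe -> K rows
  tab2 <- deconvolveContrast(E, sim$X, sim$labels,
                             probes = c("miR-a", "miR-b"), B = 50, seed = 3)
  expect_equal(nrow(tab2), 4)
  ## percent scaling divides coefficients by 100 but not the statistic
  tabP <- deconvolveContrast(E, sim$X, sim$labels, probes = "miR-a", B = 50,
                             seed = 3, coefScale = "percent")
  expect_equal(tabP$beta1, tab$beta1 / 100, tolerance = 1e-12)
  expect_equal(tabP$t, tab$t, tolerance = 1e-12)
  expect_error(deconvolveContrast(E, sim$X, sim$labels, probes = "nope"),
               "not in expression")
})
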