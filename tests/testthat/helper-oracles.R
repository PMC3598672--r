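## Independent brute-force oracles and small fixture builders.

## Zero-intercept least squares via explicit normal equations.
oracleOriginFit <- function(y, X) {
  XtXinv <- solve(t(X) %*% X)
  beta <- unname(drop(XtXinv %*% t(X) %*% y))
  res <- y - drop(X %*% beta)
  sigma2 <- sum(res^2) / (length(y) - ncol(X))
  list(beta = beta, se = unname(sqrt(diag(XtXinv) * sigma2)))
}

## BH step-up by direct enumeration of the definition:
## q_i = min over j with p_(j) >= p_(i) of m p_(j) / j, capped at 1.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

## Two-sample pooled-variance difference of means, by the textbook formulas.
oraclePooledT <- function(y1, y2) {
  n1 <- length(y1); n2 <- length(y2)
  s2 <- (sum((y1 - mean(y1))^2) + sum((y2 - mean(y2))^2)) / (n1 + n2 - 2)
  coef <- mean(y2) - mean(y1)
  se <- sqrt(s2 * (1 / n1 + 1 / n2))
  list(coef = coef, se = se, t = coef / se, sigma = sqrt(s2),
       df = n1 + n2 - 2)
}

## Small hand-built count set: nEndo endogenous probes plus 2 positive and
## 8 negative controls, all counts supplied explicitly.
toyCountSet <- function(endo, pos = NULL, neg = NULL) {
  n <- ncol(endo)
  if (is.null(pos))
    pos <- matrix(50, 2, n, dimnames = list(c("POS_A", "POS_B"), colnames(endo)))
  if (is.null(neg))
    neg <- matrix(0, 8, n, dimnames = list(paste0("NEG_", LETTERS[1:8]),
                                           colnames(endo)))
  cts <- rbind(endo, pos, neg)
  MiRCountSet(cts, probeClass = rep(c("endogenous", "pos", "neg"),
                                    c(nrow(endo), nrow(pos), nrow(neg))))
}

## Cell-specific simulation used by the deconvolution harnesses: two groups,
## Dirichlet fractions, expression = X beta + N(0, sigma), with an additive
## effect on the PBMC coefficient of group 2.
simulateDeconvInstance <- function(n1, n2, effect, sigma = 0.5, seed = 1L,
                                   alpha = defaultDirichletAlpha()) {
  f1 <- fractions(simulateCellFractions(n1, alpha$HC, seed = seed))
  f2 <- fractions(simulateCellFractions(n2, alpha$pre, seed = seed + 50000L))
  X <- rbind(f1, f2)
  rownames(X) <- paste0("s", seq_len(n1 + n2))
  labels <- factor(rep(c("g1", "g2"), c(n1, n2)), levels = c("g1", "g2"))
  beta1 <- c(granulocytes = 8, PBMC = 8)
  beta2 <- beta1
  beta2["PBMC"] <- beta2["PBMC"] + effect
  set.seed(seed + 90000L)
  y <- c(X[seq_len(n1), , drop = FALSE] %*% beta1,
         X[n1 + seq_len(n2), , drop = FALSE] %*% beta2) +
       rnorm(n1 + n2, 0, sigma)
  list(y = y, X = X, labels = labels, beta1 = beta1, beta2 = beta2,
       sigma = sigma)
}
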