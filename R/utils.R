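#' @importFrom stats rgamma rnorm rpois rnbinom sd var pt p.adjust aov anova
#'   median mad runif
#' @importFrom methods new validObject is slot
#' @importFrom utils read.csv write.csv packageVersion
NULL

## Dirichlet sampler via normalised gammas; rows index draws.
.rdirichlet <- function(n, alpha) {
  if (length(alpha) < 2L)
    stop("'alpha' must have length >= 2")
  bad <- which(!is.finite(alpha) | alpha <= 0)
  if (length(bad))
    stop(sprintf("Dirichlet concentration must be strictly positive; entry %d is %s",
                 bad[1L], format(alpha[bad[1L]])))
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n, ncol = k)
  g / rowSums(g)
}

## Newton inversion of the trigamma function (monotone decreasing on (0, Inf)).
.trigammaInverse <- function(x) {
  stopifnot(length(x) == 1L, is.finite(x))
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(100L)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

## Derive a stream-specific 32-bit seed from a master seed.
.deriveSeed <- function(seed, k) {
  as.integer((as.double(seed) + 100003 * as.double(k)) %% 2147483647)
}

.assertScalarSeed <- function(seed) {
  if (is.null(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite integer")
  as.integer(seed)
}

## Canonical CSV writer: fixed 15 significant digits so identical numbers
## serialise to identical bytes across runs.
.writeCanonicalCsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) {
    out <- formatC(x, digits = 15L, format = "g")
    out[is.na(x)] <- NA_character_
    out
  })
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
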