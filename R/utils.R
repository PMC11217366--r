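## Reporting convention: round half away from zero (55.5% -> 56%), unlike
## base round()'s round-half-even.
.roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Evaluate a block under a fixed RNG state, restoring the caller's stream.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Order subtype labels canonically (LumA, LumB, HER2-E, BL, NL), unknown
## labels last in alphabetical order.
.canonicalOrder <- function(labels) {
  known <- intersect(.SUBTYPES, labels)
  c(known, sort(setdiff(labels, .SUBTYPES)))
}

## Inverse of the type-7 empirical quantile function: the percentile (0..100)
## at which value v sits within x, linearly interpolated between order
## statistics and clamped to [0, 100].
.percentileOf <- function(x, v) {
  xs <- sort(x)
  n <- length(xs)
  if (v <= xs[1L]) return(0)
  if (v >= xs[n]) return(100)
  probs <- seq(0, 1, length.out = n)
  100 * stats::approx(xs, probs, xout = v, ties = mean)$y
}

## Type-7 quantile (R default): linear interpolation between closest order
## statistics — must match .percentileOf for the sgPct round trip.
.quantile7 <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
}

.checkSameSamples <- function(idsA, idsB) {
  if (!setequal(idsA, idsB)) {
    extraA <- setdiff(idsA, idsB)
    extraB <- setdiff(idsB, idsA)
    stop("call tables cover different samples; only in A: [",
         paste(extraA, collapse = ", "), "]; only in B: [",
         paste(extraB, collapse = ", "), "]")
  }
}
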