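# Small in-code fixtures shared across test files.

toyMatrix <- function(nr = 5, nc = 4, seed = 42, scale = "log_generic") {
  set.seed(seed)
  m <- matrix(rnorm(nr * nc, mean = 8, sd = 2), nr, nc,
              dimnames = list(sprintf("g%02d", seq_len(nr)),
                              sprintf("s%02d", seq_len(nc))))
  ExpressionMatrix(m, scale = scale)
}

toyCounts <- function(nr = 5, nc = 4, seed = 42) {
  set.seed(seed)
  m <- matrix(rpois(nr * nc, lambda = 200), nr, nc,
              dimnames = list(sprintf("g%02d", seq_len(nr)),
                              sprintf("s%02d", seq_len(nc))))
  ExpressionMatrix(m, scale = "counts")
}

table1Path <- function() {
  system.file("extdata", "paloma2_table1.tsv", package = "subtypeConcord")
}

table2Path <- function() {
  system.file("extdata", "pallet_table2.tsv", package = "subtypeConcord")
}

# Independent Spearman with average ranks, built from first principles so the
# classifier has a second route to compare against.
bruteSpearman <- function(a, b) {
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Random strictly increasing map: positive-coefficient odd polynomial plus
# scaled softplus pieces, enough variety to exercise rank invariance.
randomMonotoneMap <- function() {
  a <- runif(1, 0.2, 3); b <- runif(1, 0, 2); c0 <- runif(1, -2, 2)
  k <- runif(1, 0.1, 1)
  function(x) a * x + b * x^3 / (1 + x^2) + k * log1p(exp(x)) + c0
}
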