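test_that("log2CPM matches its definition and conserves column sums", {
  x <- ExpressionMatrix(matrix(c(750000, 250000), 2, 1,
                               dimnames = list(c("g1", "g2"), "s1")),
                        scale = "counts")
  out <- exprValues(log2CPM(x))
  expect_equal(out[, 1], log2(c(750000, 250000) + 1), ignore_attr = TRUE)

  cx <- toyCounts(50, 8, seed = 11)
  v <- exprValues(cx)
  v[3, ] <- 0                        # an all-zero gene stays a zero row
  cx <- ExpressionMatrix(v, scale = "counts")
  lg <- exprValues(log2CPM(cx))
  expect_true(all(lg[3, ] == 0))
  cpm <- 2^lg - 1
  expect_lt(max(abs(colSums(cpm) - 1e6)), 1e-6)

  v[, 2] <- 0
  expect_error(log2CPM(ExpressionMatrix(v, scale = "counts")), "s02")
})

test_that("quantile normalization equals the mean-of-order-statistics oracle", {
  m <- matrix(c(2, 4, 6, 8, 2, 4), 3, 2,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
  x <- ExpressionMatrix(m, scale = "log_generic")
  qn <- exprValues(quantileNormalize(x))
  ref <- rowMeans(apply(m, 2, sort))           # brute-force reference
  oracle <- apply(m, 2, function(col) ref[rank(col)])
  expect_equal(qn, oracle, ignore_attr = TRUE)

  # permuted columns land on permutations of the same reference
  set.seed(12)
  p <- sample(20)
  m2 <- cbind(s1 = rnorm(20)[p], s2 = rnorm(20))
  rownames(m2) <- paste0("g", 1:20)
  qn2 <- exprValues(quantileNormalize(ExpressionMatrix(m2, "log_generic")))
  expect_equal(unname(sort(qn2[, 1])), unname(sort(qn2[, 2])),
               tolerance = 1e-12)

  # identical sorted columns, and idempotence
  x3 <- toyMatrix(30, 5, seed = 13)
  q1 <- quantileNormalize(x3)
  s <- apply(exprValues(q1), 2, sort)
  expect_lt(max(abs(s - s[, 1])), 1e-12)
  q2 <- quantileNormalize(q1)
  expect_lt(max(abs(exprValues(q2) - exprValues(q1))), 1e-12)

  expect_error(quantileNormalize(toyMatrix(5, 1)), "at least 2")
})

test_that("quantile normalization averages ties over the spanned reference values", {
  m <- matrix(c(1, 1, 5, 2, 7, 4), 3, 2,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
  qn <- exprValues(quantileNormalize(ExpressionMatrix(m, "log_generic")))
  ref <- rowMeans(apply(m, 2, sort))
  expect_equal(unname(qn[1:2, 1]), rep(mean(ref[1:2]), 2), tolerance = 1e-12)
})

test_that("upper-quartile FPKM matches a brute-force computation", {
  set.seed(14)
  n <- 20
  counts <- matrix(rpois(n * 3, 100), n, 3,
                   dimnames = list(sprintf("g%02d", 1:n), c("a", "b", "c")))
  len <- sample(500:3000, n)
  pc <- rep(c(TRUE, FALSE), length.out = n)
  x <- ExpressionMatrix(counts, scale = "counts")
  out <- exprValues(uqFPKM(x, len, pc))
  for (j in 1:3) {
    uq <- unname(quantile(counts[pc, j], 0.75, type = 7))
    expect_equal(out[, j], log2(counts[, j] / (len / 1e3 * uq) + 1),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  # count equal to the sample UQ at length 1000 -> pre-log value exactly 1
  # (gene 2 is non-protein-coding, so editing it leaves the UQ untouched)
  uq1 <- unname(quantile(counts[pc, 1], 0.75, type = 7))
  c2 <- counts; c2[2, 1] <- uq1
  len2 <- len; len2[2] <- 1000
  out2 <- exprValues(uqFPKM(ExpressionMatrix(c2, "counts"), len2, pc))
  expect_equal(unname(2^out2[2, 1] - 1), 1, tolerance = 1e-12)
  # doubling a sample's counts leaves its values unchanged (UQ doubles too)
  c3 <- counts; c3[, 2] <- 2 * c3[, 2]
  out3 <- exprValues(uqFPKM(ExpressionMatrix(c3, "counts"), len, pc))
  expect_equal(out3[, 2], out[, 2], tolerance = 1e-12)
  # a sample whose protein-coding counts are mostly zero has UQ 0
  c4 <- counts; c4[pc, 3] <- 0
  expect_error(uqFPKM(ExpressionMatrix(c4, "counts"), len, pc), "c")
})

test_that("housekeeping normalization subtracts the per-sample housekeeping mean", {
  x <- toyMatrix(10, 6, seed = 15)
  hk <- c("g01", "g04", "g07")
  out <- housekeepingNormalize(x, hk)
  expect_lt(max(abs(colMeans(exprValues(out)[hk, ]))), 1e-12)
  # constant housekeeping level c shifts everything down by c
  v <- exprValues(x); v[hk, 2] <- 5
  out2 <- exprValues(housekeepingNormalize(ExpressionMatrix(v, "log_generic"), hk))
  expect_equal(out2[, 2], v[, 2] - 5, tolerance = 1e-12, ignore_attr = TRUE)
  # per-sample offsets cancel
  set.seed(16)
  off <- rnorm(6)
  v3 <- sweep(exprValues(x), 2, off, "+")
  out3 <- housekeepingNormalize(ExpressionMatrix(v3, "log_generic"), hk)
  expect_lt(max(abs(exprValues(out3) - exprValues(out))), 1e-12)
  expect_error(housekeepingNormalize(x, c("g01", "nope")), "nope")
})

test_that("sgPct reference maps the global median to the right subgroup percentile", {
  # subgroup = full cohort with an odd sample count -> percentile 50 everywhere
  x <- toyMatrix(8, 9, seed = 17)
  ref <- buildSgPctReference(x, rep(TRUE, 9))
  expect_lt(max(abs(ref@percentile - 50)), 1e-9)

  # cohort {1..10}, subgroup {4..8}: percentile of the global median 5.5
  m <- matrix(1:10, 1, 10, dimnames = list("g1", paste0("s", 1:10)))
  x2 <- ExpressionMatrix(m, scale = "log_generic")
  ref2 <- buildSgPctReference(x2, paste0("s", 4:8))
  # brute force: type-7 inverse within c(4,5,6,7,8) at v = 5.5
  expect_equal(ref2@percentile, 37.5, tolerance = 1e-9)
  expect_equal(ref2@globalMedian, 5.5)
  expect_equal(ref2@subgroupMedian, 6)

  # global median below the subgroup minimum clamps to 0
  m3 <- rbind(g1 = c(1, 1, 1, 1, 10, 12, 14))
  colnames(m3) <- paste0("s", 1:7)
  ref3 <- buildSgPctReference(ExpressionMatrix(m3, "log_generic"),
                              paste0("s", 5:7))
  expect_equal(ref3@percentile, 0)

  expect_error(buildSgPctReference(x, c(TRUE, rep(FALSE, 8))), "at least 2")
})

test_that("sgPct centering reduces to median centering at percentile 50", {
  x <- toyMatrix(10, 11, seed = 18)
  ref <- buildSgPctReference(x, rep(TRUE, 11))     # all percentiles 50
  out <- exprValues(sgPctCenter(x, ref))
  med <- apply(exprValues(x), 1, median)
  expect_lt(max(abs(out - (exprValues(x) - med))), 1e-9)
  # constant gene centers to zero
  v <- exprValues(x); v[4, ] <- 3.3
  refc <- buildSgPctReference(ExpressionMatrix(v, "log_generic"), rep(TRUE, 11))
  outc <- exprValues(sgPctCenter(ExpressionMatrix(v, "log_generic"), refc))
  expect_lt(max(abs(outc[4, ])), 1e-12)
  expect_error(sgPctCenter(toyMatrix(12, 4, seed = 1), ref), "no factors")
})

test_that("sgPct centering of the reference subgroup subtracts the global median", {
  set.seed(19)
  x <- toyMatrix(30, 41, seed = 19)
  sub <- rep(c(TRUE, TRUE, FALSE), length.out = 41)
  ref <- buildSgPctReference(x, sub)
  subgroup <- ExpressionMatrix(exprValues(x)[, sub], scale = "log_generic")
  out <- exprValues(sgPctCenter(subgroup, ref))
  recovered <- exprValues(subgroup) - out   # the value actually subtracted
  expect_lt(max(abs(recovered - ref@globalMedian)), 1e-9)
})

test_that("sgMd centering moves test medians onto the reference subgroup medians", {
  x <- toyMatrix(12, 15, seed = 20)
  ref <- buildSgPctReference(x, rep(c(TRUE, FALSE, TRUE), 5))
  test <- toyMatrix(12, 9, seed = 21)
  out <- sgMdCenter(test, ref)
  expect_lt(max(abs(apply(exprValues(out), 1, median) - ref@subgroupMedian)),
            1e-12)
  # fixed point: already-aligned medians are untouched
  aligned <- ExpressionMatrix(
    exprValues(test) - (apply(exprValues(test), 1, median) - ref@subgroupMedian),
    scale = "log_generic")
  out2 <- sgMdCenter(aligned, ref)
  expect_lt(max(abs(exprValues(out2) - exprValues(aligned))), 1e-12)
  # a shifted copy of the subgroup recovers the original values
  set.seed(22)
  shift <- rnorm(12)
  sub <- ExpressionMatrix(exprValues(x)[, rep(c(TRUE, FALSE, TRUE), 5)] + shift,
                          scale = "log_generic")
  out3 <- sgMdCenter(sub, ref)
  orig <- exprValues(x)[, rep(c(TRUE, FALSE, TRUE), 5)]
  centered_orig <- orig - (apply(orig, 1, median) - ref@subgroupMedian)
  expect_lt(max(abs(exprValues(out3) - centered_orig)), 1e-12)
})

test_that("centering schemes commute with shared per-gene offsets", {
  x <- toyMatrix(15, 21, seed = 23)
  sub <- rep(c(TRUE, FALSE, TRUE), 7)
  test <- toyMatrix(15, 10, seed = 24)
  set.seed(25)
  delta <- rnorm(15)
  xs <- ExpressionMatrix(exprValues(x) + delta, "log_generic")
  ts <- ExpressionMatrix(exprValues(test) + delta, "log_generic")
  # sgPct centers within the test cohort, so a shared offset cancels exactly
  a <- exprValues(sgPctCenter(test, buildSgPctReference(x, sub)))
  b <- exprValues(sgPctCenter(ts, buildSgPctReference(xs, sub)))
  expect_lt(max(abs(a - b)), 1e-9)
  # sgMd aligns onto the reference subgroup's absolute location, so the
  # shared offset propagates into the output unchanged
  a2 <- exprValues(sgMdCenter(test, buildSgPctReference(x, sub)))
  b2 <- exprValues(sgMdCenter(ts, buildSgPctReference(xs, sub)))
  expect_lt(max(abs(b2 - (a2 + delta))), 1e-9)
})

test_that("technical calibration applies, inverts, and is recoverable by fitting", {
  x <- toyMatrix(25, 40, seed = 26)
  idf <- CalibrationFactors(geneIds(x), rep(1, 25), rep(0, 25))
  expect_lt(max(abs(exprValues(applyCalibration(x, idf)) - exprValues(x))),
            1e-15)
  set.seed(27)
  fac <- CalibrationFactors(geneIds(x), runif(25, 0.6, 1.6), rnorm(25))
  y <- applyCalibration(x, fac)
  back <- applyCalibration(y, invertCalibration(fac))
  expect_lt(max(abs(exprValues(back) - exprValues(x))), 1e-10)

  # least-squares factors fitted on a noisily measured distorted copy
  # recover the source within the measurement noise
  noise_sd <- 0.2
  distorted <- ExpressionMatrix(
    exprValues(applyCalibration(x, fac)) +
      matrix(rnorm(25 * 40, sd = 0), 25, 40), "log_generic")
  fit <- fitCalibration(distorted, x)
  rec <- applyCalibration(distorted, fit)
  rmse <- sqrt(rowMeans((exprValues(rec) - exprValues(x))^2))
  expect_lt(max(rmse), 1e-10)   # noise-free distortion: exact inversion

  noisy <- ExpressionMatrix(
    exprValues(x) + matrix(rnorm(25 * 40, sd = noise_sd), 25, 40),
    "log_generic")
  noisy_dist <- applyCalibration(noisy, fac)
  fit2 <- fitCalibration(noisy_dist, x)
  rec2 <- applyCalibration(noisy_dist, fit2)
  rmse2 <- sqrt(rowMeans((exprValues(rec2) - exprValues(x))^2))
  expect_lt(mean(rmse2), noise_sd)

  expect_error(applyCalibration(toyMatrix(30, 4, seed = 1), fac), "no factors")
})
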