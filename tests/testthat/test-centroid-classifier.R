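makeToyCentroids <- function(nGenes = 30, labels = c("LumA", "LumB", "HER2-E", "BL"),
                             seed = 31, method = "spearman") {
  cfg <- simulationConfig(nGenes = nGenes, subtypes = labels,
                          referenceComposition = setNames(rep(1 / length(labels),
                                                              length(labels)), labels),
                          trialComposition = setNames(rep(1 / length(labels),
                                                          length(labels)), labels))
  cs <- makeCentroids(cfg, seed = seed)
  CentroidSet(centroidValues(cs), method = method)
}

test_that("a sample equal to a centroid is called as that centroid with rho 1", {
  cs <- makeToyCentroids()
  v <- centroidValues(cs)[, "LumA", drop = FALSE]
  colnames(v) <- "s1"
  cl <- classify(ExpressionMatrix(v, "centered"), cs,
                 classifierConfig(method = "spearman"))
  expect_identical(unname(calls(cl)), "LumA")
  expect_equal(unname(scores(cl)[1, "LumA"]), 1, tolerance = 1e-12)
})

test_that("Spearman calls match a brute-force rank-correlation oracle", {
  # 6-gene worked instance with hand-laid-out centroid rank patterns
  genes <- paste0("g", 1:6)
  cen <- matrix(c(1, 2, 3, 4, 5, 6,
                  6, 5, 4, 3, 2, 1,
                  2, 1, 4, 3, 6, 5,
                  3, 6, 1, 5, 2, 4), 6, 4,
                dimnames = list(genes, c("LumA", "LumB", "HER2-E", "BL")))
  cen <- cen + 0  # numeric
  set.seed(32)
  v <- matrix(rnorm(6 * 10), 6, 10,
              dimnames = list(genes, paste0("s", 1:10)))
  cl <- classify(ExpressionMatrix(v, "centered"),
                 CentroidSet(cen, "spearman"),
                 classifierConfig(method = "spearman", minGenes = 3))
  for (j in 1:10) {
    rho <- sapply(colnames(cen), function(k) bruteSpearman(v[, j], cen[, k]))
    expect_equal(unname(scores(cl)[j, names(rho)]), unname(rho),
                 tolerance = 1e-12)
    expect_identical(unname(calls(cl))[j], names(which.max(rho)))
  }
})

test_that("Spearman calls are invariant under strictly monotone per-sample maps", {
  cs <- makeToyCentroids(40)
  co <- simulateCohort(cs, c(LumA = .4, LumB = .3, `HER2-E` = .2, BL = .1),
                       30, noiseSd = 1, seed = 33)
  base <- calls(classify(co, cs, classifierConfig(method = "spearman")))
  set.seed(34)
  changed <- 0L
  for (i in 1:25) {
    v <- exprValues(co)
    for (j in seq_len(ncol(v))) v[, j] <- randomMonotoneMap()(v[, j])
    tr <- classify(ExpressionMatrix(v, "centered"), cs,
                   classifierConfig(method = "spearman"))
    changed <- changed + sum(calls(tr) != base)
  }
  expect_identical(changed, 0L)
})

test_that("Pearson calls are invariant under positive-slope affine maps", {
  cs <- makeToyCentroids(40, method = "pearson")
  co <- simulateCohort(cs, c(LumA = .4, LumB = .3, `HER2-E` = .2, BL = .1),
                       30, noiseSd = 1, seed = 35)
  base <- calls(classify(co, cs, classifierConfig(method = "pearson")))
  set.seed(36)
  for (i in 1:10) {
    a <- runif(30, 0.2, 4); b <- rnorm(30, sd = 3)
    v <- sweep(sweep(exprValues(co), 2, a, "*"), 2, b, "+")
    tr <- classify(ExpressionMatrix(v, "centered"), cs,
                   classifierConfig(method = "pearson"))
    expect_identical(calls(tr), base)
  }
})

test_that("accuracy is perfect at zero noise and does not improve with noise", {
  cs <- makeToyCentroids(50, labels = c("LumA", "LumB", "HER2-E", "BL", "NL"))
  comp <- c(LumA = .2, LumB = .2, `HER2-E` = .2, BL = .2, NL = .2)
  acc <- sapply(c(0, 1, 2.5), function(sd) {
    mean(sapply(1:5, function(s) {
      co <- simulateCohort(cs, comp, 60, noiseSd = sd, seed = 100 * s + sd * 10)
      truth <- SummarizedExperiment::colData(co)$true_subtype
      mean(calls(classify(co, cs, classifierConfig(method = "spearman"))) == truth)
    }))
  })
  expect_equal(acc[1], 1)
  expect_true(acc[2] >= acc[3])
})

test_that("degenerate inputs are refused", {
  cs <- makeToyCentroids(30)
  v <- matrix(1, 30, 2, dimnames = list(geneIds(cs), c("flat1", "flat2")))
  expect_error(classify(ExpressionMatrix(v, "centered"), cs,
                        classifierConfig(method = "pearson")), "flat1")
  few <- ExpressionMatrix(matrix(rnorm(8), 4, 2,
                                 dimnames = list(geneIds(cs)[1:4],
                                                 c("a", "b"))), "centered")
  expect_error(classify(few, cs, classifierConfig(minGenes = 10)), "minGenes")
})

test_that("margin is zero exactly when the top correlations tie", {
  cs <- makeToyCentroids(30)
  co <- simulateCohort(cs, c(LumA = .25, LumB = .25, `HER2-E` = .25, BL = .25),
                       40, noiseSd = 1, seed = 37)
  cl <- classify(co, cs, classifierConfig(method = "spearman"))
  expect_identical(unname(tieFlags(cl)), unname(margins(cl) <= 1e-12))
  expect_true(all(margins(cl) >= 0))
})

test_that("top-two extraction matches a sorting oracle", {
  sc <- matrix(c(0.9, 0.85, 0.1, 0.0), 1, 4,
               dimnames = list("s1", c("LumA", "LumB", "HER2-E", "BL")))
  x <- SubtypeCalls("s1", "LumA", sc)
  tt <- topTwo(x)
  expect_equal(tt$delta, 0.05, tolerance = 1e-12)
  expect_identical(tt$best_label, "LumA")
  expect_identical(tt$second_label, "LumB")

  # degenerate all-equal scores resolve by tie order
  sc2 <- matrix(0.5, 1, 4,
                dimnames = list("s1", c("BL", "HER2-E", "LumB", "LumA")))
  x2 <- SubtypeCalls("s1", "LumA", sc2)
  tt2 <- topTwo(x2)
  expect_identical(tt2$best_label, "LumA")
  expect_identical(tt2$second_label, "LumB")
  expect_equal(tt2$delta, 0)

  set.seed(38)
  sc3 <- matrix(runif(1000 * 4, -1, 1), 1000, 4,
                dimnames = list(sprintf("s%04d", 1:1000),
                                c("LumA", "LumB", "HER2-E", "BL")))
  calls3 <- colnames(sc3)[max.col(sc3)]
  x3 <- SubtypeCalls(rownames(sc3), calls3, sc3)
  tt3 <- topTwo(x3)
  for (i in c(1, 17, 500, 1000)) {
    o <- order(sc3[i, ], decreasing = TRUE)
    expect_identical(tt3$best_label[i], colnames(sc3)[o[1]])
    expect_identical(tt3$second_label[i], colnames(sc3)[o[2]])
    expect_equal(tt3$delta[i], sc3[i, o[1]] - sc3[i, o[2]], tolerance = 1e-12)
  }
  expect_true(all(tt3$delta >= 0))
})

test_that("the switching experiment moves exactly the small-margin samples", {
  cs <- makeToyCentroids(30)
  co <- simulateCohort(cs, c(LumA = .4, LumB = .3, `HER2-E` = .2, BL = .1),
                       200, noiseSd = 1.5, seed = 39)
  cl <- classify(co, cs, classifierConfig(method = "spearman"))
  sw <- switchToSecond(cl, threshold = 0.1)
  tt <- topTwo(cl)
  expect_identical(unname(switchedFlags(sw)), tt$delta <= 0.1)
  expect_equal(sw@metadata$switch$fraction_switched, mean(tt$delta <= 0.1))
  moved <- switchedFlags(sw)
  expect_true(all(calls(sw)[moved] != calls(cl)[moved]))
  expect_true(all(calls(sw)[!moved] == calls(cl)[!moved]))
  # switched samples carry their second-best label
  expect_identical(unname(calls(sw)[moved]), tt$second_label[moved])

  sw0 <- switchToSecond(cl, threshold = 0)
  expect_identical(unname(switchedFlags(sw0)), unname(tieFlags(cl)))
  expect_error(switchToSecond(cl, threshold = -0.1), ">= 0")
})

test_that("adjacency audit labels transitions under the subtype ordering", {
  sc <- diag(4)[c(1, 1, 2, 3, 4), ]
  colnames(sc) <- c("LumA", "LumB", "HER2-E", "BL")
  rownames(sc) <- paste0("s", 1:5)
  orig <- SubtypeCalls(rownames(sc), c("LumA", "LumA", "LumB", "HER2-E", "BL"), sc)
  new_calls <- c("LumB", "HER2-E", "LumA", "BL", "LumB")
  swt <- SubtypeCalls(rownames(sc), new_calls, sc,
                      switched = rep(TRUE, 5))
  audit <- adjacencyAudit(orig, swt)
  expect_identical(audit$transitions$adjacent, c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(audit$summary$n_switched, 5)
  expect_equal(audit$summary$n_adjacent, 3)

  swt2 <- SubtypeCalls("s1", "NL", matrix(c(1, 0, 0, 0, 0), 1,
                       dimnames = list("s1", c("NL", "LumA", "LumB", "HER2-E", "BL"))),
                       switched = TRUE)
  orig2 <- SubtypeCalls("s1", "NL", scores(swt2))
  expect_error(adjacencyAudit(orig2, swt2), "not in the adjacency order")
})

test_that("the Prosigna-style pipeline reduces correctly and never emits NL", {
  cs <- makeToyCentroids(40, method = "pearson")
  cfg4 <- simulationConfig(nGenes = 40,
                           subtypes = c("LumA", "LumB", "HER2-E", "BL"),
                           referenceComposition = c(LumA = .25, LumB = .25,
                                                    `HER2-E` = .25, BL = .25),
                           trialComposition = c(LumA = .25, LumB = .25,
                                                `HER2-E` = .25, BL = .25))
  co <- simulateCohort(cs, cfg4$trialComposition, 50, noiseSd = 0, seed = 40)
  hk <- geneIds(cs)[1:8]
  idf <- CalibrationFactors(geneIds(cs), rep(1, 40), rep(0, 40))
  pro <- prosignaClassify(co, cs, hk, idf)
  # identity factors reduce to housekeeping-normalized Pearson calls
  manual <- classify(housekeepingNormalize(co, hk), cs,
                     classifierConfig(method = "pearson"))
  expect_identical(calls(pro), calls(manual))
  expect_false("NL" %in% calls(pro))
  # noiseless cohorts are recovered perfectly (housekeeping subtraction is a
  # per-sample shift, which Pearson ignores)
  truth <- SummarizedExperiment::colData(co)$true_subtype
  expect_equal(mean(calls(pro) == truth), 1)

  cs5 <- makeToyCentroids(40, labels = c("LumA", "LumB", "HER2-E", "BL", "NL"),
                          method = "pearson")
  expect_error(prosignaClassify(co, cs5, hk), "without NL")
})
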