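#' Simulation configuration
#'
#' Study conditions for the synthetic cohorts: a mixed-subtype reference
#' cohort (TCGA-like composition), a trial cohort drawn only from an
#' ER+/HER2--like (luminal-dominant) composition, additive Gaussian noise
#' around subtype centroids on the log scale, and per-gene affine plus
#' optional per-sample monotone platform distortion.
#'
#' Defaults: 50 genes (a classifier-panel-sized signature); reference
#' composition
#' LumA .30, LumB .20, HER2-E .12, BL .28, NL .10 (a mixed population with a
#' substantial basal fraction); trial composition LumA .55, LumB .35,
#' HER2-E .08, BL .01, NL .01 (luminal dominance of an ER+/HER2- trial);
#' noise SD 1.0 log2 units around unit-SD centroids (per-gene noise
#' comparable to the subtype signal, as in log-expression signatures); adjacent-subtype
#' centroid correlation 0.6 decaying geometrically with distance along
#' NL-LumA-LumB-HER2-E-BL; platform distortion scale ~ lognormal(0, 0.15),
#' shift ~ N(0, 0.5); per-gene baseline abundance ~ N(8, 1.5).
#'
#' @param nGenes number of genes (>= 10).
#' @param subtypes subtype labels (subset of LumA, LumB, HER2-E, BL, NL).
#' @param referenceComposition,trialComposition named per-subtype
#'   proportions, each summing to 1.
#' @param noiseSd Gaussian noise SD around centroids (log scale, >= 0).
#' @param nReference,nTrial cohort sizes.
#' @param adjacentCor target correlation between adjacent subtype centroids.
#' @param platformScaleSdLog,platformShiftSd per-gene affine distortion:
#'   scale ~ lognormal(0, scaleSdLog) (positive by construction), shift ~
#'   N(0, shiftSd).
#' @param monotoneDistortion also apply a random increasing piecewise-linear
#'   map per sample.
#' @param baselineMean,baselineSd per-gene baseline log-abundance added to
#'   raw cohorts.
#' @return A \code{SimulationConfig} list.
#' @export
simulationConfig <- function(nGenes = 50L,
                             subtypes = c("LumA", "LumB", "HER2-E", "BL", "NL"),
                             referenceComposition = c(LumA = 0.30, LumB = 0.20,
                                                      `HER2-E` = 0.12,
                                                      BL = 0.28, NL = 0.10),
                             trialComposition = c(LumA = 0.55, LumB = 0.35,
                                                  `HER2-E` = 0.08,
                                                  BL = 0.01, NL = 0.01),
                             noiseSd = 1.0, nReference = 300L, nTrial = 150L,
                             adjacentCor = 0.6,
                             platformScaleSdLog = 0.15, platformShiftSd = 0.5,
                             monotoneDistortion = FALSE,
                             baselineMean = 8, baselineSd = 1.5) {
  nGenes <- as.integer(nGenes)
  if (nGenes < 10L) stop("nGenes must be >= 10")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  bad <- setdiff(subtypes, .SUBTYPES)
  if (length(bad)) stop("unknown subtype(s): ", paste(bad, collapse = ", "))
  for (comp in list(referenceComposition, trialComposition)) {
    if (!setequal(names(comp), subtypes))
      stop("compositions must be named by the subtypes")
    if (abs(sum(comp) - 1) > 1e-9)
      stop("composition proportions must sum to 1")
  }
  structure(list(nGenes = nGenes, subtypes = subtypes,
                 referenceComposition = referenceComposition[subtypes],
                 trialComposition = trialComposition[subtypes],
                 noiseSd = noiseSd, nReference = as.integer(nReference),
                 nTrial = as.integer(nTrial), adjacentCor = adjacentCor,
                 platformScaleSdLog = platformScaleSdLog,
                 platformShiftSd = platformShiftSd,
                 monotoneDistortion = monotoneDistortion,
                 baselineMean = baselineMean, baselineSd = baselineSd),
            class = "SimulationConfig")
}

## Positions along the biological line NL-LumA-LumB-HER2-E-BL; centroid
## correlation targets decay as adjacentCor^distance.
.subtypePositions <- c(NL = 0, LumA = 1, LumB = 2, `HER2-E` = 3, BL = 4)

#' Target centroid correlation matrix of a configuration
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return Correlation matrix over \code{config$subtypes}.
#' @export
targetCentroidCor <- function(config) {
  pos <- .subtypePositions[config$subtypes]
  d <- abs(outer(pos, pos, "-"))
  r <- config$adjacentCor^d
  dimnames(r) <- list(config$subtypes, config$subtypes)
  r
}

#' Generate subtype centroids with controlled pairwise correlations
#'
#' Draws unit-SD, mean-zero prototype profiles whose empirical pairwise
#' correlations equal the configuration's targets exactly (Gaussian draws
#' are whitened, then coloured by the Cholesky factor of the target matrix),
#' so adjacent subtypes along NL-LumA-LumB-HER2-E-BL are more similar than
#' distant ones. Deterministic given the seed.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param seed integer seed.
#' @return A \linkS4class{CentroidSet} (method \code{"spearman"}).
#' @export
makeCentroids <- function(config = simulationConfig(), seed = 1L) {
  k <- length(config$subtypes)
  if (config$nGenes <= k + 1L)
    stop("nGenes too small to realize the requested correlation structure")
  R <- targetCentroidCor(config)
  .withSeed(seed, {
    z <- matrix(stats::rnorm(config$nGenes * k), config$nGenes, k)
    zc <- scale(z, center = TRUE, scale = FALSE)
    w <- zc %*% solve(chol(stats::cov(zc)))      # exact identity covariance
    y <- w %*% chol(R)
    dimnames(y) <- list(sprintf("g%04d", seq_len(config$nGenes)),
                        config$subtypes)
    CentroidSet(y, method = "spearman")
  })
}

#' Simulate a cohort around subtype centroids
#'
#' Each sample is its (composition-drawn) subtype centroid plus i.i.d.
#' Gaussian noise per gene; at \code{noiseSd = 0} samples equal their
#' centroids exactly.
#'
#' @param centroids a \linkS4class{CentroidSet}.
#' @param composition named per-subtype proportions over the centroid
#'   labels, summing to 1.
#' @param n number of samples (> 0).
#' @param noiseSd Gaussian noise SD (>= 0).
#' @param seed integer seed.
#' @param cohort cohort label stored in the sample annotations.
#' @param prefix sample-id prefix.
#' @return An \linkS4class{ExpressionMatrix} (scale \code{"log_generic"})
#'   whose annotations carry \code{cohort} and \code{true_subtype}.
#' @export
simulateCohort <- function(centroids, composition, n, noiseSd = 0.5,
                           seed = 1L, cohort = "synthetic", prefix = cohort) {
  stopifnot(is(centroids, "CentroidSet"))
  n <- as.integer(n)
  if (n <= 0L) stop("n must be positive")
  labs <- subtypeLabels(centroids)
  if (!setequal(names(composition), labs))
    stop("composition must be named by the centroid subtypes")
  if (abs(sum(composition) - 1) > 1e-9)
    stop("composition proportions must sum to 1")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  cv <- centroidValues(centroids)
  .withSeed(seed, {
    truth <- sample(labs, n, replace = TRUE, prob = composition[labs])
    v <- cv[, truth, drop = FALSE] +
      matrix(stats::rnorm(nrow(cv) * n, sd = noiseSd), nrow(cv), n)
    colnames(v) <- sprintf("%s_%04d", prefix, seq_len(n))
    ann <- data.frame(sample_id = colnames(v), cohort = cohort,
                      true_subtype = truth, stringsAsFactors = FALSE)
    ExpressionMatrix(v, scale = "log_generic", annotation = ann)
  })
}

## Random increasing piecewise-linear map over the value range of one
## sample: positive lognormal slopes over 5 segments, anchored at the
## sample minimum.
.monotoneMap <- function(v, slopesdlog = 0.4) {
  kx <- seq(min(v), max(v), length.out = 6L)
  if (kx[1L] == kx[6L]) return(v)
  sl <- exp(stats::rnorm(5L, sd = slopesdlog))
  ky <- kx[1L] + cumsum(c(0, sl * diff(kx)))
  stats::approx(kx, ky, xout = v)$y
}

#' Apply synthetic platform distortion
#'
#' Per-gene affine distortion (scale drawn lognormal so it is positive by
#' construction, shift Gaussian) and, when enabled, an additional random
#' increasing piecewise-linear map per sample. The drawn parameters are
#' returned so tests can invert the distortion.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param config a \code{\link{simulationConfig}} supplying
#'   \code{platformScaleSdLog}, \code{platformShiftSd},
#'   \code{monotoneDistortion}.
#' @param seed integer seed.
#' @return List: \code{matrix} (distorted \linkS4class{ExpressionMatrix}),
#'   \code{factors} (the affine distortion as
#'   \linkS4class{CalibrationFactors}), \code{monotone} (whether a
#'   per-sample map was applied).
#' @export
applyPlatformBias <- function(x, config = simulationConfig(), seed = 1L) {
  stopifnot(is(x, "ExpressionMatrix"))
  v <- exprValues(x)
  .withSeed(seed, {
    sc <- exp(stats::rnorm(nrow(v), sd = config$platformScaleSdLog))
    sh <- stats::rnorm(nrow(v), sd = config$platformShiftSd)
    out <- v * sc + sh
    if (isTRUE(config$monotoneDistortion))
      for (j in seq_len(ncol(out))) out[, j] <- .monotoneMap(out[, j])
    list(matrix = .replaceValues(x, out, exprScale(x)),
         factors = CalibrationFactors(rownames(v), sc, sh),
         monotone = isTRUE(config$monotoneDistortion))
  })
}

#' Build a full trial-versus-reference scenario
#'
#' The composition-bias experiment in one bundle: centroids; a mixed
#' reference cohort with its ER+/HER2--like subgroup mask (luminal-dominant
#' by construction: LumA, LumB and NL samples); a trial cohort drawn from
#' the luminal-dominant trial composition; and a platform-distorted copy of
#' the trial cohort with the injected distortion parameters. A shared
#' per-gene baseline abundance is added to both cohorts, so classification
#' requires centering. In this scenario naive within-trial median centering
#' degrades accuracy against truth, while sgPct/sgMd centering against the
#' reference restores it (see \code{\link{scenarioAccuracy}}).
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param seed integer seed.
#' @return List: \code{centroids}, \code{reference}, \code{subgroup}
#'   (logical mask over reference samples), \code{trial},
#'   \code{trialDistorted}, \code{biasFactors}, \code{baseline},
#'   \code{config}, \code{seed}.
#' @export
makeTrialScenario <- function(config = simulationConfig(), seed = 1L) {
  centroids <- makeCentroids(config, seed = seed)
  baseline <- .withSeed(seed + 1L, stats::rnorm(config$nGenes,
                                                config$baselineMean,
                                                config$baselineSd))
  addBaseline <- function(x) .replaceValues(x, exprValues(x) + baseline,
                                            "log_generic")
  reference <- addBaseline(simulateCohort(centroids,
                                          config$referenceComposition,
                                          config$nReference, config$noiseSd,
                                          seed = seed + 2L,
                                          cohort = "reference", prefix = "ref"))
  subgroup <- colData(reference)$true_subtype %in% c("LumA", "LumB", "NL")
  colData(reference)$in_subgroup <- subgroup
  trial <- addBaseline(simulateCohort(centroids, config$trialComposition,
                                      config$nTrial, config$noiseSd,
                                      seed = seed + 3L,
                                      cohort = "trial", prefix = "trial"))
  colData(trial)$in_subgroup <- TRUE
  bias <- applyPlatformBias(trial, config, seed = seed + 4L)
  list(centroids = centroids, reference = reference, subgroup = subgroup,
       trial = trial, trialDistorted = bias$matrix,
       biasFactors = bias$factors, monotone = bias$monotone,
       baseline = baseline, config = config, seed = seed)
}

#' Truth-recovery accuracy of a centering scheme on the trial cohort
#'
#' Centers the scenario's trial cohort by the chosen scheme, classifies it
#' against the scenario centroids (Spearman) and scores the calls against
#' the simulated true subtypes.
#'
#' @param scenario a \code{\link{makeTrialScenario}} bundle.
#' @param centering \code{"sgpct"}, \code{"sgmd"}, \code{"naive"}
#'   (within-trial median centering) or \code{"none"}.
#' @param distorted classify the platform-distorted trial copy instead of
#'   the clean one.
#' @return List: \code{accuracy}, \code{calls}
#'   (\linkS4class{SubtypeCalls}), \code{truth}.
#' @export
scenarioAccuracy <- function(scenario,
                             centering = c("sgpct", "sgmd", "naive", "none"),
                             distorted = FALSE) {
  centering <- match.arg(centering)
  trial <- if (distorted) scenario$trialDistorted else scenario$trial
  centered <- switch(centering,
    sgpct = sgPctCenter(trial, buildSgPctReference(scenario$reference,
                                                   scenario$subgroup)),
    sgmd = sgMdCenter(trial, buildSgPctReference(scenario$reference,
                                                 scenario$subgroup)),
    naive = medianCenter(trial),
    none = trial)
  cl <- classify(centered, scenario$centroids,
                 classifierConfig(method = "spearman"))
  truth <- stats::setNames(colData(trial)$true_subtype, colnames(trial))
  list(accuracy = mean(calls(cl) == truth[sampleIds(cl)]), calls = cl,
       truth = truth)
}

#' Serialize a trial scenario to the standard file formats
#'
#' Writes every component (expression TSVs, annotations, centroids, bias
#' factors, scenario metadata JSON) under a directory, using the formats the
#' readers in this package consume.
#'
#' @param scenario a \code{\link{makeTrialScenario}} bundle.
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
writeScenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeExpressionMatrix(scenario$reference, p("reference_expr.tsv"))
  writeSampleAnnotation(sampleAnnotation(scenario$reference),
                        p("reference_annotation.tsv"))
  writeExpressionMatrix(scenario$trial, p("trial_expr.tsv"))
  writeExpressionMatrix(scenario$trialDistorted, p("trial_distorted_expr.tsv"))
  writeSampleAnnotation(sampleAnnotation(scenario$trial),
                        p("trial_annotation.tsv"))
  writeCentroidSet(scenario$centroids, p("centroids.tsv"))
  writeCalibrationFactors(scenario$biasFactors, p("bias_factors.tsv"))
  jsonlite::write_json(list(seed = scenario$seed,
                            monotone = scenario$monotone,
                            baseline = scenario$baseline,
                            config = unclass(scenario$config)),
                       p("scenario.json"), auto_unbox = TRUE, digits = NA)
  files <- c(reference = p("reference_expr.tsv"),
             reference_annotation = p("reference_annotation.tsv"),
             trial = p("trial_expr.tsv"),
             trial_distorted = p("trial_distorted_expr.tsv"),
             trial_annotation = p("trial_annotation.tsv"),
             centroids = p("centroids.tsv"),
             bias_factors = p("bias_factors.tsv"),
             scenario = p("scenario.json"))
  invisible(files)
}
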