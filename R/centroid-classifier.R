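#' Nearest-centroid classifier configuration
#'
#' @param method correlation method; defaults to the centroid set's own
#'   method at classification time when \code{NULL}.
#' @param minGenes minimum number of overlapping genes to attempt a call
#'   (>= 3).
#' @param tieOrder subtype preference used to break exact correlation ties
#'   (ties are always flagged, never silent).
#' @param switchThreshold margin threshold for the second-centroid switching
#'   experiment (default 0.1).
#' @return A \code{ClassifierConfig} list.
#' @export
classifierConfig <- function(method = NULL, minGenes = 10L,
                             tieOrder = c("LumA", "LumB", "HER2-E", "BL", "NL"),
                             switchThreshold = 0.1) {
  if (!is.null(method)) method <- match.arg(method, c("spearman", "pearson"))
  minGenes <- as.integer(minGenes)
  if (minGenes < 3L) stop("minGenes must be >= 3")
  if (switchThreshold < 0) stop("switchThreshold must be >= 0")
  structure(list(method = method, minGenes = minGenes, tieOrder = tieOrder,
                 switchThreshold = switchThreshold),
            class = "ClassifierConfig")
}

## Rank labels for tie-breaking: position in tieOrder, unknowns after.
.tieRank <- function(labels, tieOrder) {
  r <- match(labels, tieOrder)
  r[is.na(r)] <- length(tieOrder) + seq_len(sum(is.na(r)))
  r
}

#' Nearest-centroid subtype classification
#'
#' Correlates every sample's (centered, log-scale) profile with each subtype
#' centroid over their shared genes — Spearman rank correlation (average
#' ranks for ties) for PAM50-style calls, Pearson for Prosigna-style calls —
#' and assigns the subtype with the largest correlation. Missing classifier
#' genes are dropped pairwise (the correlation is computed over the
#' intersection), so a panel measuring 49 of 50 centroid genes still yields
#' calls. The full correlation vector, the top-two margin
#' \eqn{\delta = \rho_{(1)} - \rho_{(2)}} and a tie flag are retained per
#' sample.
#'
#' @param x an \linkS4class{ExpressionMatrix} (typically scale
#'   \code{"centered"}).
#' @param centroids a \linkS4class{CentroidSet}.
#' @param config a \code{\link{classifierConfig}}.
#' @return A \linkS4class{SubtypeCalls} with correlation scores;
#'   \code{metadata} records the method, genes used and genes missing.
#' @export
classify <- function(x, centroids, config = classifierConfig()) {
  stopifnot(is(x, "ExpressionMatrix"), is(centroids, "CentroidSet"))
  method <- if (is.null(config$method)) centroidMethod(centroids) else config$method
  ov <- intersect(geneIds(centroids), rownames(x))
  if (length(ov) < config$minGenes)
    stop(sprintf("only %d gene(s) shared with the centroid set (minGenes = %d)",
                 length(ov), config$minGenes))
  v <- exprValues(x)[ov, , drop = FALSE]
  flat <- apply(v, 2L, function(s) diff(range(s)) == 0)
  if (any(flat))
    stop("zero-variance profile (correlation undefined) for sample(s): ",
         paste(colnames(v)[flat], collapse = ", "))
  rho <- stats::cor(v, centroidValues(centroids)[ov, , drop = FALSE],
                    method = method)
  labs <- colnames(rho)
  pref <- .tieRank(labs, config$tieOrder)
  pick <- apply(rho, 1L, function(r) {
    cand <- which(r >= max(r) - 1e-12)
    cand[which.min(pref[cand])]
  })
  srt <- apply(rho, 1L, function(r) sort(r, decreasing = TRUE)[1:2])
  margin <- srt[1L, ] - srt[2L, ]
  SubtypeCalls(colnames(v), labs[pick], rho, scoreType = "correlation",
               margin = pmax(margin, 0), tie = margin <= 1e-12,
               metadata = list(method = method, genes_used = length(ov),
                               genes_missing = setdiff(geneIds(centroids), ov)))
}

#' Prosigna-style classification pipeline
#'
#' The research-use-only Prosigna scheme as a composable pipeline:
#' housekeeping-gene signal normalization, then per-gene affine technical
#' calibration (the "two sets of scaling factors"), then Pearson
#' nearest-centroid classification against a four-subtype centroid set — so
#' no NL call can ever be emitted.
#'
#' @param x a log-scale \linkS4class{ExpressionMatrix}.
#' @param centroids a four-subtype (no NL) \linkS4class{CentroidSet} with
#'   method \code{"pearson"}.
#' @param hkGenes housekeeping gene ids present in \code{x}.
#' @param factors optional \linkS4class{CalibrationFactors}; \code{NULL}
#'   skips calibration (identity factors).
#' @param config a \code{\link{classifierConfig}}; the method is forced to
#'   Pearson.
#' @return A \linkS4class{SubtypeCalls}.
#' @export
prosignaClassify <- function(x, centroids, hkGenes, factors = NULL,
                             config = classifierConfig()) {
  stopifnot(is(centroids, "CentroidSet"))
  if ("NL" %in% subtypeLabels(centroids))
    stop("prosignaClassify expects a four-subtype centroid set without NL")
  x <- housekeepingNormalize(x, hkGenes)
  if (!is.null(factors)) x <- applyCalibration(x, factors)
  config$method <- "pearson"
  classify(x, centroids, config)
}

#' Top-two centroid correlations per sample
#'
#' The borderline-subtype view of a call table: for each sample the two
#' classes with the largest scores and the margin
#' \eqn{\delta = \rho_{(1)} - \rho_{(2)} \ge 0}; samples with small
#' \eqn{\delta} sit near the boundary between two subtypes.
#'
#' @param x a \linkS4class{SubtypeCalls}.
#' @param tieOrder label preference for ordering exactly tied scores.
#' @return \code{data.frame} with \code{sample_id}, \code{best_label},
#'   \code{second_label}, \code{rho_1}, \code{rho_2}, \code{delta}.
#' @export
topTwo <- function(x, tieOrder = c("LumA", "LumB", "HER2-E", "BL", "NL")) {
  stopifnot(is(x, "SubtypeCalls"))
  sc <- scores(x)
  if (ncol(sc) < 2L) stop("top-two analysis needs at least 2 classes")
  pref <- .tieRank(colnames(sc), tieOrder)
  res <- t(apply(sc, 1L, function(r) {
    o <- order(-r, pref)
    c(o[1L], o[2L], r[o[1L]], r[o[2L]])
  }))
  data.frame(sample_id = sampleIds(x),
             best_label = colnames(sc)[res[, 1L]],
             second_label = colnames(sc)[res[, 2L]],
             rho_1 = res[, 3L], rho_2 = res[, 4L],
             delta = res[, 3L] - res[, 4L],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Second-centroid switching experiment
#'
#' Re-assigns every sample whose top-two margin is within the threshold
#' (\eqn{\delta \le} \code{threshold}, default 0.1) to its second-closest
#' centroid, flagging it as switched — probing how sensitive downstream
#' conclusions are to borderline assignments.
#'
#' @param x an unswitched \linkS4class{SubtypeCalls}.
#' @param threshold non-negative margin threshold; 0 switches exact ties
#'   only.
#' @param tieOrder passed to \code{\link{topTwo}}.
#' @return A \linkS4class{SubtypeCalls} whose \code{metadata$switch} records
#'   the threshold, count and fraction switched.
#' @export
switchToSecond <- function(x, threshold = 0.1,
                           tieOrder = c("LumA", "LumB", "HER2-E", "BL", "NL")) {
  stopifnot(is(x, "SubtypeCalls"))
  if (threshold < 0) stop("switch threshold must be >= 0")
  tt <- topTwo(x, tieOrder)
  hit <- tt$delta <= threshold
  call <- x@call
  call[hit] <- tt$second_label[hit]
  meta <- x@metadata
  meta$switch <- list(threshold = threshold, n_switched = sum(hit),
                      fraction_switched = mean(hit))
  SubtypeCalls(x@sampleIds, call, x@scores, scoreType = x@scoreType,
               margin = x@margin, tie = x@tie, switched = hit,
               metadata = meta)
}

#' Audit switch transitions for subtype adjacency
#'
#' Labels every switched sample's transition as adjacent or not under the
#' biological ordering of the subtypes (default LumA-LumB-HER2-E-BL):
#' borderline samples are expected to move between neighbouring subtypes.
#'
#' @param original,switched \linkS4class{SubtypeCalls} over the same samples,
#'   before and after \code{\link{switchToSecond}}.
#' @param order linear subtype order defining adjacency.
#' @return List with \code{transitions} (\code{data.frame}: sample_id, from,
#'   to, adjacent) and \code{summary} (n_switched, n_adjacent,
#'   n_nonadjacent).
#' @export
adjacencyAudit <- function(original, switched,
                           order = c("LumA", "LumB", "HER2-E", "BL")) {
  stopifnot(is(original, "SubtypeCalls"), is(switched, "SubtypeCalls"))
  .checkSameSamples(sampleIds(original), sampleIds(switched))
  sw <- switchedFlags(switched)
  ids <- sampleIds(switched)[sw]
  from <- calls(original)[ids]
  to <- calls(switched)[ids]
  bad <- setdiff(unique(c(from, to)), order)
  if (length(bad))
    stop("label(s) not in the adjacency order: ", paste(bad, collapse = ", "))
  adj <- abs(match(from, order) - match(to, order)) == 1L
  list(transitions = data.frame(sample_id = ids, from = unname(from),
                                to = unname(to), adjacent = unname(adj),
                                row.names = NULL, stringsAsFactors = FALSE),
       summary = list(n_switched = length(ids), n_adjacent = sum(adj),
                      n_nonadjacent = sum(!adj)))
}
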