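#' log2 counts per million
#'
#' Per sample, \code{cpm = counts / library_size * 1e6}; returned values are
#' \code{log2(cpm + 1)} (the pseudocount keeps zero counts finite).
#'
#' @param x an \linkS4class{ExpressionMatrix} with scale \code{"counts"}.
#' @return An \linkS4class{ExpressionMatrix} with scale \code{"log2cpm"}.
#' @export
log2CPM <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (exprScale(x) != "counts") stop("log2CPM expects scale 'counts'")
  v <- exprValues(x)
  libsize <- colSums(v)
  if (any(libsize <= 0))
    stop("zero library size for sample(s): ",
         paste(colnames(v)[libsize <= 0], collapse = ", "))
  cpm <- sweep(v, 2L, libsize, "/") * 1e6
  .replaceValues(x, log2(cpm + 1), "log2cpm")
}

#' Quantile normalization
#'
#' Forces every sample onto the same empirical distribution: the across-sample
#' mean of order statistics. Ties within a sample receive the mean of the
#' reference values they span. Delegates to
#' \code{\link[limma]{normalizeQuantiles}}.
#'
#' @param x an \linkS4class{ExpressionMatrix} with at least two samples.
#' @return An \linkS4class{ExpressionMatrix}, same scale tag.
#' @export
quantileNormalize <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (ncol(x) < 2L)
    stop("quantile normalization needs at least 2 samples")
  out <- limma::normalizeQuantiles(exprValues(x), ties = TRUE)
  dimnames(out) <- dimnames(exprValues(x))
  .replaceValues(x, out, exprScale(x))
}

#' Upper-quartile FPKM
#'
#' Per sample, \code{value_g = counts_g / (length_g/1e3 * UQ_s)} where
#' \code{UQ_s} is the 75th percentile of that sample's protein-coding gene
#' counts (zeros included); output is \code{log2(value + 1)}.
#'
#' @param x an \linkS4class{ExpressionMatrix} with scale \code{"counts"}.
#' @param geneLength positive gene lengths in bp, named by gene or in row
#'   order.
#' @param proteinCoding logical mask (named or in row order); at least one
#'   gene must be protein-coding.
#' @return An \linkS4class{ExpressionMatrix} with scale \code{"logfpkm"}.
#' @export
uqFPKM <- function(x, geneLength, proteinCoding) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (exprScale(x) != "counts") stop("uqFPKM expects scale 'counts'")
  v <- exprValues(x)
  if (!is.null(names(geneLength))) geneLength <- geneLength[rownames(v)]
  if (!is.null(names(proteinCoding))) proteinCoding <- proteinCoding[rownames(v)]
  if (length(geneLength) != nrow(v) || anyNA(geneLength) || any(geneLength <= 0))
    stop("geneLength must give a positive length for every gene")
  if (length(proteinCoding) != nrow(v) || anyNA(proteinCoding))
    stop("proteinCoding must give a flag for every gene")
  if (!any(proteinCoding)) stop("at least one protein-coding gene required")
  uq <- apply(v[proteinCoding, , drop = FALSE], 2L, .quantile7, p = 0.75)
  if (any(uq <= 0))
    stop("zero upper-quartile count for sample(s): ",
         paste(colnames(v)[uq <= 0], collapse = ", "))
  fpkm <- sweep(v / (geneLength / 1e3), 2L, uq, "/")
  .replaceValues(x, log2(fpkm + 1), "logfpkm")
}

#' Housekeeping-gene normalization
#'
#' Subtracts, per sample, the arithmetic mean of the housekeeping genes' log
#' values — the log-scale equivalent of dividing by their geometric mean
#' (the Prosigna-style signal normalization over eight housekeeping genes).
#'
#' @param x a log-scale \linkS4class{ExpressionMatrix}.
#' @param hkGenes housekeeping gene ids; all must be present.
#' @return An \linkS4class{ExpressionMatrix}, scale \code{"log_generic"}.
#' @export
housekeepingNormalize <- function(x, hkGenes) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (exprScale(x) == "counts")
    stop("housekeepingNormalize expects log-scale values")
  miss <- setdiff(hkGenes, rownames(x))
  if (length(miss))
    stop("housekeeping gene(s) missing from matrix: ",
         paste(miss, collapse = ", "))
  v <- exprValues(x)
  hk <- colMeans(v[hkGenes, , drop = FALSE])
  .replaceValues(x, sweep(v, 2L, hk, "-"), "log_generic")
}

#' Build a subgroup-specific percentile (sgPct) centering reference
#'
#' For every gene, finds the percentile of the reference subgroup's empirical
#' distribution (type-7 linear interpolation) at which the full reference
#' cohort's median sits, clamped to [0, 100]. This percentile — not the
#' median itself — is what gets transferred to a compositionally biased
#' cohort by \code{\link{sgPctCenter}}.
#'
#' @param reference an \linkS4class{ExpressionMatrix} (e.g. a TCGA-like
#'   mixed-subtype cohort on the log scale).
#' @param subgroup logical mask or sample ids selecting the ER+/HER2--like
#'   subgroup (size >= 2); may equal the full cohort.
#' @return A \linkS4class{NormalizationReference}.
#' @export
buildSgPctReference <- function(reference, subgroup) {
  stopifnot(is(reference, "ExpressionMatrix"))
  v <- exprValues(reference)
  if (is.character(subgroup)) subgroup <- colnames(v) %in% subgroup
  if (length(subgroup) != ncol(v))
    stop("subgroup mask must cover every reference sample")
  if (sum(subgroup) < 2L) stop("subgroup must contain at least 2 samples")
  sub <- v[, subgroup, drop = FALSE]
  gm <- apply(v, 1L, stats::median)
  sm <- apply(sub, 1L, stats::median)
  pct <- vapply(seq_len(nrow(v)),
                function(g) .percentileOf(sub[g, ], gm[g]), numeric(1))
  ref <- NormalizationReference(rownames(v), gm, sm, pct,
                                source = sprintf("cohort n=%d, subgroup n=%d",
                                                 ncol(v), sum(subgroup)))
  # construction-time check: the subgroup quantile at p_g reproduces the
  # global median wherever it was not clamped to the boundary
  interior <- pct > 0 & pct < 100
  if (any(interior)) {
    back <- vapply(which(interior),
                   function(g) .quantile7(sub[g, ], pct[g] / 100), numeric(1))
    err <- max(abs(back - gm[interior]))
    if (err > 1e-8 * max(1, max(abs(gm))))
      stop("sgPct reference failed its quantile round-trip check (max error ",
           format(err), ")")
  }
  ref
}

.matchRefGenes <- function(v, geneIds, what) {
  idx <- match(rownames(v), geneIds)
  if (anyNA(idx))
    stop(what, ": no factors/reference for gene(s): ",
         paste(rownames(v)[is.na(idx)], collapse = ", "))
  idx
}

#' Subgroup-specific percentile (sgPct) centering
#'
#' Centers every gene of a test cohort by subtracting the test cohort's own
#' empirical quantile (type-7) at the reference-derived percentile
#' \code{p_g}. When \code{p_g = 50} for all genes this reduces to per-gene
#' median centering of the test cohort.
#'
#' @param x test cohort \linkS4class{ExpressionMatrix} (log scale).
#' @param ref a \linkS4class{NormalizationReference} from
#'   \code{\link{buildSgPctReference}} covering all genes of \code{x}.
#' @return An \linkS4class{ExpressionMatrix} with scale \code{"centered"}.
#' @export
sgPctCenter <- function(x, ref) {
  stopifnot(is(x, "ExpressionMatrix"), is(ref, "NormalizationReference"))
  v <- exprValues(x)
  idx <- .matchRefGenes(v, ref@geneIds, "sgPctCenter")
  ctr <- vapply(seq_len(nrow(v)),
                function(g) .quantile7(v[g, ], ref@percentile[idx[g]] / 100),
                numeric(1))
  .replaceValues(x, v - ctr, "centered")
}

#' Subgroup-median (sgMd) centering
#'
#' Moves each gene's test-cohort median onto the reference subgroup median:
#' \code{out = x - (median_test - subgroup_median_ref)}.
#'
#' @inheritParams sgPctCenter
#' @return An \linkS4class{ExpressionMatrix} with scale \code{"centered"}.
#' @export
sgMdCenter <- function(x, ref) {
  stopifnot(is(x, "ExpressionMatrix"), is(ref, "NormalizationReference"))
  v <- exprValues(x)
  idx <- .matchRefGenes(v, ref@geneIds, "sgMdCenter")
  md <- apply(v, 1L, stats::median)
  .replaceValues(x, v - (md - ref@subgroupMedian[idx]), "centered")
}

#' Per-gene median centering
#'
#' Naive within-cohort centering (subtract each gene's own median across the
#' cohort) — the baseline that subgroup-specific centering improves on when
#' the cohort's subtype composition is biased.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @return An \linkS4class{ExpressionMatrix} with scale \code{"centered"}.
#' @export
medianCenter <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  v <- exprValues(x)
  .replaceValues(x, v - apply(v, 1L, stats::median), "centered")
}

#' Apply per-gene affine technical calibration
#'
#' \code{out_g = scale_g * x_g + shift_g} on the log scale, mapping one
#' platform's values onto the scale another platform's classifier parameters
#' were trained on.
#'
#' @param x an \linkS4class{ExpressionMatrix} (log scale).
#' @param factors a \linkS4class{CalibrationFactors} covering all genes.
#' @return An \linkS4class{ExpressionMatrix}, same scale tag.
#' @export
applyCalibration <- function(x, factors) {
  stopifnot(is(x, "ExpressionMatrix"), is(factors, "CalibrationFactors"))
  v <- exprValues(x)
  idx <- .matchRefGenes(v, factors@geneIds, "applyCalibration")
  .replaceValues(x, v * factors@scale[idx] + factors@shift[idx], exprScale(x))
}

#' Invert calibration factors algebraically
#'
#' @param factors a \linkS4class{CalibrationFactors}.
#' @return The inverse factors: \code{x -> (x - shift)/scale}.
#' @export
invertCalibration <- function(factors) {
  stopifnot(is(factors, "CalibrationFactors"))
  CalibrationFactors(factors@geneIds, 1 / factors@scale,
                     -factors@shift / factors@scale)
}

#' Fit per-gene affine calibration between paired matrices
#'
#' Ordinary least squares per gene mapping \code{from} onto \code{to}
#' (samples paired by position): \code{to ~ scale * from + shift}. Used to
#' estimate technical calibration factors from samples profiled on both
#' platforms.
#'
#' @param from,to \linkS4class{ExpressionMatrix} objects over the same genes
#'   and paired samples.
#' @return A \linkS4class{CalibrationFactors}.
#' @export
fitCalibration <- function(from, to) {
  stopifnot(is(from, "ExpressionMatrix"), is(to, "ExpressionMatrix"))
  a <- exprValues(from); b <- exprValues(to)
  if (!identical(rownames(a), rownames(b)) || ncol(a) != ncol(b))
    stop("fitCalibration needs matrices over identical genes and paired samples")
  am <- rowMeans(a); bm <- rowMeans(b)
  ac <- a - am
  va <- rowSums(ac^2)
  if (any(va == 0))
    stop("zero variance in 'from' for gene(s): ",
         paste(rownames(a)[va == 0], collapse = ", "))
  slope <- rowSums(ac * (b - bm)) / va
  if (any(slope <= 0))
    stop("non-positive fitted slope for gene(s): ",
         paste(rownames(a)[slope <= 0], collapse = ", "),
         " (platforms anti-correlated?)")
  CalibrationFactors(rownames(a), slope, bm - slope * am)
}
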