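## Extract a named label vector from SubtypeCalls or a named character vector.
.labelVector <- function(x) {
  if (is(x, "SubtypeCalls")) return(calls(x))
  if (is.character(x) && (!length(x) || !is.null(names(x)))) return(x)
  stop("expected a SubtypeCalls object or a named character vector of calls")
}

#' Cross-method contingency table of subtype calls
#'
#' Counts samples by (method A call, method B call). Labels are ordered
#' canonically (LumA, LumB, HER2-E, BL, NL) unless explicit orders are
#' given.
#'
#' @param a,b \linkS4class{SubtypeCalls} (or named label vectors) over the
#'   same samples.
#' @param labelsA,labelsB optional fixed row/column label orders.
#' @param methodA,methodB display names.
#' @return A \linkS4class{ContingencyTable} (rows = A, columns = B).
#' @export
contingency <- function(a, b, labelsA = NULL, labelsB = NULL,
                        methodA = "method_a", methodB = "method_b") {
  la <- .labelVector(a); lb <- .labelVector(b)
  .checkSameSamples(names(la), names(lb))
  lb <- lb[names(la)]
  if (is.null(labelsA)) labelsA <- .canonicalOrder(unique(la))
  if (is.null(labelsB)) labelsB <- .canonicalOrder(unique(lb))
  cnt <- table(factor(la, levels = labelsA), factor(lb, levels = labelsB))
  m <- matrix(as.integer(cnt), nrow(cnt), ncol(cnt),
              dimnames = list(labelsA, labelsB))
  ContingencyTable(m, methodA = methodA, methodB = methodB)
}

#' Overall agreement between two subtyping methods
#'
#' Fraction of samples on the diagonal over the labels the two methods
#' share, computed on the unmerged table; the percent is rounded to integer
#' (half away from zero).
#'
#' @param x a \linkS4class{ContingencyTable}.
#' @return List: \code{fraction}, \code{percent}, \code{numerator},
#'   \code{denominator}.
#' @export
overallAgreement <- function(x) {
  stopifnot(is(x, "ContingencyTable"))
  shared <- intersect(rownames(x@counts), colnames(x@counts))
  if (!length(shared))
    stop("the two methods share no subtype label")
  num <- sum(x@counts[cbind(shared, shared)])
  n <- sum(x@counts)
  list(fraction = num / n, percent = .roundHalfUp(100 * num / n),
       numerator = num, denominator = n)
}

#' Merge subtype labels in a contingency table
#'
#' Adds each mapped label's row (and column, where present) into its target,
#' e.g. \code{c(NL = "LumA")} folds normal-like calls into LumA — the merge
#' used before computing kappa against a four-subtype method that never
#' emits NL.
#'
#' @param x a \linkS4class{ContingencyTable}.
#' @param mergeMap named character vector, \code{from = to}.
#' @return The merged \linkS4class{ContingencyTable}.
#' @export
mergeLabels <- function(x, mergeMap) {
  stopifnot(is(x, "ContingencyTable"))
  cnt <- x@counts
  for (from in names(mergeMap)) {
    to <- mergeMap[[from]]
    if (from %in% rownames(cnt)) {
      if (!to %in% rownames(cnt))
        stop("merge target '", to, "' not among row labels")
      cnt[to, ] <- cnt[to, ] + cnt[from, ]
      cnt <- cnt[setdiff(rownames(cnt), from), , drop = FALSE]
    }
    if (from %in% colnames(cnt)) {
      if (!to %in% colnames(cnt))
        stop("merge target '", to, "' not among column labels")
      cnt[, to] <- cnt[, to] + cnt[, from]
      cnt <- cnt[, setdiff(colnames(cnt), from), drop = FALSE]
    }
  }
  ContingencyTable(cnt, methodA = x@methodA, methodB = x@methodB)
}

#' Cohen's kappa (unweighted) with optional label merging
#'
#' \eqn{\kappa = (P_o - P_e)/(1 - P_e)} with the expected agreement
#' \eqn{P_e} from the product of the marginals. Labels in \code{mergeMap}
#' are folded first (e.g. NL into LumA); after merging, rows and columns
#' must share one label set. The large-sample standard error
#' \eqn{\sqrt{P_o (1-P_o)} / ((1-P_e)\sqrt{n})} is returned alongside.
#'
#' @param x a \linkS4class{ContingencyTable}.
#' @param mergeMap optional named character vector, \code{from = to}.
#' @return List: \code{kappa}, \code{se}, \code{po}, \code{pe}, \code{n},
#'   \code{merged_labels}.
#' @export
cohensKappa <- function(x, mergeMap = NULL) {
  stopifnot(is(x, "ContingencyTable"))
  if (length(mergeMap)) x <- mergeLabels(x, mergeMap)
  cnt <- x@counts
  labs <- union(rownames(cnt), colnames(cnt))
  if (!setequal(rownames(cnt), colnames(cnt))) {
    # embed into the common label set (zero rows/columns for absent labels)
    full <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
    full[rownames(cnt), colnames(cnt)] <- cnt
    cnt <- full
  } else {
    cnt <- cnt[labs, labs, drop = FALSE]
  }
  n <- sum(cnt)
  po <- sum(diag(cnt)) / n
  pe <- sum(rowSums(cnt) * colSums(cnt)) / n^2
  if (1 - pe < 1e-12)
    stop("degenerate marginals: expected agreement is 1, kappa undefined")
  k <- (po - pe) / (1 - pe)
  list(kappa = k, se = sqrt(po * (1 - po) / n) / (1 - pe), po = po, pe = pe,
       n = n, merged_labels = labs)
}

#' Axis-conditional (mis)assignment rates
#'
#' Each cell as a percentage of its column total (\code{axis = "column"},
#' the reporting-style "X% of samples assigned L by method B were assigned M by
#' method A") or row total. Percents are rounded to integer (half away from
#' zero); zero-total axes yield \code{NA} and are flagged.
#'
#' @param x a \linkS4class{ContingencyTable}.
#' @param axis \code{"column"} or \code{"row"}.
#' @return List: \code{percent} (rounded matrix), \code{fraction} (raw),
#'   \code{undefined} (labels with zero totals).
#' @export
conditionalRates <- function(x, axis = c("column", "row")) {
  stopifnot(is(x, "ContingencyTable"))
  axis <- match.arg(axis)
  cnt <- x@counts
  tot <- if (axis == "column") colSums(cnt) else rowSums(cnt)
  frac <- if (axis == "column") sweep(cnt, 2L, tot, "/")
          else sweep(cnt, 1L, tot, "/")
  frac[!is.finite(frac)] <- NA_real_
  list(percent = .roundHalfUp(100 * frac), fraction = frac,
       undefined = names(tot)[tot == 0])
}

#' Partition samples into clear-defined and discord sets
#'
#' Clear-defined samples are those on which the two methods agree exactly
#' (no label merging); the rest are borderline-defined or discord.
#'
#' @param a,b \linkS4class{SubtypeCalls} (or named label vectors) over the
#'   same samples.
#' @return List: \code{clear_defined}, \code{discord} (sample ids).
#' @export
partitionDiscord <- function(a, b) {
  la <- .labelVector(a); lb <- .labelVector(b)
  .checkSameSamples(names(la), names(lb))
  lb <- lb[names(la)]
  agree <- la == lb
  list(clear_defined = names(la)[agree], discord = names(la)[!agree])
}

#' Subtype distribution of a call table
#'
#' Counts and percentages (one decimal, half away from zero) per subtype.
#'
#' @param x a \linkS4class{SubtypeCalls} or named label vector.
#' @param labels optional fixed label order.
#' @return \code{data.frame}: \code{label}, \code{count}, \code{percent},
#'   \code{fraction}.
#' @export
subtypeDistribution <- function(x, labels = NULL) {
  l <- .labelVector(x)
  if (!length(l)) stop("empty call table")
  if (is.null(labels)) labels <- .canonicalOrder(unique(l))
  cnt <- table(factor(l, levels = labels))
  data.frame(label = labels, count = as.integer(cnt),
             percent = .roundHalfUp(100 * as.integer(cnt) / length(l), 1L),
             fraction = as.integer(cnt) / length(l),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full concordance report between two subtyping methods
#'
#' Bundles \code{\link{contingency}}, \code{\link{overallAgreement}} (on the
#' unmerged table), \code{\link{cohensKappa}} (after \code{mergeMap}),
#' row- and column-conditional rates, per-method distributions and the
#' clear-defined/discord partition. Rounding follows the reporting
#' conventions (integer percents for agreement and conditional rates, one
#' decimal for distributions, two decimals for kappa); raw fractions are
#' always retained.
#'
#' @param a,b \linkS4class{SubtypeCalls} (or named label vectors) over the
#'   same samples.
#' @param mergeMap label merge applied to kappa only (e.g.
#'   \code{c(NL = "LumA")}).
#' @param methodA,methodB display names.
#' @param labelsA,labelsB optional fixed label orders.
#' @return A \linkS4class{ConcordanceReport}.
#' @export
concordanceReport <- function(a, b, mergeMap = NULL,
                              methodA = "method_a", methodB = "method_b",
                              labelsA = NULL, labelsB = NULL) {
  tab <- contingency(a, b, labelsA = labelsA, labelsB = labelsB,
                     methodA = methodA, methodB = methodB)
  reportFromTable(tab, a = a, b = b, mergeMap = mergeMap)
}

#' Concordance report from a bare contingency table
#'
#' Same statistics as \code{\link{concordanceReport}} computed from counts
#' alone (as when only a published cross-table is available). Without call
#' tables the clear-defined/discord partition uses placeholder ids derived
#' from the cells.
#'
#' @param tab a \linkS4class{ContingencyTable}.
#' @param a,b optional call tables for the discord partition.
#' @param mergeMap label merge applied to kappa only.
#' @return A \linkS4class{ConcordanceReport}.
#' @export
reportFromTable <- function(tab, a = NULL, b = NULL, mergeMap = NULL) {
  stopifnot(is(tab, "ContingencyTable"))
  agree <- overallAgreement(tab)
  kap <- cohensKappa(tab, mergeMap)
  kap$kappa_rounded <- .roundHalfUp(kap$kappa, 2L)
  if (!is.null(a) && !is.null(b)) {
    part <- partitionDiscord(a, b)
    distA <- subtypeDistribution(a, labels = rownames(tab@counts))
    distB <- subtypeDistribution(b, labels = colnames(tab@counts))
  } else {
    part <- .partitionFromTable(tab)
    distA <- .distributionFromCounts(rowSums(tab@counts))
    distB <- .distributionFromCounts(colSums(tab@counts))
  }
  new("ConcordanceReport", table = tab,
      mergeMap = if (length(mergeMap)) mergeMap else character(),
      agreement = agree, kappa = kap,
      conditionalRates = list(column = conditionalRates(tab, "column"),
                              row = conditionalRates(tab, "row")),
      distributions = list(method_a = distA, method_b = distB),
      clearDefined = part$clear_defined, discord = part$discord)
}

.distributionFromCounts <- function(cnt) {
  n <- sum(cnt)
  data.frame(label = names(cnt), count = as.integer(cnt),
             percent = .roundHalfUp(100 * as.integer(cnt) / n, 1L),
             fraction = as.integer(cnt) / n,
             row.names = NULL, stringsAsFactors = FALSE)
}

## Synthetic per-cell sample ids ("<rowlab>_<collab>_<i>") when only counts
## are known; the partition sizes are what matters downstream.
.partitionFromTable <- function(tab) {
  cnt <- tab@counts
  ids <- character(0); agree <- logical(0)
  for (i in rownames(cnt)) for (j in colnames(cnt)) {
    k <- cnt[i, j]
    if (k > 0) {
      ids <- c(ids, sprintf("%s_%s_%d", i, j, seq_len(k)))
      agree <- c(agree, rep(i == j, k))
    }
  }
  list(clear_defined = ids[agree], discord = ids[!agree])
}

#' Lift bare labels into a SubtypeCalls object
#'
#' Builds a degenerate call table (one-hot scores, margin 1) from a named
#' label vector — enough to drive the comparison pipeline from published
#' calls that carry no correlation profiles.
#'
#' @param labels named character vector (names = sample ids).
#' @param classes class set; defaults to the labels observed, canonically
#'   ordered.
#' @return A \linkS4class{SubtypeCalls} with one-hot \code{"posterior"}
#'   scores.
#' @export
callsFromLabels <- function(labels, classes = NULL) {
  if (is.null(names(labels))) stop("labels must be named by sample id")
  if (is.null(classes)) classes <- .canonicalOrder(unique(labels))
  sc <- matrix(0, length(labels), length(classes),
               dimnames = list(names(labels), classes))
  sc[cbind(seq_along(labels), match(labels, classes))] <- 1
  SubtypeCalls(names(labels), unname(labels), sc, scoreType = "posterior")
}

#' Reconstruct per-sample calls from a contingency table
#'
#' Expands counts into two aligned label vectors with synthetic sample ids —
#' the inverse of \code{\link{contingency}} up to sample identity, used to
#' drive the pipeline from a published cross-table.
#'
#' @param tab a \linkS4class{ContingencyTable}.
#' @param prefix prefix for the generated sample ids.
#' @return List of two named label vectors, \code{a} and \code{b}.
#' @export
callsFromContingency <- function(tab, prefix = "s") {
  stopifnot(is(tab, "ContingencyTable"))
  cnt <- tab@counts
  a <- character(0); b <- character(0)
  for (i in rownames(cnt)) for (j in colnames(cnt)) {
    k <- cnt[i, j]
    if (k > 0) { a <- c(a, rep(i, k)); b <- c(b, rep(j, k)) }
  }
  ids <- sprintf("%s%04d", prefix, seq_along(a))
  list(a = stats::setNames(a, ids), b = stats::setNames(b, ids))
}
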