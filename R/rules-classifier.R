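#' Evaluate binary gene-pair rules within each sample
#'
#' Rule r is true in a sample iff expression(gene_low) < expression(gene_high)
#' there — a strict within-sample comparison (equality is false), which is
#' what makes rule-based calls "absolute": they depend only on each sample's
#' own gene ordering, not on cohort composition or normalization.
#'
#' @param x an \linkS4class{ExpressionMatrix} containing every rule gene.
#' @param rules a \linkS4class{RuleSet}.
#' @return Logical matrix, rules x samples.
#' @export
evaluateRules <- function(x, rules) {
  stopifnot(is(x, "ExpressionMatrix"), is(rules, "RuleSet"))
  miss <- setdiff(ruleGenes(rules), rownames(x))
  if (length(miss))
    stop("rule gene(s) missing from matrix: ", paste(miss, collapse = ", "))
  v <- exprValues(x)
  b <- v[rules@geneLow, , drop = FALSE] < v[rules@geneHigh, , drop = FALSE]
  rownames(b) <- paste0("rule_", seq_len(nRules(rules)))
  b
}

#' Naive-Bayes call from evaluated rules
#'
#' Per sample, \code{log posterior_k = log prior_k + sum_r [b_r log p_rk +
#' (1 - b_r) log(1 - p_rk)]}; the call is the maximum-posterior class and the
#' margin is the gap between the two largest normalized posteriors.
#'
#' @param binary logical rules x samples matrix from
#'   \code{\link{evaluateRules}} (row order must match the rule set).
#' @param rules the \linkS4class{RuleSet} providing conditional
#'   probabilities and priors (all strictly inside (0,1): smooth at
#'   training/loading).
#' @param tieOrder label preference for exact posterior ties.
#' @return A \linkS4class{SubtypeCalls} with posterior scores (each sample's
#'   posteriors sum to 1).
#' @export
nbClassify <- function(binary, rules,
                       tieOrder = c("LumA", "LumB", "HER2-E", "BL", "NL")) {
  stopifnot(is(rules, "RuleSet"))
  if (nrow(binary) != nRules(rules))
    stop("binary matrix rows must match the rule set (",
         nrow(binary), " vs ", nRules(rules), ")")
  b <- binary * 1
  cp <- rules@condProb
  ll <- t(log(cp)) %*% b + t(log1p(-cp)) %*% (1 - b)   # classes x samples
  ll <- ll + log(rules@priors[rownames(ll)])
  post <- apply(ll, 2L, function(l) {
    e <- exp(l - max(l)); e / sum(e)
  })
  post <- t(post)                                       # samples x classes
  labs <- colnames(post)
  pref <- .tieRank(labs, tieOrder)
  pick <- apply(post, 1L, function(r) {
    cand <- which(r >= max(r) - 1e-12)
    cand[which.min(pref[cand])]
  })
  srt <- apply(post, 1L, function(r) sort(r, decreasing = TRUE)[1:2])
  margin <- srt[1L, ] - srt[2L, ]
  SubtypeCalls(colnames(binary), labs[pick], post, scoreType = "posterior",
               margin = pmax(margin, 0), tie = margin <= 1e-12,
               metadata = list(n_rules = nRules(rules)))
}

#' One-step rule-based classification
#'
#' \code{\link{evaluateRules}} followed by \code{\link{nbClassify}}.
#'
#' @inheritParams evaluateRules
#' @inheritParams nbClassify
#' @return A \linkS4class{SubtypeCalls}.
#' @export
rulesClassify <- function(x, rules,
                          tieOrder = c("LumA", "LumB", "HER2-E", "BL", "NL")) {
  nbClassify(evaluateRules(x, rules), rules, tieOrder = tieOrder)
}

#' Restrict a rule set to an available gene panel
#'
#' Retains exactly the rules whose both genes are measured by the panel —
#' e.g. a targeted panel covering both genes of 42 of 100 rules keeps those
#' 42.
#'
#' @param rules a \linkS4class{RuleSet}.
#' @param availableGenes gene ids the panel measures.
#' @return The restricted \linkS4class{RuleSet}; its \code{retained}
#'   attribute records retained/total counts.
#' @export
subsetRules <- function(rules, availableGenes) {
  stopifnot(is(rules, "RuleSet"))
  keep <- rules@geneLow %in% availableGenes & rules@geneHigh %in% availableGenes
  if (!any(keep))
    stop("no rule has both genes on the panel")
  out <- RuleSet(rules@geneLow[keep], rules@geneHigh[keep],
                 rules@condProb[keep, , drop = FALSE], rules@priors)
  attr(out, "retained") <- c(retained = sum(keep), total = length(keep))
  out
}

## Entropy (nats) of a Bernoulli proportion vector.
.h <- function(p) {
  p <- c(p, 1 - p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Train a binary-rule naive-Bayes classifier
#'
#' Reference training for synthetic experiments (published rule tables can
#' instead be loaded with \code{\link{readRuleSet}}). Candidate rules are all
#' ordered pairs of the most variable genes; each pair is scored by its best
#' one-vs-rest information gain of the within-sample indicator
#' expression(low) < expression(high) against class membership, and the
#' top \code{nRules} pairs are kept. Conditional probabilities are estimated
#' with additive smoothing; class priors are uniform (an "absolute"
#' single-sample assignment should not encode the training cohort's
#' composition). Fully deterministic.
#'
#' @param reference a log-scale \linkS4class{ExpressionMatrix}.
#' @param labels class label per sample (>= 2 classes, each with >= 2
#'   samples).
#' @param nRules number of rules to keep.
#' @param smoothing additive pseudo-count (> 0) keeping probabilities inside
#'   (0,1).
#' @param nTopGenes candidate pool: this many most-variable genes.
#' @return A \linkS4class{RuleSet}.
#' @export
trainRules <- function(reference, labels, nRules = 50L, smoothing = 1,
                       nTopGenes = 40L) {
  stopifnot(is(reference, "ExpressionMatrix"))
  labels <- as.character(labels)
  v <- exprValues(reference)
  if (length(labels) != ncol(v))
    stop("one label per sample required")
  tab <- table(labels)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need >= 2 classes with >= 2 samples each")
  if (smoothing <= 0) stop("smoothing must be > 0")
  pool <- head(order(apply(v, 1L, stats::var), decreasing = TRUE), nTopGenes)
  pool <- sort(pool)                       # deterministic gene order
  pairs <- t(utils::combn(pool, 2L))
  b <- v[pairs[, 1L], , drop = FALSE] < v[pairs[, 2L], , drop = FALSE]
  classes <- names(tab)
  n <- ncol(v)
  hy <- vapply(classes, function(k) .h(mean(labels == k)), numeric(1))
  # one-vs-rest information gain of each candidate rule for each class
  ig <- t(apply(b, 1L, function(r) {
    pr <- mean(r)
    if (pr == 0 || pr == 1) return(rep(0, length(classes)))  # constant rule
    vapply(classes, function(k) {
      y <- labels == k
      cond <- pr * .h(mean(y[r])) + (1 - pr) * .h(mean(y[!r]))
      hy[k] - cond
    }, numeric(1))
  }))
  # round-robin over classes so every subtype gets its own discriminators
  # (a globally top-scoring list can leave two similar classes unseparated)
  ranked <- lapply(seq_along(classes), function(k) order(ig[, k],
                                                         decreasing = TRUE))
  top <- integer(0)
  i <- 1L
  while (length(top) < min(nRules, nrow(b))) {
    for (k in seq_along(classes)) {
      cand <- ranked[[k]][i]
      if (ig[cand, k] > 0 && !cand %in% top) top <- c(top, cand)
      if (length(top) >= min(nRules, nrow(b))) break
    }
    if (i >= nrow(b)) break
    i <- i + 1L
  }
  if (!length(top)) stop("no informative rule found (degenerate labels?)")
  gl <- rownames(v)[pairs[top, 1L]]
  gh <- rownames(v)[pairs[top, 2L]]
  cp <- vapply(classes, function(k) {
    bk <- b[top, labels == k, drop = FALSE]
    (rowSums(bk) + smoothing) / (ncol(bk) + 2 * smoothing)
  }, numeric(length(top)))
  cp <- matrix(cp, nrow = length(top), dimnames = list(NULL, classes))
  priors <- stats::setNames(rep(1 / length(classes), length(classes)), classes)
  RuleSet(gl, gh, cp, priors)
}
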