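## TSV dialects: UTF-8, tab-separated, '.' decimal point. Expression and
## centroid tables are genes-in-rows with a leading "gene_id" column; sample
## (or subtype) ids form the header. Comment lines start with '#'.

#' @importFrom utils read.delim write.table
NULL

.readTSV <- function(path, comment.char = "") {
  read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE, comment.char = comment.char,
             colClasses = "character", quote = "")
}

## Convert character columns to numeric, reporting the first offending cell
## by row id / column name instead of coercing to NA.
.numericBody <- function(df, ids, what) {
  m <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(ids, colnames(df)))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !toupper(trimws(df[[j]])) %in% c("NA", ""))
    if (anyNA(v)) {
      i <- if (length(bad)) bad[1L] else which(is.na(v))[1L]
      stop(sprintf("%s: non-numeric value '%s' at row '%s', column '%s'",
                   what, df[i, j], ids[i], colnames(df)[j]))
    }
    m[, j] <- v
  }
  m
}

.checkUniqueIds <- function(ids, what) {
  d <- unique(ids[duplicated(ids)])
  if (length(d))
    stop(sprintf("%s: duplicate id(s): %s", what, paste(d, collapse = ", ")))
}

#' Read an expression matrix from TSV
#'
#' Expects genes in rows and samples in columns, with the first column named
#' \code{gene_id} (use \code{transpose = TRUE} for samples-in-rows exports).
#'
#' @param path TSV file.
#' @param scale scale tag to attach (\code{"counts"}, \code{"log2cpm"},
#'   \code{"logfpkm"}, \code{"log_generic"}, \code{"centered"}).
#' @param transpose set \code{TRUE} when the file holds samples in rows.
#' @param annotation optional sample annotation \code{data.frame} (see
#'   \code{\link{ExpressionMatrix}}).
#' @return An \linkS4class{ExpressionMatrix}; row and column order follow the
#'   file.
#' @export
readExpressionMatrix <- function(path, scale, transpose = FALSE,
                                 annotation = NULL) {
  df <- .readTSV(path)
  if (colnames(df)[1L] != "gene_id")
    stop("expression TSV must have 'gene_id' as its first column: ", path)
  ids <- df[[1L]]
  .checkUniqueIds(ids, "expression matrix gene ids")
  .checkUniqueIds(colnames(df)[-1L], "expression matrix sample ids")
  m <- .numericBody(df[-1L], ids, "expression matrix")
  if (transpose) m <- t(m)
  ExpressionMatrix(m, scale = scale, annotation = annotation)
}

#' Write an expression matrix to TSV
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
  stopifnot(is(x, "ExpressionMatrix"))
  df <- data.frame(gene_id = rownames(x), exprValues(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict an expression matrix to a classifier's gene universe
#'
#' Keeps the genes shared between the matrix and \code{genes}, reordered to
#' follow \code{genes} (the convention classifier parameter files use), and
#' reports the classifier genes the matrix lacks — e.g. a 50-gene centroid
#' set against a panel measuring 49 of them retains 49 and reports 1 missing.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param genes ordered gene ids of the classifier parameters (or a
#'   \linkS4class{CentroidSet} / \linkS4class{RuleSet} to take them from).
#' @return List with \code{matrix} (restricted \code{ExpressionMatrix}),
#'   \code{missing} (classifier genes absent from the matrix) and
#'   \code{nRetained}.
#' @export
alignGenes <- function(x, genes) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (is(genes, "CentroidSet")) genes <- geneIds(genes)
  else if (is(genes, "RuleSet")) genes <- ruleGenes(genes)
  keep <- intersect(genes, rownames(x))
  if (!length(keep))
    stop("no overlap between matrix genes and classifier genes")
  miss <- setdiff(genes, rownames(x))
  out <- .replaceValues(x, exprValues(x)[keep, , drop = FALSE], exprScale(x))
  list(matrix = out, missing = miss, nRetained = length(keep))
}

#' Read / write a centroid table
#'
#' TSV with \code{gene_id} first column and one column per subtype label.
#'
#' @param path TSV file.
#' @param method correlation method the centroids were trained for.
#' @return A \linkS4class{CentroidSet}.
#' @export
readCentroidSet <- function(path, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  df <- .readTSV(path)
  if (colnames(df)[1L] != "gene_id")
    stop("centroid TSV must have 'gene_id' as its first column: ", path)
  ids <- df[[1L]]
  .checkUniqueIds(ids, "centroid gene ids")
  CentroidSet(.numericBody(df[-1L], ids, "centroid table"), method = method)
}

#' @rdname readCentroidSet
#' @param x a \linkS4class{CentroidSet}.
#' @export
writeCentroidSet <- function(x, path) {
  stopifnot(is(x, "CentroidSet"))
  df <- data.frame(gene_id = rownames(x@values), x@values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a binary-rule set
#'
#' TSV with columns \code{gene_low}, \code{gene_high}, then one
#' \code{p_<class>} conditional-probability column per class; class priors
#' are carried in a leading \code{#priors} line
#' (\code{#priors<TAB>LumA=0.2<TAB>...}).
#'
#' @param path TSV file.
#' @return A \linkS4class{RuleSet}.
#' @export
readRuleSet <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  pl <- grep("^#priors", lines, value = TRUE)
  if (length(pl) != 1L)
    stop("rule set TSV must carry exactly one '#priors' line: ", path)
  kv <- strsplit(strsplit(sub("^#priors\\t?", "", pl), "\t")[[1L]], "=")
  priors <- vapply(kv, function(p) as.numeric(p[2L]), numeric(1))
  names(priors) <- vapply(kv, `[`, character(1), 1L)
  df <- read.delim(text = lines[!startsWith(lines, "#")], sep = "\t",
                   check.names = FALSE, stringsAsFactors = FALSE, quote = "")
  pcols <- grep("^p_", colnames(df), value = TRUE)
  if (!all(c("gene_low", "gene_high") %in% colnames(df)) || !length(pcols))
    stop("rule set TSV needs gene_low, gene_high and p_<class> columns")
  cp <- as.matrix(df[pcols])
  colnames(cp) <- sub("^p_", "", pcols)
  if (any(!is.finite(cp)) || any(cp <= 0) || any(cp >= 1))
    stop("rule set: conditional probabilities must lie strictly in (0, 1)")
  if (abs(sum(priors) - 1) > 1e-9)
    stop("rule set: priors must sum to 1 (got ", sum(priors), ")")
  RuleSet(df$gene_low, df$gene_high, cp, priors)
}

#' @rdname readRuleSet
#' @param x a \linkS4class{RuleSet}.
#' @export
writeRuleSet <- function(x, path) {
  stopifnot(is(x, "RuleSet"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#priors\t",
                    paste(names(x@priors), format(x@priors, digits = 17),
                          sep = "=", collapse = "\t")), con)
  cp <- x@condProb
  colnames(cp) <- paste0("p_", colnames(cp))
  df <- data.frame(gene_low = x@geneLow, gene_high = x@geneHigh, cp,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write subtype call tables
#'
#' TSV with columns \code{sample_id}, \code{call}, one \code{rho_<class>}
#' score column per class, \code{margin}, \code{tie}, \code{switched}.
#'
#' @param path TSV file.
#' @param scoreType whether the score columns hold centroid correlations or
#'   rule-classifier posteriors.
#' @return A \linkS4class{SubtypeCalls}.
#' @export
readCalls <- function(path, scoreType = c("correlation", "posterior")) {
  scoreType <- match.arg(scoreType)
  df <- .readTSV(path)
  need <- c("sample_id", "call", "margin", "tie", "switched")
  if (!all(need %in% colnames(df)))
    stop("calls TSV must have columns: ", paste(need, collapse = ", "))
  rcols <- grep("^rho_", colnames(df), value = TRUE)
  sc <- .numericBody(df[rcols], df$sample_id, "calls table")
  colnames(sc) <- sub("^rho_", "", rcols)
  SubtypeCalls(df$sample_id, df$call, sc, scoreType = scoreType,
               margin = as.numeric(df$margin),
               tie = as.logical(df$tie), switched = as.logical(df$switched))
}

#' @rdname readCalls
#' @param x a \linkS4class{SubtypeCalls}.
#' @export
writeCalls <- function(x, path) {
  stopifnot(is(x, "SubtypeCalls"))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], format, digits = 17)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample annotation tables
#'
#' TSV with \code{sample_id} plus any of \code{cohort}, \code{in_subgroup},
#' \code{true_subtype}.
#'
#' @param path TSV file.
#' @return \code{data.frame}.
#' @export
readSampleAnnotation <- function(path) {
  df <- .readTSV(path)
  if (!"sample_id" %in% colnames(df))
    stop("annotation TSV must have a 'sample_id' column: ", path)
  .checkUniqueIds(df$sample_id, "sample annotation")
  if ("in_subgroup" %in% colnames(df))
    df$in_subgroup <- as.logical(df$in_subgroup)
  df
}

#' @rdname readSampleAnnotation
#' @param x annotation \code{data.frame}.
#' @export
writeSampleAnnotation <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a subgroup-centering reference
#'
#' TSV with columns \code{gene_id}, \code{global_median},
#' \code{subgroup_median}, \code{percentile}; provenance in a leading
#' \code{#source} line.
#'
#' @param path TSV file.
#' @return A \linkS4class{NormalizationReference}.
#' @export
readNormalizationReference <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  src <- sub("^#source\\t?", "", grep("^#source", lines, value = TRUE))
  if (!length(src)) src <- "unspecified"
  df <- read.delim(text = lines[!startsWith(lines, "#")], sep = "\t",
                   check.names = FALSE, stringsAsFactors = FALSE, quote = "")
  NormalizationReference(df$gene_id, df$global_median, df$subgroup_median,
                         df$percentile, source = src[1L])
}

#' @rdname readNormalizationReference
#' @param x a \linkS4class{NormalizationReference}.
#' @export
writeNormalizationReference <- function(x, path) {
  stopifnot(is(x, "NormalizationReference"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#source\t", x@source), con)
  df <- data.frame(gene_id = x@geneIds,
                   global_median = format(x@globalMedian, digits = 17),
                   subgroup_median = format(x@subgroupMedian, digits = 17),
                   percentile = format(x@percentile, digits = 17),
                   stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write per-gene calibration factors
#'
#' TSV with columns \code{gene_id}, \code{scale}, \code{shift}.
#'
#' @param path TSV file.
#' @return A \linkS4class{CalibrationFactors}.
#' @export
readCalibrationFactors <- function(path) {
  df <- .readTSV(path)
  CalibrationFactors(df$gene_id, as.numeric(df$scale), as.numeric(df$shift))
}

#' @rdname readCalibrationFactors
#' @param x a \linkS4class{CalibrationFactors}.
#' @export
writeCalibrationFactors <- function(x, path) {
  stopifnot(is(x, "CalibrationFactors"))
  df <- data.frame(gene_id = x@geneIds, scale = format(x@scale, digits = 17),
                   shift = format(x@shift, digits = 17),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a cross-method contingency table
#'
#' TSV with first column \code{label} (method A, rows) and one column per
#' method B label; method names may be carried in \code{#method_a} /
#' \code{#method_b} comment lines.
#'
#' @param path TSV file.
#' @return A \linkS4class{ContingencyTable}.
#' @export
readContingencyTable <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- function(tag, default) {
    hit <- grep(paste0("^#", tag), lines, value = TRUE)
    if (length(hit)) sub(paste0("^#", tag, "\\t?"), "", hit[1L]) else default
  }
  df <- read.delim(text = lines[!startsWith(lines, "#")], sep = "\t",
                   check.names = FALSE, stringsAsFactors = FALSE, quote = "")
  if (colnames(df)[1L] != "label")
    stop("contingency TSV must have 'label' as its first column: ", path)
  m <- as.matrix(df[-1L])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  ContingencyTable(m, methodA = meta("method_a", "method_a"),
                   methodB = meta("method_b", "method_b"))
}

#' @rdname readContingencyTable
#' @param x a \linkS4class{ContingencyTable}.
#' @export
writeContingencyTable <- function(x, path) {
  stopifnot(is(x, "ContingencyTable"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste0("#method_a\t", x@methodA),
               paste0("#method_b\t", x@methodB)), con)
  df <- data.frame(label = rownames(x@counts), x@counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a concordance report as JSON
#'
#' @param x a \linkS4class{ConcordanceReport} (or a plain list of report
#'   fields, e.g. a full \code{\link{runComparison}} bundle).
#' @param path output JSON file.
#' @return \code{path} invisibly; \code{readReport} returns the parsed list.
#' @export
writeReport <- function(x, path) {
  if (is(x, "ConcordanceReport")) x <- reportAsList(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Flatten a ConcordanceReport to plain lists (for JSON)
#'
#' @param x a \linkS4class{ConcordanceReport}.
#' @export
reportAsList <- function(x) {
  stopifnot(is(x, "ConcordanceReport"))
  cnt <- x@table@counts
  list(
    method_a = x@table@methodA,
    method_b = x@table@methodB,
    n = sum(cnt),
    labels_a = rownames(cnt),
    labels_b = colnames(cnt),
    counts = lapply(seq_len(nrow(cnt)), function(i) as.integer(cnt[i, ])),
    merge_map = as.list(x@mergeMap),
    agreement = x@agreement,
    kappa = x@kappa,
    conditional_rates = x@conditionalRates,
    distributions = x@distributions,
    clear_defined_ids = x@clearDefined,
    discord_ids = x@discord
  )
}
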