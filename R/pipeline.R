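## Resolve a config entry that may be an in-memory object or a file path.
.resolve <- function(x, reader, dir = NULL) {
  if (is.null(x) || !is.character(x)) return(x)
  path <- if (!is.null(dir) && !file.exists(x) && file.exists(file.path(dir, x)))
    file.path(dir, x) else x
  reader(path)
}

## Run one classification pipeline spec over an expression matrix.
.applyPipeline <- function(expr, spec, dir = NULL) {
  classifier <- match.arg(spec$classifier, c("centroid", "rules"))
  if (classifier == "rules") {
    rules <- .resolve(spec$rules, readRuleSet, dir)
    if (is.null(rules)) stop("rules classifier needs a 'rules' entry")
    return(rulesClassify(expr, rules))
  }
  centroids <- .resolve(spec$centroids, function(p)
    readCentroidSet(p, method = spec$method %||% "spearman"), dir)
  if (is.null(centroids)) stop("centroid classifier needs a 'centroids' entry")
  if (!is.null(spec$hk_genes))
    expr <- housekeepingNormalize(expr, unlist(spec$hk_genes))
  fac <- .resolve(spec$calibration, readCalibrationFactors, dir)
  if (!is.null(fac)) expr <- applyCalibration(expr, fac)
  center <- spec$center %||% "none"
  if (center %in% c("sgpct", "sgmd")) {
    ref <- .resolve(spec$reference, readNormalizationReference, dir)
    if (is.null(ref)) stop("'", center, "' centering needs a 'reference' entry")
    expr <- if (center == "sgpct") sgPctCenter(expr, ref)
            else sgMdCenter(expr, ref)
  } else if (center == "naive") {
    expr <- medianCenter(expr)
  } else if (center != "none") {
    stop("unknown centering scheme: ", center)
  }
  cfg <- classifierConfig(method = spec$method %||% NULL,
                          minGenes = spec$min_genes %||% 10L)
  classify(expr, centroids, cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a head-to-head comparison of two subtyping pipelines
#'
#' Orchestrates the full comparison design: classify one expression input
#' with two classifier/normalization combinations (or load two precomputed
#' call tables), then compute the contingency table, overall agreement,
#' Cohen's kappa under the configured label merge, conditional rates,
#' subtype distributions, the clear-defined/discord partition, top-two
#' margins, and the second-centroid switching experiment with its adjacency
#' audit. The run is a pure function of (config, inputs): rerunning yields
#' identical output.
#'
#' @param config a list, or path to a YAML file with the same structure
#'   (file paths inside resolved relative to the YAML's directory). Either
#'   supply precomputed calls — \code{calls_a}, \code{calls_b} (paths or
#'   \linkS4class{SubtypeCalls}) — or an input and two pipelines:
#'   \describe{
#'     \item{expr}{path to an expression TSV or an
#'       \linkS4class{ExpressionMatrix}; \code{scale} (default
#'       \code{"log_generic"}) tags file input.}
#'     \item{pipelines}{named list of exactly two specs; each has
#'       \code{classifier} ("centroid"/"rules") and the components it
#'       needs: \code{centroids}, \code{method}, \code{center}
#'       ("none"/"naive"/"sgpct"/"sgmd"), \code{reference},
#'       \code{calibration}, \code{hk_genes}, \code{rules},
#'       \code{min_genes}.}
#'   }
#'   Common fields: \code{merge_map} (e.g. \code{list(NL = "LumA")},
#'   applied to kappa only), \code{switch_threshold} (default 0.1),
#'   \code{adjacency_order} (default LumA, LumB, HER2-E, BL),
#'   \code{method_names}, \code{out_dir}.
#' @return List: \code{calls_a}, \code{calls_b}, \code{report}
#'   (\linkS4class{ConcordanceReport}), \code{top_two_a}, \code{top_two_b},
#'   \code{switched_a}, \code{switch_audit}, \code{files} (when
#'   \code{out_dir} is set).
#' @export
runComparison <- function(config) {
  dir <- NULL
  if (is.character(config)) {
    dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  mergeMap <- unlist(config$merge_map) %||% NULL
  thr <- config$switch_threshold %||% 0.1
  adjOrder <- unlist(config$adjacency_order) %||% c("LumA", "LumB", "HER2-E", "BL")
  if (!is.null(config$calls_a)) {
    callsA <- .resolve(config$calls_a, readCalls, dir)
    callsB <- .resolve(config$calls_b, readCalls, dir)
    nms <- unlist(config$method_names) %||% c("method_a", "method_b")
  } else {
    if (length(config$pipelines) != 2L)
      stop("config must name exactly two pipelines (or calls_a/calls_b)")
    expr <- .resolve(config$expr, function(p)
      readExpressionMatrix(p, scale = config$scale %||% "log_generic"), dir)
    if (is.null(expr)) stop("config needs an 'expr' entry")
    callsA <- .applyPipeline(expr, config$pipelines[[1L]], dir)
    callsB <- .applyPipeline(expr, config$pipelines[[2L]], dir)
    nms <- names(config$pipelines) %||% c("pipeline_a", "pipeline_b")
  }
  .checkSameSamples(sampleIds(callsA), sampleIds(callsB))
  report <- concordanceReport(callsA, callsB, mergeMap = mergeMap,
                              methodA = nms[1L], methodB = nms[2L])
  ttA <- topTwo(callsA)
  ttB <- topTwo(callsB)
  swA <- switchToSecond(callsA, threshold = thr)
  audit <- tryCatch(adjacencyAudit(callsA, swA, order = adjOrder),
                    error = function(e) list(transitions = NULL,
                                             summary = list(note = conditionMessage(e))))
  out <- list(calls_a = callsA, calls_b = callsB, report = report,
              top_two_a = ttA, top_two_b = ttB, switched_a = swA,
              switch_audit = audit)
  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    dir.create(od, showWarnings = FALSE, recursive = TRUE)
    files <- c(calls_a = file.path(od, "calls_a.tsv"),
               calls_b = file.path(od, "calls_b.tsv"),
               contingency = file.path(od, "contingency.tsv"),
               report = file.path(od, "report.json"),
               top_two_a = file.path(od, "top_two_a.tsv"),
               switched_a = file.path(od, "switched_a.tsv"),
               switch_audit = file.path(od, "switch_audit.json"))
    writeCalls(callsA, files["calls_a"])
    writeCalls(callsB, files["calls_b"])
    writeContingencyTable(report@table, files["contingency"])
    writeReport(report, files["report"])
    write.table(ttA, files["top_two_a"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeCalls(swA, files["switched_a"])
    jsonlite::write_json(list(summary = audit$summary,
                              transitions = audit$transitions,
                              switch = swA@metadata$switch),
                         files["switch_audit"], auto_unbox = TRUE,
                         digits = NA, null = "null")
    out$files <- files
  }
  out
}
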