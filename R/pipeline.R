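#' Run the full screening pipeline
#'
#' Orchestrates an end-to-end run: quality-control filtering, GFP+ ratio
#' summarization, Z-scoring, high/low classification, and optionally the
#' embryonic-lethality analysis and the ToxCast-style target-family
#' enrichment.  Inputs are either explicit tables or a [SimConfig] from
#' which all three tables are generated; a run is fully deterministic
#' given the configuration seed.
#'
#' @param wells well-record table (ignored when \code{simConfig} given).
#' @param lethality optional lethality plate table.
#' @param assays optional assay-record table.
#' @param simConfig optional [SimConfig]; when supplied, the three input
#'   tables are generated from it.
#' @param zThreshold Z-score classification threshold (default 1).
#' @param deadThreshold QC dead-worm fraction cutoff (default 0.10).
#' @param sigmaConvention \code{"sample"} or \code{"population"}.
#' @param construction Fisher 2x2 construction for the enrichment stage.
#' @param control control label for the lethality stage.
#' @param excludeChemicals chemicals removed before Z-scoring (input-level
#'   exclusions such as assay-interfering fluorescence).
#' @param outDir optional output directory; when given, every stage table
#'   is written there via [exportTables()].
#' @return a run report: a list with elements \code{qc} (kept/excluded
#'   wells), \code{summaries}, \code{zmatrix} (a [ZScoreMatrix]),
#'   \code{classification}, \code{lethality}, \code{bioactivity},
#'   \code{enrichment}, \code{counts} (stage bookkeeping) and
#'   \code{provenance}.
#' @examples
#' rep <- runPipeline(simConfig = simConfig(nChemicals = 8, seed = 11))
#' rep$counts
#' @export
runPipeline <- function(wells = NULL, lethality = NULL, assays = NULL,
                        simConfig = NULL, zThreshold = 1,
                        deadThreshold = 0.10,
                        sigmaConvention = c("sample", "population"),
                        construction = c("vs_rest", "vs_total"),
                        control = "DMSO", excludeChemicals = character(),
                        outDir = NULL) {
  sigmaConvention <- match.arg(sigmaConvention)
  construction <- match.arg(construction)
  prov <- list(package_version =
                 as.character(utils::packageVersion("ReproScreen")),
               z_threshold = zThreshold, dead_threshold = deadThreshold,
               sigma_convention = sigmaConvention,
               fisher_construction = construction)
  if (!is.null(simConfig)) {
    wells <- simulateScreen(simConfig)
    lethality <- simulateLethality(simConfig)
    assays <- simulateAssays(simConfig)
    prov$seed <- simConfig@seed
    prov$config_hash <- configHash(simConfig)
  }
  if (is.null(wells)) stop("either 'wells' or 'simConfig' is required")
  if (length(excludeChemicals))
    wells <- wells[!wells$chemical_id %in% excludeChemicals, ,
                   drop = FALSE]
  qc <- withCallingHandlers(
    qcFilter(wells, deadThreshold = deadThreshold),
    error = function(e) stop("stage qc_filter: ", conditionMessage(e),
                             call. = FALSE))
  tested <- unique(wells[, c("chemical_id", "concentration")])
  summaries <- summarizeScreen(qc$kept)
  zmat <- tryCatch(
    computeZScores(summaries, tested = tested,
                   sigmaConvention = sigmaConvention),
    error = function(e) stop("stage zscores: ", conditionMessage(e),
                             call. = FALSE))
  classification <- classifyChemicals(zmat, threshold = zThreshold)
  lethRes <- NULL
  if (!is.null(lethality))
    lethRes <- tryCatch(
      lethalityAnalysis(lethality, control = control),
      error = function(e) stop("stage lethality: ", conditionMessage(e),
                               call. = FALSE))
  bio <- enr <- NULL
  if (!is.null(assays)) {
    bio <- bioactivitySummary(assays)
    grp <- classification[classification$label %in% c("high", "low"), ]
    if (nrow(grp) >= 2L && length(unique(grp$label)) == 2L) {
      fc <- familyCounts(
        assays[assays$chemical_id %in% grp$chemical_id, , drop = FALSE],
        stats::setNames(grp$label, grp$chemical_id))
      if (nrow(fc) >= 2L &&
          sum(fc$count_bottom) > 0 && sum(fc$count_top) > 0)
        enr <- familyEnrichment(fc, construction = construction)
    }
  }
  report <- list(
    qc = qc,
    summaries = summaries,
    zmatrix = zmat,
    classification = classification,
    lethality = lethRes,
    bioactivity = bio,
    enrichment = enr,
    counts = data.frame(
      stage = c("wells_in", "wells_kept", "wells_excluded",
                "chemicals", "high", "low", "unclassified"),
      n = c(nrow(wells), nrow(qc$kept), nrow(qc$excluded),
            nrow(classification),
            sum(classification$label == "high"),
            sum(classification$label == "low"),
            sum(classification$label == "unclassified"))),
    provenance = prov)
  class(report) <- c("screenRunReport", "list")
  if (!is.null(outDir)) exportTables(report, outDir)
  report
}

#' @export
print.screenRunReport <- function(x, ...) {
  cat("Screen pipeline run\n")
  cat(sprintf("  wells: %d in, %d kept, %d excluded\n",
              x$counts$n[1], x$counts$n[2], x$counts$n[3]))
  cat(sprintf("  chemicals: %d (%d high, %d low, %d unclassified at Z > %g)\n",
              x$counts$n[4], x$counts$n[5], x$counts$n[6], x$counts$n[7],
              x$provenance$z_threshold))
  if (!is.null(x$lethality)) {
    sig <- x$lethality$comparisons
    cat(sprintf("  lethality: %d/%d comparisons significant\n",
                sum(sig$significant), nrow(sig)))
  }
  if (!is.null(x$enrichment))
    cat(sprintf("  enrichment: %d families, top: %s (p = %.3g)\n",
                nrow(x$enrichment), x$enrichment$family[1],
                x$enrichment$fisher_p[1]))
  invisible(x)
}

#' Export every stage table of a pipeline run
#'
#' Writes CSV mirrors of the run's tables (exclusion log, per-concentration
#' summaries, Z-score matrix with \code{NT}/\code{NDA} markers,
#' classification, lethality comparisons, bioactivity, enrichment) plus a
#' JSON run report.  Re-export of the same report is byte-identical (no
#' timestamps are embedded).
#'
#' @param report a run report from [runPipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
exportTables <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wr <- function(df, file) {
    p <- file.path(dir, file)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$qc$excluded, "exclusions.csv")
  wr(report$summaries, "summaries.csv")
  p <- file.path(dir, "zscores.csv")
  writeZScoreMatrix(report$zmatrix, p)
  paths <- c(paths, p)
  wr(report$classification, "classification.csv")
  if (!is.null(report$lethality)) {
    wr(report$lethality$group_means, "lethality_means.csv")
    wr(report$lethality$comparisons, "lethality_comparisons.csv")
  }
  if (!is.null(report$bioactivity)) wr(report$bioactivity,
                                       "bioactivity.csv")
  if (!is.null(report$enrichment)) {
    enr <- report$enrichment
    enr$construction <- attr(enr, "construction")
    wr(enr, "enrichment.csv")
  } else if (!is.null(report$bioactivity)) {
    wr(data.frame(family = character(), count_bottom = integer(),
                  count_top = integer(), fisher_p = numeric(),
                  fdr_p = numeric()), "enrichment.csv")
  }
  rj <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(counts = report$counts, provenance = report$provenance),
    rj, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, rj)
  invisible(paths)
}

#' Reproduce the published summary analyses from packaged fixtures
#'
#' Re-runs, from the plain-text fixtures shipped with the package, the
#' desk-reproducible published results: the high/low classification of the
#' 25 published chemicals, the bioactivity ratios recomputed from the
#' active/total counts, and the target-family enrichment from the
#' per-family counts.
#'
#' @param zThreshold classification threshold (default 1).
#' @param construction Fisher 2x2 construction (see [familyEnrichment()]).
#' @return a list with elements \code{classification}, \code{counts}
#'   (chemicals with Z above threshold at >= 1, 2, 3 concentrations),
#'   \code{bioactivity}, \code{group_comparison} and \code{enrichment}.
#' @examples
#' rep <- reproducePublished()
#' rep$counts
#' @export
reproducePublished <- function(zThreshold = 1,
                               construction = c("vs_rest", "vs_total")) {
  construction <- match.arg(construction)
  zmat <- publishedZScores()
  cls <- classifyChemicals(zmat, threshold = zThreshold)
  bio <- publishedBioactivity()
  ratios <- bioactivitySummary(data.frame(
    chemical_id = rep(bio$chemical, bio$n_total),
    hit_call = unlist(lapply(seq_len(nrow(bio)), function(i)
      rep(c(TRUE, FALSE),
          c(bio$n_active[i], bio$n_total[i] - bio$n_active[i]))))))
  ratios <- merge(ratios, bio[, c("chemical", "group", "ratio_printed")],
                  by.x = "chemical_id", by.y = "chemical")
  cmp <- compareGroupBioactivity(
    ratios$bioactivity_ratio[ratios$group == "high"],
    ratios$bioactivity_ratio[ratios$group == "low"])
  fc <- publishedFamilyCounts()
  enr <- familyEnrichment(
    fc[, c("family", "count_bottom", "count_top")],
    construction = construction)
  list(classification = cls,
       counts = c(any = countAbove(zmat, zThreshold, 1L),
                  atLeast2 = countAbove(zmat, zThreshold, 2L),
                  atLeast3 = countAbove(zmat, zThreshold, 3L)),
       bioactivity = ratios,
       group_comparison = cmp,
       enrichment = enr)
}
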