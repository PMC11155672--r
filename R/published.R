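.extdata <- function(file)
  system.file("extdata", file, package = "ReproScreen", mustWork = TRUE)

#' Published summary tables of the 133-chemical screen
#'
#' Loaders for the plain-text fixtures shipped with the package: the
#' published chemical-by-concentration Z-score matrices of the 25 high/low
#' classified chemicals, the per-chemical ToxCast bioactivity counts, and
#' the per-target-family active-hit counts (with the p-values as printed,
#' for cross-checking).  No raw well-level data were deposited for the
#' screen; these summary tables are the fixed in-study inputs that the
#' package can re-analyze without any download.
#'
#' Note the published CAS column contains two apparent typos (the same CAS
#' listed for thiabendazole and triflumizole, and a perfluorononanoic-acid
#' CAS listed for norflurazon); identifiers are treated as opaque labels
#' and rows are keyed by chemical name.
#'
#' @return \code{publishedZScores()}: a [ZScoreMatrix] of the 25 published
#'   chemicals (rownames are chemical names; \code{rowData} carries the CAS
#'   label and the published group).  \code{publishedBioactivity()}: a
#'   \code{data.frame} with chemical, group, active/total assay counts and
#'   the printed ratio.  \code{publishedFamilyCounts()}: a
#'   \code{data.frame} with per-family active-hit counts in the bottom and
#'   top chemical groups and the printed Fisher and FDR-adjusted p-values.
#' @examples
#' table(classifyChemicals(publishedZScores())$label)
#' @export
publishedZScores <- function() {
  df <- utils::read.csv(.extdata("published_zscores.csv"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, c("10", "30", "50", "100")])
  rownames(m) <- df$chemical
  status <- matrix("OK", nrow(m), ncol(m), dimnames = dimnames(m))
  status[m == "NT"] <- "NT"
  status[m == "NDA"] <- "NDA"
  z <- suppressWarnings(
    matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m)))
  obj <- zScoreMatrixFromZ(z, status)
  rowData(obj)$cas <- df$cas
  rowData(obj)$published_group <- df$group
  obj
}

#' @rdname publishedZScores
#' @export
publishedBioactivity <- function()
  utils::read.csv(.extdata("published_bioactivity.csv"),
                  stringsAsFactors = FALSE)

#' @rdname publishedZScores
#' @export
publishedFamilyCounts <- function()
  utils::read.csv(.extdata("published_target_families.csv"),
                  stringsAsFactors = FALSE)
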