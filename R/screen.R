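.wellCols <- c("chemical_id", "concentration", "bio_repeat",
               "tech_replicate", "n_total", "n_dead", "n_gfp_pos",
               "ectopic")

.wellLabel <- function(wells, i) {
  lab <- if (all(c("plate_id", "well_position") %in% names(wells)))
    paste0(wells$plate_id[i], "/", wells$well_position[i]) else
    paste0("row ", i)
  paste0(lab, " (", wells$chemical_id[i], ")")
}

#' Validate a well-record table
#'
#' Checks the structural invariants of well-level screen records: required
#' columns present, non-negative counts, \code{n_dead <= n_total},
#' \code{n_gfp_pos <= n_total}, and \code{n_total > 0}.  Violations raise
#' an error naming the offending well.
#'
#' @param wells a \code{data.frame} of well records (see
#'   [simulateScreen()] for the column contract).
#' @return invisibly, \code{wells}.
#' @export
validateWells <- function(wells) {
  missing <- setdiff(.wellCols, names(wells))
  if (length(missing))
    stop("well table lacks columns: ", paste(missing, collapse = ", "))
  bad <- which(wells$n_total <= 0)
  if (length(bad))
    stop("invalid record (n_total = 0) at well ", .wellLabel(wells, bad[1]))
  bad <- which(wells$n_dead < 0 | wells$n_dead > wells$n_total)
  if (length(bad))
    stop("invalid record (n_dead outside [0, n_total]) at well ",
         .wellLabel(wells, bad[1]))
  bad <- which(wells$n_gfp_pos < 0 | wells$n_gfp_pos > wells$n_total)
  if (length(bad))
    stop("invalid record (n_gfp_pos outside [0, n_total]) at well ",
         .wellLabel(wells, bad[1]))
  invisible(wells)
}

#' Quality-control filter for screen wells
#'
#' Excludes a well if and only if its dead-worm fraction
#' \code{n_dead/n_total} strictly exceeds \code{deadThreshold} (default
#' 10%) or its ectopic-reporter-expression flag is set.  Every exclusion is
#' logged with its reason (\code{"dead_fraction"} takes precedence when
#' both apply).
#'
#' @param wells a well-record \code{data.frame}.
#' @param deadThreshold maximum tolerated dead-worm fraction (default 0.10).
#' @return a list with elements \code{kept} (the surviving wells) and
#'   \code{excluded} (the excluded wells plus a \code{reason} column).
#' @examples
#' w <- data.frame(chemical_id = "a", concentration = 100, bio_repeat = 1,
#'                 tech_replicate = 1, n_total = 100, n_dead = 15,
#'                 n_gfp_pos = 2, ectopic = FALSE)
#' qcFilter(w)$excluded$reason
#' @export
qcFilter <- function(wells, deadThreshold = 0.10) {
  if (nrow(wells) == 0L) stop("'wells' must be non-empty")
  validateWells(wells)
  deadFrac <- wells$n_dead / wells$n_total
  tooDead <- deadFrac > deadThreshold
  out <- tooDead | wells$ectopic
  excluded <- wells[out, , drop = FALSE]
  excluded$reason <- ifelse(tooDead[out], "dead_fraction", "ectopic")
  rownames(excluded) <- NULL
  kept <- wells[!out, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, excluded = excluded)
}

#' GFP+ worm ratio of a well
#'
#' The screen's primary readout: the ratio of worms containing at least one
#' GFP-positive embryo to the total number of worms in the well.
#'
#' @param wells a well-record \code{data.frame} (one or more rows).
#' @return numeric vector of per-well ratios.
#' @examples
#' wellRatio(data.frame(chemical_id = "a", concentration = 1, bio_repeat = 1,
#'                      tech_replicate = 1, n_total = 100, n_dead = 0,
#'                      n_gfp_pos = 5, ectopic = FALSE))
#' @export
wellRatio <- function(wells) {
  validateWells(wells)
  wells$n_gfp_pos / wells$n_total
}

#' Average GFP+ ratios per chemical and concentration
#'
#' Computes the quantity the Z-scores are built from: per-well GFP+ worm
#' ratios are averaged over technical replicates within each biological
#' repeat, and the biological-repeat means are then averaged (unweighted).
#' Missing repeats simply reduce \code{n_repeats_used}; a (chemical,
#' concentration) pair with no surviving wells yields no row and becomes an
#' \code{NDA} marker in the downstream [ZScoreMatrix].
#'
#' @param wells a QC-filtered well-record \code{data.frame}.
#' @return a \code{data.frame} with columns \code{chemical_id},
#'   \code{concentration}, \code{x} (mean ratio over biological repeats)
#'   and \code{n_repeats_used}.
#' @export
summarizeScreen <- function(wells) {
  if (nrow(wells) == 0L)
    return(data.frame(chemical_id = character(), concentration = numeric(),
                      x = numeric(), n_repeats_used = integer()))
  validateWells(wells)
  wells$ratio <- wells$n_gfp_pos / wells$n_total
  repMeans <- stats::aggregate(
    ratio ~ chemical_id + concentration + bio_repeat, data = wells,
    FUN = mean)
  out <- stats::aggregate(ratio ~ chemical_id + concentration,
                          data = repMeans, FUN = mean)
  nrep <- stats::aggregate(bio_repeat ~ chemical_id + concentration,
                           data = repMeans, FUN = length)
  out <- merge(out, nrep, by = c("chemical_id", "concentration"))
  names(out)[names(out) == "ratio"] <- "x"
  names(out)[names(out) == "bio_repeat"] <- "n_repeats_used"
  out <- out[order(out$chemical_id, out$concentration), ]
  rownames(out) <- NULL
  out
}

#' Compute the chemical-by-concentration Z-score matrix
#'
#' For each concentration group, \code{mu} is the mean and \code{sigma} the
#' standard deviation of the averaged ratios \code{x} across chemicals with
#' data, and each chemical's Z-score is \code{(x - mu)/sigma}.  Cells with
#' no data are marked \code{NT} (never tested) or \code{NDA} (tested but no
#' well survived quality control), distinguished via \code{tested}.
#'
#' @param summaries output of [summarizeScreen()].
#' @param tested optional \code{data.frame} with columns
#'   \code{chemical_id}, \code{concentration} listing every combination
#'   present before quality control; combinations absent from it are marked
#'   \code{NT}, combinations present in it but absent from
#'   \code{summaries} are marked \code{NDA}.  With \code{tested = NULL}
#'   all missing cells are \code{NT}.
#' @param sigmaConvention \code{"sample"} (n-1 denominator, default) or
#'   \code{"population"} (n); exposed because the convention is a genuine
#'   choice in Z-score screening practice.
#' @param chemicals,concentrations optional row/column universes (defaults:
#'   those observed).
#' @return a [ZScoreMatrix].
#' @examples
#' s <- data.frame(chemical_id = c("a", "b", "c"), concentration = 10,
#'                 x = c(0.1, 0.2, 0.3), n_repeats_used = 4L)
#' zMatrix(computeZScores(s))
#' @export
computeZScores <- function(summaries, tested = NULL,
                           sigmaConvention = c("sample", "population"),
                           chemicals = NULL, concentrations = NULL) {
  sigmaConvention <- match.arg(sigmaConvention)
  if (is.null(chemicals))
    chemicals <- sort(unique(c(summaries$chemical_id,
                               tested$chemical_id)))
  if (is.null(concentrations))
    concentrations <- sort(unique(c(summaries$concentration,
                                    tested$concentration)))
  x <- matrix(NA_real_, length(chemicals), length(concentrations),
              dimnames = list(chemicals, as.character(concentrations)))
  x[cbind(summaries$chemical_id,
          as.character(summaries$concentration))] <- summaries$x
  status <- matrix("NT", nrow(x), ncol(x), dimnames = dimnames(x))
  if (!is.null(tested))
    status[cbind(as.character(tested$chemical_id),
                 as.character(tested$concentration))] <- "NDA"
  status[!is.na(x)] <- "OK"
  mu <- sig <- rep(NA_real_, ncol(x))
  z <- x
  for (j in seq_len(ncol(x))) {
    v <- x[, j][!is.na(x[, j])]
    if (length(v) < 3L)
      stop("fewer than 3 chemicals with data at concentration ",
           colnames(x)[j])
    mu[j] <- mean(v)
    sig[j] <- if (sigmaConvention == "population")
      sqrt(mean((v - mu[j])^2)) else stats::sd(v)
    if (sig[j] == 0)
      stop("degenerate group: zero standard deviation at concentration ",
           colnames(x)[j])
    z[, j] <- (x[, j] - mu[j]) / sig[j]
  }
  se <- SummarizedExperiment(
    assays = list(z = z, x = x, status = status),
    colData = DataFrame(concentration = concentrations, mu = mu,
                        sigma = sig,
                        n_chemicals = colSums(!is.na(x)),
                        row.names = colnames(x)))
  metadata(se)$sigmaConvention <- sigmaConvention
  metadata(se)$normalized <- TRUE
  new("ZScoreMatrix", se)
}

#' Build a ZScoreMatrix from already-computed Z-scores
#'
#' Used for externally supplied matrices such as the published screen
#' tables, where only the Z-scores (not the underlying ratios or the full
#' chemical set) are available; the normalization identity is therefore not
#' enforced on such objects.
#'
#' @param z numeric matrix of Z-scores (chemicals x concentrations,
#'   \code{NA} for missing cells).
#' @param status optional character matrix (\code{"OK"}/\code{"NT"}/
#'   \code{"NDA"}) matching \code{z}; default: \code{NT} where \code{z} is
#'   missing.
#' @return a [ZScoreMatrix] with \code{metadata(x)$normalized = FALSE}.
#' @export
zScoreMatrixFromZ <- function(z, status = NULL) {
  if (is.null(status)) {
    status <- matrix(ifelse(is.na(z), "NT", "OK"), nrow(z), ncol(z),
                     dimnames = dimnames(z))
  }
  se <- SummarizedExperiment(
    assays = list(z = z, x = matrix(NA_real_, nrow(z), ncol(z),
                                    dimnames = dimnames(z)),
                  status = status),
    colData = DataFrame(
      concentration = suppressWarnings(as.numeric(colnames(z))),
      mu = NA_real_, sigma = NA_real_,
      n_chemicals = colSums(!is.na(z)), row.names = colnames(z)))
  metadata(se)$sigmaConvention <- NA_character_
  metadata(se)$normalized <- FALSE
  new("ZScoreMatrix", se)
}

#' @rdname ZScoreMatrix-class
#' @export
setMethod("zMatrix", "ZScoreMatrix", function(x) assay(x, "z"))

#' @rdname ZScoreMatrix-class
#' @export
setMethod("xMatrix", "ZScoreMatrix", function(x) assay(x, "x"))

#' @rdname ZScoreMatrix-class
#' @export
setMethod("statusMatrix", "ZScoreMatrix", function(x) assay(x, "status"))

#' @rdname ZScoreMatrix-class
#' @export
setMethod("concStats", "ZScoreMatrix", function(x)
  as.data.frame(colData(x)))

#' @rdname ZScoreMatrix-class
#' @export
setMethod("sigmaConvention", "ZScoreMatrix", function(x)
  metadata(x)$sigmaConvention)

setMethod("show", "ZScoreMatrix", function(object) {
  cat(sprintf("ZScoreMatrix: %d chemicals x %d concentrations (%s uM)\n",
              nrow(object), ncol(object),
              paste(colData(object)$concentration, collapse = ", ")))
  st <- assay(object, "status")
  cat(sprintf("  cells: %d OK, %d NT, %d NDA; sigma convention: %s\n",
              sum(st == "OK"), sum(st == "NT"), sum(st == "NDA"),
              metadata(object)$sigmaConvention))
  invisible(NULL)
})

.classifyRows <- function(z, threshold) {
  labels <- character(nrow(z)); maxz <- rep(NA_real_, nrow(z))
  nabove <- integer(nrow(z))
  allMissing <- FALSE
  for (i in seq_len(nrow(z))) {
    v <- z[i, ][!is.na(z[i, ])]
    if (length(v) == 0L) {
      labels[i] <- "unclassified"; allMissing <- TRUE
      next
    }
    maxz[i] <- max(v)
    nabove[i] <- sum(v > threshold)
    labels[i] <- if (maxz[i] > threshold) "high"
      else if (maxz[i] == threshold) "unclassified" else "low"
  }
  if (allMissing)
    warning("chemical(s) with all Z-scores missing reported as unclassified")
  data.frame(chemical_id = rownames(z), label = labels, max_z = maxz,
             n_concs_above_threshold = nabove, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' @rdname classifyChemicals
#' @export
setMethod("classifyChemicals", "ZScoreMatrix", function(x, threshold = 1)
  .classifyRows(zMatrix(x), threshold))

#' @rdname classifyChemicals
#' @export
setMethod("classifyChemicals", "matrix", function(x, threshold = 1) {
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  .classifyRows(x, threshold)
})

#' @rdname countAbove
#' @export
setMethod("countAbove", "ZScoreMatrix",
  function(x, threshold = 1, minConcentrations = 1L)
    countAbove(zMatrix(x), threshold, minConcentrations))

#' @rdname countAbove
#' @export
setMethod("countAbove", "matrix",
  function(x, threshold = 1, minConcentrations = 1L)
    sum(rowSums(x > threshold, na.rm = TRUE) >= minConcentrations))

#' Read and write screen tables
#'
#' CSV input/output for the documented table contracts.  Missing Z-score
#' cells are written as \code{NT}/\code{NDA} per the status assay.
#'
#' @param path CSV file path.
#' @return \code{readWellTable()} returns a validated well-record
#'   \code{data.frame}.
#' @export
readWellTable <- function(path) {
  wells <- utils::read.csv(path, stringsAsFactors = FALSE)
  wells$ectopic <- as.logical(wells$ectopic)
  validateWells(wells)
  wells
}

#' @rdname readWellTable
#' @param x object to write.
#' @export
writeZScoreMatrix <- function(x, path) {
  z <- zMatrix(x); st <- statusMatrix(x)
  out <- matrix(as.character(signif(z, 8)), nrow(z), ncol(z))
  out[st != "OK"] <- st[st != "OK"]
  df <- data.frame(chemical_id = rownames(z), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[-1] <- colnames(z)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname readWellTable
#' @export
readZScoreMatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  status <- matrix("OK", nrow(m), ncol(m),
                   dimnames = list(df[[1]], colnames(m)))
  status[m == "NT"] <- "NT"; status[m == "NDA"] <- "NDA"
  z <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                               dimnames = dimnames(status)))
  zScoreMatrixFromZ(z, status)
}
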