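#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

.checkProb <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    return(sprintf("'%s' must be a probability in [0, 1]", field))
  NULL
}

.checkCount <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != as.integer(x))
    return(sprintf("'%s' must be an integer count >= %d", field, min))
  NULL
}

#' Configuration of the synthetic screen generator
#'
#' An S4 class holding every parameter of the seeded synthetic-data
#' generators ([simulateScreen()], [simulateLethality()],
#' [simulateAssays()]).  The defaults produced by [simConfig()] emulate the
#' structure of the 133-chemical aneuploidy screen: up to four nominal
#' concentrations, 4--5 biological repeats in experimental duplicates,
#' roughly 100 worms per well, a baseline GFP+ worm rate below 0.2%, and a
#' minority of active chemicals with monotonic or non-monotonic
#' concentration profiles.
#'
#' @slot chemicals character vector of chemical identifiers.
#' @slot concentrations numeric vector of nominal concentrations (uM),
#'   strictly increasing.
#' @slot nBioRepeats integer, biological repeats per chemical (4--5 in the
#'   emulated design).
#' @slot nTechReplicates integer, technical (experimental) replicates per
#'   biological repeat (2 in the emulated design).
#' @slot wormsPerWell integer, worms dispensed per well (~100).
#' @slot baselineGfpRate numeric, probability that an unexposed worm carries
#'   at least one GFP+ embryo (default 0.002, the natural male rate).
#' @slot effectProfiles numeric matrix (chemicals x concentrations) of
#'   per-worm GFP+ probabilities; arbitrary per-concentration vectors, so
#'   non-monotonic profiles are representable.
#' @slot deadRateParams list with elements \code{shape1}, \code{shape2}
#'   (Beta parameters of the per-well dead fraction) and \code{edgeShift}
#'   (additive dead-rate shift for edge wells, default 0).
#' @slot ectopicRate numeric, probability a well is flagged for ectopic
#'   reporter expression.
#' @slot lethalityTruth named numeric vector of per-chemical embryonic
#'   lethality probabilities (includes the control label).
#' @slot controlLabel character, label of the vehicle control (\code{"DMSO"}).
#' @slot embryosPerPlate numeric, mean embryos laid per lethality plate.
#' @slot nLethalityExperiments integer, independent lethality experiments.
#' @slot platesPerExperiment integer, plates per experiment.
#' @slot assayParams list of in vitro assay-table parameters; see
#'   [simConfig()].
#' @slot seed integer seed that fully determines all three tables.
#'
#' @seealso [simConfig()], [simulateScreen()]
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    chemicals = "character",
    concentrations = "numeric",
    nBioRepeats = "integer",
    nTechReplicates = "integer",
    wormsPerWell = "integer",
    baselineGfpRate = "numeric",
    effectProfiles = "matrix",
    deadRateParams = "list",
    ectopicRate = "numeric",
    lethalityTruth = "numeric",
    controlLabel = "character",
    embryosPerPlate = "numeric",
    nLethalityExperiments = "integer",
    platesPerExperiment = "integer",
    assayParams = "list",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  errs <- character()
  add <- function(e) if (!is.null(e)) errs <<- c(errs, e)
  if (length(object@chemicals) < 1L || anyDuplicated(object@chemicals))
    add("'chemicals' must be a non-empty set of unique identifiers")
  conc <- object@concentrations
  if (length(conc) < 1L || anyNA(conc) || any(diff(conc) <= 0))
    add("'concentrations' must be strictly increasing")
  add(.checkCount(object@nBioRepeats, "nBioRepeats"))
  add(.checkCount(object@nTechReplicates, "nTechReplicates"))
  add(.checkCount(object@wormsPerWell, "wormsPerWell"))
  add(.checkProb(object@baselineGfpRate, "baselineGfpRate"))
  add(.checkProb(object@ectopicRate, "ectopicRate"))
  ep <- object@effectProfiles
  if (!is.numeric(ep) ||
      !identical(rownames(ep), object@chemicals) ||
      !identical(colnames(ep), as.character(conc)))
    add("'effectProfiles' must be a numeric matrix with one row per chemical and one column per concentration")
  else add(.checkProb(as.vector(ep), "effectProfiles"))
  dp <- object@deadRateParams
  if (!all(c("shape1", "shape2", "edgeShift") %in% names(dp)) ||
      !is.numeric(dp$shape1) || !is.numeric(dp$shape2) ||
      dp$shape1 < 0 || dp$shape2 <= 0)
    add("'deadRateParams' must contain non-negative shape1, positive shape2 and edgeShift")
  if (length(object@lethalityTruth) > 0) {
    add(.checkProb(object@lethalityTruth, "lethalityTruth"))
    if (is.null(names(object@lethalityTruth)))
      add("'lethalityTruth' must be a named vector")
  }
  if (!is.numeric(object@embryosPerPlate) || object@embryosPerPlate < 1)
    add("'embryosPerPlate' must be >= 1")
  add(.checkCount(object@nLethalityExperiments, "nLethalityExperiments"))
  add(.checkCount(object@platesPerExperiment, "platesPerExperiment"))
  ap <- object@assayParams
  if (is.null(ap$familyNames) || length(ap$familyNames) == 0L)
    add("'assayParams$familyNames' must be a non-empty family list")
  if (!is.null(ap$familyWeights) &&
      length(ap$familyWeights) != length(ap$familyNames))
    add("'assayParams$familyWeights' must match 'assayParams$familyNames'")
  if (length(object@seed) != 1L || is.na(object@seed))
    add("'seed' must be a single integer")
  if (length(errs)) paste(errs, collapse = "; ") else TRUE
})

#' Chemical-by-concentration Z-score container
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' screen's Z-score matrix.  Rows are chemicals, columns are nominal
#' concentration groups.  Assays:
#' \describe{
#'   \item{\code{z}}{Z-scores, \code{NA} where missing.}
#'   \item{\code{x}}{mean GFP+ worm ratios over biological repeats (may be
#'     all-\code{NA} when the object was built from published Z-scores).}
#'   \item{\code{status}}{\code{"OK"}, \code{"NT"} (not tested) or
#'     \code{"NDA"} (tested, but no well survived quality control).}
#' }
#' Column data carry the per-concentration mean \code{mu}, standard
#' deviation \code{sigma} and number of chemicals with data.  The Z-score of
#' chemical i at concentration c is \eqn{z = (x - \mu_c)/\sigma_c}, with
#' \eqn{\mu_c}, \eqn{\sigma_c} taken across chemicals within the
#' concentration group.
#'
#' When the object was produced by [computeZScores()]
#' (\code{metadata(x)$normalized} is \code{TRUE}) the validity method
#' enforces the normalization identity: within each concentration the
#' non-missing Z-scores have mean 0 and standard deviation 1 (under the
#' recorded sigma convention) to within 1e-9.
#'
#' @seealso [computeZScores()], [classifyChemicals()], [publishedZScores()]
#' @exportClass ZScoreMatrix
setClass("ZScoreMatrix", contains = "SummarizedExperiment")

setValidity("ZScoreMatrix", function(object) {
  an <- assayNames(object)
  if (!all(c("z", "status") %in% an))
    return("assays must include 'z' and 'status'")
  st <- assay(object, "status")
  if (!all(st %in% c("OK", "NT", "NDA")))
    return("'status' values must be one of OK, NT, NDA")
  z <- assay(object, "z")
  if (!identical(is.na(z), st != "OK"))
    return("'z' must be NA exactly where status is not OK")
  if (isTRUE(metadata(object)$normalized)) {
    conv <- metadata(object)$sigmaConvention
    for (j in seq_len(ncol(z))) {
      v <- z[st[, j] == "OK", j]
      if (length(v) < 2L) next
      m <- mean(v)
      s <- if (identical(conv, "population"))
        sqrt(mean((v - m)^2)) else stats::sd(v)
      if (abs(m) > 1e-9 || abs(s - 1) > 1e-9)
        return(sprintf("normalization identity violated in column %d", j))
    }
  }
  TRUE
})
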