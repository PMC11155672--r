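#' Construct a synthetic-screen configuration
#'
#' Builds a validated [SimConfig] whose defaults emulate the design of the
#' 133-chemical aneuploidy screen: four nominal concentrations (10, 30, 50,
#' 100 uM), four biological repeats in experimental duplicates, ~100 worms
#' per well, a baseline GFP+ worm rate of 0.2%, and 13 active chemicals
#' whose per-concentration effect profiles include monotonic and
#' non-monotonic shapes reaching up to roughly 8 population standard
#' deviations.  Dead-worm fractions follow a bounded Beta distribution with
#' an upper tail beyond the 10% quality-control cutoff so that the well
#' filter is exercised.
#'
#' @param nChemicals number of chemicals (default 133).
#' @param chemicals optional character vector of chemical identifiers
#'   (default \code{"chem001"}, ...).
#' @param concentrations nominal concentrations in uM, strictly increasing.
#' @param nBioRepeats biological repeats (4--5 in the emulated design).
#' @param nTechReplicates technical replicates per repeat (default 2); the
#'   two replicates use two distinct plate layouts so a given chemical
#'   occupies different well positions.
#' @param wormsPerWell worms dispensed per well (default 100).
#' @param baselineGfpRate per-worm probability of carrying at least one
#'   GFP+ embryo in unexposed animals (default 0.002).
#' @param effectProfiles optional chemicals x concentrations matrix of
#'   per-worm GFP+ probabilities; default [defaultEffectProfiles()].
#' @param nActive number of active chemicals in the default profiles.
#' @param deadRateParams list(shape1, shape2, edgeShift): Beta parameters of
#'   the per-well dead fraction plus an additive edge-well shift (default
#'   Beta(1.5, 30), shift 0).
#' @param ectopicRate probability a well is flagged for ectopic reporter
#'   expression (default 0.02).
#' @param lethalityTruth named per-chemical embryonic-lethality
#'   probabilities; default: control and background chemicals at 0.02, the
#'   two most active chemicals at 0.20 (the reported effect size of the two
#'   quaternary ammonium hits at 100 uM).
#' @param controlLabel vehicle-control label (default \code{"DMSO"}).
#' @param embryosPerPlate mean embryos laid per lethality plate (~100).
#' @param nLethalityExperiments,platesPerExperiment lethality design
#'   (3 experiments x 3 plates = 9 plates per chemical).
#' @param assayParams list of assay-table parameters: \code{nAssaysRange}
#'   (uniform range of assays per chemical), \code{hitRateShape1/2} (Beta
#'   parameters of the per-chemical hit rate), \code{hitRate} (optional
#'   fixed hit rate overriding the Beta draw), \code{ac50MissingRate}
#'   (fraction of active rows lacking an AC50), \code{ac50MeanLog},
#'   \code{ac50SdLog} (log10-normal AC50 parameters, uM scale),
#'   \code{familyNames}, \code{familyWeights} (intended-target-family
#'   sampling distribution, including the "channel 1"/"channel 2"
#'   pseudo-families).
#' @param seed integer seed; a single seed fully determines all three
#'   generated tables.
#' @return a validated [SimConfig].
#' @examples
#' cfg <- simConfig(nChemicals = 10, seed = 1)
#' head(simulateScreen(cfg))
#' @export
simConfig <- function(nChemicals = 133L,
                      chemicals = sprintf("chem%03d", seq_len(nChemicals)),
                      concentrations = c(10, 30, 50, 100),
                      nBioRepeats = 4L,
                      nTechReplicates = 2L,
                      wormsPerWell = 100L,
                      baselineGfpRate = 0.002,
                      effectProfiles = NULL,
                      nActive = max(0L, min(13L, length(chemicals) - 1L)),
                      deadRateParams = list(shape1 = 1.5, shape2 = 30,
                                            edgeShift = 0),
                      ectopicRate = 0.02,
                      lethalityTruth = NULL,
                      controlLabel = "DMSO",
                      embryosPerPlate = 100,
                      nLethalityExperiments = 3L,
                      platesPerExperiment = 3L,
                      assayParams = list(),
                      seed = 1L) {
  if (is.null(effectProfiles))
    effectProfiles <- defaultEffectProfiles(chemicals, concentrations,
                                            baselineGfpRate, nActive)
  if (is.null(lethalityTruth)) {
    active <- names(which(apply(effectProfiles, 1, max) >
                            baselineGfpRate))
    top2 <- utils::head(
      active[order(-apply(effectProfiles[active, , drop = FALSE], 1, max))],
      2L)
    lethalityTruth <- stats::setNames(
      rep(0.02, length(chemicals) + 1L), c(controlLabel, chemicals))
    lethalityTruth[top2] <- 0.20
  }
  defAssay <- list(
    nAssaysRange = c(250L, 1250L),
    hitRateShape1 = 2, hitRateShape2 = 6, hitRate = NULL,
    ac50MissingRate = 0.1, ac50MeanLog = 0.5, ac50SdLog = 1,
    familyNames = NULL, familyWeights = NULL)
  assayParams <- utils::modifyList(defAssay, assayParams,
                                   keep.null = TRUE)
  if (is.null(assayParams$familyNames)) {
    fam <- publishedFamilyCounts()
    assayParams$familyNames <- c(fam$family, "channel 1", "channel 2")
    assayParams$familyWeights <-
      c(fam$count_bottom + fam$count_top, 162, 163)
  }
  new("SimConfig",
      chemicals = as.character(chemicals),
      concentrations = as.numeric(concentrations),
      nBioRepeats = as.integer(nBioRepeats),
      nTechReplicates = as.integer(nTechReplicates),
      wormsPerWell = as.integer(wormsPerWell),
      baselineGfpRate = baselineGfpRate,
      effectProfiles = effectProfiles,
      deadRateParams = deadRateParams,
      ectopicRate = ectopicRate,
      lethalityTruth = lethalityTruth,
      controlLabel = controlLabel,
      embryosPerPlate = embryosPerPlate,
      nLethalityExperiments = as.integer(nLethalityExperiments),
      platesPerExperiment = as.integer(platesPerExperiment),
      assayParams = assayParams,
      seed = as.integer(seed))
}

#' Default per-chemical effect profiles
#'
#' Assigns \code{nActive} chemicals one of six fixed per-concentration
#' shapes (expressed as multiples of the baseline GFP+ rate), cycling
#' through strong monotonic, strong non-monotonic, low-dose-only,
#' mid-dose-only, high-dose-only and mild shapes; all remaining chemicals
#' stay at baseline.  The shapes mirror the qualitative dose-response
#' patterns seen among the screen's hits (including apparent
#' non-monotonicity).
#'
#' @param chemicals chemical identifiers.
#' @param concentrations nominal concentrations (any number; shapes are
#'   recycled/truncated across concentrations).
#' @param baselineGfpRate baseline per-worm GFP+ probability.
#' @param nActive number of active chemicals (assigned from the start of
#'   \code{chemicals}, deterministically).
#' @return numeric matrix of per-worm GFP+ probabilities with chemicals as
#'   rows and concentrations as columns.
#' @export
defaultEffectProfiles <- function(chemicals, concentrations,
                                  baselineGfpRate = 0.002,
                                  nActive = 13L) {
  shapes <- list(
    c(25, 25, 28, 20),   # strong at all concentrations
    c(10, 27, 3, 8),     # strong, erratic
    c(6, 5, 2.5, 3),     # non-monotonic: strongest at low doses
    c(1, 4, 1, 1),       # mid-dose only
    c(1, 1, 1.5, 6),     # high-dose only
    c(1, 1.5, 1, 3))     # mild
  k <- length(concentrations)
  prof <- matrix(baselineGfpRate, nrow = length(chemicals), ncol = k,
                 dimnames = list(chemicals, as.character(concentrations)))
  if (nActive > 0L) {
    for (i in seq_len(min(nActive, length(chemicals)))) {
      s <- rep_len(shapes[[(i - 1L) %% length(shapes) + 1L]], k)
      prof[i, ] <- pmin(1, baselineGfpRate * s)
    }
  }
  prof
}

# Two plate layouts: layout A assigns (chemical, concentration) combinations
# to 96-well positions in row-major order; layout B reverses the order
# within each plate, so every chemical sits at a different position in its
# two technical replicates.  Edge wells are those in the outer rows/columns.
.wellPositions <- function(nCombos, layout = c("A", "B")) {
  layout <- match.arg(layout)
  rows <- LETTERS[1:8]; cols <- 1:12
  grid <- as.vector(t(outer(rows, sprintf("%02d", cols), paste0)))
  nPlates <- ceiling(nCombos / 96L)
  pos <- character(nCombos); plate <- integer(nCombos)
  for (p in seq_len(nPlates)) {
    idx <- ((p - 1L) * 96L + 1L):min(p * 96L, nCombos)
    w <- grid[seq_along(idx)]
    if (layout == "B") w <- rev(w)
    pos[idx] <- w; plate[idx] <- p
  }
  data.frame(plate = plate, well = pos,
             edge = grepl("^[AH]|01$|12$", pos),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic well-level screen table
#'
#' Realizes the observation model the screen analysis assumes: each well
#' receives \code{wormsPerWell} worms; a per-well dead fraction is drawn
#' from Beta(\code{shape1}, \code{shape2}) (plus \code{edgeShift} for edge
#' wells, clamped to [0, 1]) and the dead count binomially from it; among
#' the surviving worms the number carrying at least one GFP+ embryo is
#' binomial with the chemical's per-concentration effect probability; an
#' ectopic-expression flag is Bernoulli.  One record is emitted per
#' (chemical, concentration, biological repeat, technical replicate), and
#' the output is fully determined by \code{config@seed}.
#'
#' @param config a validated [SimConfig].
#' @return a \code{data.frame} of well records with columns
#'   \code{chemical_id}, \code{concentration}, \code{bio_repeat},
#'   \code{tech_replicate}, \code{plate_id}, \code{well_position},
#'   \code{n_total}, \code{n_dead}, \code{n_gfp_pos}, \code{ectopic}.
#' @examples
#' wells <- simulateScreen(simConfig(nChemicals = 5, seed = 7))
#' @export
simulateScreen <- function(config) {
  validObject(config)
  set.seed(config@seed)
  grid <- expand.grid(
    tech_replicate = seq_len(config@nTechReplicates),
    bio_repeat = seq_len(config@nBioRepeats),
    concentration = config@concentrations,
    chemical_id = config@chemicals,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("chemical_id", "concentration", "bio_repeat",
                   "tech_replicate")]
  nCombos <- length(config@chemicals) * length(config@concentrations)
  layA <- .wellPositions(nCombos, "A")
  layB <- .wellPositions(nCombos, "B")
  comboKey <- paste(rep(config@chemicals,
                        each = length(config@concentrations)),
                    config@concentrations, sep = "@")
  idx <- match(paste(grid$chemical_id, grid$concentration, sep = "@"),
               comboKey)
  useB <- grid$tech_replicate %% 2L == 0L
  lay <- layA[idx, ]
  lay[useB, ] <- layB[idx[useB], ]
  n <- nrow(grid)
  dp <- config@deadRateParams
  deadFrac <- if (dp$shape1 == 0) rep(0, n) else
    stats::rbeta(n, dp$shape1, dp$shape2)
  deadFrac <- pmin(1, pmax(0, deadFrac + dp$edgeShift * lay$edge))
  nTotal <- rep(config@wormsPerWell, n)
  nDead <- stats::rbinom(n, nTotal, deadFrac)
  pEff <- config@effectProfiles[cbind(grid$chemical_id,
                                      as.character(grid$concentration))]
  nGfp <- stats::rbinom(n, nTotal - nDead, pEff)
  data.frame(
    chemical_id = grid$chemical_id,
    concentration = grid$concentration,
    bio_repeat = grid$bio_repeat,
    tech_replicate = grid$tech_replicate,
    plate_id = paste0("P", lay$plate,
                      ifelse(useB, "B", "A"), "-R", grid$bio_repeat),
    well_position = lay$well,
    n_total = nTotal,
    n_dead = nDead,
    n_gfp_pos = nGfp,
    ectopic = stats::runif(n) < config@ectopicRate,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic embryonic-lethality table
#'
#' For each requested chemical (and the vehicle control) emits
#' \code{nLethalityExperiments x platesPerExperiment} plates (9 by default).
#' Embryos laid per plate are Poisson around \code{embryosPerPlate}
#' (minimum 1); hatched larvae are binomial with success probability
#' \code{1 - lethality}.
#'
#' @param config a validated [SimConfig].
#' @param chemicals chemicals to include (default: every name in
#'   \code{config@lethalityTruth}); each must have a lethality truth entry.
#' @return a \code{data.frame} with columns \code{chemical_id},
#'   \code{experiment}, \code{plate}, \code{n_embryos}, \code{n_hatched}.
#' @export
simulateLethality <- function(config, chemicals = NULL) {
  validObject(config)
  truth <- config@lethalityTruth
  if (is.null(chemicals)) chemicals <- names(truth)
  missing <- setdiff(chemicals, names(truth))
  if (length(missing))
    stop("no lethalityTruth entry for: ", paste(missing, collapse = ", "))
  set.seed(config@seed + 1L)
  nPlates <- config@nLethalityExperiments * config@platesPerExperiment
  out <- do.call(rbind, lapply(chemicals, function(ch) {
    emb <- pmax(1L, stats::rpois(nPlates, config@embryosPerPlate))
    data.frame(
      chemical_id = ch,
      experiment = rep(seq_len(config@nLethalityExperiments),
                       each = config@platesPerExperiment),
      plate = rep(seq_len(config@platesPerExperiment),
                  config@nLethalityExperiments),
      n_embryos = emb,
      n_hatched = stats::rbinom(nPlates, emb, 1 - truth[[ch]]),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic ToxCast-style assay table
#'
#' Per chemical, draws a number of assays uniformly from
#' \code{assayParams$nAssaysRange}, a per-chemical hit rate from
#' Beta(\code{hitRateShape1}, \code{hitRateShape2}) (or the fixed
#' \code{hitRate} if given), binary hit calls, an intended target family
#' per assay from \code{familyNames} with weights \code{familyWeights}
#' (including the non-descriptive "channel" pseudo-families), and, for
#' active rows, an AC50 of \code{10^Normal(ac50MeanLog, ac50SdLog)} uM that
#' is missing with probability \code{ac50MissingRate}.
#'
#' @param config a validated [SimConfig].
#' @param chemicals chemicals to include (default all in the config).
#' @return a \code{data.frame} with columns \code{chemical_id},
#'   \code{assay_id}, \code{hit_call} (logical), \code{ac50_uM} (NA when
#'   missing) and \code{intended_target_family}.
#' @export
simulateAssays <- function(config, chemicals = config@chemicals) {
  validObject(config)
  ap <- config@assayParams
  set.seed(config@seed + 2L)
  out <- do.call(rbind, lapply(chemicals, function(ch) {
    nA <- sample(seq(ap$nAssaysRange[1], ap$nAssaysRange[2]), 1L)
    hitRate <- if (!is.null(ap$hitRate)) ap$hitRate else
      stats::rbeta(1, ap$hitRateShape1, ap$hitRateShape2)
    hit <- stats::rbinom(nA, 1L, hitRate) == 1L
    ac50 <- rep(NA_real_, nA)
    act <- which(hit)
    hasAC50 <- act[stats::runif(length(act)) >= ap$ac50MissingRate]
    ac50[hasAC50] <- 10^stats::rnorm(length(hasAC50),
                                     ap$ac50MeanLog, ap$ac50SdLog)
    data.frame(
      chemical_id = ch,
      assay_id = sprintf("%s_assay%04d", ch, seq_len(nA)),
      hit_call = hit,
      ac50_uM = ac50,
      intended_target_family = sample(ap$familyNames, nA, replace = TRUE,
                                      prob = ap$familyWeights),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write the three synthetic tables and a provenance record
#'
#' Writes \code{wells.csv}, \code{lethality.csv} and \code{assays.csv} under
#' \code{dir}, plus \code{provenance.json} recording the seed, the design
#' dimensions and a content hash of the configuration.
#'
#' @param config a validated [SimConfig].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
writeSimTables <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    wells = file.path(dir, "wells.csv"),
    lethality = file.path(dir, "lethality.csv"),
    assays = file.path(dir, "assays.csv"),
    provenance = file.path(dir, "provenance.json"))
  utils::write.csv(simulateScreen(config), paths["wells"],
                   row.names = FALSE)
  utils::write.csv(simulateLethality(config), paths["lethality"],
                   row.names = FALSE)
  utils::write.csv(simulateAssays(config), paths["assays"],
                   row.names = FALSE)
  prov <- list(
    seed = config@seed,
    n_chemicals = length(config@chemicals),
    concentrations = config@concentrations,
    n_bio_repeats = config@nBioRepeats,
    n_tech_replicates = config@nTechReplicates,
    config_hash = configHash(config))
  jsonlite::write_json(prov, paths["provenance"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Read or write a simulation configuration as JSON
#'
#' Serializes the scalar and tabular fields of a [SimConfig] to JSON and
#' rebuilds a validated object from such a file.  (YAML is not supported;
#' configuration files are JSON.)
#'
#' @param path JSON file path.
#' @return for \code{readSimConfig()}, a validated [SimConfig].
#' @export
readSimConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  prof <- NULL
  if (!is.null(x$effectProfiles)) {
    prof <- as.matrix(x$effectProfiles)
    dimnames(prof) <- list(x$chemicals, as.character(x$concentrations))
  }
  simConfig(
    chemicals = x$chemicals,
    concentrations = x$concentrations,
    nBioRepeats = x$nBioRepeats,
    nTechReplicates = x$nTechReplicates,
    wormsPerWell = x$wormsPerWell,
    baselineGfpRate = x$baselineGfpRate,
    effectProfiles = prof,
    deadRateParams = x$deadRateParams,
    ectopicRate = x$ectopicRate,
    lethalityTruth = if (!is.null(x$lethalityTruth))
      unlist(x$lethalityTruth) else NULL,
    controlLabel = x$controlLabel,
    embryosPerPlate = x$embryosPerPlate,
    assayParams = if (!is.null(x$assayParams)) x$assayParams else list(),
    seed = x$seed)
}

#' @rdname readSimConfig
#' @param config a [SimConfig] to serialize.
#' @export
writeSimConfig <- function(config, path) {
  x <- list(
    chemicals = config@chemicals,
    concentrations = config@concentrations,
    nBioRepeats = config@nBioRepeats,
    nTechReplicates = config@nTechReplicates,
    wormsPerWell = config@wormsPerWell,
    baselineGfpRate = config@baselineGfpRate,
    effectProfiles = unname(apply(config@effectProfiles, 1, identity,
                                  simplify = FALSE)),
    deadRateParams = config@deadRateParams,
    ectopicRate = config@ectopicRate,
    lethalityTruth = as.list(config@lethalityTruth),
    controlLabel = config@controlLabel,
    embryosPerPlate = config@embryosPerPlate,
    assayParams = config@assayParams[
      !vapply(config@assayParams, is.null, logical(1))],
    seed = config@seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
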