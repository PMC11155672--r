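#' @rdname ZScoreMatrix-class
#' @param x a \code{ZScoreMatrix}.
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))

#' @rdname ZScoreMatrix-class
#' @export
setGeneric("xMatrix", function(x) standardGeneric("xMatrix"))

#' @rdname ZScoreMatrix-class
#' @export
setGeneric("statusMatrix", function(x) standardGeneric("statusMatrix"))

#' @rdname ZScoreMatrix-class
#' @export
setGeneric("concStats", function(x) standardGeneric("concStats"))

#' @rdname ZScoreMatrix-class
#' @export
setGeneric("sigmaConvention", function(x) standardGeneric("sigmaConvention"))

#' Classify chemicals as high or low Z-score
#'
#' Applies the screen's ranking rule: a chemical is \code{high} if any of
#' its non-missing Z-scores strictly exceeds \code{threshold} at any tested
#' concentration, \code{low} if all non-missing Z-scores are strictly below
#' \code{threshold}, and \code{unclassified} when its maximum Z-score equals
#' the threshold exactly or when every entry is missing (the latter with a
#' warning).  Missing entries (\code{NT}/\code{NDA}) are ignored.
#'
#' @param x a [ZScoreMatrix] or a plain numeric matrix (chemicals x
#'   concentrations, \code{NA} for missing).
#' @param threshold numeric classification threshold (default 1, i.e. one
#'   standard deviation above the concentration-group mean).
#' @return a \code{data.frame} with columns \code{chemical_id},
#'   \code{label} (\code{high}/\code{low}/\code{unclassified}),
#'   \code{max_z} and \code{n_concs_above_threshold}.
#' @examples
#' z <- rbind(diazinon = c(NA, 0.857, NA, 1.416),
#'            monobenzyl = c(-0.385, -0.082, -0.425, -0.615))
#' classifyChemicals(z)
#' @export
setGeneric("classifyChemicals",
  function(x, threshold = 1) standardGeneric("classifyChemicals"))

#' Count chemicals exceeding a Z threshold at several concentrations
#'
#' Counts chemicals whose Z-score strictly exceeds \code{threshold} at at
#' least \code{minConcentrations} non-missing concentrations.
#'
#' @inheritParams classifyChemicals
#' @param minConcentrations minimum number of concentrations at which the
#'   threshold must be exceeded.
#' @return integer count.
#' @examples
#' z <- rbind(a = c(2, 3, 0, 1.5), b = c(0, 1.2, 0, 0))
#' countAbove(z, 1, 2)
#' @export
setGeneric("countAbove",
  function(x, threshold = 1, minConcentrations = 1L)
    standardGeneric("countAbove"))
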