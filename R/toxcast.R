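.assayCols <- c("chemical_id", "hit_call")

#' Per-chemical bioactivity summary
#'
#' For each chemical, the number of active hit calls, the total number of
#' assays tested, and the bioactivity ratio \code{n_active/n_total} (full
#' precision; a \code{ratio_display} column rounds to 3 decimals as the
#' published tables do).  A chemical with zero assays is reported with
#' \code{NA} ratios (missing-data marker).
#'
#' @param assays assay-record \code{data.frame} with columns
#'   \code{chemical_id}, \code{hit_call} (logical or 0/1) and optionally
#'   \code{ac50_uM}, \code{intended_target_family}.
#' @param chemicals optional chemical universe; chemicals without any assay
#'   row get the missing-data marker.
#' @return a \code{data.frame} with columns \code{chemical_id},
#'   \code{n_active}, \code{n_total}, \code{bioactivity_ratio},
#'   \code{ratio_display}.
#' @examples
#' a <- data.frame(chemical_id = "x", hit_call = c(TRUE, FALSE))
#' bioactivitySummary(a)
#' @export
bioactivitySummary <- function(assays, chemicals = NULL) {
  if (length(setdiff(.assayCols, names(assays))))
    stop("assay table lacks columns: ",
         paste(setdiff(.assayCols, names(assays)), collapse = ", "))
  hit <- as.logical(assays$hit_call)
  tot <- table(assays$chemical_id)
  act <- tapply(hit, assays$chemical_id, sum)
  out <- data.frame(chemical_id = names(tot),
                    n_active = as.integer(act[names(tot)]),
                    n_total = as.integer(tot),
                    stringsAsFactors = FALSE)
  if (!is.null(chemicals)) {
    miss <- setdiff(chemicals, out$chemical_id)
    if (length(miss))
      out <- rbind(out, data.frame(chemical_id = miss, n_active = NA,
                                   n_total = 0L))
    out <- out[match(chemicals, out$chemical_id), ]
  }
  out$bioactivity_ratio <- ifelse(out$n_total > 0,
                                  out$n_active / out$n_total, NA_real_)
  out$ratio_display <- round(out$bioactivity_ratio, 3)
  rownames(out) <- NULL
  out
}

#' Log10 AC50 values for a chemical's active assays
#'
#' Transforms AC50 values (uM) of active hit calls to log10; active assays
#' lacking an AC50 receive the conventional imputed value 3.0 (i.e.
#' 1000 uM) on the log10 scale.  Inactive assays contribute nothing.
#'
#' @param assays assay records, typically restricted to one chemical; must
#'   contain \code{hit_call} and \code{ac50_uM}.
#' @param impute log10 value assigned to active assays without an AC50
#'   (default 3).
#' @return numeric vector, one value per active assay.
#' @examples
#' a <- data.frame(chemical_id = "x", hit_call = c(TRUE, TRUE, TRUE),
#'                 ac50_uM = c(1, NA, 1000))
#' log10AC50(a)
#' @export
log10AC50 <- function(assays, impute = 3) {
  act <- assays[as.logical(assays$hit_call), , drop = FALSE]
  if (any(!is.na(act$ac50_uM) & act$ac50_uM <= 0))
    stop("invalid record: AC50 must be positive")
  ifelse(is.na(act$ac50_uM), impute, log10(act$ac50_uM))
}

#' Welch t-test between two groups of bioactivity ratios
#'
#' Unpaired two-tailed t-test with Welch's correction comparing the
#' per-chemical bioactivity ratios of the high and low Z-score groups.
#'
#' @param ratiosHigh,ratiosLow numeric vectors (at least 2 values each).
#' @return a list: \code{mean_high}, \code{mean_low}, \code{t}, \code{df},
#'   \code{p}.
#' @export
compareGroupBioactivity <- function(ratiosHigh, ratiosLow) {
  if (length(ratiosHigh) < 2L || length(ratiosLow) < 2L)
    stop("each group needs at least 2 values")
  fit <- stats::t.test(ratiosHigh, ratiosLow, var.equal = FALSE)
  list(mean_high = mean(ratiosHigh), mean_low = mean(ratiosLow),
       t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Active-hit counts per intended target family and chemical group
#'
#' Cross-tabulates active hit calls by intended target family and chemical
#' group (bottom = low Z-score, top = high Z-score).  The non-descriptive
#' \code{"channel 1"}/\code{"channel 2"} pseudo-families are excluded (they
#' are retained in bioactivity summaries but carry no target information);
#' chemicals active only in channel categories consequently drop out of the
#' family analysis.  Records with a missing family are ignored.
#'
#' @param assays assay records including \code{intended_target_family}.
#' @param groups group assignment: either a named character vector
#'   (chemical -> \code{"top"}/\code{"bottom"}) or a \code{data.frame} with
#'   columns \code{chemical_id} and \code{group}.  Labels \code{"high"} and
#'   \code{"low"} are accepted as synonyms of \code{"top"}/\code{"bottom"}.
#' @return a \code{data.frame} with columns \code{family},
#'   \code{count_bottom}, \code{count_top}.
#' @export
familyCounts <- function(assays, groups) {
  if (is.data.frame(groups))
    groups <- stats::setNames(as.character(groups$group),
                              groups$chemical_id)
  groups <- c(high = "top", top = "top",
              low = "bottom", bottom = "bottom")[tolower(groups)] |>
    stats::setNames(names(groups))
  if (anyNA(groups)) stop("group labels must be top/high or bottom/low")
  miss <- setdiff(unique(assays$chemical_id), names(groups))
  if (length(miss))
    stop("no group assignment for: ", paste(miss, collapse = ", "))
  act <- assays[as.logical(assays$hit_call), , drop = FALSE]
  fam <- act$intended_target_family
  keep <- !is.na(fam) & !grepl("^channel", tolower(trimws(fam)))
  act <- act[keep, , drop = FALSE]
  if (nrow(act) == 0L)
    return(data.frame(family = character(), count_bottom = integer(),
                      count_top = integer()))
  tab <- table(factor(act$intended_target_family),
               factor(groups[act$chemical_id],
                      levels = c("bottom", "top")))
  data.frame(family = rownames(tab),
             count_bottom = as.integer(tab[, "bottom"]),
             count_top = as.integer(tab[, "top"]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, optionally with a family size \code{m} larger
#' than the number of p-values supplied (the adjustment then behaves as if
#' the extra tests had p = 1).
#'
#' @param p numeric p-values in [0, 1].
#' @param m family size (default \code{length(p)}).
#' @return adjusted p-values, capped at 1, never below the raw values.
#' @examples
#' benjaminiHochberg(0.000431, m = 42)  # 0.000431 * 42
#' @export
benjaminiHochberg <- function(p, m = length(p)) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("'m' must be >= length(p)")
  stats::p.adjust(p, method = "BH", n = m)
}

#' Target-family enrichment between chemical groups
#'
#' Tests each intended target family for differential representation of
#' active hit calls between the bottom (low Z-score) and top (high
#' Z-score) chemical groups with a two-sided Fisher exact test, adjusts
#' across families with Benjamini-Hochberg, and computes one overall
#' chi-square test of independence on the full families x groups table.
#'
#' The published analysis does not state how each family's 2x2 table was
#' constructed, so two documented constructions are provided:
#' \describe{
#'   \item{\code{"vs_rest"} (default)}{family's active counts vs the
#'     remaining (non-family) active counts in each group — the standard
#'     enrichment contrast.}
#'   \item{\code{"vs_total"}}{family's active counts vs each group's total
#'     active count.}
#' }
#' The choice is recorded in the \code{construction} attribute of the
#' result.  Neither construction reproduces the published per-family
#' p-values exactly from the published counts (the published contingency
#' tables evidently used additional, unpublished margins); \code{vs_rest}
#' is the closer of the two and is the default.
#'
#' @param counts per-family count table from [familyCounts()] (columns
#'   \code{family}, \code{count_bottom}, \code{count_top}); needs at least
#'   2 families and positive totals in both groups.
#' @param construction 2x2 construction, see Details.
#' @param m Benjamini-Hochberg family size (default: number of families).
#' @return a \code{data.frame} with columns \code{family},
#'   \code{count_bottom}, \code{count_top}, \code{fisher_p}, \code{fdr_p}
#'   and \code{flagged_zero_total}, ordered by \code{fisher_p}; attributes
#'   \code{chisq_stat}, \code{chisq_df}, \code{chisq_p} and
#'   \code{construction}.
#' @examples
#' fc <- publishedFamilyCounts()[, c("family", "count_bottom", "count_top")]
#' head(familyEnrichment(fc))
#' @export
familyEnrichment <- function(counts,
                             construction = c("vs_rest", "vs_total"),
                             m = NULL) {
  construction <- match.arg(construction)
  if (nrow(counts) < 2L) stop("need at least 2 families")
  B <- sum(counts$count_bottom); Tt <- sum(counts$count_top)
  if (B <= 0 || Tt <= 0) stop("both group totals must be positive")
  if (is.null(m)) m <- nrow(counts)
  zero <- counts$count_bottom + counts$count_top == 0
  p <- vapply(seq_len(nrow(counts)), function(i) {
    if (zero[i]) return(1)
    b <- counts$count_bottom[i]; t <- counts$count_top[i]
    tab <- if (construction == "vs_rest")
      matrix(c(b, B - b, t, Tt - t), 2) else matrix(c(b, B, t, Tt), 2)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  out <- data.frame(family = counts$family,
                    count_bottom = counts$count_bottom,
                    count_top = counts$count_top,
                    fisher_p = p,
                    fdr_p = benjaminiHochberg(p, m),
                    flagged_zero_total = zero,
                    stringsAsFactors = FALSE)
  out <- out[order(out$fisher_p, out$family), ]
  rownames(out) <- NULL
  nz <- !zero
  chi <- suppressWarnings(
    stats::chisq.test(cbind(counts$count_bottom[nz],
                            counts$count_top[nz])))
  attr(out, "chisq_stat") <- unname(chi$statistic)
  attr(out, "chisq_df") <- unname(chi$parameter)
  attr(out, "chisq_p") <- chi$p.value
  attr(out, "construction") <- construction
  out
}
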