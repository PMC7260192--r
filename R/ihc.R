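#' Ki67 response between baseline and end of treatment
#'
#' The trial's primary endpoint: a relative fall in the Ki67-positive
#' tumour-cell fraction of at least 50% between baseline and the
#' end-of-treatment biopsy. The protocol states ">= 50% decrease" in one
#' place and "> 50% fall" in another; the inclusive rule is the default
#' and \code{strict = TRUE} selects the exclusive one.
#'
#' @param baselinePct,eotPct Ki67-positive percentages (0-100).
#' @param threshold relative-decrease threshold (default 0.50).
#' @param strict require the decrease to strictly exceed the threshold.
#' @return list with \code{relative_change} ((baseline - eot)/baseline)
#'   and \code{responder}.
#' @export
ki67Response <- function(baselinePct, eotPct, threshold = 0.50,
                         strict = FALSE) {
    if (any(baselinePct <= 0))
        stop("Ki67 response undefined for baseline fraction 0")
    if (any(c(baselinePct, eotPct) < 0) || any(c(baselinePct, eotPct) > 100))
        stop("Ki67 fractions must lie in [0, 100]")
    change <- (baselinePct - eotPct) / baselinePct
    resp <- if (strict) change > threshold else change >= threshold
    list(relative_change = change, responder = resp)
}

#' Cleaved-PARP score
#'
#' Percent of cleaved-PARP positive cells, requiring a minimum of 500
#' invasive tumour cells; below that the sample is recorded as
#' insufficient invasive tumour (IIT).
#'
#' @param cellsCounted invasive tumour cells assessed.
#' @param positiveCount cleaved-PARP positive cells.
#' @param minCells minimum assessable cells (default 500).
#' @return list with \code{percent} (NA when IIT) and \code{iit}.
#' @export
cparpScore <- function(cellsCounted, positiveCount, minCells = 500L) {
    if (any(cellsCounted < 0) || any(positiveCount < 0))
        stop("counts must be nonnegative")
    if (any(positiveCount > cellsCounted))
        stop("positive count exceeds cells counted")
    iit <- cellsCounted < minCells
    pct <- ifelse(iit, NA_real_, 100 * positiveCount / cellsCounted)
    list(percent = pct, iit = iit)
}

#' RAD51/geminin focus score
#'
#' From per-field counts of tumour cells, geminin (GMNN) positive cells
#' and RAD51-positive cells (cells with 5 or more RAD51 nuclear foci),
#' computes the proliferation fraction (GMNN-positive / tumour cells x
#' 100) and the RAD51 score (RAD51-positive / GMNN-positive x 100).
#' Counts are pooled across fields before forming ratios (ratio of sums,
#' not mean of ratios); with several blinded scorers each scorer's counts
#' are pooled separately and the reported score is the mean of per-scorer
#' scores. Validity requires at least \code{minTumourCells} pooled tumour
#' cells and \code{minGmnn} pooled GMNN-positive cells for every scorer; a
#' valid sample with score strictly below \code{cutoff} percent is HR
#' deficient (impaired focus formation).
#'
#' @param fields data.frame with columns \code{tumour_cells},
#'   \code{gmnn_positive}, \code{rad51_positive} and optionally
#'   \code{scorer} (single scorer assumed when absent).
#' @param minTumourCells,minGmnn validity minima (defaults 300 and 30).
#' @param cutoff HR-deficiency cutoff in percent (default 20).
#' @return a \linkS4class{Rad51Result}.
#' @examples
#' f <- data.frame(tumour_cells = c(80, 90, 70, 85, 75),
#'                 gmnn_positive = c(9, 8, 7, 8, 8),
#'                 rad51_positive = c(2, 2, 2, 2, 2))
#' rad51Score(f)
#' @export
rad51Score <- function(fields, minTumourCells = 300L, minGmnn = 30L,
                       cutoff = 20) {
    need <- c("tumour_cells", "gmnn_positive", "rad51_positive")
    miss <- setdiff(need, names(fields))
    if (length(miss))
        stop("fields table lacks column(s): ", paste(miss, collapse = ", "))
    if (nrow(fields) == 0L) stop("need at least one field")
    if (any(fields$rad51_positive > fields$gmnn_positive) ||
        any(fields$gmnn_positive > fields$tumour_cells) ||
        any(fields$tumour_cells < 0))
        stop("inconsistent counts: need rad51 <= gmnn <= tumour cells >= 0")
    if (is.null(fields$scorer)) fields$scorer <- "scorer1"

    pooled <- lapply(split(fields, fields$scorer), function(d)
        c(tumour = sum(d$tumour_cells), gmnn = sum(d$gmnn_positive),
          rad51 = sum(d$rad51_positive)))
    valid <- all(vapply(pooled, function(p)
        p[["tumour"]] >= minTumourCells && p[["gmnn"]] >= minGmnn,
        logical(1L)))
    perScorer <- vapply(pooled, function(p)
        if (p[["gmnn"]] > 0) 100 * p[["rad51"]] / p[["gmnn"]] else NA_real_,
        numeric(1L))
    prolif <- mean(vapply(pooled, function(p)
        100 * p[["gmnn"]] / p[["tumour"]], numeric(1L)))
    score <- mean(perScorer)
    new("Rad51Result",
        proliferationFraction = prolif,
        rad51Score = if (valid) score else NA_real_,
        valid = valid,
        hrDeficient = isTRUE(valid && score < cutoff),
        perScorerScores = perScorer,
        cutoff = cutoff)
}
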