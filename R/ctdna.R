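#' Poisson quantification of a droplet digital PCR well
#'
#' Converts positive/total droplet counts to template copies in the well by
#' inverting the Poisson partition model: with per-droplet occupancy
#' \eqn{\lambda}, the fraction of positive droplets is
#' \eqn{1 - e^{-\lambda}}, so the copies in the counted droplets are
#' \eqn{-\ln(1 - k/N) \times N}.
#'
#' @param positive positive droplet count(s).
#' @param total total accepted droplet count(s).
#' @return Estimated copies among the counted droplets (vectorised).
#'   Zero positives give exactly 0 copies. Saturated wells
#'   (\code{positive == total}) are an error: the concentration is
#'   unbounded and such wells must be re-run at dilution, not clipped.
#' @examples
#' quantifyWell(1500, 15000)   # -log(0.9) * 15000
#' @export
quantifyWell <- function(positive, total) {
    stopifnot(length(positive) == length(total) || length(total) == 1L)
    if (any(total <= 0)) stop("total droplet count must be > 0")
    if (any(positive < 0) || any(positive > total))
        stop("need 0 <= positive <= total")
    if (any(positive == total))
        stop("saturated well (positive == total): concentration unbounded")
    -log1p(-positive / total) * total
}

#' Copies per millilitre of plasma for one timepoint
#'
#' Sums Poisson-inverted copies over the wells a plasma sample was divided
#' into (the trial assay splits a 2 ml plasma equivalent equally into 2
#' wells) and divides by the plasma volume they jointly represent.
#'
#' @param wells data.frame with columns \code{positive} and \code{total},
#'   one row per well.
#' @param plasmaMl plasma millilitre-equivalents represented by all wells
#'   together.
#' @return list with \code{copies_per_ml} and \code{total_positive_droplets}.
#' @export
copiesPerMl <- function(wells, plasmaMl) {
    if (!is.data.frame(wells) || nrow(wells) < 1L)
        stop("need at least one well")
    if (!is.numeric(plasmaMl) || plasmaMl <= 0)
        stop("plasmaMl must be > 0")
    copies <- quantifyWell(wells$positive, wells$total)
    list(copies_per_ml = sum(copies) / plasmaMl,
         total_positive_droplets = as.integer(sum(wells$positive)))
}

#' Plasma DNA mass from the RPPH1 reference assay
#'
#' Converts single-copy reference gene (RPPH1) copies per well to DNA mass
#' by the c-value, 3.3 pg per haploid genome, reported in nanograms.
#'
#' @param rpph1CopiesPerWell nonnegative copy count(s).
#' @return mass in ng.
#' @export
dnaMassNg <- function(rpph1CopiesPerWell) {
    if (any(rpph1CopiesPerWell < 0)) stop("copies must be nonnegative")
    rpph1CopiesPerWell * 3.3e-3
}

.timepointTable <- function(df, label) {
    need <- c("mutation", "positive", "total", "plasma_ml")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop(label, " table lacks column(s): ", paste(miss, collapse = ", "))
    out <- lapply(split(df, df$mutation), function(d) {
        q <- copiesPerMl(d[, c("positive", "total")], d$plasma_ml[1L])
        data.frame(mutation = d$mutation[1L],
                   copies_per_ml = q$copies_per_ml,
                   total_positive = q$total_positive_droplets)
    })
    do.call(rbind, out)
}

#' Day-15 circulating DNA ratio (CDR15)
#'
#' The circulating DNA ratio at day 15 is the end-of-treatment ctDNA
#' copies/ml over baseline copies/ml. Mutations whose baseline sample had
#' fewer than \code{minBaselineDroplets} positive droplets (default 4) are
#' excluded; a patient is evaluable only if at least one tracked mutation
#' passes. Where several mutations are tracked, a weighted mean of the
#' per-mutation ratios is taken with weights proportional to baseline
#' copies/ml, which makes the weighted mean identical to pooled EOT
#' copies/ml over pooled baseline copies/ml. ctDNA is suppressed when the
#' ratio is strictly below \code{cutoff} (default 0.25). The
#' end-of-treatment droplet count is deliberately not thresholded: complete
#' clearance of ctDNA yields a ratio of 0.
#'
#' @param baseline,eot data.frames of per-well droplet counts with columns
#'   \code{mutation}, \code{positive}, \code{total}, \code{plasma_ml}
#'   (plasma ml-equivalents represented by that mutation's wells jointly).
#' @param cutoff suppression cutoff on the ratio scale.
#' @param minBaselineDroplets minimum baseline positive droplets per
#'   mutation.
#' @return a \linkS4class{CdrResult}.
#' @examples
#' b <- data.frame(mutation = "m1", positive = c(100, 110),
#'                 total = 15000, plasma_ml = 2)
#' e <- data.frame(mutation = "m1", positive = c(10, 12),
#'                 total = 15000, plasma_ml = 2)
#' cdr15(b, e)
#' @export
cdr15 <- function(baseline, eot, cutoff = 0.25, minBaselineDroplets = 4L) {
    bl <- .timepointTable(baseline, "baseline")
    et <- .timepointTable(eot, "eot")
    shared <- intersect(bl$mutation, et$mutation)
    if (length(shared) == 0L)
        stop("no mutation identifiers shared between baseline and EOT")
    bl <- bl[match(shared, bl$mutation), ]
    et <- et[match(shared, et$mutation), ]
    keep <- bl$total_positive >= minBaselineDroplets
    if (!any(keep)) {
        return(new("CdrResult",
                   perMutationRatios = setNames(numeric(0), character(0)),
                   weights = setNames(numeric(0), character(0)),
                   cdr15 = NA_real_, evaluable = FALSE, suppressed = FALSE,
                   cutoff = cutoff))
    }
    bl <- bl[keep, ]
    et <- et[keep, ]
    ratios <- setNames(et$copies_per_ml / bl$copies_per_ml, bl$mutation)
    w <- setNames(bl$copies_per_ml / sum(bl$copies_per_ml), bl$mutation)
    cdr <- sum(w * ratios)
    new("CdrResult", perMutationRatios = ratios, weights = w,
        cdr15 = cdr, evaluable = TRUE, suppressed = cdr < cutoff,
        cutoff = cutoff)
}

#' Compute CDR15 for every patient in a droplet-count table
#'
#' @param ddpcr data.frame with columns \code{patient}, \code{mutation},
#'   \code{timepoint} ("baseline"/"eot"), \code{positive}, \code{total},
#'   \code{plasma_ml}.
#' @inheritParams cdr15
#' @return data.frame with one row per patient: \code{patient},
#'   \code{cdr15}, \code{evaluable}, \code{suppressed},
#'   \code{n_mutations_evaluable}.
#' @export
cdr15Cohort <- function(ddpcr, cutoff = 0.25, minBaselineDroplets = 4L) {
    out <- lapply(split(ddpcr, ddpcr$patient), function(d) {
        bl <- d[d$timepoint == "baseline", ]
        et <- d[d$timepoint == "eot", ]
        if (nrow(bl) == 0L || nrow(et) == 0L) {
            return(data.frame(patient = d$patient[1L], cdr15 = NA_real_,
                              evaluable = FALSE, suppressed = FALSE,
                              n_mutations_evaluable = 0L))
        }
        res <- cdr15(bl, et, cutoff = cutoff,
                     minBaselineDroplets = minBaselineDroplets)
        data.frame(patient = d$patient[1L], cdr15 = res@cdr15,
                   evaluable = res@evaluable, suppressed = res@suppressed,
                   n_mutations_evaluable = length(res@perMutationRatios))
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
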