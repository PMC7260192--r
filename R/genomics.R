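.hrFeatureNames <- c("sub_sig3", "sub_sig8", "rearr_sig3", "rearr_sig5",
                     "del_mh_prop", "hrd_loh")

#' GRCh37 chromosome lengths
#'
#' Named lengths (bp) of the 22 autosomes and X, used to decide whether a
#' loss-of-heterozygosity segment spans a whole chromosome.
#'
#' @return named numeric vector.
#' @export
grch37ChromLengths <- function() {
    c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430,
      chr4 = 191154276, chr5 = 180915260, chr6 = 171115067,
      chr7 = 159138663, chr8 = 146364022, chr9 = 141213431,
      chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
      chr13 = 115169878, chr14 = 107349540, chr15 = 102531392,
      chr16 = 90354753, chr17 = 81195210, chr18 = 78077248,
      chr19 = 59128983, chr20 = 63025520, chr21 = 48129895,
      chr22 = 51304566, chrX = 155270560)
}

#' Non-negative least-squares mutational signature exposure fit
#'
#' Estimates per-signature exposures for one sample by minimising
#' \eqn{\|counts - S^T e\|_2} subject to \eqn{e \ge 0}, where S is the
#' signature catalog (signatures x channels, rows summing to 1).
#'
#' @param catalog numeric matrix, signatures x channels, with rownames
#'   (signature labels) and colnames (channel labels); every row must sum
#'   to 1 and entries must be nonnegative.
#' @param counts named (or catalog-ordered) mutation counts per channel.
#' @return list with \code{exposures} (named, nonnegative) and
#'   \code{residual} (Euclidean norm of the unexplained counts).
#' @examples
#' cat2 <- rbind(sigA = c(0.5, 0.5, 0), sigB = c(0, 0.5, 0.5))
#' colnames(cat2) <- c("c1", "c2", "c3")
#' fitExposures(cat2, c(c1 = 100, c2 = 200, c3 = 100))
#' @export
fitExposures <- function(catalog, counts) {
    if (is.null(rownames(catalog)) || is.null(colnames(catalog)))
        stop("catalog must carry signature rownames and channel colnames")
    if (any(catalog < 0) || any(abs(rowSums(catalog) - 1) > 1e-9))
        stop("catalog rows must be nonnegative and sum to 1")
    if (!is.null(names(counts))) {
        if (!setequal(names(counts), colnames(catalog)))
            stop("channel labels of counts do not match the catalog")
        counts <- counts[colnames(catalog)]
    } else if (length(counts) != ncol(catalog)) {
        stop("counts length does not match catalog channels")
    }
    if (any(counts < 0)) stop("counts must be nonnegative")
    if (all(counts == 0)) {
        return(list(exposures = setNames(rep(0, nrow(catalog)),
                                         rownames(catalog)),
                    residual = 0))
    }
    fit <- pracma::lsqnonneg(t(catalog), as.numeric(counts))
    list(exposures = setNames(fit$x, rownames(catalog)),
         residual = sqrt(max(fit$resid.norm, 0)))
}

.mergeSegments <- function(seg) {
    seg <- seg[order(seg$start), , drop = FALSE]
    if (nrow(seg) > 1L) {
        if (any(seg$start[-1L] < seg$end[-nrow(seg)]))
            stop("overlapping copy-number segments on ", seg$chrom[1L])
        keep <- logical(nrow(seg))
        keep[1L] <- TRUE
        for (i in 2L:nrow(seg)) {
            prev <- max(which(keep))
            if (seg$start[i] == seg$end[prev] &&
                seg$major_cn[i] == seg$major_cn[prev] &&
                seg$minor_cn[i] == seg$minor_cn[prev]) {
                seg$end[prev] <- seg$end[i]
            } else keep[i] <- TRUE
        }
        seg <- seg[keep, , drop = FALSE]
    }
    seg
}

#' HRD-LOH index from allele-specific copy-number segments
#'
#' Counts loss-of-heterozygosity segments (minor copy number 0, major at
#' least 1) longer than 15 Mb that do not span the entire chromosome.
#' Adjacent segments with identical copy number are merged before sizing,
#' so the index is invariant to how a segmentation splits a constant-CN
#' region. Coordinates are 0-based half-open.
#'
#' @param segments data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{major_cn}, \code{minor_cn}; non-overlapping within
#'   each chromosome.
#' @param chromLengths named chromosome lengths; defaults to GRCh37.
#' @param minSizeBp minimum LOH segment size (default 15 Mb).
#' @return integer count.
#' @export
hrdLohIndex <- function(segments, chromLengths = grch37ChromLengths(),
                        minSizeBp = 15e6) {
    need <- c("chrom", "start", "end", "major_cn", "minor_cn")
    miss <- setdiff(need, names(segments))
    if (length(miss))
        stop("segments table lacks column(s): ", paste(miss, collapse = ", "))
    if (nrow(segments) == 0L) return(0L)
    if (any(segments$end <= segments$start))
        stop("segments must have end > start")
    if (any(segments$major_cn < 0 | segments$minor_cn < 0))
        stop("copy numbers must be nonnegative")
    unknown <- setdiff(unique(segments$chrom), names(chromLengths))
    if (length(unknown))
        stop("no chromosome length for: ", paste(unknown, collapse = ", "))
    total <- 0L
    for (d in split(segments, segments$chrom)) {
        d <- .mergeSegments(d)
        loh <- d$minor_cn == 0 & d$major_cn >= 1
        size <- d$end - d$start
        whole <- size >= chromLengths[[d$chrom[1L]]]
        total <- total + sum(loh & size > minSizeBp & !whole)
    }
    as.integer(total)
}

#' Construct a weighted logistic HR-deficiency model
#'
#' @param intercept intercept of the linear predictor.
#' @param weights named coefficients over the six features
#'   \code{sub_sig3}, \code{sub_sig8}, \code{rearr_sig3},
#'   \code{rearr_sig5}, \code{del_mh_prop}, \code{hrd_loh}.
#' @param center,scale named standardisation constants applied to
#'   log(x + offset).
#' @param offset offset added before the log transform (default 1; the
#'   source publications do not print the value, so it is configurable).
#' @return an \linkS4class{HrdetectModel}.
#' @export
hrdetectModel <- function(intercept, weights, center, scale, offset = 1) {
    new("HrdetectModel", intercept = intercept, weights = weights,
        center = center, scale = scale, offset = offset)
}

#' Default HR-deficiency classifier
#'
#' The shipped model uses the published coefficients of the weighted
#' logistic HR-deficiency classifier over the six genomic features
#' (microhomology-deletion proportion carrying the largest weight,
#' substitution signature 3, rearrangement signatures 3 and 5, HRD-LOH
#' index, substitution signature 8). The training-cohort standardisation
#' constants are not printed in the trial report; the shipped
#' \code{center}/\code{scale} are package calibration constants placed
#' between the feature scales that the synthetic cohort generator produces
#' for deficient and proficient tumours, and can be replaced wholesale via
#' [hrdetectModel()] (or a JSON model file with [readHrdetectModel()]) when
#' scoring data on another scale.
#'
#' @return an \linkS4class{HrdetectModel}.
#' @export
defaultHrdetectModel <- function() {
    hrdetectModel(
        intercept = -3.364,
        weights = c(sub_sig3 = 1.611, sub_sig8 = 0.091, rearr_sig3 = 1.153,
                    rearr_sig5 = 0.847, del_mh_prop = 2.398, hrd_loh = 0.667),
        center = c(sub_sig3 = 5.75, sub_sig8 = 5.60, rearr_sig3 = 3.40,
                   rearr_sig5 = 4.00, del_mh_prop = 0.22, hrd_loh = 2.20),
        scale = c(sub_sig3 = 1.00, sub_sig8 = 0.50, rearr_sig3 = 1.00,
                  rearr_sig5 = 0.60, del_mh_prop = 0.12, hrd_loh = 0.50),
        offset = 1)
}

#' Score a feature vector with the weighted logistic HR-deficiency model
#'
#' Each feature x is transformed to \code{(log(x + offset) - center) /
#' scale}; the score is the logistic of the intercept plus the weighted
#' sum, and a sample is classified positive when the score strictly
#' exceeds the threshold (default 0.70).
#'
#' @param features named numeric vector (or single-row data.frame) with
#'   entries \code{sub_sig3}, \code{sub_sig8}, \code{rearr_sig3},
#'   \code{rearr_sig5}, \code{del_mh_prop}, \code{hrd_loh}.
#' @param model an \linkS4class{HrdetectModel}.
#' @param threshold classification threshold (default 0.70, strict).
#' @return an \linkS4class{HrdetectResult}.
#' @export
hrdetectScore <- function(features, model = defaultHrdetectModel(),
                          threshold = 0.70) {
    if (is.data.frame(features)) features <- unlist(features[1L, ])
    feats <- names(model@weights)
    miss <- setdiff(feats, names(features))
    if (length(miss))
        stop("missing feature(s): ", paste(miss, collapse = ", "))
    x <- features[feats]
    if (any(x < 0)) stop("features must be nonnegative")
    z <- (log(x + model@offset) - model@center[feats]) / model@scale[feats]
    lp <- model@intercept + sum(model@weights * z)
    score <- plogis(lp)
    new("HrdetectResult", score = score, positive = score > threshold,
        threshold = threshold, linearPredictor = lp)
}

#' Classify a composite HRD score
#'
#' The composite genomic-instability index (LOH + telomeric allelic
#' imbalance + large-scale state transitions) is consumed as an input; a
#' tumour is HRD-score positive when the value strictly exceeds 42.
#'
#' @param value nonnegative composite HRD score.
#' @param cutoff classification cutoff (default 42, strict).
#' @return logical.
#' @export
classifyHrdScore <- function(value, cutoff = 42) {
    if (any(value < 0)) stop("HRD score must be nonnegative")
    value > cutoff
}
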