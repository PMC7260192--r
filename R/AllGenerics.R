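#' @rdname CdrResult-class
#' @param object,x an object.
#' @export
setGeneric("cdrValue", function(object) standardGeneric("cdrValue"))

#' @rdname CdrResult-class
#' @export
setGeneric("isEvaluable", function(object) standardGeneric("isEvaluable"))

#' @rdname CdrResult-class
#' @export
setGeneric("isSuppressed", function(object) standardGeneric("isSuppressed"))

#' @rdname HrdetectResult-class
#' @param object an object.
#' @export
setGeneric("hrdScore", function(object) standardGeneric("hrdScore"))

#' @rdname HrdetectResult-class
#' @export
setGeneric("isPositive", function(object) standardGeneric("isPositive"))

#' @rdname SyntheticCohort-class
#' @param object an object.
#' @export
setGeneric("cohortTruth", function(object) standardGeneric("cohortTruth"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("cohortConfig", function(object) standardGeneric("cohortConfig"))

#' @rdname AmpliconReference-class
#' @param object an object.
#' @export
setGeneric("cpgSites", function(object) standardGeneric("cpgSites"))

setMethod("cdrValue", "CdrResult", function(object) object@cdr15)
setMethod("isEvaluable", "CdrResult", function(object) object@evaluable)
setMethod("isSuppressed", "CdrResult", function(object) object@suppressed)
setMethod("hrdScore", "HrdetectResult", function(object) object@score)
setMethod("isPositive", "HrdetectResult", function(object) object@positive)
setMethod("cohortTruth", "SyntheticCohort", function(object) object@truth)
setMethod("cohortConfig", "SyntheticCohort", function(object) object@config)
setMethod("cpgSites", "AmpliconReference", function(object)
    setdiff(object@cpgPositions, object@excludedSites))

setMethod("show", "CdrResult", function(object) {
    if (object@evaluable) {
        cat(sprintf("CDR15 = %.4g over %d mutation(s); %s (cutoff < %.3g)\n",
                    object@cdr15, length(object@perMutationRatios),
                    if (object@suppressed) "suppressed" else "not suppressed",
                    object@cutoff))
    } else {
        cat("CDR15: not evaluable (insufficient baseline positive droplets)\n")
    }
})

setMethod("show", "AmpliconReference", function(object) {
    cat(sprintf("%s amplicon: %d bp, %d CpG sites (%d excluded)\n",
                object@name, nchar(as.character(object@sequence)),
                length(object@cpgPositions), length(object@excludedSites)))
})

setMethod("show", "SimonDesign", function(object) {
    cat(sprintf(
        "Simon two-stage design: stage 1 %d (stop if <= %d responses), total %d (active if > %d)\n",
        object@n1, object@r1, object@n, object@r))
    cat(sprintf("  p0 = %.3g, p1 = %.3g\n", object@p0, object@p1))
    cat(sprintf("  exact alpha = %.4f (one-sided), power = %.4f, PET(p0) = %.3f, E[N|p0] = %.1f\n",
                object@attainedAlpha, object@attainedPower,
                object@petP0, object@expectedNP0))
})

setMethod("show", "HrdetectResult", function(object) {
    cat(sprintf("HR-deficiency score %.4f: %s (threshold > %.2f)\n",
                object@score,
                if (object@positive) "positive" else "negative",
                object@threshold))
})

setMethod("show", "Rad51Result", function(object) {
    if (!object@valid) {
        cat("RAD51 score: invalid sample (below cell-count minima)\n")
    } else {
        cat(sprintf(
            "RAD51 score %.1f%% (proliferation %.1f%%): %s (< %.0f%% = deficient)\n",
            object@rad51Score, object@proliferationFraction,
            if (object@hrDeficient) "HR deficient" else "HR proficient",
            object@cutoff))
    }
})

setMethod("show", "SampleMethylationResult", function(object) {
    cat(sprintf("Sample %s: %d/%d reads passed QC, %.3f methylated -> %s\n",
                object@sampleId, object@readsPassed, object@readsTotal,
                object@methylatedFraction,
                if (is.na(object@samplePositive)) "undetermined"
                else if (object@samplePositive) "positive" else "negative"))
})

setMethod("show", "CohortConfig", function(object) {
    cat(sprintf(
        "Cohort configuration: %d patients, HR-deficiency prevalence %.2f, seed %d\n",
        object@nPatients, object@prevalenceHrd, object@seed))
    mech <- object@prevalenceMechanisms
    cat("  mechanisms | HR deficient: ",
        paste(sprintf("%s %.2f", names(mech), mech), collapse = ", "), "\n")
})

setMethod("show", "SyntheticCohort", function(object) {
    tr <- object@truth
    cat(sprintf("Synthetic cohort of %d patients (%d HR deficient), seed %d\n",
                nrow(tr), sum(tr$hr_deficient), object@config@seed))
})
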