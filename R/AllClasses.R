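#' @import methods
#' @importFrom stats dbinom pbinom rbinom rpois rbeta rnorm rlnorm runif
#'   qbeta dhyper plogis setNames pnorm pwilcox median rgamma
#' @importFrom utils read.csv write.csv read.delim write.table head
NULL

#' Cohort simulation configuration
#'
#' Parameters of the synthetic window-trial cohort. A latent homologous
#' recombination (HR) deficiency status is drawn per patient at
#' \code{prevalenceHrd}; conditional on deficiency a mechanism (germline
#' BRCA1/2, BRCA1 promoter methylation, germline PALB2, RAD51C promoter
#' methylation, or none detectable) is drawn from
#' \code{prevalenceMechanisms}. The latent status then drives every
#' simulated assay: ctDNA dynamics (day-15 ratio drawn from a low-mode Beta
#' for deficient patients and a high-mode Beta for proficient ones),
#' promoter methylation fractions, RAD51 focus formation, and the
#' mutational-signature feature vector.
#'
#' @slot nPatients number of patients.
#' @slot prevalenceHrd probability a patient is HR deficient.
#' @slot prevalenceMechanisms named probabilities of each deficiency
#'   mechanism, conditional on HR deficiency; must sum to at most 1, the
#'   remainder is "none" (deficient with no detectable mechanism).
#' @slot ctdnaBaselineLog10Mean,ctdnaBaselineLog10Sd log10 copies/ml of the
#'   baseline ctDNA concentration (lognormal across patients).
#' @slot cdrHrdBetaParams,cdrHrpBetaParams shape pairs of the Beta
#'   distributions for the true day-15 ctDNA ratio in HR-deficient and
#'   HR-proficient patients.
#' @slot methylReadCount merged bisulfite reads simulated per sample.
#' @slot conversionErrorRate per-cytosine probability that an unmethylated
#'   cytosine escapes bisulfite conversion (appears as C).
#' @slot seqErrorRate per-base sequencing substitution error rate.
#' @slot ihcFieldCellMean mean tumour cells per scored high-power field.
#' @slot rad51ScoreHrdMean,rad51ScoreHrpMean mean end-of-treatment RAD51
#'   score (percent) in deficient and proficient patients.
#' @slot ki67ResponseRate probability of a Ki67 response (the trial's
#'   primary endpoint), independent of HR status.
#' @slot seed root seed; all assay substreams are derived from it.
#' @export
setClass("CohortConfig", representation(
    nPatients = "integer",
    prevalenceHrd = "numeric",
    prevalenceMechanisms = "numeric",
    ctdnaBaselineLog10Mean = "numeric",
    ctdnaBaselineLog10Sd = "numeric",
    cdrHrdBetaParams = "numeric",
    cdrHrpBetaParams = "numeric",
    methylReadCount = "integer",
    conversionErrorRate = "numeric",
    seqErrorRate = "numeric",
    ihcFieldCellMean = "numeric",
    rad51ScoreHrdMean = "numeric",
    rad51ScoreHrpMean = "numeric",
    ki67ResponseRate = "numeric",
    seed = "integer"
))

setValidity("CohortConfig", function(object) {
    msg <- character()
    probs <- c(prevalenceHrd = object@prevalenceHrd,
               conversionErrorRate = object@conversionErrorRate,
               seqErrorRate = object@seqErrorRate,
               ki67ResponseRate = object@ki67ResponseRate,
               object@prevalenceMechanisms)
    bad <- names(probs)[probs < 0 | probs > 1]
    if (length(bad))
        msg <- c(msg, paste0("probabilities outside [0,1]: ",
                             paste(bad, collapse = ", ")))
    if (sum(object@prevalenceMechanisms) > 1 + 1e-9)
        msg <- c(msg, "prevalenceMechanisms must sum to <= 1")
    if (object@nPatients < 1L)
        msg <- c(msg, "nPatients must be a positive count")
    if (object@methylReadCount < 1L)
        msg <- c(msg, "methylReadCount must be a positive count")
    if (object@ihcFieldCellMean <= 0)
        msg <- c(msg, "ihcFieldCellMean must be > 0")
    if (any(object@cdrHrdBetaParams <= 0) || any(object@cdrHrpBetaParams <= 0))
        msg <- c(msg, "Beta shape parameters must be > 0")
    if (object@ctdnaBaselineLog10Sd < 0)
        msg <- c(msg, "ctdnaBaselineLog10Sd must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Promoter amplicon reference
#'
#' Unconverted genomic top strand of a bisulfite PCR amplicon between the
#' primers, with the map of CpG cytosines used for methylation calling.
#' Coordinates are 0-based offsets of the CpG cytosine into the amplicon.
#' \code{excludedSites} are CpG positions removed from both numerator and
#' denominator of the per-read call (used for the two RAD51C sites found
#' consistently methylated in all samples).
#'
#' @slot name amplicon identifier, e.g. "BRCA1" or "RAD51C".
#' @slot sequence a \linkS4class{DNAString} with the unconverted sequence.
#' @slot cpgPositions 0-based offsets of CpG cytosines.
#' @slot excludedSites subset of \code{cpgPositions} excluded from calling.
#' @slot primers forward/reverse primer sequences (annotation only).
#' @export
setClass("AmpliconReference", representation(
    name = "character",
    sequence = "ANY",
    cpgPositions = "integer",
    excludedSites = "integer",
    primers = "character"
))

setValidity("AmpliconReference", function(object) {
    msg <- character()
    seqc <- as.character(object@sequence)
    n <- nchar(seqc)
    pos <- object@cpgPositions
    if (any(pos < 0L) || any(pos > n - 2L))
        msg <- c(msg, "cpgPositions out of range")
    else {
        dint <- substring(seqc, pos + 1L, pos + 2L)
        if (!all(dint == "CG"))
            msg <- c(msg, "cpgPositions must each index a C followed by G")
    }
    if (!all(object@excludedSites %in% pos))
        msg <- c(msg, "excludedSites must be a subset of cpgPositions")
    if (length(msg)) msg else TRUE
})

#' Day-15 circulating DNA ratio result
#'
#' Output of [cdr15()]. Per-mutation ratios are end-of-treatment copies/ml
#' over baseline copies/ml; mutations whose baseline samples had fewer than
#' the minimum positive droplets are excluded. Weights are proportional to
#' baseline copies/ml, so the weighted mean equals pooled EOT copies/ml over
#' pooled baseline copies/ml. A sample is evaluable if at least one tracked
#' mutation passes the baseline droplet rule, and suppressed if evaluable
#' with CDR15 strictly below the cutoff.
#'
#' @slot perMutationRatios named per-mutation EOT/baseline ratios
#'   (evaluable mutations only).
#' @slot weights named weights summing to 1 over evaluable mutations.
#' @slot cdr15 the weighted-mean ratio (NA when not evaluable).
#' @slot evaluable,suppressed flags.
#' @slot cutoff suppression cutoff (ratio scale).
#' @export
setClass("CdrResult", representation(
    perMutationRatios = "numeric",
    weights = "numeric",
    cdr15 = "numeric",
    evaluable = "logical",
    suppressed = "logical",
    cutoff = "numeric"
))

setValidity("CdrResult", function(object) {
    msg <- character()
    if (object@evaluable) {
        if (abs(sum(object@weights) - 1) > 1e-8)
            msg <- c(msg, "weights must sum to 1 over evaluable mutations")
        if (is.na(object@cdr15) || object@cdr15 < 0)
            msg <- c(msg, "cdr15 must be a nonnegative ratio when evaluable")
        if (!identical(object@suppressed, object@cdr15 < object@cutoff))
            msg <- c(msg, "suppressed must equal evaluable & cdr15 < cutoff")
    } else if (object@suppressed) {
        msg <- c(msg, "a non-evaluable sample cannot be suppressed")
    }
    if (length(msg)) msg else TRUE
})

#' Per-sample methylation summary
#'
#' @slot sampleId sample identifier.
#' @slot readsTotal,readsPassed,methylatedReads read counts.
#' @slot methylatedFraction methylated reads over passed reads.
#' @slot samplePositive flag; NA when too few reads passed QC.
#' @slot positivityThreshold fraction of methylated reads at or above which
#'   the sample is called methylation positive.
#' @export
setClass("SampleMethylationResult", representation(
    sampleId = "character",
    readsTotal = "integer",
    readsPassed = "integer",
    methylatedReads = "integer",
    methylatedFraction = "numeric",
    samplePositive = "logical",
    positivityThreshold = "numeric"
))

#' RAD51/geminin focus score
#'
#' Output of [rad51Score()]. Counts are pooled across fields per scorer
#' before forming ratios; the cross-scorer score is the mean of per-scorer
#' pooled scores. Validity requires at least 300 pooled tumour cells and 30
#' pooled geminin-positive cells; HR deficiency is a valid score strictly
#' below the cutoff (default 20 percent).
#'
#' @slot proliferationFraction geminin-positive cells per 100 tumour cells.
#' @slot rad51Score RAD51-positive cells per 100 geminin-positive cells.
#' @slot valid,hrDeficient flags.
#' @slot perScorerScores named per-scorer pooled scores.
#' @slot cutoff percent cutoff below which a valid sample is HR deficient.
#' @export
setClass("Rad51Result", representation(
    proliferationFraction = "numeric",
    rad51Score = "numeric",
    valid = "logical",
    hrDeficient = "logical",
    perScorerScores = "numeric",
    cutoff = "numeric"
))

setValidity("Rad51Result", function(object) {
    if (object@hrDeficient && !object@valid)
        return("hrDeficient cannot be TRUE on an invalid sample")
    if (object@valid && !is.na(object@rad51Score) &&
        (object@rad51Score < 0 || object@rad51Score > 100))
        return("rad51Score must lie in [0, 100]")
    TRUE
})

#' Weighted logistic HR-deficiency model
#'
#' Logistic model over six genomic features: exposures of substitution
#' signatures 3 and 8 and rearrangement signatures 3 and 5, the proportion
#' of deletions at microhomology, and the HRD-LOH index. Each feature x is
#' transformed as log(x + offset) and standardised by the model's (center,
#' scale) before entering the linear predictor.
#'
#' @slot intercept intercept of the linear predictor.
#' @slot weights named coefficients, one per feature.
#' @slot center,scale named standardisation constants, one per feature.
#' @slot offset small offset added before the log transform (default 1).
#' @export
setClass("HrdetectModel", representation(
    intercept = "numeric",
    weights = "numeric",
    center = "numeric",
    scale = "numeric",
    offset = "numeric"
))

setValidity("HrdetectModel", function(object) {
    feats <- names(object@weights)
    if (is.null(feats) || any(!nzchar(feats)))
        return("weights must be named by feature")
    for (slotnm in c("center", "scale")) {
        v <- slot(object, slotnm)
        if (!all(feats %in% names(v)))
            return(paste0(slotnm, " must cover every weighted feature"))
    }
    if (any(object@scale[feats] <= 0))
        return("scale entries must be > 0")
    TRUE
})

#' HR-deficiency score result
#'
#' @slot score classifier probability in [0, 1].
#' @slot positive flag, TRUE iff score strictly exceeds the threshold.
#' @slot threshold classification threshold (default 0.70).
#' @slot linearPredictor the untransformed linear predictor.
#' @export
setClass("HrdetectResult", representation(
    score = "numeric",
    positive = "logical",
    threshold = "numeric",
    linearPredictor = "numeric"
))

setValidity("HrdetectResult", function(object) {
    if (object@score < 0 || object@score > 1)
        return("score must lie in [0, 1]")
    if (!identical(object@positive, object@score > object@threshold))
        return("positive must equal score > threshold")
    TRUE
})

#' Simon two-stage design
#'
#' A single-arm two-stage binary-response design: enrol \code{n1} patients,
#' stop for futility if at most \code{r1} respond, otherwise enrol to a
#' total of \code{n}; declare the treatment active only if the total
#' responder count strictly exceeds \code{r}. Operating characteristics are
#' exact binomial sums (no approximations).
#'
#' @slot n1,r1 stage-1 size and futility boundary (stop if responses <= r1).
#' @slot n,r total size and final boundary (inactive if responses <= r).
#' @slot p0,p1 null and alternative response probabilities.
#' @slot alphaOneSided,beta nominal error rates used in the search.
#' @slot attainedAlpha exact rejection probability at p0.
#' @slot attainedPower exact rejection probability at p1.
#' @slot petP0 probability of early termination under p0.
#' @slot expectedNP0 expected sample size under p0.
#' @export
setClass("SimonDesign", representation(
    n1 = "integer", r1 = "integer", n = "integer", r = "integer",
    p0 = "numeric", p1 = "numeric",
    alphaOneSided = "numeric", beta = "numeric",
    attainedAlpha = "numeric", attainedPower = "numeric",
    petP0 = "numeric", expectedNP0 = "numeric"
))

setValidity("SimonDesign", function(object) {
    msg <- character()
    if (!(object@r1 < object@n1)) msg <- c(msg, "need r1 < n1")
    if (!(object@n1 <= object@n)) msg <- c(msg, "need n1 <= n")
    if (!(object@r1 <= object@r && object@r < object@n))
        msg <- c(msg, "need r1 <= r < n")
    if (length(msg)) msg else TRUE
})

#' Synthetic window-trial cohort
#'
#' Container produced by [generateCohort()]: the latent per-patient truth
#' table and the raw data bundle for each assay (droplet counts, merged
#' bisulfite reads, IHC field and scoring counts, mutation-channel counts,
#' allele-specific copy-number segments), plus the references shared across
#' patients (amplicons, signature catalog, chromosome lengths).
#'
#' @slot config the \linkS4class{CohortConfig} used.
#' @slot truth per-patient latent truth (data.frame).
#' @slot ddpcr per-well droplet counts (data.frame).
#' @slot reads named list (per patient) of named lists (per amplicon) of
#'   \code{DNAStringSet} merged bisulfite reads.
#' @slot ihcFields per-field RAD51/geminin counts (data.frame).
#' @slot ki67,cparp IHC measurements (data.frames).
#' @slot mutationCounts list with substitution and rearrangement channel
#'   count matrices (patients x channels).
#' @slot delMhProportion named per-patient microhomology-deletion fraction.
#' @slot segments copy-number segments (data.frame).
#' @slot amplicons named list of \linkS4class{AmpliconReference}.
#' @slot catalog list with substitution and rearrangement signature
#'   matrices.
#' @slot chromLengths named chromosome lengths (bp).
#' @export
setClass("SyntheticCohort", representation(
    config = "CohortConfig",
    truth = "data.frame",
    ddpcr = "data.frame",
    reads = "list",
    ihcFields = "data.frame",
    ki67 = "data.frame",
    cparp = "data.frame",
    mutationCounts = "list",
    delMhProportion = "numeric",
    segments = "data.frame",
    amplicons = "list",
    catalog = "list",
    chromLengths = "numeric"
))
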