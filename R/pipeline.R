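#' Assemble the per-patient biomarker table
#'
#' Runs every assay module over a synthetic cohort's raw data and joins
#' the results into one record per patient: CDR15 with evaluability,
#' per-amplicon methylation calls, RAD51/Ki67/cleaved-PARP scores, NNLS
#' signature exposures, HRD-LOH index and the weighted logistic
#' HR-deficiency score. A detected mechanism is any supplied germline
#' BRCA1/2 or PALB2 annotation, or promoter methylation positivity of
#' BRCA1 or RAD51C. Missing assays are marked, never imputed.
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param model an \linkS4class{HrdetectModel} for scoring.
#' @param hrdetectThreshold positivity threshold on the score.
#' @param cdrCutoff suppression cutoff for CDR15.
#' @param methylMinReads minimum passed reads for a determinate
#'   methylation call.
#' @return data.frame with one row per patient.
#' @export
assembleCohort <- function(cohort, model = defaultHrdetectModel(),
                           hrdetectThreshold = 0.70, cdrCutoff = 0.25,
                           methylMinReads = 100L) {
    truth <- cohort@truth
    ids <- truth$patient_id
    if (anyDuplicated(ids)) stop("patient identifier collision")

    cdr <- cdr15Cohort(cohort@ddpcr, cutoff = cdrCutoff)
    cdr <- cdr[match(ids, cdr$patient), ]

    methBr <- methRa <- rep(NA_real_, length(ids))
    methBrPos <- methRaPos <- rep(NA, length(ids))
    for (i in seq_along(ids)) {
        rl <- cohort@reads[[ids[i]]]
        if (is.null(rl)) next
        sb <- summarizeSample(callReads(rl$BRCA1, cohort@amplicons$BRCA1),
                              minReads = methylMinReads, sampleId = ids[i])
        sr <- summarizeSample(callReads(rl$RAD51C, cohort@amplicons$RAD51C),
                              minReads = methylMinReads, sampleId = ids[i])
        methBr[i] <- sb@methylatedFraction
        methRa[i] <- sr@methylatedFraction
        methBrPos[i] <- sb@samplePositive
        methRaPos[i] <- sr@samplePositive
    }

    rad51Eot <- rad51Base <- rep(NA_real_, length(ids))
    rad51Def <- rad51Valid <- rep(NA, length(ids))
    for (i in seq_along(ids)) {
        f <- cohort@ihcFields[cohort@ihcFields$patient == ids[i], ]
        if (nrow(f) == 0L) next
        eo <- rad51Score(f[f$timepoint == "eot", ])
        ba <- rad51Score(f[f$timepoint == "baseline", ])
        rad51Eot[i] <- eo@rad51Score
        rad51Base[i] <- ba@rad51Score
        rad51Valid[i] <- eo@valid
        rad51Def[i] <- if (eo@valid) eo@hrDeficient else NA
    }

    ki67Base <- ki67Eot <- ki67Resp <- rep(NA, length(ids))
    for (i in seq_along(ids)) {
        k <- cohort@ki67[cohort@ki67$patient == ids[i], ]
        b <- k$percent[k$timepoint == "baseline"]
        e <- k$percent[k$timepoint == "eot"]
        if (length(b) == 1L && length(e) == 1L && b > 0) {
            ki67Base[i] <- b; ki67Eot[i] <- e
            ki67Resp[i] <- ki67Response(b, e)$responder
        }
    }

    cparpEot <- rep(NA_real_, length(ids))
    cparpIit <- rep(NA, length(ids))
    for (i in seq_along(ids)) {
        cp <- cohort@cparp[cohort@cparp$patient == ids[i] &
                           cohort@cparp$timepoint == "eot", ]
        if (nrow(cp) == 1L) {
            sc <- cparpScore(cp$cells_counted, cp$positive)
            cparpEot[i] <- sc$percent
            cparpIit[i] <- sc$iit
        }
    }

    score <- lohIdx <- s3 <- s8 <- r3 <- r5 <- rep(NA_real_, length(ids))
    pos <- rep(NA, length(ids))
    for (i in seq_along(ids)) {
        if (!ids[i] %in% rownames(cohort@mutationCounts$sub)) next
        fitS <- fitExposures(cohort@catalog$sub,
                             cohort@mutationCounts$sub[ids[i], ])
        fitR <- fitExposures(cohort@catalog$rearr,
                             cohort@mutationCounts$rearr[ids[i], ])
        seg <- cohort@segments[cohort@segments$patient == ids[i], ]
        lohIdx[i] <- hrdLohIndex(seg, cohort@chromLengths)
        feats <- c(sub_sig3 = unname(fitS$exposures["sub_sig3"]),
                   sub_sig8 = unname(fitS$exposures["sub_sig8"]),
                   rearr_sig3 = unname(fitR$exposures["rearr_sig3"]),
                   rearr_sig5 = unname(fitR$exposures["rearr_sig5"]),
                   del_mh_prop = unname(cohort@delMhProportion[ids[i]]),
                   hrd_loh = lohIdx[i])
        res <- hrdetectScore(feats, model, threshold = hrdetectThreshold)
        score[i] <- res@score
        pos[i] <- res@positive
        s3[i] <- feats[["sub_sig3"]]; s8[i] <- feats[["sub_sig8"]]
        r3[i] <- feats[["rearr_sig3"]]; r5[i] <- feats[["rearr_sig5"]]
    }

    mechDetected <- truth$germline_brca | truth$germline_palb2 |
        (!is.na(methBrPos) & methBrPos) | (!is.na(methRaPos) & methRaPos)

    data.frame(
        patient_id = ids,
        control = truth$control,
        hr_deficient_truth = truth$hr_deficient,
        mechanism_truth = truth$mechanism,
        germline_brca = truth$germline_brca,
        germline_palb2 = truth$germline_palb2,
        mechanism_detected = mechDetected,
        hrdetect_score = score,
        hrdetect_positive = pos,
        sub_sig3 = s3, sub_sig8 = s8, rearr_sig3 = r3, rearr_sig5 = r5,
        del_mh_prop = unname(cohort@delMhProportion[ids]),
        hrd_loh = lohIdx,
        rad51_score_eot = rad51Eot,
        rad51_score_baseline = rad51Base,
        rad51_valid = rad51Valid,
        rad51_deficient = rad51Def,
        ki67_baseline = ki67Base,
        ki67_eot = ki67Eot,
        ki67_responder = ki67Resp,
        cparp_eot_percent = cparpEot,
        cparp_iit = cparpIit,
        methyl_brca1_fraction = methBr,
        methyl_brca1_positive = methBrPos,
        methyl_rad51c_fraction = methRa,
        methyl_rad51c_positive = methRaPos,
        cdr15 = cdr$cdr15,
        cdr_evaluable = cdr$evaluable,
        cdr_suppressed = cdr$suppressed,
        stringsAsFactors = FALSE)
}

.fisherEntry <- function(flagA, flagB, labels) {
    keep <- !is.na(flagA) & !is.na(flagB)
    a <- flagA[keep]; b <- flagB[keep]
    if (length(unique(a)) < 2L || length(unique(b)) < 2L) {
        return(list(skipped = TRUE,
                    reason = "degenerate class: a compared group is empty",
                    n = sum(keep)))
    }
    tab <- table(factor(a, levels = c(TRUE, FALSE)),
                 factor(b, levels = c(TRUE, FALSE)), dnn = labels)
    ft <- fisherExactTwoSided(as.matrix(tab))
    list(skipped = FALSE, table = as.matrix(tab), p.value = ft$p.value,
         method = "fisher_exact_two_sided", n = sum(keep))
}

.mwEntry <- function(values, flag) {
    keep <- !is.na(values) & !is.na(flag)
    x <- values[keep & flag]; y <- values[keep & !flag]
    if (length(x) < 2L || length(y) < 2L) {
        return(list(skipped = TRUE,
                    reason = "fewer than 2 patients in a compared class",
                    n = sum(keep)))
    }
    mw <- mannWhitneyU(x, y)
    list(skipped = FALSE, U = mw$U, p.value = mw$p.value,
         method = paste0("mann_whitney_", mw$method), n = sum(keep),
         mean_in = mean(x), mean_out = mean(y))
}

#' Association analyses over an assembled biomarker table
#'
#' Reproduces the trial's association structure: HR-deficiency classifier
#' class and RAD51 class against mechanism detection (Fisher exact);
#' classifier score against RAD51 class, and CDR15 against germline
#' status, RAD51 class and classifier class (Mann-Whitney); baseline to
#' end-of-treatment RAD51 score change (Wilcoxon signed rank); and the
#' Ki67 response rate with its exact binomial interval. Degenerate
#' comparisons are skipped with a recorded reason rather than erroring.
#'
#' @param records data.frame from [assembleCohort()].
#' @param includeControls keep patients flagged as controls (default
#'   FALSE, mirroring a primary sporadic-TNBC denominator).
#' @return named list of association entries.
#' @export
associations <- function(records, includeControls = FALSE) {
    if (!includeControls) records <- records[!records$control, ]
    out <- list()
    out$hrdetect_vs_mechanism <- .fisherEntry(
        records$hrdetect_positive, records$mechanism_detected,
        c("hrdetect_positive", "mechanism_detected"))
    out$rad51_vs_mechanism <- .fisherEntry(
        records$rad51_deficient, records$mechanism_detected,
        c("rad51_deficient", "mechanism_detected"))
    out$hrdetect_score_by_rad51 <- .mwEntry(
        records$hrdetect_score, records$rad51_deficient)
    cdrOk <- ifelse(records$cdr_evaluable, records$cdr15, NA_real_)
    out$cdr_by_germline <- .mwEntry(cdrOk, records$germline_brca)
    out$cdr_by_rad51 <- .mwEntry(cdrOk, records$rad51_deficient)
    out$cdr_by_hrdetect <- .mwEntry(cdrOk, records$hrdetect_positive)
    paired <- !is.na(records$rad51_score_baseline) &
        !is.na(records$rad51_score_eot)
    d <- records$rad51_score_eot[paired] - records$rad51_score_baseline[paired]
    out$rad51_baseline_to_eot <- if (sum(d != 0) >= 1L) {
        ws <- wilcoxonSignedRank(d)
        list(skipped = FALSE, W = ws$W, p.value = ws$p.value,
             method = paste0("wilcoxon_", ws$method), n = ws$n,
             median_change = median(d))
    } else list(skipped = TRUE, reason = "no nonzero paired changes", n = 0L)
    resp <- records$ki67_responder
    nResp <- sum(resp, na.rm = TRUE)
    nEval <- sum(!is.na(resp))
    ci <- if (nEval > 0) clopperPearson(nResp, nEval) else c(NA, NA)
    out$ki67_response_rate <- list(
        responders = nResp, evaluable = nEval,
        rate_percent = if (nEval > 0) 100 * nResp / nEval else NA_real_,
        ci95_percent = 100 * ci)
    out
}

#' Run the full pipeline and write its artifacts
#'
#' Generates (or loads the configuration of) a synthetic cohort, runs the
#' requested stages, and writes per-stage tables plus a single JSON
#' report. Outputs are identical for identical configuration and seed.
#'
#' @param config a \linkS4class{CohortConfig}, or the path of a YAML file
#'   whose keys are [CohortConfig()] arguments.
#' @param outDir output directory (created if needed).
#' @param seed optional override of the config seed.
#' @param writeReads also write the per-patient bisulfite reads as FASTQ
#'   (off by default; the read bundle is large).
#' @return the report, invisibly.
#' @export
runPipeline <- function(config = CohortConfig(), outDir, seed = NULL,
                        writeReads = FALSE) {
    if (is.character(config)) {
        args <- yaml::read_yaml(config)
        bad <- setdiff(names(args), names(formals(CohortConfig)))
        if (length(bad))
            stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
        if (!is.null(args$prevalenceMechanisms))
            args$prevalenceMechanisms <- unlist(args$prevalenceMechanisms)
        config <- do.call(CohortConfig, args)
    }
    if (!is.null(seed)) config@seed <- as.integer(seed)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    t0 <- Sys.time()
    cohort <- generateCohort(config)
    message(sprintf("generated cohort of %d patients [%.1fs]",
                    config@nPatients, as.numeric(Sys.time() - t0, "secs")))
    write.csv(cohort@truth, file.path(outDir, "truth.csv"), row.names = FALSE)
    write.csv(cohort@ddpcr, file.path(outDir, "ddpcr_wells.csv"),
              row.names = FALSE)
    write.csv(cohort@ihcFields, file.path(outDir, "rad51_fields.csv"),
              row.names = FALSE)
    write.csv(cohort@ki67, file.path(outDir, "ki67.csv"), row.names = FALSE)
    write.csv(cohort@cparp, file.path(outDir, "cparp.csv"), row.names = FALSE)
    write.table(cohort@segments, file.path(outDir, "segments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(vapply(cohort@amplicons, function(a)
            as.character(a@sequence), character(1L))),
        file.path(outDir, "amplicons.fasta"))
    if (writeReads) {
        rdir <- file.path(outDir, "reads")
        dir.create(rdir, showWarnings = FALSE)
        for (id in names(cohort@reads))
            for (amp in names(cohort@reads[[id]])) {
                rs <- cohort@reads[[id]][[amp]]
                q <- Biostrings::PhredQuality(
                    paste(rep("I", Biostrings::width(rs)[1L]), collapse = ""))
                Biostrings::writeQualityScaledXStringSet(
                    Biostrings::QualityScaledDNAStringSet(
                        rs, rep(q, length(rs))),
                    file.path(rdir, sprintf("%s_%s.fastq", id, amp)))
            }
    }
    t1 <- Sys.time()
    records <- assembleCohort(cohort)
    message(sprintf("assembled %d patient records [%.1fs]",
                    nrow(records), as.numeric(Sys.time() - t1, "secs")))
    write.csv(records, file.path(outDir, "biomarkers.csv"), row.names = FALSE)
    report <- list(
        config = list(n_patients = config@nPatients,
                      prevalence_hrd = config@prevalenceHrd,
                      seed = config@seed),
        cohort = list(
            n_hr_deficient_truth = sum(records$hr_deficient_truth),
            hrdetect_positive = sum(records$hrdetect_positive, na.rm = TRUE),
            rad51_deficient = sum(records$rad51_deficient, na.rm = TRUE),
            cdr_evaluable = sum(records$cdr_evaluable),
            cdr_suppressed = sum(records$cdr_suppressed)),
        associations = associations(records))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    invisible(report)
}

#' Read a weighted logistic HR-deficiency model from JSON
#'
#' The JSON object must carry \code{intercept}, \code{offset} and named
#' \code{weights}, \code{center}, \code{scale} maps.
#'
#' @param path JSON file path.
#' @return an \linkS4class{HrdetectModel}.
#' @export
readHrdetectModel <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    hrdetectModel(intercept = j$intercept, weights = unlist(j$weights),
                  center = unlist(j$center), scale = unlist(j$scale),
                  offset = if (is.null(j$offset)) 1 else j$offset)
}
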