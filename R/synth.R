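.substreamSeed <- function(seed, patient, tag) {
    ((seed %% 100000) * 20011 + patient * 10007 + tag * 101) %% 2147483647
}

.withSubstream <- function(seed, patient, tag, expr) {
    withr::with_seed(.substreamSeed(seed, patient, tag), expr)
}

#' Cohort configuration constructor
#'
#' Builds a \linkS4class{CohortConfig} with defaults calibrated to the
#' trial population this package emulates: HR-deficiency prevalence 0.69
#' among locally assessed TNBC; a detectable mechanism in about three
#' quarters of deficient tumours; day-15 ctDNA ratios drawn from a
#' low-mode Beta for deficient and a high-mode Beta for proficient
#' patients; end-of-treatment RAD51 scores well separated around the 20%
#' cutoff; and a Ki67 response rate of 0.12 independent of HR status.
#'
#' @param nPatients cohort size (default 43, the trial's accrual).
#' @param prevalenceHrd HR-deficiency prevalence (default 0.69).
#' @param prevalenceMechanisms named mechanism probabilities conditional
#'   on deficiency; remainder is "none".
#' @param ctdnaBaselineLog10Mean,ctdnaBaselineLog10Sd lognormal baseline
#'   ctDNA concentration, log10 copies/ml.
#' @param cdrHrdBetaParams,cdrHrpBetaParams Beta shapes of the true
#'   day-15 ratio per latent class.
#' @param methylReadCount merged bisulfite reads per sample.
#' @param conversionErrorRate,seqErrorRate per-base error rates.
#' @param ihcFieldCellMean mean tumour cells per scored field.
#' @param rad51ScoreHrdMean,rad51ScoreHrpMean mean EOT RAD51 score (%).
#' @param ki67ResponseRate probability of a Ki67 response.
#' @param seed root seed for all assay substreams.
#' @return a validated \linkS4class{CohortConfig}.
#' @export
CohortConfig <- function(nPatients = 43L,
                         prevalenceHrd = 0.69,
                         prevalenceMechanisms = c(
                             brca_germline = 0.35,
                             brca1_methylation = 0.25,
                             palb2_germline = 0.05,
                             rad51c_methylation = 0.10),
                         ctdnaBaselineLog10Mean = 2.0,
                         ctdnaBaselineLog10Sd = 0.6,
                         cdrHrdBetaParams = c(1.5, 10),
                         cdrHrpBetaParams = c(5, 2),
                         methylReadCount = 2000L,
                         conversionErrorRate = 0.005,
                         seqErrorRate = 0.002,
                         ihcFieldCellMean = 120,
                         rad51ScoreHrdMean = 8,
                         rad51ScoreHrpMean = 45,
                         ki67ResponseRate = 0.12,
                         seed = 1L) {
    new("CohortConfig",
        nPatients = as.integer(nPatients),
        prevalenceHrd = prevalenceHrd,
        prevalenceMechanisms = prevalenceMechanisms,
        ctdnaBaselineLog10Mean = ctdnaBaselineLog10Mean,
        ctdnaBaselineLog10Sd = ctdnaBaselineLog10Sd,
        cdrHrdBetaParams = cdrHrdBetaParams,
        cdrHrpBetaParams = cdrHrpBetaParams,
        methylReadCount = as.integer(methylReadCount),
        conversionErrorRate = conversionErrorRate,
        seqErrorRate = seqErrorRate,
        ihcFieldCellMean = ihcFieldCellMean,
        rad51ScoreHrdMean = rad51ScoreHrdMean,
        rad51ScoreHrpMean = rad51ScoreHrpMean,
        ki67ResponseRate = ki67ResponseRate,
        seed = as.integer(seed))
}

#' Synthetic signature catalog
#'
#' A fixed, reproducibly generated stand-in for the breast-cancer
#' reference catalog of 12 substitution and 6 rearrangement signatures
#' (the real catalog is an external reference consumed as input, not
#' re-derived here). Rows are signatures, columns channels, each row a
#' probability vector drawn once from a sparse Dirichlet under an internal
#' fixed seed, so the shipped catalog is a constant of the package.
#'
#' @return list with \code{sub} (12 x 96, trinucleotide channel labels)
#'   and \code{rearr} (6 x 32) matrices.
#' @export
syntheticSignatureCatalog <- function() {
    mkCatalog <- function(nSig, channels, prefix, seed) {
        withr::with_seed(seed, {
            m <- matrix(rgamma(nSig * length(channels), shape = 0.3),
                        nrow = nSig)
            m <- m / rowSums(m)
            dimnames(m) <- list(paste0(prefix, seq_len(nSig)), channels)
            m
        })
    }
    bases <- c("A", "C", "G", "T")
    subCh <- character()
    for (ref in c("C", "T")) for (alt in setdiff(bases, ref))
        for (up in bases) for (dn in bases)
            subCh <- c(subCh, paste0(up, "[", ref, ">", alt, "]", dn))
    rearrCh <- paste0(rep(c("del", "dup", "inv", "trans"), each = 8L),
                      "_bin", 1:8)
    list(sub = mkCatalog(12L, subCh, "sub_sig", 760215L),
         rearr = mkCatalog(6L, rearrCh, "rearr_sig", 760216L))
}

#' Synthetic promoter amplicons
#'
#' Deterministically constructed stand-ins for the BRCA1 and RAD51C
#' promoter amplicons (the trial's genomic amplicon sequences are not
#' printed; only the bisulfite PCR primers are). Each synthetic amplicon
#' carries the printed primer annotation, a CpG-rich interior generated
#' under an internal fixed seed, and, for RAD51C, two excluded CpG sites
#' mirroring the two sites found constitutively methylated in all
#' samples.
#'
#' @return named list of \linkS4class{AmpliconReference} objects.
#' @export
defaultAmplicons <- function() {
    mkSeq <- function(len, nCpg, seed) {
        withr::with_seed(seed, {
            repeat {
                s <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                            prob = c(0.3, 0.25, 0.2, 0.25))
                # clear accidental CpGs, then plant nCpg at spaced offsets
                cg <- which(s[-len] == "C" & s[-1L] == "G")
                s[cg] <- "A"
                pos <- round(seq(5L, len - 3L, length.out = nCpg))
                if (any(diff(pos) < 2L)) next
                s[pos] <- "C"; s[pos + 1L] <- "G"
                return(paste(s, collapse = ""))
            }
        })
    }
    brca1 <- ampliconReference(
        "BRCA1", mkSeq(120L, 10L, 411101L),
        primers = c(forward = "TATTTTGAGAGGTTGCTGTTTAG",
                    reverse = "CTAAAAAACCCCACAACCTATCCC"))
    rad51cSeq <- mkSeq(120L, 12L, 411102L)
    allCpg <- gregexpr("CG", rad51cSeq, fixed = TRUE)[[1L]] - 1L
    rad51c <- ampliconReference(
        "RAD51C", rad51cSeq,
        excludedSites = as.integer(allCpg[c(3L, 9L)]),
        primers = c(forward = "TGGTAATTGGTTAGTGTGTGT",
                    reverse = "TCCTCATCAAATATACACCCTAACT"))
    list(BRCA1 = brca1, RAD51C = rad51c)
}

#' Simulate droplet digital PCR wells
#'
#' The plasma-equivalent template is split equally over the wells; with
#' per-droplet occupancy \eqn{\lambda} (copies per well over droplets per
#' well) each accepted droplet is positive with probability
#' \eqn{1 - e^{-\lambda}}, so positive counts are binomial draws.
#'
#' @param copiesPerMl true template concentration.
#' @param plasmaMl plasma millilitre equivalents across all wells
#'   (default 2, the trial layout).
#' @param nWells wells the sample is divided into (default 2).
#' @param dropletsPerWell accepted droplets per well (default 15000).
#' @param dropletVolumeNl droplet volume annotation (default 0.85 nl).
#' @param seed optional seed (otherwise the caller's RNG stream is used).
#' @return data.frame with columns \code{well}, \code{positive},
#'   \code{total}, \code{droplet_volume_nl}.
#' @export
simulateDdpcrWells <- function(copiesPerMl, plasmaMl = 2, nWells = 2L,
                               dropletsPerWell = 15000L,
                               dropletVolumeNl = 0.85, seed = NULL) {
    if (copiesPerMl < 0) stop("copiesPerMl must be nonnegative")
    if (dropletsPerWell <= 0 || nWells < 1) stop("invalid well layout")
    sim <- function() {
        lambda <- copiesPerMl * plasmaMl / nWells / dropletsPerWell
        p <- -expm1(-lambda)
        data.frame(well = seq_len(nWells),
                   positive = rbinom(nWells, dropletsPerWell, p),
                   total = as.integer(dropletsPerWell),
                   droplet_volume_nl = dropletVolumeNl)
    }
    if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

#' Simulate merged bisulfite amplicon reads
#'
#' A \code{methylFraction} share of reads derives from the fully
#' methylated template (CpG cytosines retained, all other cytosines
#' converted to T) and the remainder from the fully converted template
#' (every cytosine to T). Incomplete conversion is modelled by reverting
#' each converted T back to C with \code{conversionErrorRate}, and
#' sequencing error as an independent per-base substitution to a uniform
#' different base (no indels: reads are short, merged amplicon reads).
#'
#' @param amplicon an \linkS4class{AmpliconReference}.
#' @param methylFraction fraction of molecules methylated.
#' @param nReads reads to simulate.
#' @param conversionErrorRate,seqErrorRate per-base error rates.
#' @param seed optional seed.
#' @return a \code{DNAStringSet} of \code{nReads} reads.
#' @export
simulateBisulfiteReads <- function(amplicon, methylFraction, nReads,
                                   conversionErrorRate = 0,
                                   seqErrorRate = 0, seed = NULL) {
    if (methylFraction < 0 || methylFraction > 1)
        stop("methylFraction must lie in [0, 1]")
    if (nReads < 1) stop("nReads must be positive")
    sim <- function() {
        refChars <- strsplit(as.character(amplicon@sequence), "")[[1L]]
        L <- length(refChars)
        methT <- strsplit(bisulfiteTemplate(amplicon, TRUE), "")[[1L]]
        convT <- strsplit(bisulfiteTemplate(amplicon, FALSE), "")[[1L]]
        isMeth <- runif(nReads) < methylFraction
        reads <- matrix(rep(convT, nReads), nrow = nReads, byrow = TRUE)
        if (any(isMeth))
            reads[isMeth, ] <- matrix(rep(methT, sum(isMeth)),
                                      nrow = sum(isMeth), byrow = TRUE)
        if (conversionErrorRate > 0) {
            wasConverted <- t(matrix(refChars == "C", L, nReads))
            wasConverted <- wasConverted & reads == "T"
            revert <- wasConverted &
                matrix(runif(nReads * L) < conversionErrorRate, nReads)
            reads[revert] <- "C"
        }
        if (seqErrorRate > 0) {
            err <- matrix(runif(nReads * L) < seqErrorRate, nReads)
            if (any(err)) {
                shift <- sample.int(3L, sum(err), replace = TRUE)
                bases <- c("A", "C", "G", "T")
                cur <- match(reads[err], bases)
                reads[err] <- bases[((cur - 1L + shift) %% 4L) + 1L]
            }
        }
        out <- Biostrings::DNAStringSet(apply(reads, 1L, paste, collapse = ""))
        names(out) <- paste0(amplicon@name, "_read", seq_len(nReads))
        out
    }
    if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

.truncNorm <- function(n, mean, sd, lo, hi) {
    pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

.simulateSegments <- function(lohTarget, chromLengths) {
    chroms <- sample(names(chromLengths))
    segs <- list()
    take <- function() {
        if (!length(chroms)) return(NA_character_)
        c1 <- chroms[1L]; chroms <<- chroms[-1L]; c1
    }
    addSeg <- function(chrom, size, major, minor, whole = FALSE) {
        len <- chromLengths[[chrom]]
        if (whole) {
            st <- 0; en <- len
        } else {
            size <- min(size, len * 0.8)
            st <- round(runif(1L, 0, len - size)); en <- st + size
        }
        segs[[length(segs) + 1L]] <<- data.frame(
            chrom = chrom, start = st, end = en,
            major_cn = major, minor_cn = minor)
    }
    nLoh <- min(lohTarget, 16L)
    for (i in seq_len(nLoh)) {
        ch <- take(); if (is.na(ch)) break
        addSeg(ch, runif(1L, 16e6, 40e6), sample(1:2, 1L), 0L)
    }
    for (i in seq_len(3L)) {           # sub-threshold LOH, never counted
        ch <- take(); if (is.na(ch)) break
        addSeg(ch, runif(1L, 4e6, 12e6), 1L, 0L)
    }
    for (i in seq_len(2L)) {           # balanced segments
        ch <- take(); if (is.na(ch)) break
        addSeg(ch, runif(1L, 10e6, 30e6), sample(1:3, 1L), 1L)
    }
    if (runif(1L) < 0.3) {             # whole-chromosome LOH, never counted
        ch <- take()
        if (!is.na(ch)) addSeg(ch, NA, 1L, 0L, whole = TRUE)
    }
    do.call(rbind, segs)
}

#' Generate a synthetic window-trial cohort
#'
#' Draws a latent HR-deficiency status per patient and, conditional on it,
#' a deficiency mechanism and all per-assay raw data: per-well droplet
#' counts at baseline and end of treatment for 1-3 tracked mutations,
#' merged bisulfite reads over both promoter amplicons, RAD51/geminin
#' field counts for two blinded scorers at both timepoints, Ki67 and
#' cleaved-PARP counts, mutation-channel counts drawn from the signature
#' catalog with Poisson noise, and allele-specific copy-number segments.
#' All randomness flows from the config's root seed through named
#' per-patient, per-assay substreams, so a fixed seed reproduces the
#' cohort exactly regardless of evaluation order.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return a \linkS4class{SyntheticCohort}.
#' @examples
#' cohort <- generateCohort(CohortConfig(nPatients = 4, methylReadCount = 50))
#' cohortTruth(cohort)[, c("patient_id", "hr_deficient", "mechanism")]
#' @export
generateCohort <- function(config) {
    validObject(config)
    n <- config@nPatients
    ids <- sprintf("P%03d", seq_len(n))
    catalog <- syntheticSignatureCatalog()
    amplicons <- defaultAmplicons()
    chromLengths <- grch37ChromLengths()
    mech <- config@prevalenceMechanisms
    mechNames <- c(names(mech), "none")
    mechProb <- c(mech, none = max(0, 1 - sum(mech)))

    truth <- .withSubstream(config@seed, 0L, 1L, {
        hrd <- runif(n) < config@prevalenceHrd
        mechanism <- ifelse(hrd,
                            sample(mechNames, n, replace = TRUE,
                                   prob = mechProb),
                            "none")
        data.frame(
            patient_id = ids,
            hr_deficient = hrd,
            mechanism = mechanism,
            germline_brca = mechanism == "brca_germline",
            germline_palb2 = mechanism == "palb2_germline",
            control = FALSE,
            true_cdr = ifelse(hrd,
                rbeta(n, config@cdrHrdBetaParams[1L], config@cdrHrdBetaParams[2L]),
                rbeta(n, config@cdrHrpBetaParams[1L], config@cdrHrpBetaParams[2L])),
            baseline_copies_per_ml = 10^rnorm(n, config@ctdnaBaselineLog10Mean,
                                              config@ctdnaBaselineLog10Sd),
            n_mutations = sample(1:3, n, replace = TRUE),
            true_methyl_brca1 = ifelse(mechanism == "brca1_methylation",
                                       rbeta(n, 8, 4), rbeta(n, 1, 80)),
            true_methyl_rad51c = ifelse(mechanism == "rad51c_methylation",
                                        rbeta(n, 8, 4), rbeta(n, 1, 80)),
            true_rad51_eot = ifelse(hrd,
                .truncNorm(n, config@rad51ScoreHrdMean, 3, 0.5, 99),
                .truncNorm(n, config@rad51ScoreHrpMean, 8, 0.5, 99)),
            ki67_responder_true = runif(n) < config@ki67ResponseRate,
            stringsAsFactors = FALSE)
    })
    truth$true_rad51_baseline <- .withSubstream(config@seed, 0L, 2L,
        truth$true_rad51_eot * runif(n, 0.2, 0.5))

    # -- ddPCR droplet counts ------------------------------------------
    ddpcr <- vector("list", n)
    for (i in seq_len(n)) {
        ddpcr[[i]] <- .withSubstream(config@seed, i, 10L, {
            nm <- truth$n_mutations[i]
            w <- runif(nm, 0.5, 1.5); w <- w / sum(w)
            blc <- truth$baseline_copies_per_ml[i] * w
            eotJitter <- rlnorm(nm, 0, 0.1)
            eotc <- blc * truth$true_cdr[i] * eotJitter
            rows <- list()
            for (m in seq_len(nm)) {
                for (tp in c("baseline", "eot")) {
                    cc <- if (tp == "baseline") blc[m] else eotc[m]
                    wells <- simulateDdpcrWells(cc)
                    rows[[length(rows) + 1L]] <- data.frame(
                        patient = ids[i],
                        mutation = sprintf("%s_mut%d", ids[i], m),
                        timepoint = tp, wells[, c("well", "positive", "total")],
                        plasma_ml = 2)
                }
            }
            do.call(rbind, rows)
        })
    }
    ddpcr <- do.call(rbind, ddpcr)

    # -- bisulfite reads ------------------------------------------------
    reads <- vector("list", n)
    names(reads) <- ids
    for (i in seq_len(n)) {
        reads[[i]] <- list(
            BRCA1 = simulateBisulfiteReads(
                amplicons$BRCA1, truth$true_methyl_brca1[i],
                config@methylReadCount, config@conversionErrorRate,
                config@seqErrorRate,
                seed = .substreamSeed(config@seed, i, 20L)),
            RAD51C = simulateBisulfiteReads(
                amplicons$RAD51C, truth$true_methyl_rad51c[i],
                config@methylReadCount, config@conversionErrorRate,
                config@seqErrorRate,
                seed = .substreamSeed(config@seed, i, 21L)))
    }

    # -- IHC -------------------------------------------------------------
    ihcFields <- vector("list", n)
    ki67 <- vector("list", n)
    cparp <- vector("list", n)
    for (i in seq_len(n)) {
        ihcFields[[i]] <- .withSubstream(config@seed, i, 30L, {
            rows <- list()
            for (tp in c("baseline", "eot")) {
                scoreTruth <- if (tp == "eot") truth$true_rad51_eot[i]
                              else truth$true_rad51_baseline[i]
                for (sc in c("scorer1", "scorer2")) {
                    pSc <- plogis(log(scoreTruth / (100 - scoreTruth)) +
                                  rnorm(1L, 0, 0.25))
                    tum <- rpois(5L, config@ihcFieldCellMean)
                    gmn <- rbinom(5L, tum, 0.2)
                    rad <- rbinom(5L, gmn, pSc)
                    rows[[length(rows) + 1L]] <- data.frame(
                        patient = ids[i], timepoint = tp, scorer = sc,
                        field = 1:5, tumour_cells = tum,
                        gmnn_positive = gmn, rad51_positive = rad)
                }
            }
            do.call(rbind, rows)
        })
        ki67[[i]] <- .withSubstream(config@seed, i, 31L, {
            basePct <- runif(1L, 30, 80)
            drop <- if (truth$ki67_responder_true[i]) runif(1L, 0.55, 0.9)
                    else runif(1L, -0.15, 0.40)
            eotPct <- min(max(basePct * (1 - drop), 0.5), 99)
            cells <- sample(200:400, 2L, replace = TRUE)
            pos <- rbinom(2L, cells, c(basePct, eotPct) / 100)
            data.frame(patient = ids[i], timepoint = c("baseline", "eot"),
                       cells_counted = cells, positive = pos,
                       percent = 100 * pos / cells)
        })
        cparp[[i]] <- .withSubstream(config@seed, i, 32L, {
            cells <- pmax(rpois(2L, 900), 1L)
            pos <- rbinom(2L, cells, c(0.005, 0.012))
            data.frame(patient = ids[i], timepoint = c("baseline", "eot"),
                       cells_counted = cells, positive = pos)
        })
    }
    ihcFields <- do.call(rbind, ihcFields)
    ki67 <- do.call(rbind, ki67)
    cparp <- do.call(rbind, cparp)

    # -- genomic features ------------------------------------------------
    subCounts <- matrix(0L, n, ncol(catalog$sub),
                        dimnames = list(ids, colnames(catalog$sub)))
    rearrCounts <- matrix(0L, n, ncol(catalog$rearr),
                          dimnames = list(ids, colnames(catalog$rearr)))
    delMh <- setNames(numeric(n), ids)
    segments <- vector("list", n)
    truth$true_sub_sig3 <- truth$true_rearr_sig3 <- truth$true_hrd_loh <- NA_real_
    for (i in seq_len(n)) {
        res <- .withSubstream(config@seed, i, 40L, {
            hrd <- truth$hr_deficient[i]
            eSub <- rgamma(12L, shape = 1.5, scale = 150)
            names(eSub) <- rownames(catalog$sub)
            eSub["sub_sig3"] <- if (hrd) 2000 * rlnorm(1L, 0, 0.3)
                                else 40 * rlnorm(1L, 0, 0.4)
            eSub["sub_sig8"] <- if (hrd) 500 * rlnorm(1L, 0, 0.3)
                                else 200 * rlnorm(1L, 0, 0.3)
            eRearr <- rgamma(6L, shape = 1.5, scale = 20)
            names(eRearr) <- rownames(catalog$rearr)
            eRearr["rearr_sig3"] <- if (hrd) 150 * rlnorm(1L, 0, 0.3)
                                    else 5 * rlnorm(1L, 0, 0.4)
            eRearr["rearr_sig5"] <- if (hrd) 100 * rlnorm(1L, 0, 0.3)
                                    else 30 * rlnorm(1L, 0, 0.3)
            dmh <- if (hrd) rbeta(1L, 10, 10) else rbeta(1L, 2, 38)
            lohN <- if (hrd) rpois(1L, 15) else rpois(1L, 2)
            segs <- .simulateSegments(lohN, chromLengths)
            list(sub = rpois(ncol(catalog$sub),
                             as.numeric(t(catalog$sub) %*% eSub)),
                 rearr = rpois(ncol(catalog$rearr),
                               as.numeric(t(catalog$rearr) %*% eRearr)),
                 dmh = dmh, segs = segs, eSub = eSub, eRearr = eRearr)
        })
        subCounts[i, ] <- res$sub
        rearrCounts[i, ] <- res$rearr
        delMh[i] <- res$dmh
        res$segs$patient <- ids[i]
        segments[[i]] <- res$segs
        truth$true_sub_sig3[i] <- res$eSub[["sub_sig3"]]
        truth$true_rearr_sig3[i] <- res$eRearr[["rearr_sig3"]]
        truth$true_hrd_loh[i] <- hrdLohIndex(res$segs, chromLengths)
    }
    segments <- do.call(rbind, segments)
    rownames(segments) <- NULL
    rownames(truth) <- NULL

    new("SyntheticCohort", config = config, truth = truth, ddpcr = ddpcr,
        reads = reads, ihcFields = ihcFields, ki67 = ki67, cparp = cparp,
        mutationCounts = list(sub = subCounts, rearr = rearrCounts),
        delMhProportion = delMh, segments = segments,
        amplicons = amplicons, catalog = catalog,
        chromLengths = chromLengths)
}
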