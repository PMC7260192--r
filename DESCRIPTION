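Package: hrdwindow
Title: Biomarker Pipeline for Homologous Recombination Deficiency Window Trials
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for short pre-surgical ("window of
    opportunity") trials of PARP inhibitors in triple negative breast
    cancer. Implements droplet digital PCR quantification of circulating
    tumour DNA and the day-15 circulating DNA ratio (CDR15) with its
    evaluability and suppression rules; per-read methylation calling from
    merged bisulfite amplicon reads over the BRCA1 and RAD51C promoters;
    RAD51/geminin, Ki67 and cleaved-PARP immunohistochemistry scoring with
    validity minima; an HRDetect-style weighted logistic score over
    mutational-signature features including non-negative least-squares
    exposure refitting and the HRD-LOH index; the trial's exact statistics
    (two-sided Fisher test, Clopper-Pearson intervals, Mann-Whitney and
    Wilcoxon tests) and an exact Simon two-stage design search; and a
    seeded synthetic-cohort generator in which a latent homologous
    recombination deficiency status drives every assay, so the whole
    pipeline is testable without access to patient-level trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    pracma,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: StatisticalMethod, Epigenetics, CopyNumberVariation, Software
RoxygenNote: 7.3.3
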