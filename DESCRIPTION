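Package: chronospec
Title: Circadian Rhythmicity and Tissue Specificity of Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline linking circadian rhythmicity to tissue
    specificity in multi-tissue time-course RNA-seq. Implements rank-based
    rhythm detection with an exact Jonckheere-Terpstra-Kendall null,
    cosinor amplitude and phase estimation, the Tau/SPM/EE
    tissue-specificity indices with a per-timepoint oscillation test,
    per-timepoint negative-binomial differential expression between
    tissues, the circadian-affected / constitutive / temporal partition of
    differentially expressed genes, two-sided Fisher exact gene-set
    enrichment, simplified weighted co-expression modules with cycling
    calls, and amplitude-change effect sizes under circadian disruption.
    Includes a negative-binomial simulator of multi-tissue circadian
    experiments with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), mclust, DESeq2, S4Vectors, fgsea, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
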