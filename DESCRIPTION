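Package: gamhap
Title: Haplotype-Resolved Genome Architecture Mapping Analysis
Version: 0.1.0
Authors@R:
    person("Jonas", "Kiefer", email = "jkiefer@example.org",
           role = c("aut", "cre"))
Description: Tools for haplotype-resolved analysis of Genome Architecture
    Mapping (GAM) data from hybrid cell lines. Calls positive genomic
    windows per nuclear profile with a sample-specific coverage threshold,
    phases windows to parental haplotypes via SNP-read coverage, and builds
    per-haplotype segregation tables. Downstream analyses include sample
    quality control and contamination screening, dataset resolution
    assessment, NPMI-normalized contact matrices, distance decay curves,
    per-distance z-scores, allele-specific and strong contact calling,
    insulation-score TAD border detection, A/B compartment eigenvector
    analysis, window detection frequency (compaction) tracks,
    allele-specific expression and peak classification, promoter state
    classification, circular permutation tests, and regulatory contact
    annotation. Includes a diploid nuclear-slicing simulator that provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
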