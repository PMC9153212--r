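Package: multiclone
Title: Multi-Region Tumor Clonal Evolution Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clonal deconvolution of multi-region deep-sequencing data from
    diffuse midline glioma and similar tumors. Estimates tumor purity from the
    clonality of a designated founder mutation, calibrates the cellular
    prevalence of allele-specific copy-number events from the allelic imbalance
    of germline heterozygous SNPs, computes cancer cell fractions of somatic
    mutations under enumerated mutation-multiplicity models, clusters mutations
    by their per-region cancer cell fraction profiles with a binomial mixture
    model, reconstructs clone phylogenies under the pigeonhole (sum) and
    crossing rules, decomposes each tumor region into clone fractions with
    founder-clone filling, and detects rare tumor subclones in histologically
    normal samples with a two-stage exact-binomial test under false discovery
    rate control. Ships a seedable synthetic-cohort generator that emulates
    multi-region autopsy studies so every stage is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
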