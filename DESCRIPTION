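Package: ffsig
Title: Fetal Fraction Signatures for Quality Control in Noninvasive
    Prenatal Diagnosis
Version: 0.1.0
Authors@R:
    person("ffsig", "developers", email = "ffsig@example.org",
           role = c("aut", "cre"))
Description: Tools to detect chromosomal situations that confound relative
    haplotype dosage (RHDO) analysis in noninvasive prenatal diagnosis of
    monogenic disease, using only the SNP allele counts already produced
    for RHDO.  Classifies panel SNPs into the five parental-genotype types,
    computes fetal-fraction estimates per type and subtype (the
    "fetal-fraction signature"), performs in-silico dilution with
    Type-4-versus-Type-1 regression, and flags trisomy, monosomy,
    uniparental disomy, dizygotic twins and mosaics from the signature.
    Includes an exact mixture-model oracle and a molecular-depth
    read-count simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    GenomicRanges,
    optparse,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
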