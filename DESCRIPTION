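Package: cstyper
Title: Genotyping of the Cs29 and Cs6 Colour-Sidedness Translocations in Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to genotype the bovine Cs29 and Cs6 structural (translocation)
    alleles associated with colour-sidedness and gonadal hypoplasia. Implements
    read-depth copy-number genotyping from windowed coverage tracks (10 kbp
    windows standardized by the genome-wide median, with an automated
    least-squares genotype caller), in-silico multiplex breakpoint PCR
    (primer-site scanning, amplicon prediction, and band-pattern decoding with
    dominant-marker semantics for Cs6), and cohort allele/genotype frequency
    estimation with exact Clopper-Pearson confidence intervals and an
    enumeration-based Fisher exact test. A synthetic-data module generates
    depth tracks, rearranged haplotype sequences, and Hardy-Weinberg
    population samples with known ground truth so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
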