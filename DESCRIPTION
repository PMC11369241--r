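Package: paramask
Title: Pseudogene-Masked Variant Calling with Long-Read Rescue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-enactment of a combined diagnostic strategy for
    genes shadowed by a high-identity pseudogene (the HYDIN/HYDIN2 geometry):
    hard-mask the pseudogene so all four homologous alleles collapse onto the
    gene, genotype small variants from the resulting skewed allele balances
    (0.25 heterozygous, 0.50 homozygous), detect exon copy-number changes on a
    four-copy depth grid that a diploid caller misses, and rescue the remaining
    cases with simulated long reads binned to gene versus pseudogene by
    paralogous sequence variants (PSVs): confirming homozygosity, phasing
    alleles, and recovering exon deletions from alignment gaps. Includes a
    synthetic gene/pseudogene simulator, a built-in seed-and-extend mapper,
    splice-consequence annotation, and cohort-level diagnostic accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
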