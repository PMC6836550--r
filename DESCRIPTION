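Package: cytowgs
Title: Whole-Genome Sequencing as a First-Line Cytogenomic Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for replacing chromosomal microarray analysis with
    short-read whole-genome sequencing in a clinical cytogenomics setting.
    Merges structural-variant calls from complementary callers, builds and
    queries structural-variant frequency databases, applies a size/quality/
    frequency filtering cascade with gene-panel rescue, exports calls as an
    array-CGH-style probe document, emulates consecutive-probe array calling
    and MLPA ratio interpretation, detects runs of homozygosity and
    uniparental disomy from SNV zygosity, genotypes short tandem repeats
    from short reads including expansions longer than the read length,
    estimates mosaic aneuploidy fractions from read-depth bins, and
    reconstructs derivative chromosomes from breakend graphs with
    breakpoint-junction microhomology, templated-insertion and formation
    mechanism analysis. Seeded simulators generate every input the toolkit
    consumes, with truth records, so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    S4Vectors,
    stats,
    utils,
    vcfR,
    xml2
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
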