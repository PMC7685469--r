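Package: radlink
Title: Detection of Fully Sex-Linked Markers and Recombination
    Suppression from Family RAD-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect a non-recombining, fully sex-linked region on a
    young (neo-)sex chromosome from RAD-seq genotypes of full-sib families.
    Implements presence/absence screens for Y-limited RADtags, a four-criterion
    segregation screen for fully sex-linked SNPs, windowed parental
    heterozygosity, estimation of the recombination-suppression boundary,
    per-parent crossover detection with Kosambi map distances, and
    interval profiling of MLH1 crossover foci.  A forward simulator of
    neo-XY meiosis and RAD genotyping in pedigrees makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
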