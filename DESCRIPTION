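Package: clonepop
Title: Microsatellite Population Genetics for Clonally Reproducing Insects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multiplexed microsatellite (SSR) population analysis of
    cyclically parthenogenetic insects such as aphids: perfect-SSR scanning of
    genome sequence, genotype table input/output and allele binning against an
    allelic ladder, replicate-based genotyping error rates (per allele, per
    locus, per multilocus profile), missing-data and minor-allele-frequency
    filtering, sex inference from X-linked hemizygosity, multilocus genotype
    (MLG) assignment and clone correction, clonal diversity indices (Shannon,
    Stoddart-Taylor, Simpson, evenness), the standardized index of association
    r-bar-D with permutation tests, Bruvo stepwise-mutation distances, binary
    Jaccard distances with principal coordinate analysis, and minimum spanning
    networks over MLGs. Includes a synthetic-population generator that emulates
    clonal lineage structure with ground-truth records, so every analysis stage
    runs and is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
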