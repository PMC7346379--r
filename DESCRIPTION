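Package: haplophase
Title: Long-Range Phasing and Haplotype Library Imputation for Large,
    Multi-Array SNP Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Heuristic haplotype phasing of diploid SNP genotypes by
    long-range phasing with surrogate parents and haplotype library
    imputation.  Scales to large datasets by random sub-setting of
    individuals with per-subset phasing and merging, and handles
    heterogeneous data from multiple overlapping SNP arrays via
    minimum-shared-marker surrogacy tests and a partial-haplotype
    library with conflict-aware merging.  Includes a forward
    breeding-population simulator (breed splits, truncation selection,
    multi-array genotype masking) with full truth retention, and
    phasing-accuracy statistics with per-breed and per-generation
    aggregation.  Genotypes are stored bit-packed and compared with
    population-count operations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
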