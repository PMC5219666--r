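Package: slafmap
Title: High-Density F2 Genetic Linkage Maps from SLAF-Seq Allele Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Construction of high-density genetic linkage maps for F2
    populations genotyped by reduced-representation sequencing (SLAF-seq).
    Covers the full analysis path: clustering of sequence tags into loci,
    minor-allele-frequency allele definition, segregation-pattern and
    SNP-type classification, Bayesian genotype calling from allele read
    counts with iterative quality pruning, marker-level depth/missingness
    filters and the 1:2:1 chi-square segregation test, two-point EM
    estimation of recombination fractions with LOD scores, LOD-threshold
    linkage grouping, simulated-annealing marker ordering that minimises
    the sum of adjacent recombination fractions, multipoint re-estimation
    of adjacent recombination fractions by a hidden Markov model,
    SMOOTH-style genotyping-error removal, k-nearest-neighbour genotype
    imputation, Kosambi map distances, insertion of segregation-distorted
    accessory markers by multipoint maximum likelihood, and detection of
    segregation distortion regions.  A synthetic-data generator simulates
    F2 meioses, gamete-viability segregation distortion and sequencing
    read counts, with ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
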