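Package: binGBS
Title: Binned Genotyping-by-Sequencing for F2 Intercross Linkage Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds high-confidence genotypes from low-coverage
    genotyping-by-sequencing (GBS) of large F2 intercrosses by pooling
    phased single-nucleotide polymorphism (SNP) allele counts into
    scaffold bins. Provides the full downstream pipeline: an allele-ratio
    and coverage sieve for segregating SNPs with rescue of genuinely
    distorted regions, binned genotype calling with uncertainty-aware
    composite calls, sex calling from sex-chromosome sequencing depth,
    linkage-map construction (two-point recombination fractions by EM,
    LOD grouping, marker seriation, Haldane/Kosambi distances, Marey
    profiles), draft-assembly revision (scaffold anchoring, orientation,
    rearrangement detection, consensus maps, read-count correlation
    placement, coordinate liftover, AGP export), per-individual
    recombination-breakpoint fine-mapping with a three-state hidden
    Markov model, and Haley-Knott QTL scans with permutation thresholds,
    variance explained, and conditioned scans. A synthetic-cross
    simulator with known truth (genotypes, breakpoints, sex, assembly
    scrambling, QTL effects) makes every stage testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
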