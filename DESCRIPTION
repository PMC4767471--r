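Package: hypokaryo
Title: Simulation and Inference for Hypodiploid Leukemia Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational genetics of hypodiploid acute
    lymphoblastic leukemia. Parses relative-to-haploid karyotype notation and
    classifies modal-number subgroups (near-haploid, low and high hypodiploid);
    simulates SNP-array profiles (B-allele frequency and log R ratio) for
    mixtures of aneuploid leukemic clones and normal cells, including doubled
    clones and cell-to-cell chromosomal instability; infers tumor purity,
    whole-chromosome allele-specific copy number, loss of heterozygosity,
    masked hypodiploidy, and chromosomal-instability flags; classifies variants
    on monosomic chromosomes as acquired or constitutional from mutant allele
    fractions via a purity-aware binomial model; classifies the clonal
    relationship of diagnosis/relapse pairs; and tests chromosome-level gene
    dosage effects with a permutation-based gene-set enrichment statistic and a
    copy-number-versus-methylation association test.
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
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
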