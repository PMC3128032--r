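Package: haplocnv
Title: Chromosome-Specific Copy Number Inference from CNV Background Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Infers the copy number of a copy number variant (CNV) on each of
    the two homologous chromosomes from phased SNP haplotypes flanking the
    variant together with per-individual total copy numbers.  Background
    haplotypes are clustered by solving a constrained Max-k-Cut problem with a
    randomized greedy algorithm (hard edges force the two haplotypes of an
    odd-total individual apart), distinct integer copy numbers are assigned to
    clusters by a solution-table heuristic for a unique-value Max-2-CSP, and a
    randomized adjustment pass re-places haplotypes of individuals whose sum
    constraint is still violated.  Includes brute-force oracles for both
    optimization problems, a synthetic-panel generator (Hardy-Weinberg
    diplotype sampling, linkage-disequilibrium decay by allele flipping,
    X-chromosome pairing, trio inheritance), and evaluation utilities
    (configuration accuracy, 1/1-to-0/2 miscall rate, trio Mendelian
    consistency, haploid and diploid copy-number distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
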