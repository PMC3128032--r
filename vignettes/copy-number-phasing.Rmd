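---
title: "Phasing CNV copy numbers onto chromosomes via background haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing CNV copy numbers onto chromosomes via background haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplocnv)
```

## The problem

Array and sequencing platforms measure the *total* copy number of a copy
number variant (CNV) in a diploid genome.  The split of that total across the
two homologous chromosomes — the *diplotype configuration* — is not observed:
a total of two may be one copy on each chromosome (1/1) or a deletion on one
and a duplication on the other (0/2), and the two configurations have very
different biological interpretations.  Because distinct copy-number alleles
tend to segregate on their own *background haplotypes* (flanking SNP alleles
in linkage disequilibrium, LD, with the copy allele), phased SNP haplotypes
around the CNV carry information about the split.  `haplocnv` recovers
chromosome-specific copy numbers from (a) phased biallelic SNP haplotypes and
(b) per-individual integer totals.

The central modelling assumption is therefore: *each chromosome-specific copy
number rides on a recognizable haplotype background*.  Recurrent CNVs (the
same event arising independently on several backgrounds) and
translocation-mediated CNVs violate the assumption; for them the flanking LD
is uninformative and no haplotype-based method can resolve the split.  The
`cnv_snp_r2()` diagnostic (mean squared correlation between each flanking SNP
and the focal copy allele) flags such loci.

## The procedure

For each CNV, the SNPs within a one-fold extension of the CNV
(`[start - L, end + L)` for a CNV of length `L`; `extension_factor = 1`) are
extracted.  Each haplotype occurrence becomes a vertex of a dense weighted
graph; edge weights are hamming distances between the haplotype strings, and
identical haplotypes from different individuals are distinct vertices at
distance zero.  The edge between the two haplotypes of an individual whose
total is odd is *hard*: an odd total forces two different chromosome-specific
copies, so those two haplotypes must not share a cluster.  All other edges
are *soft*.

**Clustering (constrained Max-k-Cut).**  Vertices are partitioned into `k`
clusters so that the total soft weight *across* clusters (the cut) is
maximal, with every hard edge on the cut.  Hard-edge weights are excluded
from the objective — they act purely as constraints, which is the literal
reading of the problem ("total weight of soft edges").  The solver is a
randomized greedy: pick `k` random distinct vertices as cluster seeds, then
place the remaining vertices in random order, each into the feasible cluster
with maximal cut gain.  The best of `restarts = 10` independent runs is
kept.  For `k > 2` this greedy is a `(k-2)/(k-1)`-approximation, a guarantee
the test suite checks empirically against a brute-force oracle.

**Value assignment (Unique Max-2-CSP).**  Each individual contributes one
constraint `X_a + X_b = Total(i)` over the cluster variables (`a = b` when
both haplotypes fell in one cluster); identical constraints collapse with
multiplicities.  The task is to assign *pairwise distinct* integers from
`D = {0..d}` to the clusters so that the satisfied multiplicity is maximal.
The heuristic seeds every variable with every value in `0..c_max`
(`c_max` = largest observed total), propagates through constraints with one
known endpoint using the majority target-sum, repeats each seeding with
`restarts = 10` random constraint orders, records the best round per seed in
a solution table, and finally unions table rows greedily in order of
satisfied count — later rows may never overwrite earlier values and
distinctness is enforced throughout.  Variables left without a value are
reported as `-1`.

**k sweep and adjustment.**  Both stages run for every `k` from 2 to
`max(totals) + 1` (capped at the vertex count); the `k` with the most
satisfied constraints wins, ties going to the smaller `k` (parsimony).
Individuals still violating their constraint are then *adjusted*: with the
cluster values frozen, both their haplotypes are re-placed into the valued
cluster pair that sums to the total and maximizes the cut, in random
individual order, best of 10 passes.  An individual whose total cannot be
formed from any pair of assigned cluster values is reported unresolved
(`-1/-1`) rather than silently dropped — real data contain loci the model
cannot fit.

## Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| `extension_factor` | 1.0 | flank width in CNV lengths; window `[start - fL, end + fL)`; 1.0 is where simulated accuracy peaks |
| `min_snps` | 10 | CNVs with fewer window SNPs are skipped — too few SNPs to carry LD information |
| `restarts` | 10 | randomized repetitions of every non-deterministic stage; few iterations suffice on top of the greedy framework |
| `seed` | none | master seed; every stage derives sub-seeds from it, so runs are byte-reproducible and restart counts are monotone |
| domain `d` | `max(c_max, k - 1)` | copies cannot exceed the largest observed total, but the distinctness requirement needs at least `k` values; values forced above `c_max` are flagged |

## Numerical and design choices

* **Coordinates** are BED-style 0-based half-open; VCF positions are
  converted on input.  Alleles are recoded per window so the major allele is
  0 — hamming distances are invariant to the coding.
* **Greedy tie-break.**  When several clusters give equal cut gain the vertex
  goes to the lowest cluster index.  A uniformly random tie-break was
  considered and rejected: all-zero gains arise systematically between
  identical haplotypes, and random ties scatter zero-distance vertices across
  clusters, breaking the intended behaviour that shared backgrounds
  co-cluster (an all-shared-haplotype panel must be called 1/1 throughout).
  Randomness still enters through the seed vertices and the placement order,
  and the approximation guarantee is tie-break independent.
* **Propagation conflicts.**  A propagated value outside `D`, or colliding
  with an already-used value, leaves the variable unassigned in that round;
  it is a conflict, not an error.  The ambiguous symbol in the propagation
  rule is read as "the current value of the known endpoint", subtracted from
  the majority target.
* **Row-union ties** (equal satisfied counts) prefer the row assigning more
  variables, then the lower row index — determinism for reproducibility.
* **Adjustment freezes values.**  The adjustment may move haplotypes between
  clusters but never revises the cluster-to-value map; revising both at once
  would re-open the CSP and lose the termination argument.
* **k starts at 2**: a single cluster cannot cut a hard edge and encodes only
  one allele.
* **Degenerate inputs**: empty windows signal `n_snps = 0` so callers can
  widen or skip; individuals with missing totals are excluded from that CNV
  only; a CNV whose totals are all missing is skipped with a reason.

## What the simulator emulates — and what it does not

`simulate_panel()` reproduces the evaluation designs the method is meant for:
diplotype configurations drawn to match Hardy–Weinberg counts *exactly*
(largest-remainder rounding; the achieved chi-square P is reported and equals
1 when the counts are feasible) or perturbed one allele at a time until the
P value first drops to a target (default 0.98); one maximally separated tag
haplotype per copy allele (pairwise hamming at least half the SNP count, so
LD decay is the only noise source); and LD decay by independent per-allele
flips with probability `ld_flip_fraction` — the achieved mean r² is reported
per data set rather than presuming a mapping from flip rate to r² bins.
`simulate_x_pairs()` builds diploid panels by randomly pairing haploid
X-chromosome calls (in males the measured X total *is* the
chromosome-specific copy).  `simulate_trios()` transmits one
(haplotype, copy) unit from each parent, so Mendelian consistency of
downstream calls should be exactly 1 at perfect LD.  Defaults are 16
individuals, a deletion allele at frequency 0.25 versus copy-1 at 0.75, and
20 SNPs — small panels in the spirit of the original evaluation.

What it does **not** emulate: coalescent haplotype diversity, recombination,
genotyping error in the totals, or realistic site-frequency spectra.  In
particular, "informative" haplotypes are exact tag copies and
"non-informative" replacements (in `simulate_oneone_panel()`) are uniform
random strings.  Real panels lie between these extremes: replacement
haplotypes drawn from a population pool partially coincide with informative
backgrounds.  Consequently the 1/1-to-0/2 miscall experiment shows a sharper
transition here than on real-data-derived panels: once the single
informative–noise constraint type outnumbers the informative–informative
type (replacement fractions above roughly one third), maximizing satisfied
constraints genuinely prefers the 0/2 value assignment — the brute-force CSP
oracle makes the same choice, so this is a property of the objective under
this noise model, not of the heuristic.  Passing simulation tests therefore
demonstrate correct mechanics and behaviour under idealized LD, not
performance on real cohorts.

## Problem sizes used by the test suite

The shipped tests run the oracle comparisons on 200 random graphs of 6–8
vertices (`k` in 3–4, integer weights 0–5) and 200+ random or planted
constraint sets (2–5 variables), the recovery experiments on 50 seeded
16-individual panels plus a five-point flip sweep, the miscall experiment on
50 replicates at 40% replacement, and trio consistency on three 10-trio
panels — sizes chosen so the whole suite completes in well under a minute
while keeping the Monte-Carlo error of the checked means small.

## Known limitations

* Recurrent and translocation-mediated CNVs violate the background-haplotype
  assumption; calls there should be treated as unreliable (screen with
  `cnv_snp_r2()`).
* Phasing is delegated upstream: the package consumes phased haplotypes and
  inherits any switch errors in them.
* SNPs physically inside a deleted (copy-0) segment are read as given in the
  phased input; their alleles on a deleted chromosome are a phasing artifact,
  which is accepted as-is and noted here as a caveat.
* The Mendelian consistency check compares copy values only (one value
  transmitted from each parent); it does not require the transmitted
  haplotype identity to match.
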