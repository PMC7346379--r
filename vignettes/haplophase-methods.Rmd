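---
title: "Long-range phasing and haplotype library imputation: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Long-range phasing and haplotype library imputation: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplophase)
```

## The problem

Given diploid SNP genotypes coded 0/1/2 (with missing values where an
individual's genotyping array does not cover a SNP), phasing assigns each
heterozygous allele to its paternal or maternal chromosome copy.  In
livestock populations, individuals have many close relatives, so long
stretches of chromosome are shared identical by descent; `haplophase`
exploits this with two cooperating heuristics that scale to very large
datasets and tolerate the block-wise missingness created by mixing
genotyping arrays.

## Long-range phasing (LRP)

The chromosome is cut into **cores** — consecutive SNP blocks phased
independently.  Within a core, a **surrogate parent** of individual $i$ is
another individual $j$ that plausibly shares one haplotype with $i$:
letting $s_{ij}$ be the number of markers genotyped in both and $o_{ij}$
the number of *opposing homozygotes* (one genotype 0, the other 2 — proof
that no haplotype is shared at that SNP, up to genotyping error), $j$ is a
surrogate of $i$ iff

$$ s_{ij} \ge m_\text{shared} \quad\text{and}\quad o_{ij} \le \lfloor
   d \cdot s_{ij} \rfloor , $$

with $m_\text{shared}$ (`min_shared_markers`) guarding against spurious
surrogacy when two arrays overlap on few markers, and $d$
(`surrogate_disagree_frac`, default 0.10) tolerating genotyping error.
Genotypes are stored as three bit planes (homozygous reference, homozygous
alternate, missing), so $o_{ij}$ and $s_{ij}$ are AND/OR population counts
over 32-SNP blocks; the block width is an internal constant that never
affects results.

Surrogates are split into paternal and maternal sides.  With a pedigree,
a surrogate is paternal when it is the sire or a surrogate of the sire
(and not of the dam); maternal symmetrically; ambiguous surrogates are
excluded from voting.  Without a pedigree — or when neither parent is
present in the individual's subset — the split is anchored arbitrarily:
the surrogate sharing most markers becomes the paternal anchor, its
surrogates join it, individuals with an opposing-homozygote conflict
against the anchor form the maternal side, and the rest stay unknown.
Which side is called "paternal" is then arbitrary but fixed, which is all
that phasing requires.

Each allele is set by **consensus of homozygous surrogates**, recursively:
a vote for individual $i$, side $s$, SNP $p$ travels along a chain $i - s_1
- \dots - s_d$ of consecutive surrogate pairs whose first link lies on
side $s$; intermediate links are heterozygous or missing at $p$ and the
terminal link is homozygous at $p$, contributing its allele as the vote.
At most `max_surrogates` (10) votes are used, shortest chains first, down
to depth `max_surrogate_depth` (10).  The allele is called when one allele
holds a strict plurality with vote share at least
`consensus_agreement_frac` (0.9); ties resolve to unphased.  The second
gamete is completed from the genotype, and output never contradicts the
genotype.

Within a chain depth, votes are consumed in *evidence-quality order* —
fewest opposing homozygotes first, then most shared markers.  This choice
matters: with error-free genotypes the 10% disagreement allowance is
generous relative to the opposing-homozygote rate of unrelated pairs
(roughly 5% of shared markers), so the surrogate relation contains many
weak edges; ranking guarantees that the handful of votes actually used
comes from the most reliable surrogates.  The disagreement rule itself
does not fix the within-depth order; this ranking is the package's own
choice.

## Sub-setting for scale

The surrogate search is quadratic in the number of individuals.  For large
datasets, individuals are partitioned at random into subsets of
`subset_size` (each individual in exactly one subset; no relatedness-aware
clustering), LRP runs within each subset, and the per-individual results
are merged.  A final remainder smaller than half a subset is folded into
the previous subset.  Subset members are processed in input order, so a
subset holding everyone reproduces the whole-set run bit for bit.
Accuracy increases with subset size (more surrogates) at quadratic cost in
time; a few thousand individuals per subset is a good compromise.

## Haplotype library imputation (HLI)

Each core keeps a **library** of distinct haplotypes, possibly partial:
an allele sequence with missing values, a frequency count, and the set of
(individual, gamete) carriers.  A partial haplotype **matches** an entry
when they are both observed at `min_match_alleles` positions or more
(default 200) with at most `library_cluster_mismatches` disagreements
(default 0).  The co-observation floor is what makes partial haplotypes
from different arrays safe to identify with one another.

A candidate haplotype is admitted to the library only when at least
`min_phased_frac_library` (80%) of the **carrier's genotyped core SNPs**
are phased.  Using the carrier's genotyped SNPs — not all core SNPs — as
the denominator is deliberate: an individual on a medium-density array can
never phase high-density-only SNPs by LRP, and the partial-haplotype
library exists precisely to admit such haplotypes.  On admission the
candidate is matched against the library: no match inserts it; matches
that are pairwise compatible are merged with it (alleles union, counts
summed, carriers union — this is how haplotypes observed on complementary
SNP subsets collapse into one, possibly bridged by a third haplotype that
overlaps both); matches that conflict with each other cannot be one
haplotype, so the candidate is inserted alongside them untouched.

HLI iterates to a fixed point.  Each pass makes one *fill sweep* over all
individuals and gametes in input order against the library as of the start
of the pass — unphased positions are filled where all matching entries
unanimously agree and the fill is consistent with the genotype and the
opposite gamete, then the opposite gamete is completed from the genotype —
followed by one *submission sweep* offering newly extended haplotypes to
the library, and a clustering step that merges near-identical entries.
Deferring submissions to the end of a sweep (rather than interleaving them
position by position) vectorises the expensive matching without changing
the fixed point: a fill missed in one pass happens in the next, the
phased-allele count is non-decreasing, and the loop terminates.  The
library can be saved and reloaded to seed phasing of new data.

## Per-core runs

Cores are independent, so they can be phased in separate processes and
stitched back together; the result is identical to a single run with the
same seed because subset assignment depends only on the seed and the
individual list, never on which cores are processed.

## The synthetic-data generator

`simulate_population()` emulates the structure of the reference test
datasets: a neutral forward Wright–Fisher history with recombination and
mutation runs through a breed-split tree (one ancestral breed, an older
split, a recent split), sites with base-generation minor allele frequency
below `maf_min` (0.05) are discarded, `n_snps` SNPs and `n_qtn`
standard-normal QTN are drawn, and each breed then undergoes
`n_generations_selection` rounds of truncation selection on a phenotype
with heritability `heritability` (default 0.3; the reference leaves it
unstated), mating the top `n_sires` males to the top `n_dams` females at
random with replacement.  Meiosis is a Poisson crossover process with no
interference on a `chrom_length`-Morgan chromosome.

Defaults describe the full-scale scenario (three breeds splitting to ten,
400 and 50 generations ago; 25 sires, 500 dams, 1000 offspring per breed
and generation; 8771 SNPs; 10,000 QTN).  The Wright–Fisher founder stage
is a scaled stand-in for a coalescent simulation: founder haplotypes start
from Beta(0.5, 0.5)-distributed site frequencies and `founder_pop_size`
defaults to 1050 so that a breed can supply 25 sires and 500 dams.  The
generator retains complete truth (haplotypes, pedigree, breed and
generation labels, phenotypes, selection log).

What the generator does *not* emulate: genotyping error (genotypes are
error-free, as in the reference simulations), real-array LD and MAF
spectra, multiple chromosomes, or the exact divergence magnitudes of the
reference coalescent (effective sizes and mutation model are not printed
there; divergence is matched qualitatively — older splits diverge more
than recent ones).  A green accuracy test therefore establishes that the
algorithms recover simulated descent structure, not that they reproduce
accuracy numbers on real bovine arrays.

Array presets mirror the reference genotyping scenarios: a single array
covering everything; two equal medium-density arrays with ~60% pairwise
overlap assigned 1:1; three arrays with ~50–65% pairwise overlap assigned
1:1:1; and a medium-density array nested in a high-density array assigned
9:1, with the MD array sized by the 6711/49,579 bovine MD:HD ratio.  True
pairwise overlap tables of commercial arrays are external to this package,
so overlap fractions are free parameters.

## Parameter defaults and desk-scale calibration

| parameter | default | meaning |
|---|---|---|
| `core_length` | 500 SNPs | core size; ~10% of the chromosome is a good rule |
| `subset_size` | 5000 | individuals per LRP subset |
| `max_surrogates` | 10 | votes per allele |
| `surrogate_disagree_frac` | 0.10 | opposing-homozygote allowance |
| `min_shared_markers` | 100 | shared-marker floor before surrogacy is tested |
| `min_phased_frac_library` | 0.80 | phased fraction for library admission |
| `min_match_alleles` | 200 | co-observed alleles for haplotype identity |
| `library_cluster_mismatches` | 0 | mismatch allowance when clustering |
| `max_surrogate_depth` | 10 | chain depth limit |
| `consensus_agreement_frac` | 0.9 | plurality share needed to call an allele |

`min_shared_markers` has no stated reference value; 100 (one fifth of the
default core) keeps cross-array surrogacy testable in every preset while
rejecting pairs with almost no overlap.  `consensus_agreement_frac` 0.9
and depth 10 are conservative choices mirroring the error-tolerance
framing of the method.  At desk scale the tests shrink cores and keep the
two ratios fixed: the shared floor at 0.2× core length and the match floor
at 0.4× core length (the 200-allele default is 0.4× the 500-SNP default
core).

## Numerical and degenerate-input choices

* Missing genotypes are `NA` internally and 9 on disk; haplotype alleles
  use `NA`/9 the same way.  SNP coordinates are 0-based half-open in core
  arithmetic; R matrices are indexed 1-based at the API surface.
* A terminal core remainder shorter than half a core is absorbed into the
  final core; a subset remainder smaller than half a subset folds into the
  previous subset.
* Conflicts between a haplotype and a homozygous genotype blank the
  position to missing by default (tolerance to genotyping error); an
  `on_conflict = "error"` mode aborts instead.
* Contradictory votes at a heterozygous SNP (both gametes voted the same
  allele) blank both gametes at that SNP.
* Individuals with zero surrogates receive genotype-forced phase only.
* Library entry order carries no meaning; merges may reorder entries.
* The library file format is this package's own (versioned header line
  `#haplophase-library v1`); carrier sets are not persisted, so a loaded
  library seeds matching but not carrier bookkeeping.
* All randomness (subset draws, the simulator, array sampling) flows from
  explicit integer seeds; runs are bit-reproducible, including under
  per-core split execution.

## Known limitations

* Chains treat any surrogate-of-surrogate as a potential vote carrier;
  when a deeper surrogate shares the *other* haplotype of an intermediate,
  its vote is noise.  The consensus threshold suppresses most of it, but
  single-vote calls at depth > 1 are the dominant source of incorrect
  phasing in dense-pedigree simulations.
* Surrogacy is tested within the core only (no tails beyond the core
  boundary), so very short cores discriminate surrogates weakly.
* No probabilistic model: no phase probabilities, no recombination-point
  inference, no X-chromosome/haploid support, no dosage input.
* Evaluation offers per-core best-of-two gamete orientation only; no
  switch-error metric is reported.
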