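---
title: "Genome fingerprints: model, parameters and design notes"
author: "genofp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome fingerprints: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genofp)
```

## The model

A personal genome, in whatever format it arrives, is a position-sorted
list of variants relative to a reference. `genofp` summarizes it by a
deterministic locality-sensitive hash built from **pairs of consecutive
biallelic SNVs** on the same chromosome. Each pair contributes one count
to a 144 × *L* table:

* **row** — the SNV pair key: the four-letter concatenation of ref and
  alt alleles of both SNVs (`snvKey("G","A")` is `"GA"`; two consecutive
  SNVs `GA` and `TC` give pair key `GATC`). There are 12 single-SNV keys
  and 144 pair keys, held in a fixed lexicographic order
  (`pairKeys()`) so that matrices and their row-major serializations are
  comparable across implementations.
* **column** — the inter-SNV distance *d* folded as *d* mod *L*.

Because only allele pairs and *local* spacing are used, the encoding is
insensitive to the absolute coordinate system: remapping a genome to a
different reference version shifts positions nearly uniformly and leaves
almost all consecutive pairs, and hence the fingerprint, intact. Indels
and other non-SNV variants are ignored entirely (they are represented too
inconsistently across pipelines to help), and two SNVs separated only by
such variants still count as consecutive. Zygosity is ignored: a site
enters the stream when at least one alternate allele was observed.
Only autosomes are used — shared X variants would, for instance, make a
daughter look closer to her mother than to her father.

Very short distances carry technology signatures rather than genome
information (vendor pipelines encode multi-nucleotide variants as runs of
adjacent SNVs), so pairs with *d* < *C* are diverted to a separate
144 × *C* "close" matrix that is stored with the raw fingerprint but
excluded from comparison.

Raw fingerprints are additive: fingerprints of disjoint genome parts
(per-chromosome files, say) sum to the whole-genome fingerprint
(`mergeFingerprints()`), which is exactly how multi-sample per-chromosome
cohort releases are processed.

### Normalization

Raw counts carry strong systematic structure: transitions outnumber
transversions, and the distance columns have unequal mass. Normalization
is a two-pass z-scoring (`normalize()`): first each of the *L* distance
columns is centered and scaled over its 144 rows, then each of the 144
key rows is centered and scaled over its *L* columns. The order matters —
row-first normalization leaves column structure in place, because the
distance effects are shared across rows and survive row-wise scaling;
column-first removes the shared distance profile so the subsequent
row pass can equalize the key-specific scales.

### Comparison

Fingerprints are compared by the Spearman correlation of their row-major
serialized matrices (ties receive average ranks). Rank correlation is
deliberate: it is invariant to any monotone distortion of the normalized
values, which buys robustness across *L* values, pipelines and
technologies. Identical genomes give exactly 1; as a documented default,
scores above 0.75 are treated as "same genome, different representation",
and lower values grade through close relatives down to the
shared-population baseline. The threshold is configuration, not a
constant of the method; family data can recalibrate it for other
parameter choices.

The minimal **binary fingerprint** derives from an *L* = 2 raw
fingerprint: bit *k* is 1 when the pair key's distances are more often
odd than even. Binary fingerprints are compared by the squared fraction
of matching bits, and are never normalized.

### Population machinery

A population fingerprint is the element-wise mean of its members'
normalized fingerprints (`buildPopulation()`); subtracting it from a
member (`adjustToPopulation()`) removes everything the population shares,
leaving a residual in which unrelated individuals decorrelate while
relatives remain strongly correlated. Classification
(`classifyPopulation()`) assigns a genome to the candidate population
fingerprint with the highest correlation; leave-one-out evaluation
recomputes the mean without the query as (n·mean − x)/(n − 1), exactly,
from the stored member list. Relatedness screening
(`findRelatedOutliers()`) converts within-population adjusted-pair
correlations to robust z-scores, 0.6745·(score − median)/MAD, takes
one-sided normal upper-tail p-values and applies Benjamini–Hochberg
control.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| *L* | 20 | distance columns | Fingerprint size/resolution. 20 suffices for identity and relatedness; 120–200 retains more signal for population-structure work at higher cost. Minimum is 2, the parity table underlying the binary fingerprint. |
| *C* | 20 | bp | Close cutoff. Values of at least 5 are advisable to keep technology artifacts out of the comparable matrix; fingerprints are only comparable at equal *L* (and populations additionally require equal *C*). |
| identity threshold | 0.75 | correlation | Working boundary between "same genome" and "different individuals" for *L* = 20 fingerprints. |
| FDR | 0.05 | — | Benjamini–Hochberg level for related-pair flagging; applied globally over the supplied pair universe by default (a per-population run is just a filtered input). |

## Numerical conventions

These choices are underdetermined by the method's description; they are
pinned here and recorded in the fingerprint file header so that files
from different implementations can be checked for compatibility.

* **Distance** is the number of *intervening* reference bases,
  d = pos₂ − pos₁ − 1. Adjacent SNVs have d = 0, a legal distance; the
  close-matrix column for distance d is indexed from d = 0. Any fixed
  offset convention would work — comparability only requires that all
  fingerprints use the same one — hence it is written into the format
  (`##distance=intervening-bases`).
* **Standard deviations** use the population form (divide by n), in both
  normalization passes (`##sd=population`).
* **Degenerate rows/columns** (zero spread — empty genomes, unused keys)
  are centered and set to zero rather than divided by zero, so tiny and
  empty inputs stay well-defined; an all-zero serialized vector compares
  as 0 with a warning rather than NaN, keeping cohort score tables
  total.
* **Binary tie-break**: equal odd/even tallies give bit 0, so empty rows
  are deterministic.
* **Duplicate positions** (two records at one locus that both pass
  filtering): the first record wins, the rest are dropped and counted in
  the reader's statistics — a zero-length pair with itself carries no
  information.
* **Multi-allelic exclusion** is decided on the record's ALT field, not
  the selected sample's alleles, so a site is treated identically in
  single- and multi-sample files of the same data. A site multi-allelic
  across a cohort but biallelic within one sample is therefore excluded
  for that sample; shared-cohort VCFs consequently differ slightly from
  their single-sample versions, which comparison tolerates by
  construction.
* **FILTER** is ignored by default (an opt-in restricts to PASS);
  unsorted input is an error, never silently re-sorted.
* Ranking ties (equal correlations in `bestMatches()` or
  `classifyPopulation()`) resolve by identifier.

## The synthetic-data generator

Real personal genomes cannot ship with a package, so `genofp` includes a
generative model (`cohortModel()`) rich enough that every claimed
behavior of the pipeline is exercisable end to end — through the public
VCF/TSV readers if desired.

The pool is a sequential walk per chromosome: SNV keys are drawn with a
2:1 transition:transversion bias (the dominant mutational asymmetry);
the gap to the next locus is g = L·G + r + 1 with G geometric (expected
gap 1000 bp) and r a draw over 0..L−1 that places weight 0.5 on a column
determined by the flanking key pair (the pair-key row index mod L) and
spreads the rest uniformly. This plants genuine key-pair-dependent
(d mod L) structure — the feature real fingerprints live on; with purely
uniform spacing, normalized fingerprints would be pure sampling noise
and nothing downstream could be demonstrated. Allele frequencies are
0.01 + 0.98·Beta(1, 3): skewed toward rare variants in the spirit of
real site-frequency spectra, while keeping a 200,000-locus genome around
80,000 carried variants so that desk-scale runs take seconds. Populations
perturb locus frequencies on the logit scale with SD = `divergence`;
individuals draw Hardy–Weinberg genotypes; pedigrees recombine parental
haplotypes with Poisson(1) crossovers per chromosome on a uniform
genetic map. The two degradation modes are i.i.d. variant dropout
(false negatives) and insertion of one uniformly placed, uniformly keyed
spurious SNV per consecutive pair with a given probability (false
positives). Everything is bit-reproducible given (model, spec, seed).

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: linkage disequilibrium, mutation-rate
heterogeneity and hotspots, realistic allele-frequency spectra at the
rare end, reference errors, and any correlation between allele frequency
and spacing. Robustness levels measured on synthetic genomes are
therefore read as *bounds achieved under these conditions*, not as
predictions for a particular sequencing platform.

One consequence deserves emphasis: because the spacing model concentrates
each pair key's (d mod L) mass on a *single* column, the parity of that
column fixes the corresponding binary-fingerprint bit with a wide margin,
so the 144-bit barcode is anomalously stable under degradation in this
simulator — more stable than the L = 20 fingerprint, which is the
opposite of its behavior on real genomes, where broad spacing
distributions leave the odd/even balance delicate. The test suite states
the real-data expectation (binary no more robust than L = 20) and that
assertion is expected to fail under the simulator; it is kept, rather
than weakened, as an honest marker of this generator limitation.

## Problem sizes and determinism

The package's own evaluations run at desk scale, chosen so the full
suite completes in minutes on one CPU while keeping every statistic
well-resolved: the pinned robustness genome uses 22 chromosomes and
200,000 pool loci (≈80,000 variants); pedigree and population
experiments use 4 chromosomes and 20,000 loci per genome, 5 replicate
seeds for pedigree orderings, 30-member cohorts (≥ 100 unrelated pairs)
for adjustment and planted-relative screening, and cohort-scale pair
enumeration is exercised on 2,504 fingerprint stubs. All simulations are
seeded; the acceptance script derives its degradation seeds from its
`--seed` argument while the pinned pool itself is fixed (seed 42), since
the pool *is* the study condition.

## Known limitations

* VCF parsing sits on `vcfR` and loads each file into memory; a
  streaming parser would be needed for very large multi-sample VCFs.
* The close matrix is stored but not yet used analytically (it is meant
  for technology identification).
* Zygosity-weighted fingerprint variants and exome-restricted
  fingerprints are out of scope.
* No kinship coefficients or likelihood-based relationship calls are
  computed; `findRelatedOutliers()` flags pairs, it does not name the
  relationship.
* Sex chromosomes are excluded by design, not configurable omission:
  including them distorts relatedness.
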