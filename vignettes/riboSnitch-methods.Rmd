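---
title: "Detecting riboSNitches: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting riboSNitches: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboSnitch)
```

## The problem

Untranslated regions of mRNAs do not fold into one structure; they
populate a Boltzmann ensemble of alternative secondary structures, and
regulation often depends on how that ensemble is balanced. A single
nucleotide substitution can act as a molecular switch — a *riboSNitch* —
repartitioning the ensemble and, with it, the accessibility of
regulatory elements. This package quantifies that effect: it scores how
much a given substitution perturbs the ensemble, assigns the score a
significance by exhaustive comparison with every other possible
substitution of the same RNA, and characterises the *nature* of the
shift by sampling structures and clustering them in a low-dimensional
projection.

## The ensemble model

For a sequence of length $n$ the admissible states are all nested
(pseudoknot-free) secondary structures: sets of base pairs $(i,j)$ over
the allowed alphabet of pairs (AU, UA, GC, CG, GU, UG) with at least
$h = 3$ unpaired bases in every hairpin loop. Each structure $S$ has an
energy $E(S)$ and Boltzmann weight $e^{-E(S)/RT}$; the partition value
is

$$Z = \sum_S e^{-E(S)/RT}, \qquad
  P(i,j) = \sum_{S \ni (i,j)} \frac{e^{-E(S)/RT}}{Z},$$

with the convention $E(\text{open chain}) = 0$, so $Z \ge 1$. $P(i,j)$
is computed exactly by inside–outside dynamic programming (McCaskill's
decomposition into hairpin, interior-loop and multibranch
contributions), in $O(n^3)$ time for the inside pass. The per-nucleotide
*accessibility vector* is the column sum
$s_k = \sum_i P(i,k)$ — the probability that residue $k$ is paired.

### The energy model

The energy function is a deliberately simplified nearest-neighbour
model, fully specified by a versioned key–value parameter file bundled
with the package (`system.file("extdata", "energy_params.txt",
package = "riboSnitch")`):

* **stacking energies** per adjacent pair step (6×6 table obeying the
  strand-reversal symmetry $E(XY/WZ) = E(ZW/YX)$), in kcal/mol;
* **loop penalties** for hairpin, bulge and interior loops, tabulated by
  loop length and extrapolated beyond the tables as
  $E(L_{\max}) + 1.75\,RT\ln(l/L_{\max})$ (Jacobson–Stockmayer form);
* a **linear multiloop model** $a + b\cdot(\text{branches}) +
  c\cdot(\text{unpaired})$ with $a = 3.4$, $b = 0.4$, $c = 0$ kcal/mol;
* $T = 310.15$ K, $R = 0.0019872$ kcal/(mol·K).

The values are of the magnitude familiar from the classic
nearest-neighbour literature but the set is this package's own: there
are no terminal-mismatch, dangling-end or helix-end terms, and interior
and bulge loops carry purely length-dependent penalties capped at 30
unpaired bases. The motivation is verifiability: with a compact,
fully-stated model, every quantity the dynamic program produces can be
checked against exhaustive enumeration (below). The scoring method
itself is engine-agnostic — any backend producing a base-pair
probability matrix can be substituted via `registerExternalEngine()`
(an adapter for ViennaRNA's `RNAfold`, `viennaRnaEngine()`, ships with
the package), which is the route to reproducing absolute correlation
values computed with full Turner parameters.

### Validation by enumeration

`enumerateStructures()` generates every admissible structure by a
brute-force recursion that never touches the DP code, scores each by
explicit loop decomposition, and is feasible up to a cap of 20 nt. The
suite checks, over hundreds of seeded random sequences, that the DP
matrix agrees with enumeration to $10^{-9}$, that the MFE structure
attains the enumerated energy minimum, and that 20 000 stochastic
traceback draws sit within total-variation distance 0.02 of the exact
Boltzmann distribution. Two behaviours are worth noting:

* **MFE ties** are broken by a deterministic traceback precedence
  (hairpin, then interior loops by ascending inner pair, then multiloop
  splits in ascending order), so repeated runs return the same
  structure; the tests assert membership in the enumerated argmin set
  rather than a particular tie choice.
* **Degenerate correlations**: if both accessibility vectors are
  constant and equal (tolerance $10^{-12}$) the Pearson coefficient is
  defined as 1; if constant but unequal, or only one constant, it is 0
  with a warning. This keeps every mutation rankable.

Long sequences are handled without rescaling by carrying the partition
arrays in extended precision; `mutationScan()` warns beyond 1000 nt,
where the all-mutations protocol is impractical anyway.

## Scoring a SNP

For a variant $m$ of sequence $x$, the score is the Pearson correlation
$r$ between the wild-type and mutant accessibility vectors (the column
sums of the two probability matrices — the operational definition; the
full matrices are available for plotting). Because the distribution of
$r$ depends strongly on sequence and length, significance is empirical:
all $3n$ possible substitutions are scored, the variant is ranked from
the bottom (ties counted conservatively, self included), and

$$p = \frac{\mathrm{rank}}{3n}.$$

A rank of 6 among 150 gives $p = 0.04$; 21 among 1599 gives
$p \approx 0.013$. The wild-type partition function is computed once
per scan and reused; identical seeds give byte-identical output tables.

## Characterising the shift

To see *what* the ensemble rearrangement looks like,
`sampleStructures()` draws structures i.i.d. from the Boltzmann
distribution by stochastic traceback (5000 per sequence by default,
mirroring the scale of published ensemble analyses). Each structure is
encoded as a length-$n$ 0/1 vector of paired positions. A *shared*
principal-component basis is built from a pooled seeded subsample (1000
per sequence by default), mean-centred, without variance scaling — the
bits are already on a common scale. Both components carry a
deterministic sign convention (largest-magnitude loading positive) so
bases are reproducible. All compared sequences are projected onto this
one basis; occupancies are then read off with seeded k-means (50
restarts) on the pooled projections, a reproducible surrogate for
calling clusters by eye on the scatterplot. The default $k = 3$ mirrors
the three-cluster structure of published ensemble maps; for designed
two-state constructs $k = 2$ is the natural choice. Cluster labels are
stabilised by relabelling in decreasing order of pooled size, and the
structure nearest each centroid is reported as the cluster
representative. With all seeds fixed, the whole chain — sampling,
basis, projection, occupancy — is bit-reproducible, and permuting the
order of the input sequences changes only row labels.

For sets of variants of one RNA, `meanAbsDeltaAccessibility()` averages
$|s_k(\text{mutant}) - s_k(\text{WT})|$ across the set; its peaks
localise the structural element the variants collectively perturb.

## What the fixtures emulate — and what they do not

The synthetic fixtures stand in for real UTRs:

* `randomRnaSequence(n, gc, seed)` — i.i.d. residues at a target GC
  content (default 0.5), the package's model of "a generic RNA";
* `designHairpin(stem, loop)` — a GC stem with an A loop whose unique
  MFE structure is the full stem, used for exact sampler calibration;
* `designSwitch(seed)` — a ≤20-nt two-helix construct (helices share a
  strand, hence are mutually exclusive) certified by the enumeration
  oracle at build time: the wild type holds helix A fully formed with
  probability > 0.8, a designated toggling mutation breaks a helix-A
  pair and ranks in the lowest tenth of the full scan, and a designated
  neutral tail mutation scores $r > 0.99$. It is the package's model
  organism for switch behaviour.

Uniform random sequences are *not* faithful models of real UTRs, and
one empirical property illustrates the gap. On real UTRs the
literature reports that the overwhelming majority of possible
mutations barely move the ensemble ($r > 0.9$), which is what makes
the rank p-value sharp. On seeded random 100-nt sequences, this
package's model puts that fraction near 0.55–0.60 — and ViennaRNA's
full Turner engine, run through the bundled adapter on the same
sequences, behaves the same way (≈0.43 on a spot check). Random
sequences are structurally more ambivalent than evolved UTRs, so
many substitutions find alternative folds to stabilise. The suite
asserts the literature-level threshold anyway and the corresponding
check is expected to fail under these study conditions; the measured
fraction is reported by the acceptance script. The *direction*
claims are robust and do hold here: the ensemble view is consistently
less mutation-sensitive than the single-structure MFE view (median
partition-based correlation above the median MFE-based correlation),
and designed switches are recovered with large, significant occupancy
shifts.

## Numerical and design choices

* Indexing is 1-based everywhere a user sees a position ("C33G"); DNA
  input and T alleles are accepted and normalised to U.
* Probabilities below $10^{-16}$ are dropped during the outside pass;
  accumulated error stays far below the $10^{-9}$ validation tolerance.
* Problem sizes in the shipped tests and acceptance script — 200
  oracle-checked sequences at ≤14 nt, 20 scanned sequences at 100 nt,
  20 000 sampler draws, 5000-structure ensembles — were chosen so the
  whole suite completes in a few minutes on one CPU while keeping every
  statistical check well-powered.
* Pseudoknots are out of scope throughout (the partition function is
  over nested structures only), as are multi-nucleotide variants and
  suboptimal-structure listings.

## Known limitations

The absolute correlation values of full Turner-parameter engines are
not reproduced by the internal model — by design; use the external
adapter when absolute agreement with published per-SNP correlations
matters. k-means occupancies are a surrogate for visual quadrant
assignment and will not numerically match hand-drawn cluster
boundaries. And the rank p-value is a relative, per-sequence quantity:
it compares a variant with the mutational neighbourhood of its own
sequence, not across transcripts.
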