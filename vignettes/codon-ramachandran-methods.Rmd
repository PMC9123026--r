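---
title: "Methods: codon-specific Ramachandran analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-specific Ramachandran analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramacodon)
```

## The question and the data model

Sixty-one sense codons encode twenty amino acids. Synonymous codons produce
the same residue, but translation kinetics differ between them, and the
question this package addresses is whether that difference leaves a
measurable trace in the backbone geometry of the folded protein: do residues
translated from synonymous codons have different distributions of the
backbone dihedral angles $(\varphi, \psi)$?

The unit of analysis is a per-residue record joining three annotations:

* the backbone dihedral pair $(\varphi, \psi)$, computed from the N/CA/C
  coordinates of a crystal structure and, when several structures cover the
  same protein position, averaged over structures;
* a secondary-structure label (DSSP class), used to condition the analysis
  on the extended-strand (E) and helical (H) modes — synonymous codons have
  different *propensities* for the modes, and conditioning removes that
  confound so that only the *shape* of the distribution within a mode is
  compared;
* the codon, recovered by translating candidate coding sequences and
  aligning them to the chain.

All angles live on the torus $S^1 \times S^1$: each component wraps at
$\pm 180^\circ$. Every statistic in the package is wrap-aware.

## Torus geometry

Angles are stored in degrees in the half-open interval $(-180, 180]$, so
that $-180$ canonicalizes to $180$. The centroid of a set of dihedral pairs
is the per-component circular mean
$\operatorname{atan2}(\sum_i \sin \theta_i, \sum_i \cos \theta_i)$; for the
pairs $(170, 170)$ and $(-170, -130)$ this gives $(180, -160)$, not the
arithmetic $(0, 20)$:

```{r torus-mean}
torus_mean(dihedral_pairs(c(170, -170), c(170, -130)))
```

When a component's resultant vector is numerically zero (two exactly
antipodal angles) the mean is undefined; `torus_mean()` raises an error
rather than returning an arbitrary direction, and the aggregation step
counts and skips such positions. The distance between two dihedral pairs is
the Euclidean combination of the per-component shortest arcs,
$\sqrt{\operatorname{arc}^2(\varphi_1 - \varphi_2) +
\operatorname{arc}^2(\psi_1 - \psi_2)}$, in degrees.

## Density estimation and the distance statistic

`estimate_density()` places a Gaussian kernel
$K(x) = \exp(-x^2 / 2\sigma^2)$ on the torus distance between each sample
and each point of a $128 \times 128$ grid and normalizes the grid to unit
mass. Defaults: $\sigma = 2^\circ$, grid bin $360/128 = 2.8125^\circ$. Two
numerical choices matter:

* Grid points are bin *left edges*, $-180 + k \cdot 360/128$; contour
  positions can shift by at most half a bin relative to a cell-center
  convention.
* Because the squared torus distance separates over the two axes, the 2-D
  radial kernel factorizes, and the KDE is computed as a cross-product of
  two per-axis kernel matrices. This is an exact algebraic rewrite of the
  definition (the unit tests compare it against a literal double loop), and
  it is what makes the permutation machinery affordable: each permuted
  density is a BLAS cross-product over a row subset of precomputed kernel
  matrices. No kernel truncation is applied; all $N \times 128^2$
  evaluations are exact.

The distance between two codon densities is the cell-wise absolute
difference sum (the discrete $L_1$ distance), ranging from 0 to 2; its
self-normalized form $d(c,c') / \sqrt{d(c,c)\, d(c',c')}$ has unit diagonal
by construction.

## The hypothesis test

For each synonymous pair (and each codon against itself, as a control), the
test proceeds in three layers:

1. **Equalized sample size.** All codons of an amino acid are compared at
   the same sample size $N = \min\{N_{\max}, \min_c N_c\}$, with
   $N_{\max} = 200$, so that a single fixed bandwidth compares like with
   like (adaptive bandwidth selection is deliberately avoided).
2. **Bootstrap aggregation.** $B = 25$ rounds each draw $N$ observations
   with replacement from each codon's pool and run a $K = 200$-permutation
   test; the exceedance counts pool into
   $p = (1 + \sum_b \eta_b) / (1 + BK)$, with denominator $1 + 5000$ under
   the defaults and an attainable floor of $1/(1+BK)$.
3. **Permutation test.** The statistic is the $L_1$ distance between the
   KDEs of the two groups; the null distribution comes from re-splitting the
   pooled observations at random, and
   $\eta = \#\{k : \hat\tau \le \tilde\tau_k\}$ counts permutations at least
   as extreme as the base statistic (ties count toward $\eta$, making the
   test conservative at ties).

Multiplicity over the 148 hypotheses per structure class (61 self + 87
synonymous under the full code) is controlled by Benjamini–Hochberg at
$q = 0.05$: with sorted p-values, $i_0 = \max\{i : p_{(i)} \le qi/M\}$,
$\alpha_M = p_{(i_0)}$, and the *strict* rule rejects $p < \alpha_M$. The
strict rule — which, unlike the textbook step-up rule, excludes ties at the
threshold including $p_{(i_0)}$ itself — is the package default;
`textbook_bh = TRUE` switches to the standard behavior. The correction is
applied per structure class ($M = 148$), not pooled over classes.

Randomness is disciplined by a single master seed: child seeds are derived
deterministically per (pair, bootstrap round), so any pair is independently
re-runnable and whole runs are byte-reproducible.

### A calibration caveat

Bootstrap resampling *with replacement* interacts with the permutation
null. Duplicated observations never straddle the base X/Y split (the two
codons have disjoint pools) but do scatter across both sides after
permutation; with a $2^\circ$ bandwidth, where two KDEs overlap essentially
only through shared atoms, this biases p-values of distinct but
identically-distributed pools downward — strongly so when a codon's pool
size is close to $N$. Self-comparisons are immune because both resamples
share one pool, which is why they work as controls (their p-values
concentrate near 0.5 and are not rejected). The plain permutation test on
directly drawn samples is well calibrated: over repeated null pairs its mean
p-value is ≈ 0.5, which the test suite and the acceptance script verify.
Interpret rejections of low-count codon pairs with this in mind.

## Data preparation

* **Dihedrals.** $\varphi_i$ uses $C_{i-1}, N_i, CA_i, C_i$ and $\psi_i$
  uses $N_i, CA_i, C_i, N_{i+1}$; chain termini and residues with missing
  backbone atoms get `NA`, and a C–N distance above 2.5 Å (a value from
  standard practice; the peptide bond is ~1.33 Å) is treated as a chain
  break so no dihedral spans a gap. Structures are read from PDB or mmCIF
  via bio3d, keeping the highest-occupancy conformer at alternate
  locations.
* **Redundancy filtering.** Pairwise similarity uses global alignment with
  match 1 and zero penalties (equal to the longest-common-subsequence
  length), normalized by $\tilde s_{ij} = s_{ij}/\sqrt{s_{ii} s_{jj}}$, and
  a farthest-first traversal retains a subset with all pairwise
  $\tilde s \le \tau = 0.7$. The start index is arbitrary by construction;
  the default is the first sequence, and argmin ties break to the lowest
  index, both for determinism.
* **Codon assignment.** Each coding sequence is translated (terminal stop
  trimmed; internal stops are errors) and globally aligned to the chain
  with BLOSUM80, gap opening 10 and extension 0.5, via
  `Biostrings::pairwiseAlignment` (a length-$L$ gap costs
  $\text{open} + L \cdot \text{extend}$ under this implementation; terminal
  gaps are penalized like internal ones). A residue keeps a codon only when
  all coding sequences agree on a single variant that actually encodes the
  residue; distinct variants mark it ambiguous, and a codon aligned to a
  mismatched amino acid is treated as unassigned.
* **Aggregation.** Observations of the same (accession, position) across
  chains combine by torus mean; codon and secondary-structure labels must
  be unanimous, and every excluded position is counted under its first
  failing rule so that the run report is lossless: positions in = retained
  + sum of exclusion counts.

## The synthetic generator

`sample_von_mises_torus()` draws independent per-axis von Mises samples
(Best–Fisher rejection sampling) with concentrations obtained by *exactly*
inverting the circular-standard-deviation relation
$\mathrm{sd} = \sqrt{-2\ln R(\kappa)}$ — at the default
$\mathrm{sd}_\varphi = 35^\circ$ the small-angle approximation
$\kappa \approx 1/\mathrm{sd}^2$ is off by a sizeable margin. The defaults
($35^\circ$ in $\varphi$, $18^\circ$ in $\psi$, one mode per structure
class) emulate a single Ramachandran mode of one secondary-structure class.
They deliberately do *not* emulate: multi-modality within a class, the
correlation between $\varphi$ and $\psi$ within a mode, residue-to-residue
dependence along a chain, or measurement error shared between chains of one
crystal form. Tests passing on this generator therefore establish the
statistical machinery's correctness and power behavior, not distributional
realism of protein data.

Ground-truth distances between generator specs: $L_1$ is evaluated from the
analytic densities on the grid. For $W_2$, because the specs are per-axis
products and the squared ground cost separates over the axes, the squared
distance decomposes into two circular 1-D transport problems, each solved
by the cyclic quantile coupling (minimizing over the cut parameter, a
convex 1-D problem) on a fine 4096-point axis grid. This is exact for the
product class the generator emits; it does not cover correlated 2-D
densities, which the generator never produces.

## Visualization

* **Confidence-banded contours.** $B = 1000$ bootstrap KDEs of
  $\min\{N, 200\}$ observations; the averaged density's
  $\lambda$-super-level sets ($\lambda \in \{0.1, 0.5, 0.9\}$) give the
  drawn contours, with the threshold chosen as the largest value whose
  super-level set holds at least $\lambda$ of the mass (ties included, so
  the set is deterministic and mass-conservative). Each bootstrap's own
  binary super-level image is averaged, and the band is where that average
  lies strictly between $\alpha = 0.1$ and $1 - \alpha$. Band width
  reflects sampling uncertainty of the *level set of the estimate*: with
  the analysis bandwidth of $2^\circ$ the estimate is intentionally
  undersmoothed, and its super-level set itself grows with $N$, so
  raw band area is only comparable across sample sizes at a bandwidth
  commensurate with the mode (the test suite uses $10^\circ$ for that
  check).
* **Uncertainty-aware MDS.** Each codon is embedded as an isotropic
  Gaussian $\mathcal N(\mu_c, \sigma_c^2 I)$. The self-distance fixes the
  scale, $\sigma_c = 0.5\, d(c,c)$; the location targets are
  $\delta^2(c,c') = d^2(c,c') - 0.5\,(d^2(c,c) + d^2(c',c'))$, clamped at
  zero before the square root (noisy inputs can drive the expression
  negative), and solved by classical (Torgerson) MDS. The clamped,
  derivation-consistent form is the default; an alternative with
  $d^2(c,c')$ inside the subtracted average is available via
  `literal_delta = TRUE` but is not self-consistent with the generative
  model, under which the default form recovers locations and scales
  exactly (verified in the tests to within 5% on model-generated input).

## Problem sizes

The test suite and the reproduction script run at desk scale, chosen so a
single CPU completes the whole suite in a few minutes: null-calibration
uses 200 independent pairs at $N = 100$ with $K = 200$; the power
experiment uses rotations $\{0, 12, 30\}^\circ$ at
$N \in \{50, 100, 200\}$ with 10 trials per cell and a reduced
$B = 3, K = 40$ (the aggregate-denominator contract is checked separately
at the full $B = 25, K = 200$); oracle comparisons use small grids and
short sequences where exhaustive enumeration is feasible.

## Known limitations

* The bootstrap/permutation interaction described above makes p-values for
  distinct codons with nearly identical distributions anti-conservative
  when pool sizes are close to the equalized $N$.
* The $W_2$ ground truth covers only product (axis-independent) densities.
* DSSP labels are consumed, never computed; structures without labels fall
  out of the conditioned analysis.
* Redundancy filtering operates on the accession reference sequences taken
  from each accession's lexicographically first chain; a curated reference
  proteome can be substituted by editing the manifest.
* One chain is read per manifest row; chimeric chains are not detected
  beyond the one-chain-one-accession rule.
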