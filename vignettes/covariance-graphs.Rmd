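---
title: "Phylogeny-weighted covariance graphs: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-weighted covariance graphs: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevgraph)
```

# The problem and the model

Residues that carry out a molecular function together — the histidines and
cysteines of a metal center, the aromatic stack of a sugar-binding site —
are under shared evolutionary constraint even when they are distant in the
primary sequence. Given a query-anchored multiple sequence alignment,
`coevgraph` scores the statistical coupling of every pair of alignment
columns, turns the scored pairs into a residue graph, and asks whether the
covarying partners (or clique co-members) of an annotated residue are
enriched for residues with the same function.

## Phylogenetic weighting

An MSA is not an i.i.d. sample: clades of near-identical sequences would
otherwise dominate every count. Each sequence is weighted by the inverse
size of its high-identity neighborhood,

$$ w_a = \frac{1}{\left|\{\,b : \mathrm{seqid}(A^a, A^b) > 0.8\,\}\right|}, $$

where the neighborhood includes the sequence itself (so isolated sequences
get weight 1 and a group of $k$ duplicates shares total weight 1). The
threshold is strict (`> 0.8`) and configurable; 80% sits in the middle of
the 70–90% band where results are insensitive to the exact value. Sequence
identity is defined as identical residue pairs over mutually non-gap
columns; `X` (unknown) never matches anything. This denominator convention
is the package's own choice — it is robust to gappy homologs, and the tests
pin it down explicitly.

For a column pair $(i, j)$, sequences carrying a gap or `X` at either
column are excluded; $N_\mathrm{eff}$ is the weight sum of the rest, and
every state probability is *sub-normalized*:

$$ p(s) = \frac{\text{weighted count of } s}{N_\mathrm{eff} + 1}. $$

The `+ 1` acts as a denominator-only pseudo-count: probabilities of a
column sum to $N_\mathrm{eff} / (N_\mathrm{eff} + 1) < 1$, which the tests
assert exactly. The package deliberately does **not** renormalize —
downstream formulas consume these probabilities as-is, and renormalizing
would silently rescale every score.

## Covariance metrics and their scale

Three metrics are computed per pair, under a 2-letter alphabet (each
residue encoded as match/mismatch against the query residue of its column)
or the 20-letter amino acid alphabet (MI and χ² only):

- mutual information (natural log; the log base is a pure rescaling, and
  nats are the convention in the coevolution literature),
- the χ² coupling $\sum_{x,y} (p_{ij} - p_i p_j)^2 / (p_i p_j)$, skipping
  zero-expectation cells,
- a Pearson correlation over PSSM-realized substitution scores: sequence
  $l$ realizes score $s_{il}$ = PSSM log-odds of its residue at query
  position $i$; means and standard deviations are *weighted population*
  statistics (divide by $N_\mathrm{eff}$, matching the $1/N_\mathrm{eff}$
  prefactor), computed by default over the pairwise non-gap sequence set
  (a `stats = "global"` flag switches to per-column sets; the original
  choice is not documented anywhere, so both are available and the
  pairwise-consistent one is the default).

Post-processing maps scores onto $[0, 1]$: χ² values become lower-tail
chi-squared CDF probabilities with one degree of freedom, and $r$ is
clipped into $[-1, 1]$ (absorbing floating-point overshoot of the weighted
σ) before taking the absolute value.

One consequence worth spelling out: because the χ² statistic is computed
on the *probability* scale (not multiplied by a count), a perfectly coupled
binary pair has $\chi^2 \approx N_\mathrm{eff}/(N_\mathrm{eff}+1) \lesssim 1$,
so its CDF transform tops out near
$F_{\chi^2_1}(1) \approx 0.68$. Background (independent) pairs scatter well
below 0.5 at realistic alignment depths. Cutoff grids for 2-letter χ²
matrices are therefore most informative between 0.1 and 0.6; the default
sweep grid still spans 0.1–0.9 so that other metrics (20-letter χ² can
exceed 1 by far before the transform; |r| fills the whole unit interval)
share one axis.

Degenerate pairs — no sequence non-gapped at both columns, or zero score
variance at a column for Pearson (a conserved column) — are masked as `NA`,
exported as `NA`, and treated as below every cutoff.

## Sparse inverse covariance estimation

All matrices can be fed through the graphical LASSO,

$$ \hat\Theta = \arg\min_\Theta \; \sum_{ij} S_{ij}\Theta_{ij}
   - \log\det\Theta + \rho \sum_{ij} |\Theta_{ij}|, $$

solved by block coordinate descent (compiled code; the penalty applies to
all entries including the diagonal, so the working covariance starts at
$S + \rho I$). The solver is validated three independent ways in the test
suite: a closed-form 2×2 soft-thresholding solution, a from-scratch
proximal-gradient (FISTA) solver, and the stationarity conditions
$|\hat\Sigma - S| \le \rho$ with equality $\rho\,\mathrm{sign}(\hat\Theta)$
on the support.

The penalty is chosen automatically: binary search over (0.01, 0.99) on a
0.01 grid for the smallest ρ at which both the estimated covariance and its
inverse are fully defined. "Defined" is operationalized as: the solver
converged within its iteration cap (default 100 sweeps) and both outputs
are finite — in practice non-convergence and NaN are indistinguishable
symptoms of an insufficient penalty on a non-positive-definite input. The
search assumes feasibility is monotone in ρ and returns the feasible upper
end of the final interval; the tests compare it against an exhaustive grid
scan. Masked input entries are imputed as 0 (independence) before
estimation, and the imputed count is kept on the result. The
post-processed matrices (CDF probabilities, |r|) are what gets regularized
by default, mirroring the processing order of the pipeline; passing
`post_process = FALSE` to `covariance_matrix()` regularizes raw χ² instead.

## Graphs, conservation, cliques

A residue graph at cutoff $c$ has all $L$ positions as nodes (isolated
nodes are retained so node identity is stable across cutoffs) and edges
for unmasked scores $\ge c$ with sequence separation
$|i - j| \ge$ `min_separation` (default 1: only self-pairs are excluded,
since functionally coupled residues are often sequence-adjacent). Node
conservation is the phylogeny-weighted Shannon entropy of the column's
amino-acid distribution — gaps and `X` excluded and frequencies
renormalized, natural log, normalized by $\ln 20$ into $[0, 1]$ (a flag
treats the gap as a 21st symbol, normalizing by $\ln 21$). Maximal cliques
(size ≥ 2; singletons are visible as isolated nodes) are enumerated with
igraph's pivoting Bron–Kerbosch implementation and then canonicalized —
members sorted, cliques ordered by size then lexicographically — so output
files are reproducible regardless of enumeration order. An exhaustive
subset-enumeration oracle cross-checks the cliques on hundreds of small
random graphs.

## Enrichment statistics

For an annotated residue $i$ with function $f$ in a protein of length $N$:

$$ LO_i^f = \ln \frac{r / (R^f - 1)}{n / (N - 1)}, $$

with $n$ the number of positions $j \ne i$ whose score with $i$ clears the
cutoff and $r$ those also annotated with $f$; $R^f$ is the total number of
$f$-residues. The clique variant replaces the covarying set with the
residue's clique co-members — *membership*, not direct coupling, drives the
count, so a clique member whose pairwise score with $i$ is below the cutoff
still counts toward $n$. `LO` is `NA` exactly when a logarithm argument is
zero or undefined ($r = 0$, $n = 0$, or $R^f \le 1$); `NA` values never
enter densities or survival probabilities, and their counts are reported
alongside. $P(LO)$ is the empirical survival fraction of finite LO values.
Natural log is used throughout (for a near-perfectly coupled site in a
~500-residue protein the formula reduces to $\ln((N-1)/n) \approx 4.05$,
the magnitude scale seen in practice); a different base would only rescale.

When a residue sits in several maximal cliques, the per-residue report
takes the maximum finite clique LO — the most favorable coevolving context.
Residues annotated with several ligand categories count once per category;
pooled LO distributions concatenate per-residue values across proteins
with no per-protein averaging.

Amino-acid propensities are $P(a|l) = \ln(f_{a,l} / F_a)$ with $f$ pooled
over all annotated residues of a category and $F$ the background
composition of the whole protein set; zero-observation cells are `NA`
rather than $-\infty$. Distances between same-ligand sites are consecutive
differences of the sorted positions within a protein (the three standard
bins 1–4, 5–29, 30–1000 then partition 100%; an `all_pairs` flag computes
all pairwise distances instead, for sensitivity checks). Distances beyond
1000 clamp into the last bin.

## The synthetic generator

`generate_msa()` emulates exactly the features the statistics depend on:

- background columns drawn i.i.d. from a residue distribution (default
  uniform over the 20 amino acids; a skewed background can be supplied for
  propensity tests),
- planted column pairs sharing a latent binary signal — each sequence
  carries either the query residue or one fixed alternative at both
  columns, re-drawn independently with probability $1 - \mathrm{strength}$,
  so strength 1 is deterministic coupling and strength 0 independence,
- redundancy groups mutated at 5% of positions per member (guaranteeing
  pairwise identity > 80% within a group, far below it to outsiders), to
  exercise the weighting,
- an optional per-cell gap rate (default 0) to exercise the
  $N_\mathrm{eff}$ exclusion logic,
- a toy integer log-odds PSSM from weighted column frequencies, emitted in
  the PSI-BLAST ASCII layout.

It does **not** emulate tree-structured phylogeny, correlated gap
patterns, indirect (transitive) couplings, or realistic amino-acid
substitution chemistry. Passing tests therefore demonstrate correctness of
the statistics and the recoverability of direct couplings under controlled
noise — not contact-prediction performance on real protein families.

The calibrated study conditions used by the heavier tests and by
`scripts/acceptance.R` are 50 columns × 200 sequences, five planted pairs
at coupling strength 0.9, 20 replicate seeds: deep enough that the top-k
χ² couplings recover ≥ 90% of planted pairs, small enough to run in
seconds. The planted-vs-decoy LO comparison uses covariance cutoff 0.1:
decoy residues have no planted partner, so at high cutoffs their LO is
`NA` by the zero-argument rule and the comparison would be vacuous; at 0.1
both groups have defined LO and planted positions separate cleanly
(mean LO ≈ +0.3 vs ≈ −0.4).

## Numerical choices and degenerate inputs

- Positions are 1-based everywhere a user sees them; the query is the
  first alignment record by default (standard for PSI-BLAST-derived MSAs).
- Non-standard residue letters (B, Z, J, U, O, …) are read as `X`; `X`
  never matches in identity computations and is an exclusion state (like
  the gap) in pair counting and entropy.
- Diagonal matrix entries are computed and exported, but excluded from
  graphs, cliques and LO counting.
- Matrix symmetry is enforced by averaging with the transpose (guards the
  last bit of floating-point asymmetry from blocked computations).
- The redundancy filter for benchmark sets (length ≥ 30, ≥ 100 homolog
  hits, pairwise identity < 25%) is greedy in input order; the original
  clustering procedure is undocumented, so this filter is a utility, not a
  reproduction.
- Single-sequence alignments produce constant off-diagonal MI/χ² (no
  information to rank pairs) and fully masked Pearson matrices (zero
  variance); all-gap columns yield degenerate pairs, masked downstream.

## Known limitations

- The graphical-LASSO feasibility criterion inherits the iteration cap:
  a pathological input that converges in 101 sweeps is treated as
  infeasible at that ρ.
- 21-letter (gap-as-state) alphabets and average-product correction are
  out of scope, as are DCA-style direct-information scores.
- `apply_benchmark_filters()` computes global alignment identity, which
  for multi-domain proteins can differ substantially from local-alignment
  identity; supply a precomputed identity matrix for full control.
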