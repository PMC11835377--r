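---
title: "Gene-family occurrence phylogenomics for tailed phages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-family occurrence phylogenomics for tailed phages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vogtree)
library(ape)
```

## The problem and the model

Tailed phages (*Caudoviricetes*) are so mosaic that no single marker gene
spans the class, which frustrates alignment-based phylogenetics.  vogtree
instead treats the *occurrence* of protein families as the phylogenetic
character: each genome is annotated against the Viral Orthologous Groups
(VOG) families, and its character state for family $v$ is simply presence
(1) or absence (0).  The evolutionary model is the two-state general
time-reversible Markov chain with stationary frequencies $\pi_0$ (absent)
and $\pi_1$ (present).  With the rate matrix normalised so that one unit of
branch length equals one expected gain-or-loss event per family,

$$P_{ij}(t) = \pi_j + (\delta_{ij} - \pi_j)\,e^{-\beta t},
  \qquad \beta = \frac{1}{2\pi_0\pi_1},$$

which is the convention of standard ML tree software for binary data, so
branch lengths are directly comparable across runs.

Constant characters cannot be observed here: a family absent from every
genome is simply not a column, and a family present in every genome is
removed before inference.  Ignoring that sampling rule inflates branch
lengths.  The likelihood is therefore conditioned on characters being
variable (an ascertainment-bias, or ASC, correction):

$$\ln L = \sum_k w_k \left[\ln L_k - \ln\!\left(1 - L_{\mathrm{const}}\right)\right],$$

where $L_k$ is the Felsenstein-pruning likelihood of pattern $k$, $w_k$ its
multiplicity after pattern compression, and $L_{\mathrm{const}}$ the summed
probability of the two constant patterns on the same tree and model.  The
test suite verifies both halves of this claim: the corrected probabilities
of all variable patterns sum to one, and on data simulated conditional on
variability the uncorrected fit overestimates branch lengths while the
corrected fit recovers them within Monte-Carlo error.

## From hit tables to characters

The profile construction stage imposes the filtering rules exactly as
stated, because every downstream number depends on them:

* a hit is significant iff its E-value is **strictly** below $10^{-5}$;
* each gene keeps its **highest-bitscore** family, with ties broken by
  lower E-value and then lexicographic family id, so the matrix does not
  depend on the order of the input rows;
* a family enters a marker subset iff it occurs in at least
  $\lceil f \cdot n \rceil$ genomes (the "at least $f$ percent" rule read
  conservatively; $f = 0.005$ is the default marker set);
* a genome is retained iff it carries at least 5 distinct marker
  families — fewer presences carry almost no topological information.

Profiles round-trip bit-exactly through the binary-fasta representation
(one 0/1 string per genome, column order fixed by a sidecar TSV), which is
what makes analyses reproducible against a fixed family set.

## Inference machinery

Likelihoods are computed by postorder pruning over compressed site
patterns in a small C++ kernel, with per-pattern rescaling against
underflow; likelihood is identical with and without compression.  The
search is deliberately simple and fully deterministic:

1. neighbour joining on Hamming distances gives the start tree;
2. $\pi_1$ is estimated by one-dimensional ML on $(0.001, 0.999)$,
   alternated with branch-length sweeps (empirical presence frequency as
   the start value);
3. each branch is optimised by Brent search on $\log t$ over
   $t \in [10^{-8}, 50]$ — the log scale matters, because the likelihood
   plateaus once a branch saturates and a linear-scale bracket can
   converge onto the plateau;
4. NNI hill climbing accepts the best strictly improving move
   (re-optimising candidate branch lengths after resetting saturated ones,
   which otherwise pin every candidate to the same plateau) until no move
   gains more than $10^{-6}$ log-units.

This recovers the exhaustive optimum on four taxa and the generating
topology in well-separated simulations; it is not a stochastic
multi-start search, so very large trees may settle in different local
optima than heavier tools.  Bootstrap support is the nonparametric
column resample (resamples that lose all variable columns are redrawn),
with 100 replicates as a desk-scale default.

## What "well separated" means for binary characters

A two-state character carries very little deep signal: the correlation
between the states of two tips decays as $e^{-2\ell}$ in the path length
$\ell$ between them.  Making internal edges *longer* therefore does not
sharpen deep bipartitions — it saturates them.  The recovery benchmark
uses a balanced eight-taxon tree with terminal edges of 0.05 and internal
edges of 0.2 expected flips: internal edges dominate the terminal ones
(so every bipartition has signal), while the deepest tip-to-tip path stays
around one expected flip (so nothing saturates).  A pilot power scan
confirmed the reasoning: with all edges at 0.3 the ML tree — under this
engine and under an independent implementation — genuinely differs from
the generating topology in most replicates, whereas the shallow design
recovers it in essentially all of them.  At 500 variable characters the
end-to-end pipeline (hit table onward) attains $\ge 90\%$ exact recovery.

## Dereplication and co-occurrence

Redundancy reduction follows the base-R clustering idiom: Euclidean
distances between binary profiles ($\sqrt{\text{differing families}}$),
`hclust(method = "average")`, and a `cutree` cut at height 5 — genomes
joined at or below that height share a cluster, so members differ in at
most $\approx 25$ families.  Genomes are sorted lexicographically before
clustering, which makes the result invariant to input order even under
tied distances.  The representative of a cluster is the genome with the
most families, then the longest, then the smallest id (the choice of
representative is a package convention; any member is defensible).

Mosaicism statistics work on the same profiles.  Family–family Pearson
correlations feed average-linkage clustering on $1 - r$ cut at $0.3$,
i.e. families correlated above $r = 0.7$ form candidate co-occurring
sets; sets need at least 3 families, and a genome is a member of a set iff
it carries strictly more than 80% of it.  Zero-variance columns have no
defined correlation and are excluded rather than imputed.  The
large-versus-small genome comparisons (fraction of genomes carrying a
conserved set by size class; per-bin profile correlation distributions
with their medians) and the group-versus-group marker cross-tabulation
are counting exercises and are tested against hand-enumerated toys.
Trait enrichment between size classes uses a two-sided Mann–Whitney U
test computed by exact enumeration whenever both groups have at most 8
observations — including under ties, which is why it is implemented
in-package — and the tie-corrected normal approximation with continuity
correction otherwise.

## Genetic-code selection and its limits

Some large phages recode stop codons, so gene callers must choose a
translation table.  The selector implements the coding-density rule: score
the genome under the standard bacterial table 11 first, and if the
fraction of bases covered by called ORFs exceeds 80% (strictly), accept
table 11 without testing alternatives; otherwise score all nineteen
candidate tables and keep the densest, ties to the lowest table number.
Density is the base-interval union of ORFs, never a sum, so overlapping
six-frame calls cannot exceed 1.

The ORF caller is intentionally simple — six frames, one ORF per
stop-bounded segment from its first start codon, stop excluded, minimum
90 nt — and that simplicity has a knowable consequence: if the stop set of
table $X$ is a subset of the stop set of table $T$, every $T$-readable
ORF is also $X$-readable, so $X$'s density can never be lower.  Among the
candidate tables the only stop sets not containing another candidate's
are {TGA} (table 6) and {TAG} (table 14); a pure density maximiser can
therefore only ever *strictly* prefer those two, and the 80% shortcut is
what protects the standard code in practice.  The synthetic generator
accordingly plants codes 11 (exercising the shortcut), 6 and 14
(strictly recoverable over the full candidate list); recoded tables such
as 15 are exercised against restricted candidate lists.  Planted genomes
are built as wall-to-wall ORFs separated by stop-dense spacers, with the
gene bodies salted by a fixed cassette of codon pieces that plant the
*other* codes' stop triplets in all six reading frames — without that, a
naive six-frame caller finds long spurious ORFs in the shifted frames of
any coding sequence.

## The synthetic-data generator

Every fixture is generated in code with known ground truth and an
explicit seed:

* trees — Yule, balanced, or caterpillar, with separate terminal and
  internal edge lengths;
* profiles — background families evolve under the two-state model
  (optionally conditioned variable, matching the ASC sampling model);
  planted family blocks are present within one clade with probability
  `block_fidelity` (0.95 default) and outside at
  `(1 - block_fidelity) * pi1`; clades are chosen disjoint and
  family-sized (near a third of the taxa) because two-tip clades are too
  fragile to carry a block;
* mosaicism — whole-block transplantation between random leaves at a
  Poisson rate, a deliberate caricature of module exchange: it creates
  marker conflict without modelling recombination along the tree;
* hit tables — one to three gene-level hits per present family with the
  true family on top by bitscore, decoys at 0.5–0.95 of the top score
  (or exact ties with larger E-values, to exercise the tie-break), and
  junk rows above the E-value threshold;
* coded genomes — as described above, hitting the target coding density
  within ±0.05.

What passing these tests shows — and does not show.  The generator
emulates the *statistical* structure the analysis assumes: conditionally
independent binary characters on a tree, clade-linked blocks, block-level
exchange.  Real phage data violate several of these assumptions (rate
heterogeneity across families, annotation noise correlated with genome
length, non-independent gene modules), so green tests certify the
machinery, not biological conclusions.

## Numerical and degenerate-input conventions

* Branch lengths live in $[10^{-8}, 50]$; optimisation snaps to a bound
  when the bound is the optimum.
* Convergence thresholds: $10^{-6}$ log-likelihood units for branch
  sweeps and NNI acceptance.
* All-gap-equivalents do not exist for binary data, but empty inputs do:
  empty hit files warn and return empty tables; writing an empty profile
  as binary fasta is fatal; conditioning on variability over a zero-length
  tree fails after a bounded number of rejection rounds.
* All stochastic operations take an explicit integer seed; the default
  is 42.  Pipeline reruns with the same inputs and seed produce
  byte-identical binary fasta and Newick outputs.

## Problem sizes used in the checks

The bundled validation (test suite and `scripts/acceptance.R`) runs the
likelihood oracle on 200 instances of up to 6 taxa, the ASC mass check up
to 10 taxa, branch-length calibration on 30 replicates of 400 conditioned
characters, topology recovery on 100 end-to-end replicates of 8 taxa by
500 characters, co-occurrence recovery on 200 genomes, and code
identification on 30 planted genomes of 12 kb.  These sizes were chosen
as the smallest at which the Monte-Carlo checks are decisive.
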