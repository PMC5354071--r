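---
title: "From ancient peptide-spectrum matches to a partitioned protein phylogeny"
author: "palaeoprot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ancient peptide-spectrum matches to a partitioned protein phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palaeoprot)
```

## The problem

Bone preserves a small proteome — dominated by collagen type I (COL1, the
heterotrimer of the *COL1A1* and *COL1A2* chains) together with a handful of
other collagens and non-collagenous proteins (NCPs) such as AHSG, PEDF or
osteomodulin — far longer than it preserves DNA. Tandem mass spectrometry of
Middle and Late Pleistocene bone therefore yields peptide–spectrum matches
(PSMs) from which genus-level phylogenetic information can still be
extracted. Doing that defensibly requires a chain of steps, each of which
this package implements as a tested, reusable component:

1. **PSM and protein acceptance** — target–decoy FDR filtering of
   database-search PSMs, an average-local-confidence (ALC) rule for de novo
   matches, and protein acceptance requiring two unique peptides and a
   minimum protein score.
2. **Authentication by deamidation** — spontaneous Gln/Asn deamidation
   accumulates with age, so genuinely ancient proteins show high spectral
   deamidation frequencies while modern laboratory contaminants (trypsin,
   keratins, caseins, lysozyme) do not; a univariate Gaussian-mixture model
   separates the two groups.
3. **Consensus sequence reconstruction** — accepted peptides are placed on
   a reference proteome, single amino-acid variants (SAAVs) are called by
   spectral majority, and per-gene consensus sequences are emitted with `X`
   at uncovered positions.
4. **Alignment preparation** — leucine is collapsed to isoleucine (the two
   are isobaric and indistinguishable by MS), collagen telopeptides are
   removed, informative NCP genes are selected, and genes are concatenated
   into a partitioned amino-acid matrix.
5. **Phylogenetics** — partitioned maximum-likelihood inference under the
   Dayhoff model with nonparametric bootstrap, and Bayesian MCMC with
   convergence diagnostics and a majority-rule consensus tree.

A synthetic-data generator produces every input the pipeline consumes, so
the whole chain can be exercised, and its statistical behaviour verified,
without any external download.

## Acceptance filters

Database-search PSMs are filtered at a PSM-level FDR of 1% by the
target–decoy procedure: sort by score, form the running decoy/target ratio,
evaluate tied scores at the end of their tie block, and monotonise from the
bottom (the q-value). Decoys that pass are retained, flagged, and ignored
downstream; this makes the filter idempotent. De novo matches need an ALC of
at least 50% (inclusive) and are additionally listed in a manual-inspection
report — no automatic rescoring is attempted. Proteins are accepted with at
least two unique peptides (distinct peptide strings after I/L collapse —
modified forms of one sequence are one peptide, since modifications are
post-translational, not sequence identity) and a protein score of at least
20. The score is a search-engine aggregate (−10lgP-style) whose exact
formula is engine-specific; when the input provides a per-protein score we
use it, otherwise we fall back to the maximum PSM score of the group, and we
document that absolute score scales are dialect-dependent. Proteins found in
the extraction blank, or listed in the contaminant catalogue, are flagged as
contaminants: they are kept for the deamidation comparison but excluded from
consensus building and phylogenetics.

## Deamidation counting and mixture clustering

Counting is spectrum-level and binary. A spectrum enters the denominator
when its peptide spans at least one reference Gln/Asn position, and the
numerator when at least one of its Gln/Asn residues carries a deamidation
modification. Spectra are deduplicated by spectrum identifier first.
Proteins covering fewer than three distinct reference Q/N positions are
ineligible for clustering. A frequency of exactly 1 raises an audit flag:
fully deamidated positions could in principle be Glu/Asp substitutions, but
we treat them as deamidation — in heavily degraded samples overall
deamidation is high, the older sample is consistently the more deamidated,
and comparative database sequences show no Q→E/N→D substitutions among these
proteins — while surfacing the flag so users can audit individual cases.

Eligible frequencies are clustered with a one-dimensional Gaussian mixture
fitted by EM (convergence when the log-likelihood improves by less than
1e-8, at most 500 iterations), over k ∈ {1, 2, 3} with equal- and
unequal-variance models, 10 seeded restarts each, and BIC
(−2·lnL + p·ln n) selection. Variances are floored at 1e-4, which keeps
boundary values (0 and 1) well behaved without a logit transform. We wrote
the EM ourselves rather than wrapping an existing clustering package because
the authentication logic needs the per-iteration log-likelihood trace (its
monotonicity is asserted in tests), seeded restarts and the variance floor;
the test suite cross-checks the fits against `mclust`. Components whose mean
lies closer to the largest component mean than to the smallest are labelled
endogenous, the rest contaminant — for the usual k = 2 this is simply the
larger-mean rule, and the labelling is invariant to permuting components.
With k = 1 every protein is labelled by comparing the single mean to a
configurable threshold (default 0.5) and a warning is emitted. Clustering is
performed per ancient sample; blank and modern-sample frequencies are
displayed but not clustered.

The paired two-sample table restricts to proteins with at least two
Q/N-containing peptides in both samples and reports the difference (first
sample minus second). On simulated data with a higher deamidation
probability for the older age class, every shared endogenous protein should
show a positive old-minus-young difference — the degradation-monotonicity
property the acceptance suite checks.

## Consensus reconstruction

Peptides are placed on their assigned reference protein in I/L-collapsed
space, allowing at most one mismatch; exact placements are found by
substring search and mismatch placements by scanning every offset. Equally
good multiple placements are flagged ambiguous and excluded from consensus
with a warning. Per position the consensus letter is the spectral majority;
ties and uncovered positions yield `X` rather than a reference fill, to
avoid reference bias in the downstream phylogenetics. A SAAV is called when
the majority letter differs from the reference and at least two spectra
support it (configurable); single-spectrum variants keep the reference
letter and are logged as low-support. Coverage is reported per gene and for
COL1 over the concatenated non-telopeptide lengths of both chains; samples
below 40% COL1 coverage are flagged — an incomplete, conserved-region-only
collagen sequence can attract an artefactually basal position in the tree —
but exclusion is left to configuration rather than automated.

## Alignment assembly

All sequences pass through the isobaric L→I collapse. The reference
annotation carries, per protein, the ranges excluded from the alignment
frame: the non-helical telopeptides for the collagen chains, and for NCPs
the flanking regions outside the phylogenetically informative covered
blocks. Removing those ranges puts every consensus sequence in the same
coordinate frame as the per-gene database sequences, so no de novo multiple
alignment is needed (the sequences are near-identical orthologs); a length
mismatch after removal is an error. A non-COL1 gene enters the alignment
only when at least one study specimen carries at least one called SAAV in it
— genes identical to the reference in all study taxa carry no signal for
placing those taxa and are dropped. Genes are concatenated in a fixed
configurable order; taxa missing a gene are X-filled, partition boundaries
are recorded 1-based inclusive and asserted to tile the matrix exactly.
Gaps (`-`) are accepted on input but converted to `X` with a warning, and
`X` is treated downstream as fully missing. Externally sourced partitions
(for instance translated nuclear genes from a prior study) append after the
base columns with taxon-name reconciliation. Writers exist for FASTA,
relaxed PHYLIP, NEXUS with charsets and RAxML-style partition files, and the
FASTA/PHYLIP readers round-trip exactly.

## The phylogenetic engine

The substitution model is the published Dayhoff (1978) PAM-based
exchangeability matrix with its equilibrium frequencies, shipped as a
checksummed plain-text data file; the rate matrix is scaled to one expected
substitution per site per unit branch length, and transition matrices come
from the spectral decomposition of the symmetrised generator. No
among-site rate-variation term is added by default — the analysis design
this package follows used the plain Dayhoff model per gene partition, with
between-partition rate multipliers carrying the rate heterogeneity.

Likelihoods are computed by Felsenstein pruning with site-pattern
compression and per-node scaling; the inner kernel is compiled (C++), and a
pure-R reference implementation is kept and cross-checked in the tests,
alongside brute-force state enumeration on tiny instances and an external
check against `phangorn::pml`. `X` and `-` contribute uniform partial
likelihood vectors. Per-partition rate multipliers are estimated by bounded
scalar likelihood maximisation and renormalised to mean 1.

ML search starts from a neighbour-joining tree on pairwise one-parameter ML
distances (computed over the columns where both sequences are unambiguous;
negative NJ branches are clamped to zero), then alternates
cached-partial branch-length optimisation with evaluation of all
nearest-neighbour interchanges, accepting the best strictly improving move
(ties broken by first-encountered edge order) until a fixed point. Bootstrap
replicates resample columns within partitions, preserving partition sizes,
and restart the search from the full-data ML tree; supports are bipartition
frequencies across replicates.

The Bayesian sampler is a single-chain Metropolis–Hastings walk (no
Metropolis coupling) over topology (uniform prior, NNI proposals), branch
lengths (exponential prior with mean 0.1; multiplicative single-branch
proposals plus a whole-tree scale move, which decorrelates total tree
length) and per-partition rate multipliers. The multipliers are kept at
site-weighted mean 1 and sampled through a Dirichlet proposal on the
corresponding simplex with a flat Dirichlet prior: leaving the rate scale
free would make it jointly unidentifiable with tree length and the chain
would wander along that ridge. Default run settings follow a standard
protein-phylogeny protocol — five million generations, sampling every 500,
10% burn-in — scaled down to 200,000 generations for the packaged 4-taxon
study, where the sampler mixes fully. Convergence is summarised by the
effective sample size `n / (1 + 2·Σρ)` with Geyer initial-positive-sequence
truncation; parameters at or below ESS 200 are flagged. The posterior tree
sample is summarised as a 50% majority-rule consensus labelled with
bipartition frequencies, rooted on the configured outgroup by splitting its
pendant edge at the midpoint.

## The synthetic study designs

`make_study("rhino12")` mirrors a 12-taxon Perissodactyl design: five extant
rhinoceroses, two extinct rhinoceros genera entering as ancient samples (a
Middle Pleistocene *Stephanorhinus*-like specimen, age class "old", and a
Late Pleistocene woolly-rhinoceros-like specimen, age class "young"), a
tapir, three equids and a bovid outgroup. Five gene partitions — the two
COL1 chains at their mature telopeptide-free lengths (1,014 and 1,002
columns) and covered blocks of COL3A1, PEDF and AHSG (30, 25, 18) — total
2,089 alignment columns; nine translated nuclear genes (BRCA1 … TYR)
totalling 3,917 columns are available for the extended design. Sequences
evolve along a fixed tree under the Dayhoff model with per-gene rate
multipliers between 0.7 (COL1A1) and 1.7 (AHSG). The branch lengths are
artifact choices: they are set large enough that 2,089 columns carry decisive
signal for every internal edge (the shortest internal branch expects ~7
substitutions) yet small enough that tryptic peptides almost always place on
the reference within the one-mismatch limit. Real collagen divergence
between rhinoceros genera is lower, which is precisely why the real study
could not resolve the *Stephanorhinus*/*Coelodonta*/*Dicerorhinus*
trichotomy; the simulated design is a scaled analogue for validating the
machinery, not a model of the real divergence depths.

The reference proteome is the reference taxon's gene sequences embedded in
synthetic flanking sequence (telopeptides for the collagens, uncovered
flanking regions for the NCPs — both annotated as alignment-excluded
ranges), 13 further endogenous bone proteins, and a 16-protein contaminant
catalogue (keratins, caseins, trypsin, lysozyme, histones, bovine albumin),
so each generating cluster offers at least 15 clusterable proteins.

The PSM simulator digests each protein tryptically (cleave after K/R except
before P, up to two missed cleavages, peptide lengths 6–30), detects each
peptide with probability 0.8, draws spectral counts per detected peptide
from a Poisson with mean 6 — depths chosen to resemble a well-preserved
bone LC-MS/MS run, where collagen peptides are observed many times — and
assigns search scores from two shifted normal distributions (targets vs
reversed-peptide decoys). Deamidation is drawn per spectrum, with
probability 0.85 for the old age class, 0.65 for the young and 0.10 for
contaminants, so the spectrum-level frequency statistic converges to the
configured probability; within a deamidated spectrum each Q/N site is
modified with the same probability, conditioned on at least one site.
Oxidation (M) and hydroxylation (P) modifications are sprinkled in at low
rates for realism, capped at six modifications per peptide. A truth record
retains every generated label for recovery scoring, and the extraction
blank contains only contaminant-derived PSMs.

What the generator deliberately does not emulate: spectral noise and
misidentification (every PSM is a correct identification; FDR filtering is
exercised through synthetic decoys, not through wrong matches), site-rate
heterogeneity in deamidation, PTM localisation error, protein inference
ambiguity (each peptide is attributed to its true protein) and alignment
error. Passing tests therefore demonstrate that the statistical machinery
is correct under its stated model, not that the model captures every
pathology of real ancient-proteome data.

## Numerical choices and degenerate inputs

Branch lengths are bounded to [1e-9, 10] and optimised to a log-likelihood
tolerance of 1e-6; EM to 1e-8; partial likelihoods are rescaled per node;
all-X partitions keep rate multiplier 1 with a warning; a constant MCMC
trace reports ESS 1 with a warning; consensus ties yield X; mixture
variances are floored at 1e-4. Problem sizes used by the tests and the
acceptance script — 20 maximum-likelihood replicates, 100 bootstrap
replicates, 100 authentication seeds, three 200,000-generation chains — are
desk-scale choices that keep a full verification run in the tens of
minutes on one core while leaving every acceptance margin wide.

## Known limitations

Single-chain MCMC (no Metropolis-coupled chains); NNI-only tree moves, which
can in principle be trapped by local optima on larger or noisier data sets;
no +Γ among-site rate variation (available as future work; the per-gene
multipliers absorb between-partition variation); no protein-inference
parsimony (PSMs arrive pre-assigned); deamidation is used comparatively, not
as an absolute clock; and the placement search allows a single mismatch, so
peptides carrying two or more substitutions in a short stretch are dropped
rather than placed.
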