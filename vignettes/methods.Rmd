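---
title: "Models and methods behind stutzpan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stutzpan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

stutzpan packages the comparative-genomics workflow used to delineate a
bacterial species inside a taxonomically difficult complex — the motivating
case is *Stutzerimonas balearica* within the former *Pseudomonas stutzeri*
group — and to screen public 16S rRNA sequences for further members of the
species once its genomic boundary is fixed. This vignette explains the
models, the defaults and why they were chosen, what the synthetic
generators do and do not emulate, and the numerical edges a user should
know about.

## Fragment-based ANIb

Average nucleotide identity by BLAST-style fragment alignment (ANIb)
operationalizes DNA-DNA hybridization: the query genome is cut into
consecutive non-overlapping 1,020 bp fragments, each fragment's best local
alignment anywhere in the subject (either strand) is computed, hits are
kept when they reach at least 30 % identity over at least 70 % of the
fragment length, and the one-way ANIb is the mean identity of the kept
hits. Bidirectional values are averaged arithmetically. The fragment
length and the 30/70 filter are the canonical fragment scheme of the
method's original definition; they are exposed in `anib_params()` because
draft assemblies with very short contigs occasionally warrant a shorter
fragment.

Two conventions matter for reproducibility:

* **Identity denominator.** Identity is identical columns divided by all
  alignment columns, gap columns included — the BLAST convention. N bases
  never count as identities.
* **Undefined values.** If no fragment survives the filter (unrelated
  genomes), the one-way value is reported as `NA` ("no alignable
  fraction"), never silently 0; `anib_pair()` falls back to the defined
  direction with a flag when only one direction is defined.

The built-in aligner is an affine-gap Smith-Waterman (match +1, mismatch
−1, gap open −5, gap extend −2, first gap character paying open+extend)
run in compiled code. For genome-scale subjects a seed-and-extend
strategy is used: exact 11-mer matches vote for alignment diagonals,
votes are binned into 64-diagonal bands, and full Smith-Waterman runs
only on the subject window around each of the top three bins with at
least three votes. The vote floor suppresses chance 11-mer matches, so
unrelated sequences fall through to the "no alignable fraction" path
instead of producing spurious micro-alignments. At 10 % divergence a
1,020 bp fragment still carries hundreds of clean 11-mers, so seeding is
not a sensitivity bottleneck anywhere near the species boundary. Because
local alignment trims mismatching fragment ends, measured identities sit
a few hundredths of a point above 100·(1 − rate) on substitution-only
simulations; the acceptance band of ±0.5 absorbs this.

**Genomospecies.** The species rule is pairwise — genomes sharing ANIb
≥ 95 % belong to one phylogenomic species — and the package reads it as
its weakest consistent closure: single linkage, i.e. connected components
of the ≥ 95 % graph. Any stricter linkage would need a justification the
rule itself does not supply; the choice is explicit in
`cluster_genomospecies()` and the threshold is an argument. The matrix
dendrogram uses average linkage on 1 − Pearson correlation between matrix
rows, the combination conventional for ANI heatmaps.

## The 70/70 pan-genome

Two proteins are candidate family members only if they share at least
70 % identity over at least 70 % of the length of the longest of the two
— the "70/70 rule". Protein alignments use BLOSUM62 with affine gaps
(10/1). The all-versus-all search prefilters pairs by shared 5-mers
(three or more), which is loss-free in practice for families above the
70 % floor (expected shared 5-mers at 70 % identity ≈ 40 per 250
residues) and reduces the search to near-linear cost; `prefilter = FALSE`
restores the exhaustive quadratic search.

Three clusterings are built from the same hit table:

* **BDBH** — for each reference-genome protein, the proteins of other
  genomes that are bidirectional best hits with it. Ties are broken by
  score, then identity, then lexicographic protein id, making the result
  deterministic.
* **COG triangles** — inter-genome BBH pairs are assembled into triangles
  (three proteins, three genomes, mutually BBH); triangles sharing an
  edge merge. Families present in fewer than three genomes can never be
  clustered by construction.
* **OMCL** — Markov clustering of the similarity graph. Edge weights are
  the symmetric pairwise alignment score (the min-of-both-directions
  convention; both directions are equal under the built-in symmetric
  scorer). Each connected component is clustered separately: self-loops
  at the node's maximum incident weight, column normalization, then
  alternating expansion (matrix square) and inflation (element-wise power
  1.5, re-normalize), pruning entries below 1e-5, until the maximum
  column change drops below 1e-6 or 100 iterations. Clusters are the
  connected components of the converged matrix. The iteration has no
  random element.

The **strict consensus core** keeps clusters whose member sets are
identical in all three clusterings and that hold exactly one protein per
genome. The **pan-genome** is defined from the OMCL/COG-triangles pair:
clusters with identical member sets in both, extended with the OMCL
clusters whose proteins no such cluster covers, plus singletons for
unassigned proteins. The extension is a deliberate design choice: a
literal intersection would discard every one- and two-genome family
(COG triangles cannot form them), yet such "cloud" clusters are the
majority of any open pan-genome and the compartment classification —
core / soft-core (≥ 95 % of genomes) / shell / cloud (≤ 2 genomes) —
would be meaningless without them. **Pan-genes** of an in-group are the
clusters present in every in-group genome and absent from every
out-group genome; the operation is a pure occupancy query and is
invariant to genome order.

Pathway profiles reuse the aligner at a permissive 30 % identity floor
with an added 50 %-of-seed coverage requirement to suppress domain-only
matches; setting `pathway_min_coverage = 0` recovers the bare identity
rule. Completeness of a pathway in a genome is set-theoretic: all seeds
present.

## Gene-discovery curves

`sample_gene_discovery()` draws random genome orderings (100 by default;
a seed is mandatory) and records, for each prefix of each ordering, the
number of clusters present in all prefix genomes (core) and in at least
one (pan). Two exponential models with offsets are fitted by
Levenberg-Marquardt nonlinear least squares:

* core: F(n) = κ·exp(−n/τ) + Ω, fitted to per-size means ("tettelin"
  strategy) or to per-size medians weighted by inverse across-permutation
  variance ("willenbrock" strategy; zero variances are floored at the
  smallest positive variance). Ω estimates the asymptotic core size.
* new genes: n_new(g) = κ_p·exp(−g/τ_p) + θ for g ≥ 2, fitted to the mean
  number of clusters first seen with the g-th genome. θ ≥ 0 is the
  asymptotic new-gene rate; θ > 0 is an open pan-genome. Pan
  extrapolation is cumulative: P(N) = P(G) + Σ n_new(g) for g = G+1…N,
  which is non-decreasing whenever θ ≥ 0.

Starting values are Ω₀ = last observed size, κ₀ = first − last,
τ₀ = G/3, with two fallback starts (τ₀ = 2 and τ₀ = G) before the fit is
declared failed; a constant curve short-circuits to the degenerate
κ = 0, Ω = constant answer. Fits are exposed as classed objects with
`coef`, `predict`, `residuals` and `plot` methods. Core extrapolation
evaluates the fitted curve directly; requests below the observed genome
count are refused (interpolation is not extrapolation).

## Distance phylogenetics

Jukes-Cantor distances d = −¾·ln(1 − 4p/3) use pairwise deletion (only
columns where neither sequence has a gap or N) and refuse p ≥ 0.75, where
the model is undefined. Neighbor joining is delegated to the standard
Saitou-Nei implementation in ape; on additive matrices the tree's
path-length matrix reproduces the input exactly, which the tests verify
against random binary trees. Negative branch lengths, which NJ can
produce on non-additive input, are clamped to zero with a warning.
Bootstrap supports resample alignment columns with replacement, rebuild
the JC/NJ tree per replicate, and count bipartitions on the full-data
tree; replicates whose resampled distances are undefined are redrawn (at
most ten times the replicate count). Protein alignments use the plain
p-distance, since the corrected-distance machinery here targets the
nucleotide analyses.

Alignment trimming approximates the Gblocks idea with three explicit
rules: keep columns with at least 50 % non-gap residues whose most
frequent residue reaches 50 % of the sequences, then drop kept runs
shorter than 5 columns. The retained column indices are recorded, and
outputs are always a subset of input columns. Alignments are accepted as
inputs throughout; the package does not ship a multiple aligner, because
every synthetic path produces substitution-only (already aligned) panels
and real analyses will have been aligned upstream.

## Two-step 16S screening

The screening region is the reference's positions 50–650, which contains
all 37 signature positions of the motivating species. Step 1 aligns the
region to the query and computes identity (identical columns over all
alignment columns) and coverage (region positions aligned to a query
base over region length, a reference-region convention chosen because
the fixed reference fragment is the screening query; it is configurable).
Identity below 99.6 % (inclusive boundary, "greater than or equal")
rejects the query as a non-member; insufficient coverage makes it
not classifiable. Step 2 maps every profile position through a global
alignment and requires the expected base at all of them. The rules are
deliberately asymmetric in their strictness: a covered mismatch is
disqualifying, but a gap, truncation, or ambiguity code at a signature
position makes the sequence *not classifiable* rather than a non-member
— missing a true strain is preferred to inventing one. Signature
profiles are plain TSV files with a two-line header, so a species
profile is editable data, not code.

## What the generators emulate — and what they do not

Every generator is a pure function of its configuration; each scenario
derives its own RNG stream from the master seed, so adding a scenario
never perturbs another, and ground truth (seed included) is serialized
beside the data.

* **Genome pairs** are i.i.d.-substitution copies of a random ancestor
  (no indels by default), so per-fragment mismatch counts are exact and
  the expected ANIb is analytic. Real genomes add rearrangement,
  repeats, and horizontal transfer; passing the ANIb tests shows the
  estimator is correct, not that 95 % is the right boundary for any
  particular genus.
* **Occupancy matrices** give every genome the full Ω-cluster core; the
  g-th genome founds round(κ·exp(−g/τ)) "epoch" clusters propagated to
  each later genome with probability 0.5, plus θ strictly private
  clusters. The private/propagated split is what makes the discovery
  process's asymptotic new-gene rate equal θ — if the θ clusters were
  also propagated, the late-ordering discovery rate would collapse
  toward zero and no fit could recover the nominal rate. The process is
  a stand-in for the fitted asymptotics (Ω, θ) only; it makes no claim
  about the phylogenetic correlation of real gene content. The default
  study condition used throughout the tests is Ω = 3,000, θ = 25,
  κ = 2,000, τ = 3 over 40 genomes with 100 permutations, sized so ten
  replicate fits run in seconds.
* **Protein families** mutate a family ancestor at per-copy rate
  (1 − w)/2, giving expected pairwise within-family identity ≈ w;
  between-family identity is that of independent random sequences. The
  generator refuses configurations without a separation gap (within
  ≤ 0.6), because clustering tests on overlapping families would be
  ill-posed.
* **16S panels** plant the signature positions inside the screening
  region, keep every in-group sequence within two region substitutions
  (hence above the 99.6 % step-1 threshold), and mutate one designated
  position in every out-group sequence while guaranteeing each other
  position is carried by someone — so exactly one position is exclusive,
  mirroring the single-exclusive-position situation the screening
  strategy was designed for. Half of the out-group carries only
  signature mutations and therefore exercises the step-1-pass /
  step-2-fail path.

## Numerical choices and known limitations

* Alignment scores use doubles throughout; fragment windows are
  ~1,020 × 1,150 cells, small enough that full traceback matrices are
  allocated per call.
* The k-mer prefilter of the protein search is heuristically loss-free
  only above roughly 60 % identity; pathway searches at the 30 % floor
  therefore skip it and align exhaustively.
* MCL non-convergence after 100 iterations yields a warning plus the
  current partition rather than an error.
* The average-linkage dendrogram refuses zero-variance matrix rows
  (Pearson correlation is undefined there); this occurs only in
  degenerate all-identical toy matrices.
* Bootstrap supports are percentages of replicates, mapped onto internal
  nodes of the full-data tree; for five-taxon trees only two internal
  edges exist and supports on trivial splits are reported as 100.
* Desk-scale problem sizes are used in tests and the acceptance script
  (102 kb genome pairs, 31 proteomes of ≤ 44 proteins, 40-genome
  occupancy processes); the algorithms scale beyond that, but the
  built-in aligner is not a substitute for a production BLAST run on
  hundreds of multi-megabase genomes.
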