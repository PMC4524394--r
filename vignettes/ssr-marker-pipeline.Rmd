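---
title: "From enriched reads to population structure: methods behind ssrmarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From enriched reads to population structure: methods behind ssrmarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrmarkers)
```

`ssrmarkers` implements the standard workflow for developing
microsatellite (SSR) markers in an understudied species and applying them
to diversity and structure questions in a germplasm collection — the kind
of panel a breeding or conservation programme assembles for a clonally
propagated crop with wild relatives. This vignette documents the models,
the parameters that matter, the numerical choices, and what the test
suite does and does not establish.

## 1. SSR mining

The miner reports **maximal perfect tandem runs** of di-, tri- and
tetra-nucleotide units. "Class I" (long, hypervariable) loci are selected
by two simultaneous thresholds: a minimum repeat count per class (di 11,
tri 7, tetra 6) and a minimum tract length of 21 bp. Both are exposed in
`find_ssrs()` and `pipeline_config()`.

Conventions that make the counts well defined:

* **Smallest-period canonicalisation.** A run whose unit is itself
  periodic (ATAT as a tetramer, a homopolymer as a dimer) is reported only
  at its smallest period, so an `(AG)n` tract is never double-counted as
  `(AGAG)n/2`.
* **Whole units only.** A trailing partial unit neither increments the
  repeat count nor extends the reported tract; the tract covers
  `repeat_count × period` bases from the leftmost position at which the
  period-p match chain starts. This is a deterministic boundary rule; the
  brute-force oracle in the test suite implements the same rule from an
  independent per-position scan, and the two agree exhaustively on all
  2-letter strings up to length 12 and on random 30–60 bp strings.
* **N breaks runs** (conservative for raw reads).
* **Class grouping is by cyclic rotation only** (GA→AG, GAA→AAG) by
  default. Collapsing a motif with its reverse complement (AG with CT) is
  available behind `strand_collapse = TRUE` but off by default: enriched
  libraries are built with probes on both strands, and published catalogs
  typically report AG and CT classes separately.

Motifs separated by at most 100 bp on one read merge into a single
compound/interrupted locus; two repeats farther apart, each with
sufficient flanks, yield two independent designable loci. Because the
field reports both conventions, the catalog is summarised both per motif
and per locus.

## 2. Primer design and melting temperatures

The picker is deliberately *not* a Primer3 re-implementation: secondary
structure, positional penalties and mispriming libraries are out of
scope, because the upstream tool is treated as a black box whose
bit-compatibility is neither attainable nor needed for pipeline
semantics. Constraints enforced: product 100–250 bp, oligo length
18–24 nt, GC 40–60 %, design-time |ΔTm| ≤ 1 °C. Ties are broken by
(smallest ΔTm, mean Tm closest to 60 °C, leftmost forward start), making
the result unique and deterministic.

Tm uses unified nearest-neighbor thermodynamics with the entropic salt
correction ΔS′ = ΔS + 0.368 (N−1) ln[Na⁺], at 50 mM monovalent salt and
200 nM total oligo (both configurable). The recommended annealing
temperature is `min(TmF, TmR) − 3 °C`, clamped to the 30–80 °C scan
window — the per-marker annealing temperatures in published tables follow
no stated rule, so a deterministic one is defined here.

Two Tm-difference thresholds coexist on purpose: ≤ 1 °C at design time
and ≤ 3 °C at validation. They apply at their respective stages and are
not reconciled.

## 3. In silico PCR and validation verdicts

Binding sites require an **exact 3′-terminal 9-mer** match (the anchor);
the alignment is then extended 5′-ward while bases match. Mismatches 5′
of the anchor shorten the matched stretch — and therefore the site's
duplex Tm, computed on the matched bases only — but do not veto the site.
The amplicon's annealing estimate is the minimum of the two site Tm
values (the limiting primer governs). Products are capped at 2000 bp and
filtered to a 30–80 °C annealing window. Amplicon size runs 5′-start to
5′-start inclusive of both primers, matching the designer's
`expected_size`, so size deltas between templates are directly
comparable.

A marker is **working** if on at least one template it yields (i) a
single putative amplicon, (ii) with annealing estimate ≥ 50 °C, and
(iii) |TmF − TmR| ≤ 3 °C; it is **putatively polymorphic** if it is
working and some template's unique product differs in size from the
expected product on the source sequence; otherwise **failed**.
Transferability to a related taxon is the percentage of markers with a
unique product on the target genome, optionally verified by requiring at
least three tandem copies of the marker's motif class (any rotation,
either strand) inside the amplicon.

## 4. Diversity statistics

For allele frequencies p at a locus (non-missing gene copies, two per
diploid call): Ne = 1/Σp², He (gene diversity) = 1 − Σp²,
PIC = 1 − Σp² − Σ\_{i<j} 2p²\_i p²\_j, I = −Σp ln p, and Ho is the
heterozygous fraction of non-missing calls. He is deliberately the
**plain frequency form** — the "gene diversity" printed by the common
marker-analysis software — because the shipped fixture was produced with
that convention; the (2n/(2n−1)) unbiased correction sits behind
`unbiased = TRUE`. Frequency classes use closed bounds: rare < 0.05,
intermediate [0.05, 0.50], abundant > 0.50.

Rarefied allelic richness is the exact hypergeometric form
Ar(g) = Σᵢ (1 − C(N−Nᵢ, g)/C(N, g)); the test suite verifies it against
exhaustive subsample enumeration for all copy-count vectors with N ≤ 12.
Private rarefied richness is the Kalinowski product-form estimator. The
standardised copy count g defaults to 2 × the smallest population size —
the convention of the usual rarefaction software; the source studies
rarely state their g, so the value used is recorded on the output. Loci
where any population has fewer than g copies are skipped for all
populations (common-g rule).

## 5. AMOVA and PhiPT

The default squared genotypic distance is the shared-allele form: per
locus d = 2 − (alleles shared between the two unordered diploid calls,
with multiplicity), summed over co-typed loci. The Smouse–Peakall
squared-Euclidean-on-allele-counts metric (per-locus values 0/1/2/3/4) is
available as `method = "euclidean"`. One-way sums of squares follow the
standard distance-based decomposition; negative Va is truncated to zero
and flagged; PhiPT = Va/(Va+Vw); the permutation p-value uses the +1
correction so it is never exactly zero.

A caveat established during development and encoded in the tests:
one-level AMOVA on diploid individuals estimates a genotypic-level
ratio — under a Balding–Nichols model with differentiation F its
expectation is 2F/(1+F), not F. Parameter-recovery tests therefore
compare PhiPT (euclidean metric) against a truth-frequency oracle of the
same estimand, Σ4·var\_j(p) / Σ(4·var\_j(p) + 2·mean\_j p(1−p)), rather
than against F itself. The shared-allele metric's PhiPT tracks yet
another functional of the frequencies; both metrics are exposed and the
default documented, since published analyses rarely state which was used.

## 6. Distances, UPGMA, structure

Nei's standard (1972) distance −ln(J\_xy/√(J\_x J\_y)) averages the
identity terms over loci; D\_A (1983) is 1 − mean Σ√(x y). The standard
form is default; which variant a given published analysis used is often
unrecoverable, so both are exposed. Disjoint profiles make the standard
distance infinite; it is reported as a configurable cap (default 10) with
a `capped` flag. Individual-level trees code each typed locus as
frequencies 0/0.5/1 from the two gene copies.

UPGMA is implemented directly (not via `hclust`) to control the tie rule:
among minimum-distance pairs, the pair whose sorted pair of cluster
labels is lexicographically smallest merges first, at height d/2, so
trees are reproducible even on degenerate (all-equal or zero) distances;
clone pairs form zero-height cherries. `ape` parses the emitted Newick,
and round-trips preserve cophenetic distances to 1e−9.

Structure inference codes genotypes as individuals × alleles copy counts
(0/1/2), imputes missing entries with column means, drops monomorphic
columns, and centers. `find_clusters` runs seeded K-means (10 restarts)
on the leading PCs (default: 95 % variance) for each K and selects the
minimum of BIC(K) = n·ln(WSS\_K/n) + K·ln(n). When the best BIC improves
on the smallest-K BIC by less than one unit the selection is flagged
`weak` — the expected outcome on panmictic data. A practical note from
development: with diffuse differentiation this BIC declines monotonically
in K at realistic sample sizes; a clean interior minimum appears when
populations differ by fixed differences, which is what the recovery tests
simulate. DAPC is linear discriminant analysis on the retained PCs (at
most K−1 axes; `n_pc < n − K` enforced as an overfit guard), with
Gaussian posterior memberships. The a-score subtracts the mean
reassignment rate under permuted labels from the observed one, penalising
over-retention of PCs.

## 7. What the synthetic generators emulate — and what they do not

* `simulate_reads` emulates an SSR-enriched single-pass sequencing run:
  a length distribution spanning ~29–677 bp with mean ~214 bp, an exact
  `round(fraction × n)` count of sub-80 bp rejects, i.i.d. background at
  configurable GC, and planted perfect SSRs. Background and flanks are
  rejection-sampled so no accidental Class I SSR occurs and junction
  bases cannot extend a planted run — the truth table is therefore exact,
  which is what makes 100 % recall/precision a meaningful assertion.
  **Not** modelled: sequencing error, homopolymer noise, chimeras,
  adapter remnants (the provider's trimming rule is unpublished). A green
  miner test certifies the detection logic, not robustness to noisy reads.
* `simulate_template_pair` builds two genomes whose loci differ by known
  repeat-count deltas (size shift = period × delta), can omit a locus, or
  can mutate one base inside the forward primer's terminal 9-mer — which
  by construction destroys the virtual-PCR anchor. Spacers avoid every
  primer anchor, so each designed pair amplifies uniquely; verdict tests
  can therefore assert recall/precision = 1 for polymorphism detection.
* `simulate_genotypes` is a Balding–Nichols model: per-population allele
  frequencies are Dirichlet(p(1−F)/F) around ancestral p (F = 0 uses p
  directly), genotypes follow Hardy–Weinberg within populations, missing
  calls are 0/0 (GenAlEx convention), and clones are exact row copies —
  matching vegetatively propagated landraces that show identical SSR
  profiles. **Not** modelled: linkage, null alleles, allele-size
  mutation processes, or isolation-by-distance.

## 8. Defaults, determinism, limitations

All stage defaults live in `pipeline_config()` and mirror the workflow's
canonical values (80 bp read filter; di 11/tri 7/tetra 6 with 21 bp
tract; 100 bp interruption; product 100–250 bp; k = 9; ≤ 2000 bp;
Ta ≥ 50 °C; |ΔTm| ≤ 3 °C; 1000 permutations; K = 2..20). Every stage
consumes an explicit seed and every output file carries the config hash
and seed; reruns are byte-identical.

Known limitations: no penta-/hexa-nucleotide repeats or alignment-based
imperfect-repeat detection; no thermodynamic mismatch corrections at the
PCR anchor; no hierarchical (multi-level) AMOVA — published analyses of
this kind run separate one-way decompositions, which is what is provided;
no bootstrap support on trees; and the structure module is
non-model-based by design (no Bayesian admixture inference).
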