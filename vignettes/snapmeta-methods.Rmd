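---
title: "Methods: mining a single metagenomic snapshot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining a single metagenomic snapshot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snapmeta)
```

A single deep shotgun library built from a complex environmental sample —
the motivating case is the fermented pollen–nectar larval food of
stingless bees — contains templates spanning several orders of magnitude
of abundance: a dominant fermenting bacterium, host organelles, food-plant
chloroplasts, and a long tail of trace taxa. `snapmeta` implements the
chain of small, explicit computations that turn one such dataset into
several genomic resources, and a simulator that generates every input
with known ground truth so each link of the chain can be validated.

## Representativeness scoring (SpM)

Given the tabular output of a nucleotide search of the assembled
scaffolds against a reference database, each candidate subject $s$
receives a weighted score

$$\mathrm{raw}(s) = \sum_{h \in \mathrm{hits}(s)} \mathrm{identity}(h)
\times \mathrm{length}(h), \qquad
\mathrm{share}(s) = \frac{\mathrm{raw}(s)}{\sum_{s'} \mathrm{raw}(s')}.$$

Only high-identity alignments enter the sum — the default filter is
$\geq 99.8\%$ identity, boundary inclusive, to focus on species-level
matches — and *every* retained alignment contributes, with no per-query
deduplication: a subject aligned repeatedly by one long scaffold really
is better represented in the assembly. Shares sum to 1, forming a
probability-like distribution over candidate references; the rank-1
subject becomes the reference for consensus assembly. Scoring is
invariant to hit order, to duplication of the whole hit list, and to any
common rescaling of identities (the normalization cancels it), and exact
ties are broken lexicographically by subject id so the selection is
deterministic. Whether an E-value cut should also precede SpM scoring is
genuinely open; the package applies none by default, keeping the identity
filter as the only retention rule, since the E-value threshold belongs to
the diversity analysis below.

## Best-hit diversity profiling

Biodiversity profiling uses a different retention rule: alignments with
E-value at most $10^{-10}$ (boundary inclusive; the threshold phrasing
does not settle strictness, and inclusivity is the conventional reading),
reduced to one best hit per scaffold — lowest E-value, ties by highest
bitscore, then first occurrence. Each assigned scaffold then casts one
vote for its subject's taxon at the chosen rank (genus, family, or
high-level group). One vote per scaffold, with no length or coverage
weighting, is the simplest counting unit consistent with best-hit
profiling; figures built from hit-level or length-weighted counts would
differ, and the package makes the unit explicit rather than asserting it
is the only choice. Subjects missing from the taxonomy map are kept as
`unassigned`, so counts always total the number of assigned scaffolds.
The match rate — assigned over total scaffolds — is reported alongside;
in diverse, under-databased environments it is typically low (on the
order of 10–15 %).

## Reference-guided consensus

The consensus module is a deliberately small, fully specified stand-in
for a production mapper + pileup caller (SMALT and bcftools in the
motivating workflow). Reads are placed by their first exact $k$-mer seed
($k = 15$ by default; $k \geq 11$ enforced) and extended without gaps;
the reverse complement is tried when the forward orientation fails; reads
with more than 10 % mismatches are left unmapped; multi-mapping seeds
resolve to the first reference occurrence, which is adequate for the
unique-region synthetic genomes it is validated on. The pileup counts
A/C/G/T support per position (read `N`s support nothing), and the
consensus takes the modal base wherever depth reaches `min_depth`
(default 1), writing `N` elsewhere. Count ties prefer the reference base
when it is among the tied set — the procedure refines a reference, so in
the absence of evidence against it the reference stands — else the
alphabetically first tied base. Substitutions only: no indels are
modelled anywhere in the package, a simplification consistent with a
coordinate-preserving consensus whose length equals the reference's
exactly. Validation is by parameter recovery: with error-free reads from
a donor genome up to 2 % diverged from the reference, the consensus
equals the donor at every covered site, and the number of `N`s equals the
number of positions below the depth cutoff.

## Assembly quality as an abundance signal

`gap_scan()` reports maximal runs of `N` as 0-based half-open intervals;
`assembly_qc()` adds the N percentage, gap-size statistics, and GC
content computed over non-N bases only (so gaps cannot dilute GC). The
completeness tier — near-complete below 0.5 % N, draft up to 10 %,
fragmented above, boundaries belonging to the worse tier — tracks
template abundance: abundant templates assemble nearly gap-free, scarce
ones fragment. The two boundaries are this package's own, chosen to
separate the reference exemplars (0.002 % and 23.47 % N) by more than an
order of magnitude on each side; they are configurable and carry no
claim beyond that. Report-level rounding is fixed so printed values are
reproducible: N % to two decimals, or three when below 0.01 %; mean gap
size to one decimal.

## Pollen diversity

For a count table of pollen types, richness $S$ counts all types
(unidentified "NI" types included — they are real, distinguishable
types), diversity is Shannon–Wiener $H' = -\sum_i p_i \ln p_i$ in nats,
and evenness is Pielou's $J = H'/\ln S$. The natural logarithm is the
package's fixed convention: with $S = 27$ and the published pair
$H' = 2.603$, $J = 0.789$, only base $e$ makes $H'/\ln S$ reproduce $J$
($2.603/\ln 27 = 0.790$), so no other base is offered. Tables may carry
raw grain counts or printed percentages; percentages are renormalized to
proportions before computing $H'$ (published tables sum to 100 only up to
rounding — the shipped transcription sums to 100.07 — and both the raw
and renormalized totals are kept). Recomputing $H'$ from rounded printed
percentages rather than raw grain counts shifts the third decimal
(2.606 vs 2.603 on the shipped table); the package documents this
discrepancy rather than resolving it, and its tests use a ±0.01
tolerance on $H'$ and ±0.005 on $J$. Family-level relative abundance
sums the per-type values without renormalization, so family totals
conserve the type total exactly.

## Species delineation

Two genomes are called distinct species when ANI falls below the band
(default `ani_low` = 95 %) or dDDH below 70 %, and the same species at or
above the band top (`ani_high` = 96 %) or at/above 70 % dDDH. ANI inside
[95, 96) is ambiguous on its own. The overall verdict combines whatever
measures are present: unanimous committal verdicts give `same` or
`distinct`, disagreement `conflict`, and no committal verdict
`ambiguous`. dDDH values are consumed as numbers computed elsewhere
(e.g. a genome-to-genome distance service); the package does not
reimplement that estimator.

The fragment-based ANI estimator exists for synthetic validation, not as
a FastANI replacement: the query is cut into non-overlapping fragments
(default 1000 bp), each placed on the subject by the same seed-and-extend
mapper, and ANI is the mean identity over fragments aligning with at
least 80 % of their length. The fragment-level mismatch cap is 0.30 —
looser than the read mapper's 0.10 — so that fragments from genomes
diverged up to the simulator's 30 % ceiling still align; a 0.10 cap
would silently discard the worse half of fragments at 10 % divergence
and bias the estimate upward. Validation is again parameter recovery:
for substitution rates $\mu \in \{0.01, 0.02, 0.05, 0.10\}$ on 100-kb
pairs, the estimate lands within one point of $(1-\mu) \times 100$, and
unrelated random genomes yield an explicit no-alignment result rather
than a number. A bidirectional mode reports both directions and their
range, mirroring how bidirectional ANI is usually quoted.

## The simulator and what it does (not) emulate

Every generator is a deterministic function of its parameters and seed
and emits ground truth beside its artifact: genomes (i.i.d. bases at a
target GC), mutated strains (per-site substitutions at rate $\mu$, true
ANI $(1-\mu)\times 100$), reads (uniform starts, both strands, optional
substitution errors), hit tables (exactly
`round(match_rate * n_scaffolds)` scaffolds receive hits; hit-bearing
scaffolds draw their taxon proportional to abundance; identities and
lengths from clipped normals shared across taxa, so per-taxon
identity×length mass is proportional to abundance; E-values are a
deterministic monotone function of bitscore — downstream logic needs
their ordering, not their statistics), gapped assemblies (N-runs of
exact sizes, non-adjacent, away from the ends, placed by a
stars-and-bars draw so tight packings remain feasible), and pollen
tables (multinomial grain counts, classically 800 grains).

The simulator deliberately omits much of real data: no indels, no
chimeras, no GC-coverage bias, no read-quality profiles, no conserved
regions shared between taxa, no database incompleteness structure.
Passing recovery tests therefore show the computations are correct under
their stated models — not that the pipeline is robust to artifacts such
as conserved-region misassignment in best-hit profiling, which real
studies must still inspect case by case.

Default study-scale conditions used by the tests: hit-table recovery
runs 200 communities of 1000 scaffolds (dominant taxon at 0.5 abundance,
at least twice the runner-up, ≥ 50 hits per taxon); consensus recovery
uses a 50-kb reference at ~3× read coverage; ANI recovery uses 100-kb
pairs with 10 replicates per rate. These sizes give the concentration
the recovery bounds rely on (binomial/multinomial standard errors well
inside the stated tolerances) while keeping the whole suite quick on a
laptop.

## Numerical and degenerate-input conventions

Shares and proportions are validated to sum to 1 within $10^{-9}$; an
empty retained-hit set raises a distinct "no retained hits" condition
rather than returning an empty table; an all-zero count table, an empty
sequence, and a richness below 2 for evenness are errors, not NAs.
External coordinates follow their formats (1-based inclusive in hit
tables), internal sequence intervals are 0-based half-open. Hit-table
serialization is canonical (fixed identity and E-value formats), so
write–read–write is byte-stable.
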