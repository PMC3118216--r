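---
title: "Seed-anchored motif discovery: models and methods"
author: "seedmotif authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-anchored motif discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedmotif)
```

# The problem

A transcription factor with a single experimentally characterized binding
site poses an awkward discovery problem: one site is far too little data to
build a binding model, yet a genome-wide search needs exactly such a model.
`seedmotif` implements an agglomerative answer. Starting from the one known
site — a fixed window at a fixed position in one promoter (the *anchor*) —
it repeatedly motif-samples the anchor promoter together with candidate
promoters, admits the candidate that best shares a motif sitting on the
anchor, and prunes unpromising candidates. The qualified set grows one
promoter per iteration; the final set yields the binding-site model, which
is then scanned genome-wide, and the hit genes are tested for Gene Ontology
term over-representation as a biological-relevance filter.

# Models

## Promoters

Promoters are TSS-relative windows, by default offsets $-250..+30$
(inclusive, no offset 0; 281 bp), oriented 5'→3' toward the gene. Where no
mapped TSS is available the strand-appropriate start of the coding span
stands in, and a TSS table can override it. Two layout rules apply:
divergently transcribed gene pairs whose intergenic gap is shorter than
500 bp share the entire gap as a single promoter attributed to both genes
(replacing their plain windows), and promoter intervals must not overlap —
residual overlaps are truncated at the midpoint of the overlapping stretch.
The midpoint rule is our resolution of an underdetermined constraint: it is
symmetric, so the result cannot depend on processing order. Whether the
shared divergent promoter should replace or supplement the windowed ones is
equally underdetermined; we replace, which keeps the no-overlap invariant
trivially true. All coordinates are 0-based half-open internally and
1-based inclusive only at GFF3/GenBank boundaries, so offset $-184$ of a
default window is sequence index 66 and the 20-mer anchor $-184..-165$ is
the half-open index interval $[66, 86)$.

## Motif and background

A motif of width $W$ is a position-specific probability matrix (PSPM)
$\theta$ with independent columns over $\{A,C,G,T\}$; columns are estimated
from aligned instances as $(c_{jb} + \kappa\,q_b)/(n + \kappa)$ with total
pseudocount $\kappa = 0.1$ spread by a base distribution $q$ (uniform by
default). Sequence not generated by the motif follows an order-$k$ Markov
background (default $k = 3$), trained on the given strand of the promoter
pool with one pseudocount per transition cell; reverse-strand scoring
reverse-complements the *segment*, never the model. A segment $x$ scores

$$\ln W(x) = \ln P(x \mid \theta) - \ln P(x \mid B),$$

and a motif's *ll score* is the sum of $\ln W$ over its instances — larger
for both sharper and more numerous occurrences. Segments containing `N` are
unscorable and are never candidates. All likelihood work uses natural logs;
information content alone is reported in bits.

## The site sampler

The Gibbs sampler holds at most one site per sequence. Visiting a sequence,
it rebuilds the PSPM from all other sequences' current sites, scores every
window on both strands, and resamples the sequence's site from a
two-component model with sequence-level prior $\pi$ (default 0.5): presence
probability $q = \pi m / (\pi m + 1 - \pi)$ with $m$ the mean candidate
weight, then position $i$ with probability $w_i / \sum_j w_j$. A run stops
after `sweeps_max` sweeps (default 100) or once the site configuration is
unchanged for `sweeps_stable` (default 5) consecutive sweeps, and the final
instance set is re-scored with the final PSPM. `sample_motif()` repeats
this from `runs` seeds (default 100, the production setting) and keeps the
highest-scoring motif, ties to the lowest seed.

Two design choices deserve comment.

*Canonical candidate order.* Candidates are sampled by inverse CDF in a
canonical order (descending weight, ties by segment string). Every random
choice thereby depends only on the multiset of candidate segments, which is
invariant under reverse-complementing the inputs: the same seed on
reverse-complemented sequences returns the same motif model (identical
PSPM and ll), the strongest form of strand-orientation stability.

*Phase-shift move.* After each sweep the sampler proposes sliding all
current sites coherently by up to ±3 positions in reading orientation and
greedily accepts the best-scoring shift. Site samplers without such a move
are well known to lock into registrations offset by a few bases from the
likelihood optimum; with only two sequences (the pair-wise stage below)
that trap is almost absorbing, so the move is essential rather than
cosmetic.

## Seed-anchored agglomeration

The qualified set starts as the seed promoter. Each iteration runs
`sample_motif` on qualified ∪ {candidate} for every pool candidate and
records (a) the motif's ll score and (b) its *anchored* score — the same
number if the motif places an instance on the seed's anchor window, none
otherwise. Then:

1. the candidate with the maximum anchored score wins and joins the
   qualified set; if even the winner fails to improve on the previous
   iteration's winning score, the procedure terminates;
2. candidates whose motif ll score falls below the 30th percentile (linear
   interpolation over this iteration's scores, all candidates) are pruned;
3. anchored candidates at or below the previous winning score are pruned.

Candidates that never anchor cannot win but stay in the pool until rule 2
removes them or the procedure ends. The percentile is computed within the
current iteration only. Per-candidate sampler seeds are derived by hashing
(master seed, iteration, candidate id), so results are independent of pool
order, and one background model trained on the initial pool serves the
whole procedure.

*Anchor tolerance.* By default an instance must coincide exactly with the
anchor window. `min_overlap` relaxes this to a minimum overlap fraction.
The relaxation matters statistically: two noisy instances drawn from the
same PSPM determine their common registration only up to a base or two —
with 95%-dominant columns, a ±1-shifted alignment of a specific instance
pair quite often outscores the exact one. Pair-wise anchoring at exact
coincidence is therefore not identifiable, and our synthetic recovery
experiments use `min_overlap = 0.75` (at width 20: at least 15 of 20 bases
on the anchor).

## Ranking, scanning, and GO qualification

Motifs from repeated executions are grouped by symmetrized,
column-averaged Kullback–Leibler distance, computed in the better of the
two orientations; motifs closer than 0.9 are one family, and families are
ordered by their best ll score. Genome scanning at prior $\pi = 0.7$
reports windows whose posterior $\pi w/(\pi w + 1 - \pi)$ exceeds 0.5 —
equivalently $w > (1-\pi)/\pi = 3/7$ — resolving same-strand overlaps
greedily by descending weight. Hits in promoters map to genes (a shared
divergent promoter contributes both genes); hits inside ORFs are reported
but excluded from enrichment study sets.

The qualification statistic is the exact hypergeometric upper tail
$P(X \ge x)$ for $x$ of $n$ study genes carrying a term against $M$ of $N$
population genes, after propagating annotations up the `is_a`/`part_of`
closure. Raw p-values are filtered at 0.1. The corrected p-value of a term
is $(1 + \#\{r: \min_t p_{rt} \le p\})/(R + 1)$ over $R$ simulated study
sets drawn uniformly without replacement (the $+1$ convention avoids zero
p-values and keeps corrected ≥ raw); the qualification threshold is 0.05,
and a motif qualifies iff at least one term passes. The FDR column is the
simulation estimate: the mean number of simulated terms per run at or
below the term's p, divided by the term's rank, as a percentage clamped to
$[0, 100]$. Terms annotating fewer than 2 population genes are reported but
never qualified (a stability guard). Table percentages are *truncated*,
not rounded, to two decimals — the convention the published tables force
(e.g. 22/154 → 14.28, 128/4339 → 2.94).

# The synthetic-data generators

Every stage is testable offline through three generators, all pure
functions of (parameters, seed) that emit machine-readable truth:

* `simulate_genome()` packs genes with a controlled fraction of divergent
  adjacent pairs (gaps 100–480 bp, so the shared-promoter rule fires) and
  wide clearances elsewhere (700 bp), writing FASTA + GFF3 + expected
  promoter intervals;
* `simulate_promoters()` draws background sequence from a Markov model and
  plants PSPM-sampled instances at controlled occupancy, position and
  strand. Planted instances default to 95%-dominant columns — the
  conservation level of a strong bacterial regulator box, and the
  recoverable regime the procedure assumes;
* `simulate_go_annotation()` writes a GAF and a two-level OBO stub in which
  one term is attached to target genes with one probability and to others
  with another, so both propagation and enrichment power/calibration are
  exercised.

What the generators do *not* emulate: real promoter composition beyond
order-3 Markov structure, overlapping/nested real operons, correlated GO
annotations, or MotifSampler's exact score normalization. A green suite
therefore demonstrates the machinery's correctness and the procedure's
statistical behavior under its own assumptions, not performance on any
particular genome.

# Numerical choices and problem sizes

Percentiles use linear interpolation between order statistics (type 7).
Argmax ties break to the lexicographically smallest id; restart ties to
the lowest seed. Degenerate inputs (all sequences shorter than the width,
zero instances, empty pools) raise typed errors or return the documented
degenerate values rather than guessing. The test and acceptance suites run
the sampler at 10–15 restarts with a 100-sweep budget on pools of up to 30
promoters of 281 bp and populations of a few hundred genes with 100–200
permutation runs — sizes at which the planted-signal experiments are
informative while the whole suite completes in minutes; the package
defaults (100 runs, 1000 permutations) remain the production setting.

# Known limitations

* The sampler is a heuristic optimizer: different seeds can return
  different local optima, which is why multi-restart selection and the
  seed-anchoring filter exist at all.
* Pair-wise iterations (the first steps of an agglomeration) carry the
  least information; exact-coincidence anchoring there is fragile, which
  `min_overlap` mitigates but does not remove.
* ll scores are internally consistent but not comparable to scores printed
  by other motif-sampling implementations, whose normalizations differ.
* The GO machinery reads GAF 2.x and minimal OBO (`is_a`, `part_of`);
  qualifiers beyond `NOT` and other relationship types are ignored.
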