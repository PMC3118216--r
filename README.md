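# seedmotif

Ab initio discovery of transcription-factor binding sites in a bacterial
genome, starting from a **single known site**.

Characterizing a regulator from one experimentally verified binding site is
a bootstrap problem: one site cannot parameterize a binding model, but a
genome-wide search needs one. `seedmotif` grows its way out of it. A known
site — a fixed 20-bp window at a fixed TSS-relative position of one
promoter, the *anchor* — seeds an iterative agglomeration: each round, a
both-strand Gibbs site sampler is run on the qualified promoters plus one
candidate at a time, the candidate whose shared motif scores best *while
placing an instance on the anchor* is admitted, and weak candidates are
pruned. The resulting motif is scanned genome-wide at a posterior-odds
threshold, and the hit genes are tested for Gene Ontology term
over-representation (exact hypergeometric test, permutation-corrected
p-values, simulation FDR) — the statistical filter that decides whether a
motif reflects a cis-regulatory signal or noise.

## The core statistic

A width-W motif is a position-specific probability matrix θ; background
sequence follows an order-3 Markov model B. A segment x scores the log
likelihood ratio

    ln W(x) = ln P(x | θ) − ln P(x | B)

and a motif's **ll score** is the sum over its occurrences — an index of
both conservation and abundance. The agglomeration admits, per iteration,
the candidate maximizing the anchored ll; prunes candidates below the 30th
percentile of the iteration's ll scores; and prunes anchored candidates
that fail to improve on the previous round. Scanning calls a hit where the
posterior π·W(x)/(π·W(x)+1−π) exceeds 0.5 (π = 0.7). A motif *qualifies*
if at least one GO term passes a raw-p filter of 0.1 and a corrected-p
threshold of 0.05 at 1000 permutation runs.

## Worked example

Everything runs offline on generated data; the generators emit ground
truth alongside every file.

```r
library(seedmotif)

# A background model and a well-conserved 20-bp site model
set.seed(1)
bg <- train_background(replicate(5, paste(sample(c("A","C","G","T"),
                                                 2000, TRUE), collapse = "")),
                       order = 3)
site <- build_pspm(rep("GCTATGCGGTTATTTGCACA", 8), pseudocount = 0.4)

# A seed promoter anchored at offsets -184..-165 (indices 66..85), five
# promoters carrying the same signal, and 24 of pure background
seedp <- simulate_promoters(1, 281, bg,
          plant = plant_spec(site, position_mode = "fixed", offset = 66),
          seed = 11)$seqs
names(seedp) <- "seedP"
carriers <- simulate_promoters(5, 281, bg,
          plant = plant_spec(site), seed = 12)$seqs
noise <- simulate_promoters(24, 281, bg, seed = 13)$seqs
names(carriers) <- paste0("hit", 1:5); names(noise) <- paste0("bgp", 1:24)

params <- agglomeration_params("seedP", c(66, 86), percentile_cut = 30,
            min_overlap = 0.75,
            sampler = sampler_params(runs = 15, width = 20))
res <- run_agglomeration(seedp, c(carriers, noise), params, global_seed = 7)
names(res$state$qualified)
#> [1] "seedP" "hit2"  "hit3"  "hit5"  "hit4"
res$motif
#> Motif: width 20  instances: 5  ll: 131.338
#>  consensus: TGTGCAAATAACCGCATAGC
```

The qualified set contains the seed plus four of the five planted carriers
and no background promoter (the percentile rule trims the tail of even the
true family once little else is left — see the methods vignette); the
final consensus is the planted site read on the opposite strand, since a
both-strand sampler reports a motif up to orientation. Scanning and
enrichment continue from there:

```r
hits <- scan_sequences(c(carriers, noise), res$motif$pspm, bg,
                       scan_params(prior = 0.7))
nrow(hits)          # promoter hits at posterior > 0.5
#> [1] 5
unique(hits$seq_id)
#> [1] "hit1" "hit2" "hit3" "hit4" "hit5"
```

with `attribute_hits()` mapping hits to genes through a `promoter_set` and
`enrichment_table()` producing the term table (corrected p, FDR%, x/n and
M/N counts with truncated percentages).

A thin command-line interface wraps the same functions
(`exec/seedmotif`): `extract-promoters`, `sample`, `agglomerate`, `scan`,
`enrich`, and `simulate genome|promoters|gaf`.

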