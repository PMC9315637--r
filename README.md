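# dilinet

Systems-pharmacology analysis of drug-induced liver injury (DILI) through
drug similarity networks.

## What it does, and for whom

Most drugs bind proteins beyond their intended target, and hepatotoxicity
can arise from any of those interactions. `dilinet` is for
pharmacologists and computational toxicologists who want to move from
drug-by-drug mechanistic studies to a cohort-level view: represent every
drug by its high-confidence protein targets and the Pfam domain families
those targets belong to, connect drugs that share target space, and ask
which groups of mechanistically similar drugs concentrate liver toxicity.

The pipeline:

1. **Filter** ChEMBL-style bioactivity records to direct, single-protein,
   potent interactions (pChEMBL ≥ 5, or exact Ki/IC50 ≤ 10 μM), with a
   full rejection audit.
2. **Profile** each drug as a set of target proteins, plus a set of Pfam
   domains found by exact binomial over-representation of its targets
   within each family (Benjamini–Hochberg corrected).
3. **Connect** each drug pair on two channels with the hypergeometric
   index `h = -log10 P(overlap >= observed)`; the two indices form a
   vector whose module α weighs the link and whose angle γ tells whether
   protein or domain evidence carries it. Pairs clear an index cutoff of 3
   (tail probability 10⁻³) to become edges.
4. **Characterise** the network topology: degree distribution against a
   discrete power law (maximum-likelihood fit, Kolmogorov–Smirnov
   bootstrap), nominal assortativity by toxicity class, greedy modularity,
   and degree-preserving rewired reference networks at the extremes of
   both ranges.
5. **Detect overlapping communities** by clustering links: single-linkage
   over edge–edge Tanimoto/Jaccard similarities, cut at maximum partition
   density, so one drug can belong to several mechanisms.
6. **Score** each community with the DILI score
   `round(100 (td + vtd) / d)` — `d` drugs, `td` hepatotoxic, `vtd`
   withdrawn-from-market (counted twice) — and annotate it with its
   dominant Pfam families, therapeutic categories, and over-representation
   of its link-defining targets against local GMT annotation sets.

A synthetic-cohort generator with planted target-sharing modules,
controllable noise and deliberately invalid records makes the whole
pipeline testable offline, with known ground truth.

## Worked example

```r
library(dilinet)

cohort <- generate_cohort(synth_config(seed = 1))   # 3 planted modules x 10 drugs
write_cohort(cohort, "cohort")

cfg <- run_config(drugs = "cohort/drugs.tsv",
                  activities = "cohort/activities.tsv",
                  domain_map = "cohort/domain_map.tsv",
                  out_dir = "out", n_bootstrap = 20, seed = 1)
res <- run_pipeline(cfg)

res$network
#> drug similarity network: 30 drugs, 117 links
res$partition
#> link communities: 3 (partition density D = 1, cut height 0.04093)
res$reports[, c("community_id", "d", "td", "vtd", "dili_score", "dominant_families")]
#>   community_id  d td vtd dili_score                       dominant_families
#> 1            1  9  8   1        100 PF00001,PF00002,PF00003,PF00004,PF00005
#> 2            2 10  5   0         50 PF00006,PF00007,PF00008,PF00009,PF00010
#> 3            3  9  1   0         11 PF00011,PF00012,PF00013,PF00014,PF00015
round(res$topology$assortativity_A, 3)
#> [1] 0.299
```

Reading the output: the detector found the three planted modules at
partition density 1 (each community is a clique in the similarity
network). The first community holds 8 hepatotoxic drugs — one of them
withdrawn, so it counts twice — among 9, giving a DILI score of
`round(100 * (8 + 1) / 9) = 100`; its five dominant Pfam families are
exactly the planted family of module 1. Toxicity was planted to
concentrate in the first module, and the network is accordingly
assortative (A = 0.299 > 0): hepatotoxic drugs link preferentially to each
other. Per-stage tables (kept activities, filter audit, profiles,
enrichment, edge/node tables, GraphML export, angle sweep, topology
summary, communities, memberships, reports) are written under `out/`.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/dilinet.R simulate --out cohort --seed 1
Rscript inst/cli/dilinet.R all --drugs cohort/drugs.tsv \
    --activities cohort/activities.tsv --domain-map cohort/domain_map.tsv \
    --out out --seed 1
```

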