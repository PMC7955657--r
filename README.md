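# peakfam

Unsupervised discovery of protein domain families from local pairwise
sequence alignments, via two rounds of Density Peak Clustering (DPC).

## The problem

Manually curated family databases (Pfam and friends) leave a large part of
the protein sequence space unannotated. Given only an all-against-database
table of local alignments (BLAST `-outfmt 6`), `peakfam` identifies
*putative families* — groups of homologous sequence regions — without any
supervision. Because proteins are multi-domain (two sequences can be nearly
identical over one region and unrelated elsewhere), the unit of clustering
is the **alignment**, not the sequence, and distances are computed from
alignment *boundaries*, never from scores.

## The method

An alignment is `B_i = (q_i, s_i, Q_i, S_i)`: query and search sequence
identifiers plus the aligned interval on each. Two DPC rounds follow.

**Primary clustering** (per query `q0`). Alignments of `q0` are compared by
the interval Jaccard distance on their query regions,

    d_ij = 1 − |Q_i ∩ Q_j| / |Q_i ∪ Q_j|  ∈ [0, 1],

a metric on residue sets. The local density `ρ_i` counts alignments within
`μ1 = 0.2` of `B_i`; the separation `δ_i` is the distance to the nearest
denser alignment (density ties resolved by rank order). Alignments are
ranked by `γ_i = ρ_i δ_i` and peaks are chosen by a multiplicative gap of at
least `10^Δ` (`Δ = 0.5`) in the ranked γ sequence, capped at `g_max = 20`.
Every alignment joins its nearest peak when closer than `μ1`; the resulting
*primary clusters* approximate the domain architecture of the query.

**Metaclustering** (across queries). Primary clusters `c`, `c0` are compared
through the search-sequence regions they share:

    D(c, c0) = 1 − M / min(N_c, N_c0),

where `M` counts one-to-one matched alignment pairs on the same search
sequence with region distance below `μ_d = 0.2`. DPC is applied again with
radius `μ2 = 0.9`; peaks must satisfy `δ_c = 1` and `ρ_c > 1`. Metaclusters
whose average cross distance falls below 0.9 are merged transitively, member
regions without a close same-sequence partner are filtered out, metaclusters
with fewer than 100 members are dropped, and membership is capped at 5000
(with 60%-identity, 1000-member seed sets exportable for MSA/profile-HMM
construction). Each surviving metacluster is a putative family.

**Evaluation.** To compare metaclusters against a reference classification
the package implements: overlap resolution of reference annotations (lowest
E-value wins, no nesting), ground-truth architectures (GTA) of member
regions, dominant architectures (DA), the consistency ladder
`%DAF ≤ %DAC ≤ %DACF ≤ %DACFA`, boundary scores `F_red`/`F_ext` with the
equivalent/reduced/extended/shifted categories, profile-hit coverage curves,
and normalized mutual information (NMI) for robustness comparisons.

**Synthetic benchmark.** A planted-truth simulator generates multi-domain
proteomes (families, architectures, linkers, fragments) and BLAST-like
alignment tables with controllable detection probability, boundary jitter
and noise, so the whole pipeline is testable end to end without databases.

## Worked example

Simulate a 60-protein proteome with three families in architectures
`-F1-`, `-F1-F2-`, `-F3-` (detection 0.9, jitter SD 3, noise 0.1/protein),
cluster it, and score the result against the planted annotations:

```sh
Rscript inst/scripts/peakfam simulate --out-dir fx --n-proteins 60 --seed 3
# [peakfam] 60 proteins, 1997 alignments -> fx
Rscript inst/scripts/peakfam cluster --alignments fx/alignments.tsv \
    --out-dir out --min-size 10
# [peakfam] 3 metaclusters, 1942 members -> out
Rscript inst/scripts/peakfam evaluate --annotations fx/annotations.tsv \
    --members out/mc_members.tsv --out out/report.tsv
```

The report (abridged) shows one metacluster per planted family, full
consistency and near-perfect boundaries:

| mc_id | size | avg_length | da_family | %DAF | %DACFA | F_red  | F_ext  | category   |
|-------|------|------------|-----------|------|--------|--------|--------|------------|
| 1     | 1306 | 83.7       | F1        | 100  | 100    | 0.030  | 0.026  | equivalent |
| 2     | 379  | 118.0      | F3        | 100  | 100    | 0.020  | 0.019  | equivalent |
| 3     | 257  | 90.4       | F2        | 100  | 100    | 0.029  | 0.022  | equivalent |

`size` counts member regions; `%DAF` is the fraction whose reference
architecture equals the metacluster's dominant architecture; `F_red`/`F_ext`
measure how much the members undershoot/overshoot the reference boundaries
(both ≈ the jitter scale here). The same run from R:

```r
library(peakfam)
pro <- simulate_proteome(benchmark_config(rng_seed = 3, n_proteins = 60))
aln <- simulate_alignments(pro)
run <- run_cluster(aln, clustering_params(min_size = 10))
run
#> peakfam run:
#>   1942 alignments on 60 queries ...
```

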