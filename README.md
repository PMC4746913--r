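# netter — structural re-ranking of gene regulatory network predictions

Network inference methods score every candidate regulatory link
`regulator -> target` from expression data and return a confidence
ranking. Those rankings are built from local association signals, so the
networks they imply rarely look like gene regulatory networks: indirect
effects let almost every gene "regulate" something, both directions of an
interaction sit side by side in the list, and the topology tends toward a
full mesh instead of sparse, modular, hub-dominated structure.

`netter` is a post-processor for such rankings. It extracts the top *x*
links and re-orders them — never adding or removing any — by minimizing

    f(l) = s(l) + α · Δ(l)

over rank permutations *l*, where `Δ(l) = Σ (orig_rank − new_rank)²`
anchors the result to the input prediction and the structural cost

    s(l) = Σ_i π_i · s_struct(g_i),   π_i = 0.5^i

evaluates nested prefix subnetworks `g_i` (the top `n, 2n, …` links)
through weighted v-shaped penalties `‖a·y + b‖` on three statistics: the
share of G4 star graphlets among connected 4-node graphlets (modularity /
hubs), the fraction of genes with outgoing links (regulator limiting), and
the largest out-degree over the link count (anti-domination). The
optimization runs as an ensemble of independent simulated-annealing
searches (auto-calibrated temperature, exponential cooling) whose outputs
are averaged rank-wise. An incremental C++ engine keeps the 3/4-node
graphlet census and all subnetwork statistics exact under single link
moves, which is what makes tens of thousands of iterations per run cheap.

The package also ships the edge-restricted AUROC/AUPR evaluation protocol
(gold standard intersected with the original top-*x*, so before/after
comparisons are fair) and a synthetic generator of modular, hub-containing
gold-standard networks with realistically corrupted prediction rankings,
so the whole pipeline is testable without external data.

## Worked example

Generate a synthetic 80-gene network, corrupt it into a noisy 200-link
prediction, re-rank with 10 annealing runs, and score before/after:

```r
library(netter)

fx  <- simulate_fixture(n_genes = 80, x = 200, seed = 104)
res <- netter_rerank(fx$prediction, x = 200, runs = 10, seed = 1,
                     anneal = anneal_config(iterations = 5000))
res
#> <netter_result> 200 links re-ranked over 10 runs; final divergence 37064

compare_rankings(res$initial, res$ranking, fx$gold)
#> <netter_comparison> AUPR 0.7516 -> 0.8117 (delta +0.0601), AUROC 0.7285 -> 0.7730 (delta +0.0446)
#>   top-75 overlap: 67 shared, TP 52 -> 58 (50 retained, 8/8 entrants true)
```

The AUPR of the prediction rises from 0.75 to 0.81 and the AUROC from 0.73
to 0.77, with the strongest gains at the top of the list: 75-link prefixes
of the two rankings share 67 links, and all 8 links that newly entered the
re-ranked prefix are true interactions. `res$ranking` holds the final
aggregated ranking (`rank` next to each link's `orig_rank`);
`write_ranking()` saves it as TSV.

A thin command-line wrapper covers the same pipeline from a shell
(`inst/exec/netter`):

```sh
netter simulate --genes 80 --top-x 200 --seed 104 --out-prefix fix
netter rerank --pred fix_prediction.tsv --top-x 200 --runs 10 --seed 1 \
              --out reranked.tsv --gold fix_gold.tsv
netter eval --pred fix_prediction.tsv --reranked reranked.tsv \
            --gold fix_gold.tsv --top-x 200
```

Defaults follow the published operating point (`x = 750`, `n = 25`,
penalty weights 25/2/75, `α = 1e−5`, `Γ = 50` links, `Θ = 70` positions,
30,000 iterations, 100 runs); everything is configurable in code or via a
YAML file (`read_netter_config()`). See the methods vignette
(`vignettes/reranking-methods.Rmd`) for the model, parameter rationale and
the design decisions.

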