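# nicheweb

Quadrat-survey niche analysis for plant communities along a degradation
gradient: species importance values, Levins niche breadth, pairwise niche
overlap, overlap-interval spectra, weighted niche-overlap networks with
modularity-based module detection, and species groups whose module
membership is stable across degradation stages.

The package is aimed at vegetation ecologists working with
space-for-time designs: repeated 1 m² quadrats sampled along a gradient
(e.g. healthy swamp wetland → wet meadow → dry meadow, labelled S1–S3),
with species composition, mean height, cover and abundance recorded per
quadrat. Raw quadrat data of this kind are frequently not deposited with the
papers that analyse them, so the package also ships a synthetic-community
generator with known niche structure (so every step of the chain can be
validated end to end) and a packaged species-by-stage reference table of
printed importance values, niche widths and module-group letters to verify
fixture-derivable quantities against.

## The indices

With utilization proportions `p_ij` (species *i*'s share of its utilization
in resource state *j*; the states are the quadrats, or transects, of one
stage) and `r` states:

* **Importance value** — IV_i = (relative height + relative cover +
  relative frequency)/3, where height and cover are species means over
  occupied quadrats and frequency is the fraction of quadrats occupied.
  Metrics are relativized to the stage maximum by default (`"max"`), or to
  the stage total (`"sum"`, IVs then sum to 1).
* **Levins niche breadth** — `B_i = 1 / Σ_j p_ij²`, from 1 (specialist) to
  `r` (perfect generalist); standardized form `(B−1)/(r−1)`.
* **Niche overlap** — Pianka: `O_ik = Σ_j p_ij p_kj / √(Σ_j p_ij² Σ_j
  p_kj²)` (symmetric, in [0, 1]); Levins: `O_ik = Σ_j p_ij p_kj / Σ_j
  p_ij²` (asymmetric). Overlaps are binned into the conventional `<0.3`,
  `0.3–0.8`, `>0.8` intervals.
* **Modularity** — weighted Newman–Girvan
  `Q = (1/2m) Σ_ik [A_ik − k_i k_k / 2m] δ(c_i, c_k)` on the overlap
  network, maximized by a deterministic CNM-style greedy agglomeration with
  local node-move refinement (plus a multilevel variant and an exhaustive
  exact search for ≤ 12-node graphs, used as an oracle in the tests).
* **Stable module groups** — maximal disjoint species sets in which every
  pair co-occurs in ≥ 2 stages and shares a module in every stage where
  both are present.

## Worked example

Verify the packaged reference table against its printed values:

```r
library(nicheweb)
verify_fixture()
#>                          check                    expected                    observed pass
#>                      n_species                          46                          46 TRUE
#>                       n_genera                          33                          33 TRUE
#>                   max_s1_width                        4.92                        4.92 TRUE
#>           max_s1_width_species         Triglochin palustre         Triglochin palustre TRUE
#>                max_s1_width_iv                        0.07                        0.07 TRUE
#>  triglochin_s1_s2_decrease_pct                       79.66                     79.6748 TRUE
#>  triglochin_s1_s3_decrease_pct                       40.70                     40.6504 TRUE
#>           stable_groups_a_to_e 5 groups: 7/6/2/2/2 members 5 groups: 7/6/2/2/2 members TRUE
#> all checks passed
```

The species with the widest S1 niche (4.92) has an importance value of only
0.07, and its width drops by 79.67 % to S2 and 40.65 % to S3 (computed from
the 2-d.p. table entries, hence the small differences from the printed
79.66 %/40.70 %). The five groups are the lettered stable modules: two
larger herb/grass assemblages (7 and 6 species) and three sedge–halophyte
pairs.

Run the whole chain on a synthetic three-stage degradation series (46
species, 54 quadrats/stage, stage homogenization 0.1 → 0.4 → 0.7):

```r
res <- run_pipeline(list(input = list(generate = list(seed = 1)), seed = 1))
res$classification
#>   stage n_pairs  pct_low  pct_mid   pct_high mean_overlap
#> 1    S1    1035 29.37198 69.75845  0.8695652    0.4214420
#> 2    S2    1035 11.59420 74.10628 14.2995169    0.5716152
#> 3    S3    1035  0.00000 35.55556 64.4444444    0.8190881
```

Mean pairwise Pianka overlap rises along the gradient (0.42 → 0.57 → 0.82
here) because each stage pulls every species' utilization profile toward a
shared optimum — the homogenization mechanism the generator uses to emulate
degradation. The low-overlap bin shrinks and the high-overlap bin grows, the
qualitative signature expected of a homogenizing gradient. Regression of
niche width on importance value over the reference table's S1 column gives

```r
tab <- load_species_table()
iv_width_regression(tab$iv_s1[tab$present_s1], tab$b_s1[tab$present_s1])
#> OLS fit (n = 27): y = 1.8706 + 4.1316 x,  R^2 = 0.3265
```

a positive but weak association — dominance is not the sole determinant of
niche breadth.

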