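# aasd — a genome-wide amino acid sequence divergence atlas

`aasd` screens a genome-wide set of single-copy orthogroups (SCOs) for
rapidly evolving genes — the signature of candidate sex-determining genes,
immune genes and other fast movers. It is aimed at comparative genomicists
who have per-orthogroup amino acid alignments (one protein per species per
gene) and want a cheap, reproducible divergence screen without inferring a
phylogeny for every gene.

## The statistic

Every orthogroup is summarised by its **amino acid sequence divergence
(AASD)**: the median over species pairs of the maximum-likelihood pairwise
distance

$$\hat t_{ab} \;=\; \arg\max_{t \in [0,\,t_{\max}]}
  \sum_{\text{shared columns}} \log\!\big(\pi_a\,P_{ab}(t)\big),
  \qquad P(t) = e^{Qt},$$

under the orthogroup's best-fit empirical substitution model
($Q_{ij} = S_{ij}\pi_j$, normalised to one expected substitution per site
per unit time; LG, WAG, JTT, Dayhoff and Blosum62 are bundled, any
PAML-format matrix loads from disk). The empirical distribution of
per-orthogroup medians is then partitioned by upper quantiles:

* **Group 1** — the top 1% of medians,
* **Group 2** — between the 1% and 5% upper quantiles,
* **Group 3** — everything else,

with Groups 1 and 2 jointly the *highly divergent* genes. Focal candidates
(e.g. Dmrt/Sox/Fox family members) can be held out of threshold estimation
and scored against the fixed cutoffs. The package also ships the
surrounding machinery: trimAl-style gap trimming and spurious-sequence
removal, species-occupancy filtering, neighbor-joining trees with
tip-to-tip (patristic) validation of the pairwise statistic, and a
synthetic-orthogroup generator with planted fast genes for calibration and
recovery testing.

## Worked example

Simulate a 300-gene study on 12 species with three planted fast genes
(rate multiplier 4), then run the full pipeline — filters, per-orthogroup
model selection, ML distances, medians, grouping, tree validation:

```r
library(aasd)

study <- generate_study(n_genes = 300, n_tips = 12, seed = 42)
fast  <- study$truth$orthogroup_id[study$truth$class == "fast"]

cfg <- aasd_config(candidates = c("LG", "WAG"), validate_n = 100,
                   focal_ids = setNames(rep("planted-fast", length(fast)), fast))
run <- run_pipeline(study, cfg)
run
#> <aasd_run> 300 retained / 300 orthogroups
#> <aasd_atlas> 300 orthogroups (297 in reference distribution)
#>   groups (q1=0.01, q2=0.05): 6 / 12 / 282
#>   median-AASD cutoffs: group1 >= 2.288, group2 >= 1.746
#>   tip-to-tip validation: r = 0.999 (n = 100)

run$flags
#> # A tibble: 3 × 6
#>   orthogroup_id family       median_aasd  rank group highly_divergent
#>   <chr>         <chr>              <dbl> <int> <int> <lgl>
#> 1 og0004        planted-fast        2.61     3     1 TRUE
#> 2 og0215        planted-fast        2.54     4     1 TRUE
#> 3 og0226        planted-fast        2.81     1     1 TRUE
```

All three planted fast genes land in Group 1: their median AASD (2.5–2.8
substitutions/site) clears the realized top-1% cutoff (2.288) estimated
from the 297 background genes, and the Pearson correlation between median
pairwise distance and median tip-to-tip NJ distance on a 100-orthogroup
subsample (r = 0.999) confirms the pairwise shortcut tracks the tree-based
measure. `tidy(run$atlas)`, `glance(run)` and `autoplot(run$atlas)` expose
the per-gene table, the one-row summary and the distribution plot;
`run$log` records why any orthogroup was dropped.

Real data enter the same way: point `run_pipeline()` at a directory of
per-orthogroup FASTA alignments (`run_pipeline("path/to/fastas", cfg)`).
A thin command-line wrapper with `simulate` and `full-run` subcommands is
installed at `inst/cli/aasd.R`.

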