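---
title: "The amino acid sequence divergence atlas: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The amino acid sequence divergence atlas: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Sex-determining genes, immune genes and other rapidly evolving loci tend to
stand out from the rest of the genome by the sheer amount of amino acid
change they have accumulated. Given a genome-wide set of single-copy
orthogroups (SCOs) — one aligned protein per species per gene — a cheap and
effective screen for such genes is to summarise every orthogroup by a single
divergence number, build the empirical distribution of those numbers, and
ask which genes sit in its upper tail. This package implements that screen
end to end: per-orthogroup maximum-likelihood (ML) pairwise amino acid
distances under empirical substitution models, the median-divergence summary
(the amino acid sequence divergence, AASD), upper-quantile classification
into divergence groups, and the supporting machinery (alignment filters,
neighbor-joining validation, and a synthetic-data generator with planted
fast genes for calibration).

## The model

Each empirical substitution model is a reversible 20-state Markov process
defined by a symmetric exchangeability matrix $S$ and stationary
frequencies $\pi$. The rate matrix is

$$Q_{ij} = S_{ij}\,\pi_j \quad (i \ne j), \qquad
  Q_{ii} = -\sum_{j \ne i} Q_{ij},$$

rescaled so that the expected substitution rate at stationarity,
$-\sum_i \pi_i Q_{ii}$, equals one. Branch lengths and distances are
therefore in expected substitutions per site. Transition probabilities are
$P(t) = e^{Qt}$, evaluated through the eigendecomposition of the
symmetrized matrix $\mathrm{diag}(\sqrt\pi)\,Q\,\mathrm{diag}(1/\sqrt\pi)$,
which is symmetric for reversible $Q$ and so has a real, numerically stable
spectrum; the decomposition is cached per model because the pipeline
evaluates $P(t)$ millions of times.

Five models ship as PAML-format files (LG, WAG, JTT, Dayhoff, Blosum62);
any other matrix in that format can be loaded from disk. Each model uses
its published stationary frequencies — no `+F` empirical-frequency
variants, and no rate-across-sites (`+G`) or invariant-sites (`+I`)
extensions. All bundled matrices then have the same number of free
parameters, which is what makes a pure likelihood ranking a valid
model-selection criterion (see below). Ambiguity codes (`B Z X J U O *`),
`.` and `-` are all treated as missing data: under a 20-state model they
carry no usable information, and treating them as gaps is the conservative
convention.

## Pairwise ML distances and the AASD statistic

For two aligned sequences the distance is the $t \in [0, t_{\max}]$
maximizing

$$\ell(t) = \sum_{\text{shared columns}} \log\big(\pi_a P_{ab}(t)\big),$$

where the sum runs over columns in which both sequences carry a residue.
Identical sequences give $t = 0$; if every shared column differs, the
likelihood is monotone up to the saturation cap and the estimate is
$t_{\max}$ (default 10 substitutions/site, which caps saturated pairs
without numerical overflow). Pairs sharing no residue-bearing column are
*masked* — reported as `NA` and excluded from all summaries — rather than
raised as errors, because trimmed empirical alignments occasionally produce
them and a single bad pair should not abort an orthogroup.

The optimizer is a bracketed Newton iteration on the analytic derivative
$\ell'(t)$, started from the equal-rates closed-form transform of the
observed mismatch proportion, with bisection fallback whenever a Newton
step leaves the bracket; convergence is declared at step sizes below
$10^{-9}$. Because $\pi_a P_{ab}(t) = \pi_b P_{ba}(t)$ for reversible
models, the implementation folds symmetric count cells together and the
estimate is exactly symmetric in its two arguments. The equal-rates model
(all $S_{ij}$ equal, uniform $\pi$) has the closed form
$\hat d = -\tfrac{19}{20}\log(1 - \tfrac{20}{19}\hat p)$, which the test
suite uses as an analytic oracle across $\hat p \in [0.01, 0.90]$; an
independent ML-distance implementation (phangorn's `dist.ml`) serves as a
cross-check on simulated alignments.

Per orthogroup, the best-fit model is chosen by maximizing the sum over
unordered pairs of the per-pair maximized log-likelihood. The canonical
tooling for this step fits a tree first and runs an information criterion;
this package deliberately scores pairs instead, because no tree is assumed
at this stage, the candidate matrices have equal parameter counts (so the
likelihood ranking is the information-criterion ranking), and the pairwise
score is exactly testable — a self-consistency test confirms that data
simulated under WAG select WAG against LG and JTT. Ties are broken
alphabetically. The orthogroup's AASD is then the median of the unmasked
upper-triangle entries of its distance matrix (midpoint convention for even
counts).

## Alignment filters

Three filters mirror standard practice for SCO alignments:

* **Gap-threshold trimming** (default 0.40): a column is kept iff the
  fraction of sequences with a residue in it is at least the threshold.
  The phrase "gap threshold of 40%" is ambiguous between "at least 40%
  residues" and "at most 40% gaps"; the former matches the trimAl `-gt`
  definition and is the default, the latter is available as
  `gap_rule = "max_gap_fraction"`.
* **Spurious-sequence removal** (defaults 0.5 / 50): a residue position is
  "good" iff at least half of the other sequences carry a residue in that
  column, and a sequence is removed iff fewer than 50% of its residue
  positions are good. This is a deliberate simplification of trimAl's
  `-resoverlap`/`-seqoverlap` rule: residue identity classes are ignored
  and any-residue overlap is used, which preserves the rule's intent while
  making it exactly enumerable in tests. Removal is decided in one pass on
  the original alignment, not iteratively.
* **Occupancy** (default half the study's species set, rounded up — e.g.
  17 of 34): orthogroups retaining fewer species after the first two
  filters are dropped, with the reason logged.

Trimming is idempotent and monotone in the threshold, and no filter ever
reorders rows or columns; these invariants are property-tested.

## Grouping and focal-gene flagging

Given $N$ orthogroup medians, entries are sorted by descending median with
ties broken by ascending orthogroup id (a stable, permutation-invariant
rule). The top $\lceil q_1 N \rceil$ entries form Group 1 (default
$q_1 = 0.01$), entries through rank $\lceil q_2 N \rceil$ form Group 2
(default $q_2 = 0.05$), and the rest Group 3; Groups 1 and 2 together are
the "highly divergent" genes. The rank-based ceil convention is chosen over
interpolated quantiles because it reproduces published genome-scale group
counts exactly (at $N = 11{,}192$ tie-free medians it gives
112/448/10,632) and it is well-defined under ties. The ceil is computed as
$\lceil qN - 10^{-9}\rceil$ because in binary floating point $0.01 \times
100$ is slightly above 1 and a naive ceiling would inflate the rank.
Whether the original upper-quantile boundaries were tie-inclusive is not
knowable from published counts alone; the stated rule is this package's
fixed convention.

Focal genes (e.g. candidate sex-determination families) can be held out of
threshold estimation and then scored against the realized cutoffs
(`exclude_focal = TRUE`, the default when a focal map is supplied). This
mirrors removing candidate genes from the reference distribution they are
judged against, and prevents a handful of extreme candidates from shifting
the thresholds they must clear.

## Validation against trees

The pairwise AASD is a shortcut: the fuller measure of divergence is the
median tip-to-tip (patristic) distance on a per-orthogroup phylogeny. The
pipeline validates the shortcut on a seeded subsample (default 200
orthogroups with fully unmasked matrices): it builds a neighbor-joining
tree from each orthogroup's ML distance matrix, computes median tip-to-tip
distances, and reports Pearson correlations (with t-transform p-values)
of the median pairwise distance against the tree medians and against the
alignment-length and species-count covariates. NJ stands in for full ML
tree inference deliberately — the validation needs a consistent tree
estimate, and NJ is exactly testable: on additive matrices it reproduces
the input path metric to $10^{-10}$, which the suite checks on random
5–8-taxon instances. Negative NJ branch lengths are clamped to zero with
the deficit moved to the sister branch (preserving the joined pair's path
length), and Q-criterion ties break deterministically in scan order.
Zero-variance inputs yield a flagged undefined correlation rather than an
error.

## The synthetic-orthogroup generator

Real SCO datasets are observational; no generative description of them
exists. The generator therefore emulates only the statistical structure
the atlas machinery relies on, with every parameter an explicit,
documented choice:

* a shared pure-birth species tree rescaled to mean root-to-tip depth 0.5
  substitutions/site (tree shape does not enter any downstream formula;
  pure-birth is the parameter-light choice);
* per-gene rate multipliers $\rho$, log-normal$(0, 0.4)$ for the
  background — a moderately right-skewed genome-wide rate spread, roughly
  an order of magnitude between the 1st and 99th percentile, and only the
  rank structure matters for quantile grouping — with a rare fast class
  (default 1% of genes) multiplied by 4;
* site-independent sequence evolution down the tree from a stationary
  root draw, alignment lengths uniform on 120–600;
* per-gene taxon dropout (default 0.1, resampled until at least 3 taxa
  survive) and Poisson gap blocks (default rate 1 per sequence, geometric
  lengths of mean 10) to exercise the filters.

The default study — 34 species, 1,000 genes, 10 planted fast genes — is a
desk-scale mirror of a genome-wide SCO analysis. A truth table records
each gene's $\rho$, class, length and retained species for recovery tests.

What the generator does *not* emulate: insertion–deletion evolution (gaps
are injected post hoc, not evolved), among-site rate heterogeneity within
a gene, codon structure and selection, paralogy, and model misspecification
across genes (all genes share one generating matrix). Passing recovery
tests therefore show that the machinery does what it claims under its own
assumptions — they do not show that real genomes satisfy those
assumptions.

## Numerical and testing choices

Problem sizes in the test suite are chosen to exercise every claim at
desk scale: closed-form oracles run at alignment length 1,000 across 90
mismatch proportions; estimator-consistency checks use length $10^5$
(mean recovery within 2% for true distances up to 2); the tip-to-tip
validation analogue uses 200 orthogroups of 34 species and checks
Pearson $r \ge 0.84$; planted-gene recovery uses 20 seeded replicates of
the 1,000-gene default study (at least 8 of 10 fast genes flagged in at
least 90% of replicates) plus a smaller multiplier sweep
($\rho$-multiplier 1, 2, 4, 8) confirming the flag rate is monotone. All
randomness flows from named integer seeds; reruns are byte-identical.

## Limitations

The AASD measures accumulated divergence, not rate: it conflates rate and
time where lineages sample different species subsets. Distances are capped
at $t_{\max}$, so extremely saturated orthogroups compress at the top of
the scale. Model selection among equal-parameter empirical matrices cannot
detect that none of the candidates fit. And the quantile groups are
relative by construction — a genome where nothing evolves fast still has a
Group 1. Interpreting flagged genes requires the biological context the
package deliberately stays out of.
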