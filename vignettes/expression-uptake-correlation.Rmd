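---
title: "Methods: expression-uptake correlation for transporter deorphanization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-uptake correlation for transporter deorphanization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Filamentous fungi encode dozens of putative sugar transporters, most of
which have no known substrate. Wet-lab deorphanization (heterologous
expression, knockout growth assays) is slow, so a screening strategy is
needed that narrows the candidate list cheaply. The strategy implemented
here exploits a simple observation: if a transporter carries a sugar and is
regulated transcriptionally, then across a panel of induction conditions
the measured uptake rate of that sugar should rise and fall with the
transporter's expression. Jointly clustering uptake-rate profiles with gene
expression profiles over the *same* conditions therefore places sugars next
to their transporters, and the per-gene Pearson correlation with a sugar's
uptake profile gives a ranked candidate list.

```{r, eval = FALSE}
library(transportome)
cfg <- pipeline_config(noise_cv = 0.1, seed = 1)
res <- run_pipeline(cfg, "run_out")
res$rankings$lactose[1:3, ]
```

## The model and its assumptions

Let $E(g, c)$ be the expression of transporter gene $g$ under induction
condition $c$, and $U(s, c)$ the uptake rate of sugar $s$ under the same
condition. The working model is additive:

$$U(s, c) \;=\; \sum_t A(t, s)\, \mathrm{act}(t, c),$$

where $A(t, s) \ge 0$ is transporter $t$'s capacity for sugar $s$ per unit
expression and $\mathrm{act}(t, c)$ is its realized activity — equal to
$E(t, c)$ for transcriptionally coupled transporters. Three structural
consequences drive both the method and its failure modes:

* **Dedicated transport.** If one transporter dominates $A(\cdot, s)$, then
  $U(s, \cdot) \propto E(t, \cdot)$ and the Pearson correlation is 1 up to
  noise: the candidate is found at rank 1.
* **Functional redundancy.** If two transporters with different induction
  patterns share a sugar, the uptake profile is their *sum*; each
  individual gene correlates imperfectly while the summed profile
  correlates perfectly. Candidates then appear as a cluster rather than a
  single top hit.
* **Expression decoupling.** A transporter regulated
  post-transcriptionally (constant activity regardless of expression)
  produces measurable uptake that tracks *no* gene's expression. The
  report flags such sugars as decoupling suspects (maximum gene correlation
  below a threshold despite nonzero uptake) rather than returning a
  spurious candidate.

The analysis assumes (i) uptake and expression are measured under matched,
aligned conditions; (ii) a 4-hour induction snapshot is representative, so
expression is a per-condition constant rather than a dynamic trajectory;
(iii) depletion over the rate window is approximately linear.

## Pipeline stages and key parameters

**Uptake rates** are reduced from supernatant depletion time courses by the
two-point formula over the window $[0, t_{end}]$ (default 15 min):
$\mathrm{rate} = (C(0) - C(t_{end}))\,V \cdot 1000 / (t_{end}\,DW)$ with
$C$ in µM, $V$ in litres, $DW$ in mg, giving nmol·min⁻¹·mg DW⁻¹. The unit
is a package choice (documented, not dictated by the assay); the two-point
reduction rather than a regression over all time points matches the
measurement protocol the method was designed around, and longer time
courses are used only for %-remaining curves. Negative raw rates (possible
for non-transported sugars when evaporation or measurement error exceeds
uptake) are preserved and flagged in the assay record but clipped to zero
when aggregated, preventing artifactual negative correlations while keeping
provenance. Replicates (typically 3) are combined by the arithmetic mean.

**Transforms.** Both blocks are log2-transformed with pseudocount 1 (zero
maps to zero; the base is irrelevant to Pearson correlation but fixed for
exported matrices) and row-standardized with the sample (n−1) standard
deviation. Constant rows — constitutively expressed or never-induced genes
— cannot be z-scored; they are mapped to all-zero rows and *flagged, never
dropped*, so weakly expressed genes survive into the final report.
"Normalization" is configurable (`zscore`/`none`) because it is inert for
correlations but visible in exported matrices.

**Joint clustering.** Distance is $d = 1 - r$ (range $[0, 2]$); pairs
involving a constant row take $d = 1$, i.e. $r$ treated as 0. Clustering is
agglomerative with unweighted average linkage (UPGMA) by default — the
standard choice for profile clustering and the default in the interactive
tools this replaces — with `complete` and `single` exposed. Ties on the
minimal inter-cluster distance are broken by the lexicographically smallest
cluster-index pair, which makes the dendrogram bit-reproducible across
platforms. The flat cut defaults to $k = 5$ clusters; no principled cut
criterion exists for this analysis, so $k$ is a parameter, and the
per-sugar rankings do not depend on it (it only annotates co-membership).

**qPCR.** Relative expression uses the 2^−ΔΔCt scheme: per-sample
ΔCt = mean target Ct − mean reference Ct over technical triplicates, ΔΔCt
between treatment and calibrator group means, fold change $2^{-\Delta\Delta
Ct}$. Standard errors are computed on the ΔCt scale (sample sd, n−1), not
on the exponentiated fold. Amplification-efficiency correction is out of
scope.

**Phylogenetics.** Distances between aligned amino-acid sequences use
pairwise deletion (sites with `-` or `X` in either sequence are excluded
per pair; `X` is treated as missing because the data contain ambiguous
residues and no convention is imposed by the distance model) and the
Poisson multiple-hit correction $d = -\ln(1 - p)$. Saturated pairs
($p \ge 0.99$) are capped at $-\ln(0.01)$ and flagged rather than erroring:
a diverse transporter set will contain saturated pairs and the tree should
still build. Trees are built by canonical neighbor joining (Q-criterion,
standard branch-length formulas); negative branch-length estimates are
clamped to zero without transferring length to adjacent edges — the
simplest documented convention, affecting lengths only, never topology.
Bootstrap support resamples alignment columns, rebuilds the tree, and
scores each internal edge of the *original* tree by the fraction of
replicates containing the same leaf bipartition (classical bootstrap on the
displayed tree, not a consensus tree). Replicates in which a pair loses all
overlapping sites are skipped and removed from the denominator.

**Clade assignment** formalizes what is usually done by eye: a query leaf
is assigned to clade X when its smallest enclosing clade-pure subtree (a
side of a tree edge containing the query and only clade-X references, with
subtending-edge support ≥ 0.5 by default) exists and is unambiguous. When
several minimal pure subtrees disagree — the situation of a query attached
to the backbone between clades — the query is reported `unplaced`. This is
one defensible rule, labelled as such; it is not claimed to be the rule
used in any particular published figure.

**Group statistics** follow the replicate-assay decision procedure:
Shapiro–Wilk on each group, Student (equal-variance, not Welch — matching
the stated procedure wording) t-test when both pass, Mann–Whitney U
otherwise (exact for combined n ≤ 20 without ties, normal approximation
with tie correction otherwise); for ≥3 groups, one-way ANOVA with Tukey HSD
and an insert-and-absorb compact letter display. Groups with zero variance
cannot be Shapiro-tested and are routed to the rank test, except the fully
degenerate equal-constant case which is reported directly as p = 1.

## What the simulator emulates — and what it does not

`preset_neurospora_like()` builds a 44-transporter × 10-sugar × 15-condition
scenario shaped like the filamentous-fungus setting: a no-carbon control, a
repressing sucrose condition under which non-exempt transporters are
multiplied by a carbon-catabolite-repression factor of 0.2 (one glucose
transporter is exempt, mirroring known exceptions), mono- and
polysaccharide inducers, fold-induction of 20 over basal on a gene's
inducing conditions, a constitutively high gene and a never-induced weak
gene (exercising constant-row handling), functional redundancy (two
cellodextrin-type transporters sharing cellobiose, mannobiose and lactose,
plus a minor lactose/galactose contributor induced by arabinose and
galactose), and optionally an expression-decoupled rhamnose transporter
with constant activity. Observation noise is multiplicative lognormal with
mean 1; the default CV of 0.1 is a free choice (replicate-level variances
for such assays are rarely published) and is exposed in the configuration.
Lognormal noise was chosen because depletion measurements are positive and
their error scales with signal; Ct noise is additive Gaussian on the Ct
scale for the same reason in reverse. Expression itself is noise-free in
the simulator: the target of inference is the uptake-expression coupling,
and putting all observation noise on the uptake side keeps the recovery
benchmark interpretable.

The simulator deliberately omits: Michaelis–Menten saturation (rates are
linear in activity), intracellular metabolism and growth feedback,
condition-to-condition correlation of noise, and dynamic expression within
the induction window. Passing tests therefore demonstrate that the
*inference machinery* is correct under the stated additive model — they do
not demonstrate that real uptake is additive, nor that real noise is
lognormal. On real data the method's resolution degrades exactly where the
redundancy and decoupling scenarios show it must.

Assays are simulated with 3 mL volume, 2 mg dry weight, and 3 biological
replicates per cell. The default starting concentration of 100 µM matches
the assay protocol; simulation-based round-trip tests raise it so that no
cell depletes within the window (a depleted cell floors at zero
concentration and is flagged rather than extrapolated).

## Numerical choices and degenerate inputs

* Time points are matched to 1e-6 min; the rate window requires exact
  presence of 0 and $t_{end}$.
* Round trips (simulate → assays → rates) are exact to < 1e-9 at zero
  noise; tests assert this.
* Correlation of constant profiles is undefined: reported as `NA` in
  rankings (ranked last), distance 1 in the matrix, flagged throughout.
* Merge heights under average linkage are checked to be nondecreasing; a
  violation (impossible for a true dissimilarity) aborts rather than
  silently producing a crossing dendrogram.
* NJ with n = 2 returns the single-edge tree (length split evenly for
  representation); n = 3 uses the closed three-point formulas.
* Newick branch lengths are printed at 15 significant digits, so
  write → read → write is idempotent and additive-tree recovery holds to
  1e-9.

## Problem sizes used in the test-suite benchmarks

The packaged checks run at sizes chosen to exercise every code path while
keeping the suite quick on a laptop: 100 random additive trees of 4–10
taxa for NJ consistency; 100 random 8×8 dissimilarities against a
brute-force re-scan oracle for the clustering; 20 simulation seeds at
noise CV 0.1 (and one noise-free run) for assignment recovery on the full
44 × 10 × 15 preset; 1000 bootstrap replicates on a 10-taxon, 200-site
alignment; 2000 null replicates for the type-I error of the two-group
procedure. `scripts/acceptance.R` recomputes all of these from scratch.

## Known limitations

* Ranking is purely correlative; no deconvolution or regression of uptake
  onto multiple transporters is attempted, so redundant transporters are
  found as a cluster, not with individual effect sizes.
* The decoupling-suspect flag thresholds the maximum gene correlation at
  0.5 (configurable). For a pure-noise uptake profile over ~44 genes and 15
  conditions the maximum spurious correlation sits near this threshold, so
  the flag is a screening aid with appreciable false-negative rate at the
  default, not a test.
* Clade assignment depends on bootstrap support of the subtending edge;
  poorly supported backbones push queries to `unplaced` by design.
* Significance of individual sugar-gene correlations is intentionally not
  computed: with 15 shared conditions the profiles are short, and the
  method's output is a ranking to be validated experimentally.
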