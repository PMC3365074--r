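---
title: "Inferring dynamic regulatory networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring dynamic regulatory networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynregnet)
```

# The problem

A perturbation time-course experiment measures gene expression in a
treated and a control arm at a few timepoints with a handful of
replicates. The transcription factors (TFs) driving the response are
often not themselves strongly differential at the mRNA level: their
*activity* (post-translational state, localization, cofactor binding) is
the latent quantity of interest. `dynregnet` reconstructs that hidden
layer and the pathway-level interactions around it from three standard
inputs: the expression matrix, a TF-to-target connectivity prior, and a
protein--protein interaction (PPI) network with pathway gene sets.

# Network component analysis

## Model

Under a log-linear model of transcriptional control, the log-ratio
expression of gene $i$ at condition $t$ relative to a reference is a
weighted sum of TF activities:

$$ E = A\,P, \qquad
   E \in \mathbb{R}^{N \times M},\;
   A \in \mathbb{R}^{N \times L},\;
   P \in \mathbb{R}^{L \times M}, $$

where $A$ holds the *control strengths* (the influence of TF $j$ on gene
$i$) and $P$ the TF *activities* over the $M$ conditions. Crucially $A$
is constrained to a known zero-pattern: $a_{ij} = 0$ unless the
connectivity prior allows TF $j$ to regulate gene $i$. The fit minimizes
$\lVert E - AP \rVert_F^2$ subject to that support constraint
(`fit_nca()`).

The decomposition is unique -- up to a per-TF diagonal rescaling -- when
the classical identifiability criteria hold: (i) the support pattern of
$A$ has full column rank; (ii) removing any TF together with all of its
targets leaves a pattern of full column rank; (iii) $P$ has full row
rank. `check_identifiability()` evaluates (i) and (ii) as *generic* rank
(the rank of a random instantiation on the support, which equals the
pattern's maximal rank with probability one; three seeds are used and
the result is verified against an exhaustive matching oracle in the test
suite). For (iii) the only data-free necessary condition is
$M \ge L$, and that is what the report states.

## Criterion (iii) is advisory, not blocking

A deliberate design choice: `fit_nca()` *refuses* to run when the
structural criteria (i)/(ii) fail, but only *warns* when $M < L$. Time
courses are short -- four to six conditions against tens of TFs is the
normal regime -- and supports in which every TF has private targets
remain identifiable per TF (each TF's activity is determined, up to
scale, by the rows of its own targets). Refusing to fit would rule out
the method's primary use case. For the same reason
`reduce_to_identifiable()` takes `enforce_iii` (default `TRUE`,
following the strict reading; the pipeline passes `FALSE`).

## Fitting

Alternating least squares, the natural algorithm for a bilinear problem
with a linear constraint pattern:

* given $P$, each gene's supported strengths solve an ordinary
  least-squares problem against the rows of $P$ its support indexes
  (genes with identical support signatures are solved as one block);
* given $A$, $P$ is the unconstrained least-squares solution.

Each step can only lower the objective, so the objective trace is
monotonically non-increasing (asserted in tests at every iteration).
Convergence is declared on relative objective decrease below `tol`
(default `1e-8`, on the scale of double-precision residual noise for
these problem sizes) rather than on parameter change, since parameters
are only determined up to the diagonal rescaling anyway. `max_iter`
defaults to 2000; the generator's instances converge in tens of
iterations. Because the objective is non-convex, the fit restarts from
`n_restarts = 10` seeded random initializations ($P$ initialized from
the pseudo-inverse of a random on-support $A$) and keeps the best final
objective. Singular subproblems fall back to a tiny ridge
($\lambda = 10^{-10}$) with a warning.

The diagonal ambiguity is fixed by `normalize_result()`: the default
`unit_max_activity` convention rescales each TF to peak $|$activity$|$
1, with the sign chosen so the activity correlates non-negatively with
the TF's own expression log-ratio when available (otherwise first
non-zero entry positive). The operation leaves the objective untouched
and is idempotent. Uncertainty comes from a gene-resampling bootstrap
(`bootstrap_nca()`): resampling the few conditions would be meaningless
at $M \le 6$, so rows are resampled, each resample is re-checked for
structural identifiability (failing draws are redrawn and counted), and
every refit is aligned by the normalization convention before
percentiles are taken.

# Differential expression

`moderated_t()` is an empirical-Bayes moderated two-sample $t$: gene
variances (pooled over the arms) are shrunk toward a prior variance
$s_0^2$ with prior degrees of freedom $d_0$, both estimated by moment
matching of $\log s^2$ against its scaled-$F$ sampling distribution, and
the statistic is referred to $t_{d + d_0}$. With $d_0 = 0$ it reduces
exactly to the ordinary pooled $t$; the test suite also verifies
agreement with limma's implementation to near machine precision on a
heteroscedastic fixture. Fold change is the difference of arm means on
the log2 scale -- the replicate design has no covariates, so a fitted
coefficient would be identical.

Gene selection (`select_degs()`) uses the conventional microarray rule:
linear fold change above 1.5 *in either direction* (the response
involves both activated and deactivated regulators), raw $p < 0.05$, and
the predicate must hold in **more than one** time stage. Raw p-values
are deliberate -- the rule mirrors common practice for this assay class
-- and selection is provably monotone in both thresholds.

# Connectivity priors

`load_prior()` reads a TF--target edge list, keeping self-regulation and
TF--TF edges and collapsing duplicates. `augment_by_clustering()` adds
data-driven candidate edges: TFs and candidate targets are clustered on
the correlation distance $1 - |r|$ (average linkage, matching the
magnitude-based threshold), each TF's candidates are the genes sharing
its cluster when the tree is cut at height $1 - r_{\text{thr}}$, and a
pair is kept only if its pairwise $|r|$ exceeds the threshold (default
0.8), with the correlation sign recorded. The subtree rule is one
reading of "genes in the TF's subtree"; since every emitted pair must
independently pass the pairwise $|r|$ filter, the cut height only
controls how many candidates are examined, not the guarantee on what is
added. Signs are annotations: the decomposition estimates strengths
freely and reports their signs as outputs.

`reduce_to_identifiable()` prunes greedily: duplicate target sets are
collapsed first, then the dependent TF with the fewest targets is
dropped (dependence located by pivoted QR on a random instantiation)
until the checker passes; the result is a subset of the input and a
fixed point of the procedure.

# Pathway enrichment

Over-representation of the selected genes in each pathway uses the exact
hypergeometric upper tail ($p = P(X \ge k)$, via `phyper`; the test
suite checks it against exhaustive enumeration on universes up to 25).
Pathways are reported when at least two selected genes overlap and
raw $p < 0.1$. The background universe defaults to the union of the
pathway file restricted to the measured genes -- the study-level
background is a configuration choice, not something the method can
infer.

# Pathway crosstalk

Each PPI edge $(x, y)$ receives a score combining three p-values: the
differential-expression p-values of the endpoints and the two-sided
p-value of their Pearson correlation across the stage's samples,

$$ S(e) = -2\bigl(\ln p_1 + \ln p_2 + \ln p_3\bigr), $$

Fisher's combination with $k = 3$. Fisher is used because the scoring
role calls for a general combination that is monotone in each source and
handles sources of different power; Stouffer's $Z$ is available as an
alternative (`method = "stouffer"`) and the choice is recorded in the
network object. P-values of zero are floored at the smallest positive
double with a warning, keeping scores finite.

The interaction of pathways $P_i, P_j$ sums $S(e)$ over their overlap
$O_{ij}$: edges with one endpoint in each pathway, in either
orientation, counted once -- including edges lying wholly inside
$P_i \cap P_j$, since shared genes are precisely where crosstalk is
expected to concentrate. Significance comes from a permutation null:
$B$ draws of two random gene sets of the same sizes from the sampling
universe (default in `crosstalk_dynamics()`: genes in at least one
pathway that are in the network, i.e. the pathway-covered subnetwork;
configurable to all network nodes), with the add-one estimator
$p = (1 + \#\{C_b \ge C\})/(B + 1)$, so $p$ is never exactly 0 and a
pair with empty observed overlap is reported directly with $p = 1$.
`B` defaults to 10^4-scale values for desk use and is a plain argument
when the full 10^6 is wanted. Stage-wise dynamics reuse one derived
seed per pair across stages, so identical data at two stages gives
identical p-values.

Two caveats the tests make explicit. First, permutation p-values are
discrete (a grid of $(B+1)$ values with an atom at 1 from empty
overlaps), so Kolmogorov--Smirnov uniformity checks against a continuous
uniform are approximate, and p-values across pairs sharing a pathway are
correlated. Second, the Fisher score is heavy-tailed in the node
p-values: one edge touching a strongly differential gene can outscore
dozens of background-weight edges. C-score *rankings* across pairs
therefore mix topological enrichment with differential-expression
content -- which is the method's point on real data, but means a pure
topology benchmark must switch the expression signal off (see below).

# The synthetic-data generator

`simulate_study()` produces every input with the structure the analysis
assumes, and nothing else:

* **Connectivity** (`generate_connectivity()`): each TF gets one private
  anchor target plus pool targets dealt round-robin. The anchors embed
  an identity submatrix in the support, so criteria (i) and (ii) hold by
  construction -- generated priors are identifiable by design, which the
  tests then verify through the checker rather than assume.
* **Activities** (`generate_tfa_profiles()`): TFs are assigned early /
  mid / late phases; profiles are piecewise-linear triangular peaks at
  the first, middle or last non-zero timepoint, zero at $t = 0$, random
  sign, mild amplitude jitter. Peak shapes are deliberately
  non-parametric: phases are a qualitative notion and any kinetic model
  would add unidentifiable structure.
* **Expression** (`generate_expression()`): treated log2 expression is
  baseline + $A_{\text{true}}P_{\text{true}}$ + $N(0, \sigma)$; the
  control arm is baseline + noise; baselines are drawn once per gene so
  fold changes are well defined; both arms share the noise model,
  matching the symmetric replicate design (3 per arm per timepoint at
  0/4/12/24 h by default). At $\sigma = 0$ the log-ratio matrix equals
  $A_{\text{true}}P_{\text{true}}$ to machine precision. The default
  $\sigma = 0.1$ (log2) is a typical within-replicate scatter for
  two-channel microarray ratios; it is a free parameter, not calibrated
  to any particular platform. Genes whose true effect clears both
  $\log_2 1.5$ and $4\sigma$ in at least two stages are recorded as
  planted DEGs.
* **PPI + pathways** (`generate_ppi_pathways()`): uniform background
  edges at `edge_prob`; pathways either overlap by chance (default) or
  partition a gene sample (`disjoint = TRUE`); for each planted pathway
  pair the cross-pathway edge probability is multiplied by
  `cross_edge_boost` (clamped at 1 with a warning).

What the generator does *not* emulate: probe-level artifacts,
normalization residue, batch effects, correlated noise, hub structure in
the PPI graph, or realistically scale-free pathway sizes. Green tests on
this generator therefore demonstrate correctness of the algorithms under
their stated model, not robustness to everything real data does.

# Benchmark configurations used by the tests

The acceptance-style tests run at sizes chosen to finish in seconds on
one core while still being honest instances of each property:

* decomposition recovery: 50 genes x 10 TFs x 6 conditions (noiseless,
  and $\sigma = 0.1$ over five seeded replicates);
* DEG selection: 100 target genes with 25 planted multi-stage effects,
  $\sigma = 0.1$, 3 replicates per arm;
* crosstalk null calibration: 25 chance-overlapping pathways of 15 genes
  on a 150-gene background, 200 pairs at $B = 2000$;
* crosstalk power: 25 *disjoint* pathways of 20 genes over 500 genes,
  3 planted pairs at 20x boost on a sparse (`edge_prob = 0.005`)
  background, with the expression layer silenced (`amplitude = 0`) so
  the benchmark isolates the planted topological signal the C score is
  being asked to detect.

# Known limitations

* The model assumes expression is controlled entirely by transcription;
  mRNA stability and post-transcriptional effects are folded into the
  residual.
* Strengths and activities are only identified up to the diagonal
  convention; comparisons across fits must use the same normalization.
* The moment-matching variance prior is an approximation to a full
  marginal-likelihood fit (in practice indistinguishable from limma's
  estimator on the suite's fixtures).
* With fewer conditions than TFs the activity matrix cannot have full
  row rank; per-TF estimates remain usable for supports with private
  targets, but linear combinations of activity rows across TFs sharing
  all their targets are not resolved.
* The crosstalk permutation preserves pathway sizes but not degree
  structure; on hub-dominated real PPI networks a degree-preserving
  null would be stricter.
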