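---
title: "Methods: target-gene network inference in cgrf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: target-gene network inference in cgrf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgrf)
```

`cgrf` narrows a genes-by-timepoints expression matrix down to the genes
relevant to one target gene and infers directed lagged relationships among
them. This vignette records the statistical model behind each stage, the
parameters that matter, the numerical conventions, and the choices we made
where the design was genuinely open.

## Data model and preprocessing

The whole pipeline operates on an `expr_mat`: a tibble with a `gene_id`
column and one numeric column per time point (column names are the time
stamps, strictly increasing, arbitrary units). Genes whose trajectory is
exactly constant are removed first — constancy is tested as exact equality
of all entries, not with a tolerance, because such rows carry no temporal
signal and break standardization. Every remaining gene is then z-scored
(sample standard deviation, n − 1 denominator). Standardization happens
once, before clustering, and *all* later stages — smoothing, distances,
and the VAR fit — see the standardized matrix, so every stage works on one
consistent scale and distance ranks are comparable across genes of very
different absolute expression.

The pipeline accepts the matrix as given and applies no variance-
stabilising or log transformation; whether the input should be logged is a
property of the upstream quantification and is deliberately left to the
user.

## Fuzzy C-means clustering

Gene trajectories are clustered by fuzzy C-means, minimising

$$L(K, m) = \sum_{k=1}^{K} \sum_{i=1}^{N} u_{ki}^{m}\,
\lVert y_i - c_k \rVert^2, \qquad \sum_k u_{ki} = 1,$$

with squared Euclidean distance exactly (no alternative metrics inside the
clustering step). The alternating updates — centroids as $u^m$-weighted
means, memberships proportional to $d^{-2/(m-1)}$ — each monotonically
decrease $L$, so the recorded objective trace is non-increasing; iteration
stops when the absolute objective change drops below `tol` (default 1e-6)
or after `max_iter = 300` sweeps. A gene coinciding exactly with a
centroid gets its full membership there (the degenerate-distance case is
handled explicitly).

Two parameters need choosing:

* **Fuzzifier `m`** (dimensionless, > 1). The default is the
  Schwämmle–Jensen closed form in the number of genes `N` and time points
  `D`,
  $m = 1 + (1418/N + 22.05)D^{-2} + (12.33/N + 0.243)
  D^{-0.0406\ln N - 0.1134}$.
  For dense time courses this is barely above 1 (e.g. ≈ 1.01 at
  N ≈ 18,000, D = 480): in many dimensions larger fuzzifiers collapse all
  memberships toward uniformity, so nearly-hard clustering is the sane
  regime. `m` can always be overridden.
* **Number of clusters `K`**. `gap_statistic()` compares the hardened
  clustering's total within-cluster dispersion
  $W_k = \sum_k \sum_{i \in k} \lVert y_i - \bar y_k \rVert^2$ against
  `b` reference datasets drawn uniformly over each feature's observed
  range, and reports the whole curve with standard errors plus the argmax
  `k_hat`. We compute dispersion on *hardened* (argmax) labels — the
  fuzzy objective itself depends on `m` in a way that makes data and
  reference dispersions incomparable — and we deliberately emit the full
  curve rather than trusting the argmax: on smooth expression profiles
  the argmax routinely over-segments, and an elbow read off the curve is
  often the better choice. The argmax is also intrinsically noisy in high
  dimensions (uniform-box references concentrate differently from
  correlated trajectories), which is why the automatic `k = "auto"` path
  should be treated as guidance, not ground truth.

Memberships are initialised from a symmetric Dirichlet(1) draw per gene
under the run seed, making fits exactly reproducible. Ties in the hardened
assignment (and in `select_cluster_of()`) break toward the smallest
cluster index.

## Smoothing the target gene

The target trajectory is modelled as $y_t = f(t) + \epsilon_t$ and $f$
estimated by local polynomial regression: at each observed time $x$ a
degree-0/1/2 polynomial is fitted by weighted least squares with tricube
weights $W(\Delta; u) = (1 - (\Delta/u)^3)^3$ for $\Delta < u$. The
bandwidth at $x$ is the $\lfloor \alpha T \rfloor$-th smallest distance to
$x$ for $\alpha \le 1$ (so α is the neighbourhood *fraction*), and
$\alpha \cdot \max_t \Delta_t(x)$ for $\alpha > 1$. The floor is clamped
to at least `degree + 2` neighbours, the minimum leaving a positive-weight
point count able to identify the local polynomial; if ties in distances
still leave fewer than `degree + 1` points with positive weight, the fit
errors and asks for a larger α. Evaluation is only at the observed times —
no extrapolation.

The smoother is linear in `y`; its matrix trace drives generalized
cross-validation, $GCV(\alpha) = T^{-1}\sum \hat\epsilon_t^2 /
(1 - \mathrm{tr}(L)/T)^2$, minimised over a grid (default 0.02–1.00 in
steps of 0.02; default degree 2). An interpolating α (trace = T) scores
+∞ with a warning. Exact score ties — including the
polynomial-reproduction case where every residual is machine zero — break
toward the *largest* (smoothest) α; "exact" here means within 1e-12, so
machine noise does not defeat the rule. The pipeline smooths the
standardized target, consistent with the one-scale convention above.

## Distances to the smoothed target

Similarity is measured between every gene and the *smoothed* target — the
fitted curve captures the pattern of interest better than the noisy
observations do. Two families are implemented:

* **Lock-step** Minkowski distances
  $d_{L_n}(Y,Z) = (\sum_j |Y_j - Z_j|^n)^{1/n}$ (absolute differences, so
  odd orders are well defined); Manhattan and Euclidean are the n = 1, 2
  cases.
* **Dynamic time warping**: the minimum over monotone, continuous warping
  paths from (1,1) to $(t_Y, t_Z)$ of the normalized weighted cost
  $\sum_s d(p_s) w_s / \sum_s w_s$ with pointwise cost
  $|Y_{u_s} - Z_{v_s}|$. Step weights follow the index-step (Sakoe–Chiba)
  convention: the symmetric form weights diagonal moves 2 and axis moves 1
  (start cell 2), making the weight total $t_Y + t_Z$ independent of the
  path, so the dynamic program minimises the normalized distance exactly;
  the asymmetric form weights each step by the advance of the first
  series' index (total $t_Y$). We adopted index steps because weights
  defined on value differences would be sign-indefinite and break the
  minimisation. No global path constraint is imposed by default. The DP
  core is in C++ (O($t_Y t_Z$) per gene), as every mature DTW
  implementation does.

The metric registry (`manhattan`, `euclidean`, `minkowski`, `dtw`) is a
documented extension point; autocorrelation-, periodogram- and
correlation-based dissimilarities are intentionally out of scope. The
target gene stays in the distance table — its distance to its own smooth
is positive and is itself informative.

## Selecting significant genes, with rescue

If the target's cluster contained exactly the genes closest to the
smoothed target, the cluster's genes sorted by distance would occupy
global ranks 1..n. The selection step tests that literally: for windows
n = 10, 11, … the first n global ranks are compared to 1..n with a
two-sided Wilcoxon signed-rank test, and the scan stops at the first
significant disagreement (default threshold 0.05); the significant count
is the last non-significant window. If no window is significant the whole
cluster is kept, and a cluster smaller than the start window is kept whole
with a warning. Start = 10 and step = 1 are the defaults; the p-value
trace of every tested window is returned for inspection. No
multiple-testing correction is applied across the incremental tests —
the scan is a stopping rule, not a family of simultaneous inferences —
and this is a known statistical caveat.

The signed-rank test itself discards zero differences (the classic
reduced-sample convention), midranks ties, and uses the exact null
distribution of the positive-rank sum for effective n ≤ 25 — computed by
convolution over doubled midranks, so exactness survives ties — switching
to the tie-corrected normal approximation (no continuity correction)
above. This matters because rank differences in the scan are frequently
zero or tied; an implementation that abandons exactness under ties would
quietly change the stopping rule.

Finally, genes of *other* clusters whose distance is within the
significant genes' range (≤ the largest significant distance, boundary
inclusive) are rescued, ordered by distance. The inclusive cutoff is this
package's definition of "in the range"; hard labels for the rescue come
from the membership argmax. The selected set entering the network stage
is significant ∪ rescued ∪ {target} — the target is force-included even
when the scan would exclude it, since the question is precisely which
genes relate to it.

## VAR(1) network inference

Over the p selected genes the pipeline fits
$y(t+1) = A\,y(t) + B + \epsilon(t)$, $\epsilon \sim N(0, \Sigma)$, by
OLS with intercept; $A_{ij} \ne 0$ encodes a directed lagged arc
j → i. The residual covariance uses denominator $T - 1 - (p+1)$ (samples
minus parameters per equation); if that is non-positive the uncorrected
second-moment matrix is reported with a warning. When the Gram matrix is
singular (p ≥ T − 1) the fit falls back to the Moore–Penrose
pseudoinverse, flags `rank_deficient`, and warns loudly — estimates in
that regime are not trustworthy, merely defined.

Edges are weighted by the **lagged partial correlation**: with
$a_{1k}$ the coefficient of $y_k(t)$ in the forward regression of
$y_i(t+1)$ on all $y(t)$, and $a^*_{1k}$ the coefficient of $y_i(t+1)$ in
the reverse regression of $y_k(t)$, the weight is
$\sqrt{a_{1k} a^*_{1k}}\,\mathrm{sgn}(a^*_{1k})$. The product is
algebraically non-negative (both coefficients equal the same partial
correlation times positive variance ratios) and the implementation
asserts this at run time. The vectorized route computes all p values per
target from the precision matrix of the joint (past, one future)
covariance — one (p+1)×(p+1) inversion per target gene — and is tested to
agree with the literal two-regression definition to 1e-10.

The **dynamic correlation** alternative treats each trajectory as a
sampled function under the trapezoid-weighted inner product
$\langle g,h \rangle = \sum_j g(t_j) h(t_j)(t_{j+1}-t_{j-1})/(2T)$ with
one-sided differences at the boundary ($t_0 := t_1$,
$t_{T+1} := t_T$ — the end weights are otherwise undefined). Each series
is standardized *functionally*, centring by $\langle f, 1\rangle$ and
scaling by the inner-product variance; we chose the functional variance
(rather than the ordinary sample variance) so that the self-correlation
is exactly 1 and the matrix is a genuine correlation matrix. Partial
correlations follow by precision-matrix inversion,
$-\omega_{kl}/\sqrt{\omega_{kk}\omega_{ll}}$, with an optional shrinkage
toward the identity for singular inputs.

Edge significance testing via empirical-Bayes local FDR is deliberately
out of scope; edges are ranked by absolute weight and the strongest
`top_edges` (default 150) reported, with exact-tie break lexicographic by
(source, target). Self-loops are excluded from rankings by default
because autoregressive terms dominate trivially. Both the directed lagged
edges and the undirected dynamic edges are emitted and labelled; they
answer different questions (lagged direct influence vs. contemporaneous
functional association) and neither is reduced to the other.

## The synthetic generator: what it emulates, and what it does not

`simulate_dataset()` produces the study conditions used throughout the
tests: by default 200 genes × 480 time points over 24 h (the dense
sampling regime of modern circadian time courses, at reduced gene count),
four background archetypes — unit-variance sinusoids phased
2πk/n_clusters apart plus one monotone trend — with i.i.d. Gaussian
observation noise (sd 0.5 on unit-amplitude archetypes), and a six-gene
stable VAR(1) core (triangular coefficients, spectral radius 0.3, planted
target drivers ±0.5) superimposed on the target's archetype so the core
clusters with the target-like background genes. Cluster labels, core
membership and the planted adjacency are returned as ground truth, and
identical seeds give identical matrices.

The generator emulates the *structure* the method exploits — cluster
archetypes, a distinctive target pattern, sparse lagged drivers — but not
several features of real RNA-seq time courses: counts and
mean–variance coupling, library-size and batch effects, unequal sampling,
missing observations, or the heavy right tail of between-gene variance.
Passing tests therefore demonstrate correctness of the algorithms under
the planted model, not robustness to those real-data pathologies.

Test and acceptance problem sizes are scaled to what the planted
structure needs rather than to the motivating dataset: clustering
recovery uses 60 genes × 48 points over 20 seeds, VAR edge recovery
20 genes × 480 points over 20 seeds, and the end-to-end runs the full
200 × 480 default over 20 seeds.

## Degenerate inputs and numerical conventions

* Distance ties in `global_ranks()` break by input order (ranks are a
  permutation of 1..N by construction).
* All-zero paired differences give a signed-rank p-value of 1.
* A cluster smaller than the Wilcoxon start window is kept whole, with a
  warning rather than an error: the scan is undefined, not wrong.
* Gap-statistic references and the fuzzy initialisation consume
  sub-seeds drawn once under the run seed, so per-k results do not shift
  when `k_max` changes the loop order.
* TSV output goes through a fixed writer so that identical configs and
  seeds give byte-identical artifacts; the run manifest (flat
  `key: value`, numbers at full precision) re-reads as a configuration
  and replays the run exactly.

## Known limitations

* The incremental Wilcoxon scan is weak against a *few* interlopers: a
  handful of far-ranked genes inside an otherwise well-ordered window
  shifts the rank-sum by little, so the stopping point reacts a few genes
  late. It locates the boundary well when the rank break is abrupt.
* With a near-1 fuzzifier the Dirichlet initialisation occasionally
  isolates the target in a tiny cluster; the pipeline then keeps that
  cluster whole and rescues by distance, but regulator recovery in that
  run can fail. Inspecting the reported cluster sizes (and re-running
  with another seed or an explicit `k`) is the practical remedy.
* Lagged partial correlations are only meaningful when T comfortably
  exceeds p; the pseudoinverse path exists for completeness, not for
  inference.
* The Gap-statistic argmax over-segments smooth trajectory data; use the
  emitted curve.
* Edge ranking by absolute partial correlation provides no error control;
  the ranks are hypotheses for follow-up, not significance statements.
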