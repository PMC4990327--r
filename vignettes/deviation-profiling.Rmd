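---
title: "Gene-expression deviation profiling and Cancer Transcriptomic Profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-expression deviation profiling and Cancer Transcriptomic Profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctprofiler)
```

## The model

ctprofiler implements a cohort-relative, scale-free summary of bulk or
single-cell expression data. For a normalized log2 expression matrix
$X \in \mathbb{R}^{G \times S}$ (probes $g$ in rows, samples $s$ in columns),
each probe is mean-centered across the cohort,

$$ d_{gs} = x_{gs} - \bar{x}_{g\cdot}, $$

and the deviation is discretized relative to the probe's own standard
deviation $\sigma_g$:

$$ t_{gs} = \begin{cases}
  -1 & d_{gs} < -c\,\sigma_g \\
  +1 & d_{gs} > +c\,\sigma_g \\
  \phantom{+}0 & \text{otherwise.}
\end{cases} $$

The cut $c = 0.43$ is the standard-normal quantile at $2/3$
(`equal_tercile_threshold()` returns $\Phi^{-1}(2/3) \approx 0.4307$), so
that under Gaussian deviations each of the three codes occurs with
probability $1/3$. The ternary profile of a sample is its column
$t_{\cdot s} \in \{-1, 0, +1\}^G$.

Samples are clustered on their ternary profiles into exactly three groups
(k-means or a one-dimensional self-organizing map), and each group is
summarized by its centroid — the per-probe mean of its members' codes, a
"target vector" with entries in $[-1, 1]$. The three centroids constitute a
Cancer Transcriptomic Profile (CTP) model. A new sample, from the same or a
different cancer type, is discretized **within its own cohort** (its own
per-probe means and standard deviations) and assigned to the CTP whose
centroid it correlates with best (Pearson). Because both the discretization
and the correlation are invariant to per-probe location and positive scale,
the assignment is insensitive to tissue-of-origin expression-level
differences and to monotone per-probe rescalings — the property that makes
cross-cancer transfer meaningful.

Two assumptions are implicit and worth stating: (i) a cohort is homogeneous
enough that a single per-probe mean/σ is a sensible reference (mixed-batch
cohorts should be corrected before profiling); (ii) three groups. The number
of groups is deliberately hard-wired — the CTP concept *is* three recurring
profiles, and the package refuses `k != 3` rather than quietly generalizing.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `threshold_factor` | 0.43 | fraction of per-probe σ | equal-tercile cut under normality; tunable but every entry point defaults to 0.43 |
| `std_mode` | `"sample"` | — | n−1 denominator; `"population"` exposed for auditability |
| `n_restarts` | 10 | — | k-means restarts / SOM trainings kept by best objective |
| `min_common_probes` | 100 | probes | floor on model–cohort probe intersection for assignment |
| `seed` | — | — | every stochastic step takes one and records it in its output |

Numerical conventions: boundary deviations exactly at $\pm c\sigma_g$ code
as 0 (strict inequalities; a measure-zero event on continuous data);
zero-variance probes code as all-zero (neutral) rather than erroring;
correlation ties at assignment are broken by model label order and flagged
in the output. Groups coming out of a clustering are named A/B/C by
decreasing size, ties broken by the lexicographically smallest member sample
id, so that reruns and cross-method comparisons are reproducible; the
original survival connotations of A/B/C apply only to the cohort a model was
first defined on. Missing values in input files are rejected by default;
optional row-mean imputation maps them to deviation 0, the neutral code,
which cannot create spurious ±1 calls.

## Clustering details

k-means runs on the raw ternary codes as coordinates (the pipeline
discretizes first, then clusters), squared-Euclidean objective, best of 10
restarts. The SOM is a deliberately small implementation: a 1×3 chain of
units, each unit one group, trained for 20 epochs with a learning rate
decaying linearly from 0.5 to 0.01 and a neighborhood radius of 1 for the
first half of training and 0 thereafter; samples map to their best-matching
unit, and the best of `n_restarts` trainings by quantization error is kept.
These hyperparameters are conventions chosen for determinism, not tuned
quantities; they are recorded in every model file. On well-separated data
the two methods agree on ≥ 75% of samples (asserted in the test suite), and
clustering on raw codes versus correlations was resolved in favor of raw
codes to match the profile-then-cluster pipeline.

## The de Finetti mapping

Each assigned sample carries three correlations $(r_A, r_B, r_C)$. The
package maps them to barycentric coordinates with **shifted-similarity
weights**

$$ w_i = \frac{1 + r_i}{\sum_j (1 + r_j)}, $$

i.e. $w_i \propto 2 - d_i$ where $d_i = 1 - r_i$ is the Pearson correlation
distance to centroid $i$; the degenerate all-$(-1)$ triple maps to the
center. This convention is the package's own (the transform behind the
original figures is not published): it is parameter-free, total on
$[-1,1]^3$, and reproduces the geometry the method predicts — samples with
uniformly weak correlations (normal tissue, pure noise) sit near the
triangle center, samples strongly correlated with one centroid and
anti-correlated with the others approach that centroid's vertex. A
clamp-negatives-and-normalize rule was considered and rejected: a sample's
winning correlation is always positive while the other two are typically
negative (the three centroids of a mean-centered ternary cohort are
mutually anti-correlated), so clamping sends *every* sample to a vertex and
erases exactly the central clustering of weakly correlated samples the plot
exists to show. A consequence worth noting: no mapping that distinguishes
weak from strong correlation triples can be invariant under positive
rescaling of the triple, and this one is not. Vertices are fixed (A
lower-left at (0,0), B lower-right at (1,0), C top at (0.5, √3/2)).

## Synthetic cohorts

`generate_noise_cohort()` draws i.i.d. standard-normal values — the null in
which every deviation from the probe mean is pure fluctuation, with
Gaussian per-probe deviations. Unit variance is without loss of generality
because discretization is σ-relative.

`generate_planted_cohort()` emulates the structure the method assumes:
three groups whose signal probes (default fraction 0.3) carry
group-specific mean shifts of ±`effect_size`·`noise_sd` (default 3σ),
cycling the three rotations of the pattern (+1, 0, −1) so the planted
ternary prototypes are pairwise distinct; remaining probes are pure noise.
Defaults (150 samples, 2000 probes, equal thirds) give a well-separated
cohort on which clustering recovers the planted labels with adjusted Rand
index ≥ 0.95. What the generator does **not** emulate: probe–probe
correlation, batch effects, heavy-tailed platform noise, unbalanced
cancer-type composition. Passing tests on these cohorts therefore
demonstrate correctness of the machinery and qualitative behavior
(structure in, structure out; noise in, nothing out), not the quantitative
agreement levels published for the original multi-study microarray corpus,
which would require those cohorts.

## The null simulation

`run_null_simulation()` generates 14 independent "virtual cancer types" of
50 patients each (the study-scale defaults), runs the full protocol on each
— discretize, cluster into three CTPs, compute centroids — restricts the
centroids to one shared random subset of 716 probes (mimicking selection of
a functional gene set), and correlates matched-label centroids across every
pair of types. Independent noise yields cross-type correlations scattered
around zero; the seed-averaged absolute mean stays below 0.02, which is the
package's acceptance bound (`scripts/acceptance.R` recomputes it at 5000
probes over 10 seeds, ~17 s; the statistic is insensitive to the probe
count before subsetting, which the test suite asserts). Within-type
centroid pair correlations are reported but deliberately not asserted: with
de-novo clustering per type — the only self-contained reading — the three
centroids of a mean-centered cohort are anti-correlated by construction
(we observe ≈ −0.35), and their value depends on the assignment reference,
which is a modeling choice rather than a prediction of the null.

## Cohort statistics

*Cluster diameter* is the per-label mean of members' winning correlations —
tighter groups score higher; empty labels report `NA`, never 0. Group
comparisons (`compare_diameters()`) report both Welch's t and the Wilcoxon
rank-sum test, since the appropriate family for small numbers of per-cohort
diameters is a judgment call; Welch is the headline default.

*Subset robustness* rebuilds centroids from a restricted gene set while
**reusing the full model's training-sample grouping**, then measures
permutation-matched agreement of subset-model and full-model assignments.
Reusing the grouping isolates the gene-subset effect from clustering
instability; de-novo re-clustering is available behind `recluster = TRUE`.
Dispersion over random draws is the standard deviation across replicates,
and is labeled as such in the report.

## Problem sizes and limitations

The test suite runs on cohorts of 45–150 samples and 300–10000 probes, and
the acceptance computation uses 14 × 50 samples at 5000 probes; these sizes
were chosen as the smallest at which the asserted properties are stable
over seeds. Known limitations: no multi-platform probe translation (models
transfer by identifier intersection, and a thin intersection is an error);
no survival analysis; no normalization — input must already be normalized
log2 expression; the three-group contract is absolute, so cohorts genuinely
lacking three populated groups fail loudly at clustering or centroid time.
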