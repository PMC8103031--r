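---
title: "Joint tri-factorization of multi-omics data: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint tri-factorization of multi-omics data: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomics)
```

## The model

`triomics` integrates `P` non-negative molecule-by-sample matrices
`X⁽ᵖ⁾ ∈ R^{mₚ×n}` that share their sample columns. Each matrix is
tri-factorized around a common sample basis:

$$X^{(p)} \approx U^{(p)} S^{(p)} V$$

where the columns of `U⁽ᵖ⁾` hold per-factor molecular loadings, the rows of
`V` hold per-factor sample loadings shared by all omics, and the small
`k × k` matrix `S⁽ᵖ⁾` absorbs the scale difference between the two — without
it, the molecular and sample factors of omics measured on very different
scales would have to compensate for each other. The joint objective is

$$\min \sum_p \pi_p \lVert X^{(p)} - U^{(p)} S^{(p)} V \rVert_F^2
  + \beta\left(\mathrm{tr}[V^L L^a (V^L)^T]
  - \mathrm{tr}[V^L L^p (V^L)^T]\right) + \omega \lVert \Pi \rVert^2$$

subject to non-negativity of all factors and `π` on the probability simplex.

**Semi-supervision.** Samples with known group labels enter through two
graphs over the labeled columns `V^L`: an *affinity* graph `W^a` connecting
same-group pairs and a *penalty* graph `W^p` connecting different-group
pairs, with Pearson correlations of a side feature matrix (e.g. copy-number
profiles) as edge weights. For a Laplacian `L = D − W`,
`tr[V L Vᵀ] = ½ Σᵢⱼ Wᵢⱼ ‖vᵢ − vⱼ‖²`, so minimizing the affinity trace draws
same-group samples together in latent space while the subtracted penalty
trace pushes different-group samples apart.

**Learned omic weights.** Fixing the factors, the weight subproblem
`min Σ πₚ cₚ + ω Σ πₚ²` over the simplex (with `cₚ` the omic's squared
residual) is a strictly convex quadratic program with the exact
water-filling solution `πₚ = max(0, (λ − cₚ)/(2ω))`, `λ` chosen so the
weights sum to one. Cleaner omics get (weakly) larger weights; a
sufficiently noisy omic can be switched off entirely. We solve it in closed
form — an `O(P log P)` sort — and keep a brute-force active-set enumeration
as an independent oracle in the tests only.

## Optimization

`U`, `S`, `V^L`, `V^UL` are updated by multiplicative rules derived from the
KKT conditions of the objective's Lagrangian, e.g.

$$U^{(p)} \leftarrow U^{(p)} \circ
  \frac{X^{(p)} V^T (S^{(p)})^T}{U^{(p)} S^{(p)} V V^T (S^{(p)})^T}.$$

One sweep runs `U⁽ᵖ⁾`, `S⁽ᵖ⁾` for every omic, then `V^L`, then `V^UL`, then
the π step. In the `V^L` rule the graph contribution places `β V^L(D^p +
W^a)` in the numerator and `β V^L(D^a + W^p)` in the denominator, so both
stay non-negative.

Numerical choices:

* **Denominator guard.** `1e-12` is added to every update denominator. This
  avoids 0/0 without perturbing fixed points beyond machine precision: an
  exact factorization with strictly positive factors changes by less than
  `1e-10` relative under every rule (asserted in the tests).
* **Initialization.** All factor entries are i.i.d. strictly positive
  uniform draws, scaled so that the initial product `U S V` matches the data
  mean in expectation. Strictly positive starts matter: multiplicative
  updates can never revive an entry that hits exactly zero.
* **Stopping.** The sweep loop stops when
  `|O_t − O_{t−1}| / max(1, O_{t−1}) < tol` (default `1e-6`, at most 500
  sweeps). Non-convergence is a warning plus `converged = FALSE`, never an
  error.
* **Monotonicity.** With `β = 0` each factor subproblem is a non-negative
  least-squares in that factor, so the classical auxiliary-function argument
  applies rule by rule and the objective is non-increasing across a full
  sweep; the tests assert this to `1e-8` relative on random fixtures. With
  `β > 0` the subtracted penalty trace makes a global guarantee unavailable;
  convergence of the objective change below `tol` is asserted empirically on
  the packaged fixtures instead.
* **Degenerate labelings.** With zero labeled samples the graph term is
  dropped (fully unsupervised fit); with all samples labeled the `V^UL` step
  is a no-op.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 4 | number of latent factors; should equal the number of groups |
| `beta` | 10 | weight of the affinity-minus-penalty graph term |
| `omega` | 1e5 | pull of the omic weights toward uniform |
| `tol` | 1e-6 | relative objective-change stopping threshold |
| `max_iter` | 500 | sweep budget |

`beta` and `omega` default to reference values appropriate for
*unnormalized* expression-scale inputs. `omega` should be read relative to
the Frobenius residuals: it bounds how far the weights can move from
uniform (`|πₚ − 1/P| ≤ max|cₚ − c̄|/(2ω)` on the interior). On unit-scale
data — including most synthetic fixtures in this package — residuals are
orders of magnitude smaller, and `omega = 1e5` both freezes the weights and,
because the stopping rule is relative to the total objective, can end the
fit before the reconstruction has converged. For such data we use
`omega ≈ 1`. Column normalization of the inputs is available
(`normalize = TRUE` in `run_pipeline()`) but off by default, consistent with
the large default `omega`.

## From factors to modules

For each factor column of `U⁽ᵖ⁾` (separately per omic, so that small omics
are not swamped by large ones), members are molecules with
`z = (x − x̄)/S_x > 2`, with the sample (n−1) standard deviation and a
*strict* inequality. Selection is invariant to positive affine rescaling of
the loadings, so the factor scale ambiguity is harmless here. Members are
projected onto the interaction network and connected components extracted on
the undirected skeleton (direction is kept in the output edge lists);
members absent from the network are reported as unmapped rather than
silently dropped, since whether membership should require network presence
is a judgment call left to the user.

Factors are matched one-to-one to groups by maximizing the total group-mean
labeled loading over all injective assignments (exhaustive; `k ≤ 8` in
practice). We chose the global matching over independent per-factor argmax
because the latter can collapse two factors onto one group when loadings
overlap. Unlabeled samples take the group of their argmax factor; ties go to
the lowest factor index and all-zero columns are reported `"unassigned"`.

Enrichment of module members against annotation sets uses the one-sided
hypergeometric tail with the union of input molecule ids as the default
background (overridable); raw p-values by default with an optional
Benjamini–Hochberg adjustment.

## Choosing k by consensus

For each candidate `k`, `consensus_select_k()` refits from random restarts,
assigns every sample to its argmax factor and accumulates co-assignment
frequencies. Before the argmax, rows of `V` are L2-normalized: the
tri-factorization is invariant to scaling factor `f` by `c` in `V` and
`1/c` in `S`, so comparing raw rows of `V` across factors is arbitrary and
makes co-assignments flip between restarts.

Stability is scored by the cophenetic correlation between `1 − C` and the
cophenetic distances of its average-linkage dendrogram. The recommended `k`
maximizes this correlation, with one deliberate refinement: ranks whose
correlation is within `1e-6` of the maximum count as equally stable, and the
**largest** of them is recommended. The reason is empirical and structural:
below the true rank the best rank-`k` fit of clean block data is essentially
determined by the data, so every restart agrees and stability is perfect
*even though the rank is wrong*; instability appears only above the true
rank. Breaking exact ties toward the smallest `k` therefore systematically
under-selects on well-separated data, while the largest equally-stable rank
is the one carrying the full group structure. On noisy data exact ties are
rare and the rule reduces to the plain argmax.

## What the synthetic generator does and does not emulate

`simulate_multiomics()` plants disjoint molecular blocks per factor
(high/low loading contrast 0.8–1.2 vs 0–0.2), diagonal-dominant `S` (the
off-diagonal scale is the `coupling` parameter), group-structured `V`,
truncated Gaussian noise with standard deviation `noise_sd × mean(signal)`,
stratified partial labels, a side feature matrix whose within-group
correlations exceed between-group ones, and a network with higher edge
probability inside planted blocks. Defaults: `P = 2`, `m = (300, 80)`,
`n = 120`, `k = 4`, `noise_sd = 0.1`, `labeled_fraction = 0.25`.

Truncation at zero (rather than strictly positive noise) gives mild
zero-inflation, as in real expression matrices. What the generator does
*not* emulate: count-distribution mean–variance relationships of sequencing
data, batch effects, molecules shared across omics, overlapping modules, and
group sizes that differ by an order of magnitude. Tests passing on these
fixtures demonstrate correctness of the optimization and the recovery
machinery under the planted model — not performance on real cohorts.

Problem sizes in the packaged validation runs: the recovery experiment uses
the default fixture above with five replicate seeds (each fit ≤ 500 sweeps);
rank selection uses noiseless fixtures of 40 and 64 samples with 10 restarts
per candidate `k`.

## Known limitations

* With large `omega` the weights stay near uniform, so a heavily corrupted
  omic is down-weighted only marginally and can still distort the shared
  `V`: in the five-seed corruption experiment the corrupted omic's weight is
  lower in all replicates under the default seeds, but factors occasionally
  get spent on fitting the noise matrix, inflating the intact omic's
  residual. Smaller `omega` lets the weights react more decisively.
* Multiplicative updates can stall in local minima (e.g. one factor fitting
  a global offset); restarts are the standard remedy and are what the
  consensus machinery exploits.
* The penalty trace is subtracted, so the objective is unbounded below for
  extreme `β`; with the default `β = 10` and correlation-bounded edge
  weights this is not observed on the packaged fixtures, but monotone
  descent is only guaranteed at `β = 0`.
* Dense linear algebra throughout; matrices beyond ~10⁴ molecules per omic
  will be slow.
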