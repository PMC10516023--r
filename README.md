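# msiva

Joint blind source separation of two (or more) data modalities into
**linked cross-modal subspaces** and **unique unimodal sources**, with
data-driven selection of the subspace structure.

## The problem

Multimodal studies — e.g. structural MRI (gray-matter maps) and
functional MRI (mALFF maps) on the same subjects — need latent-variable
models that capture what the modalities share *and* what each contributes
alone. Classical multimodal ICA/IVA assumes every source is
one-dimensional and independent within its modality, which is often too
rigid: related sources plausibly form dependent groups that are linked
across modalities as whole blocks. This package estimates that richer
model. Each modality `X[m] (V features x N subjects)` is a linear mixture
`X[m] = A[m] S[m]` of `C` sources, and a *subspace structure* partitions
the sources of each modality into linked blocks (equal size across
modalities, dependent within and across) and unimodal 1D blocks
(independent of everything else). Estimation minimizes the mutual
information among subspaces,

    L(W) = - sum_m ln|det W[m]|
           + (1/N) sum_n sum_k  -ln p_k( P_k s_hat_n ),

with each subspace density `p_k` a Kotz family member
`p(v) ~ ||v||^(2(eta-1)) exp(-lambda ||v||^(2 beta))` (normalization
constants included, so losses are comparable across structures), by
alternating greedy combinatorial alignment of source rows with L-BFGS
refinement. Candidate structures S1–S5 (twelve sources per modality; S5 is
plain IVA) are ranked by final loss. Ground-truth recovery is scored with
the normalized multidataset Moreau–Amari intersymbol interference (ISI,
0 = perfect); cross-modal linkage with the two-stage mean correlation
coefficient (MCC), per-subspace CCA, and the randomized dependence
coefficient (RDC). Downstream tools reconstruct per-subspace data,
extract voxelwise SVD-shared cross-modal patterns, predict phenotypes
from post-CCA sources, and run a two-stage voxelwise brain-age delta
analysis with confound correction, predictor partialization and
BH-FDR-corrected phenotype association maps.

A synthetic-data module generates multimodal mixtures of correlated
multivariate-Laplace subspace sources (Gaussian scale mixtures;
cross-modal correlations uniform in [0.65, 0.85]) with full ground truth,
so the whole pipeline is exercisable end to end without any data deposit.

## Worked example

Generate an S2-structured dataset (five linked 2D subspaces + two
unimodal sources per modality) at reduced scale, fit it with the
MGPCA+ICA workflow, and evaluate:

```r
library(msiva)
s   <- make_candidate("S2")
d   <- generate_multimodal(s, V = 2000, N = 1000, seed = 1)
fit <- msiva_fit(d, s, workflow = "msiva", n_outer = 10, seed = 1)
fit
#> <msiva_model> structure: S2  workflow: msiva
#>   final loss: 25.6516  outer rounds: 2

interference(fit, d$A, d$structure)
#> <msiva_interference> ISI: 0.0238  per-modality: 0.02961, 0.02909

round(sapply(posthoc_cca(fit), `[[`, "canonical_correlation"), 3)
#> [1] 0.761 0.770 0.796 0.781 0.816

sel <- select_structure(d, candidates = c("S2", "S5"),
                        workflow = "msiva", seed = 1)
sel[, c("structure", "loss", "isi", "rank")]
#>   structure     loss        isi rank
#> 1        S2 25.65164 0.02379555    1
#> 2        S5 26.52656 0.06081283    2
```

Reading the numbers: the ISI of 0.024 means the composite unmixing
recovers the ground-truth subspaces nearly perfectly up to permutation
and scale (uniform interference would score 1; the residual here is
finite-sample estimation noise at N = 1000 — it shrinks roughly as
1/sqrt(N)). The five per-subspace canonical correlations (0.76–0.82) sit
inside the generator's [0.65, 0.85] linkage band, as they should. In the
selection table the generating structure S2 beats the plain-IVA
structure S5 on final loss, which is the model-selection criterion when
no ground truth is available.

The methods vignette (`vignettes/msiva-methods.Rmd`) documents the model,
the optimization, every tunable default, and the design decisions.

## Acceptance script

`scripts/acceptance.R` re-runs the headline synthetic quantities from
scratch against the installed package: one reduced-scale S2 fit scored by
ISI against the known mixing, plus generator calibration at N = 3000
(extreme linked-pair cross-modal correlations and the worst-case
unimodal-source correlation). Run it from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It writes one JSON object with a numeric `value` (and the problem size
`n`) per quantity; all randomness derives from `--seed`.
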