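# tftensor

Transcription factors (TFs) regulate genes combinatorially, but each
experimental window onto their interactions — ChIP-seq co-binding,
co-expression, promoter co-methylation, DNase-footprint co-occupancy — is
incomplete and noisy in its own way, and no single one yields a reliable
interaction map. `tftensor` integrates them in a network paradigm: each
evidence source becomes a symmetric weighted TF×TF network, the normalized
networks are stacked into an incomplete 3-way tensor, and a variational
Bayesian CANDECOMP/PARAFAC (CP) factorization with automatic rank
determination denoises and completes the stack. The factors are fused into
one precise weighted TF interaction network from which strong
interactions, hub TFs, and lineage-specific versus housekeeping edges are
called and evaluated by ROC/AUC against network-averaging gold standards.

The package is aimed at computational biologists studying combinatorial
transcriptional regulation, and at anyone needing a tested Bayesian tensor
completion with ARD in R.

## The model

The observed tensor $\mathcal{Y}$ (TF × TF × evidence layer), with binary
observation mask $\mathcal{O}$, is modeled as

$$\mathcal{Y} = \sum_{r=1}^{R} a^{(1)}_r \circ a^{(2)}_r \circ a^{(3)}_r
  + \varepsilon, \qquad \varepsilon_{ijk} \sim \mathcal{N}(0, \tau^{-1}),$$

with zero-mean Gaussian priors on the factor rows sharing a diagonal
precision $\Lambda = \mathrm{diag}(\lambda_1,\dots,\lambda_R)$ across
modes, and Gamma hyperpriors on each $\lambda_r$ and on $\tau$. The fit
starts overcomplete and the sparsity-inducing $\lambda_r$ shrink
unsupported components to zero, so the effective rank is inferred from the
data. Inference is mean-field variational Bayes with closed-form conjugate
updates; the evidence lower bound is monotone and is the convergence
criterion. Fusion weights each rank-one TF×TF matrix by the mean of its
layer-mode factor column — exactly the slice-mean of the reconstructed
tensor, so it reduces to plain network averaging when the factorization is
exact. See the methods vignette (`vignettes/tftensor-methods.Rmd`) for the
full account.

## Worked example

A synthetic panel of cell-type regulatory networks for one blood-like
lineage, integrated into a cell-lineage network:

```r
library(tftensor)

nets <- gen_regulatory_networks(
  n_tfs = 30,
  lineages = c(BL = 4, CA = 4, EN = 4),
  shared_modules   = list(1:6),                 # housekeeping module
  specific_modules = list(BL = list(7:12),      # one module per lineage
                          CA = list(13:18),
                          EN = list(19:24)),
  edge_noise = 0.05, seed = 11,
  baseline_occupancy = 0.1, module_target_count = 7)

# co-occupancy Jaccard networks for the 4 blood cell types, normalized
cts  <- lapply(nets$BL, function(n) normalize_network(cooccupancy_jaccard(n)))
tens <- stack_tensor(cts)
tens
#> observed_tensor: 30 x 30 x 4, 3480/3600 entries observed

fit <- bcpf(tens, cp_prior_config(R_init = 8, seed = 11))
fit
#> cp_state: rank 8, E[tau] = 29.14, 414 recorded sweeps (converged)

cl <- fuse_network_mode(fit)       # the fused cell-lineage network
strong <- strong_interactions(cl)  # Q3 + 1.5*IQR per-TF rule
head(strong, 5)
#>    tf_a tf_b    weight
#> 8  TF02 TF05 1.0000000
#> 24 TF09 TF11 0.9992667
#> 7  TF01 TF05 0.9884143
#> 15 TF05 TF06 0.9811571
#> 1  TF01 TF02 0.9771869

hub_tfs(strong)
#> [1] "TF07" "TF08" "TF09" "TF10" "TF11" "TF12"
```

The 54 strong edges concentrate on the planted modules, and the hub list
is exactly the blood-specific module TF07–TF12 — within the blood lineage
the shared module and the blood module are both present in every cell
type, but the specific module's TFs end up with the highest strong-edge
degrees. Against the planted truth, both the fused lineage network
(CL-Net) and the plain average of the four cell-type networks (AI-Net)
reach AUC 1.0000 here; the factorization's advantage appears once noise
and missingness grow (see the acceptance properties below). Repeating the
classification across the three lineages and calling
`classify_edges(strong_per_lineage)` labels each strong edge
`specific:<lineage>`, `shared`, or `housekeeping`.

For file-based work, `run_pipeline()` executes the staged pipeline
(simulate → build-networks → normalize → factorize → fuse → call-strong →
classify → evaluate) from a YAML or list config, writing every artifact as
TSV/JSON beside the resolved configuration.

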