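# mpgcn — multi-path graph convolutional networks for molecular property estimation

Estimating a chemical property (aqueous solubility, hydration free
energy, bioactivity) from molecular structure is a central task in
computational drug discovery. Graph convolutional networks learn the
feature extraction instead of relying on hand-designed fingerprints, but
most architectures specialise in one kind of structure — atom
connectivity, bond types, or 3D geometry. `mpgcn` implements a network
that extracts all three **simultaneously**, through parallel feature
extraction paths, and merges them with a per-atom attention mechanism.

For atom features `H_i` (60-dimensional one-hot blocks: element, degree,
H count, charge, aromaticity, ring membership) and `σ` the rectified
linear unit, each path updates features via pair terms over the
neighbour set `N(i)` (self included):

* node path: `P_ij = σ(W_np (H_i‖H_j) + B_np)`,
  `H_i' = σ(Σ_{j∈N(i)} W_n P_ij + B_n)`
* edge path: as above with the pre-activation scaled by the scalar edge
  parameter `E_ij = Σ_b w_b A_b[i,j] + c`, a learned 1×1 convolution
  across the five bond-channel adjacency matrices (self, single, double,
  triple, aromatic); a fixed categorical mode (w = 1…5) is provided for
  the corresponding ablation
* 3D path: pair terms weighted by relative coordinates `x_i − x_j`
  (and y, z), with the atom's own feature re-attached by concatenation
  (`σ(W_t (H_i‖Q_i))`), or dropped in the no-self variant

Per atom, attention scores over the enabled paths are soft-maxed into
weights `α_i^p` (summing to 1) and the streams merged as
`H_i = σ(W_agg Σ_p α_i^p H_i^p)`; concatenation / sum / max aggregators
are alternatives. A dimension-wise sum over atoms forms the molecular
vector; an affine head produces the prediction. Training is two-stage:
each path first learns independently with a temporary head, then the
paths are frozen and only the aggregation and final head are trained.
The evaluation protocol is repeated random 8:1:1 splits with metrics
averaged over trials (MAE for regression; accuracy, recall, precision,
F1 and ROC/AUC for classification).

Everything — forward passes, analytic backpropagation, Adam, early
stopping — is implemented in base R and verified against
finite-difference gradients and naive per-node loop oracles in the test
suite. A synthetic molecular-graph generator with exactly known
structure–property ground truth makes every path testable without any
external download.

## A worked example

Fit a node-path model on a synthetic "composition" task, whose exact
ground truth is a per-element weighted atom count:

```r
library(mpgcn)

records <- make_dataset(synth_spec(n_molecules = 500, mode = "composition",
                                   noise_sd = 0.1, seed = 1))
records[[1]]$graph
#> <molecular_graph 'synth_0001': 12 atoms, 11 bonds, 3D>
#>   bonds: SINGLE=5 DOUBLE=5 TRIPLE=1 AROMATIC=0
#>   elements: C O S C N S O O C C C O

fit <- mpgcn(records,
             model = model_config(paths = "node", seed = 1),
             training = train_config(max_epochs = 200, seed = 1))
summary(fit)
#> mpgcn fit: paths=node, T=2, M=60, 21901 parameters
#> training molecules: 450 (+50 validation)
#> stage-1 epochs: node=32; stage-2 epochs: 179
#> training MAE: 0.7236

predict(fit, records[1:3])
#>      predicted observed
#> [1,]     26.24    27.00
#> [2,]     11.99    11.95
#> [3,]     19.76    21.07
```

The targets here range from about 5 to 30 (the summed element weights of
4–12-atom molecules), so a training MAE of 0.72 — against injected noise
of sd 0.1 — means the path has learned the composition signal. `plot(fit)`
shows the stage-wise loss curves; `coef(fit)`, `residuals(fit)` and
`save_checkpoint(fit$model, ...)` behave as expected of an R model
object. Real datasets enter through `read_csv_dataset()` (SMILES) or
`read_sdf_dataset()` (SDF V2000 with a named property field), and
`run_trials()` runs the full repeated-split protocol. A command-line
wrapper with `train` / `evaluate` / `predict` / `synth` / `featurize`
subcommands is installed at `inst/cli/mpgcn`.

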