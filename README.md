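# cytomil

Attention-based multiple instance learning (MIL) for single-cell blood
smear cytomorphology.

## The problem

A stained peripheral blood smear yields a few hundred single
white-blood-cell images per patient, but the diagnosis — one of four
genetic subtypes of acute myeloid leukemia (*PML::RARA*, *NPM1*,
*CBFB::MYH11*, *RUNX1::RUNX1T1*) or healthy control — is only known at the
patient level, and often rests on a small minority of diagnostic cells.
cytomil treats each patient as a *bag* of unlabeled cell instances and
learns to classify the bag while reporting, per class, how much each cell
contributed. It is written for computational hematology researchers who
want a fully inspectable, CPU-only implementation of this model class with
every pipeline stage testable on synthetic data.

## The model

Instance features $x_k \in \mathbb{R}^d$ are embedded cell-wise,
$h_k = \mathrm{relu}(W_e^\top x_k + b_e)$, and scored by a **class-wise
attention matrix**

$$\alpha_{i,k} \;=\; \frac{\exp\{W_i^\top \tanh(V_i h_k)\}}
  {\sum_{j=1}^{N}\exp\{W_i^\top \tanh(V_i h_j)\}},$$

one softmax over the bag's cells *per class* $i$, so attention values
never compete across classes. Attention pooling
$z_i = \sum_k \alpha_{i,k} h_k$ gives one bag feature per class, a linear
head with non-negative evidence weights produces logits
$s_i = u_i^\top z_i + c_i$, and $p = \mathrm{softmax}(s)$. The model
returns the prediction together with the predicted class's attention row,
is permutation invariant, and — because a bag of one cell has attention
1 — doubles as a single-cell classifier ("deconvolution" of the smear).
Training minimizes bag-level cross-entropy with Adam, one step per bag,
early-stopped on validation loss, inside patient-level class-stratified
5-fold cross-validation.

Around the model, the package provides the data-cleaning cascade (Canny
edge-sum blur filter, < 20% blast-percentage exclusion from the routine
differential count, manual-exclusion hook, consort accounting), a small
trainable CNN feature extractor implementing the pre-pooling feature
contract (ResNet34 recipe carried as configuration; 12,800 features at
144×144), attention/annotation quartile concordance, per-class
representative cells, subsampling robustness curves, and a UMAP
fit/transform stage. A synthetic cohort generator plants rare
class-specific cells among shared background noise so that every claim the
model makes is checkable against known ground truth.

## Worked example

```r
library(cytomil)

spec <- synthetic_cohort_spec(
  n_classes = 3, bags_per_class = 10, bag_size_range = c(16, 30),
  feature_dim = 8, planted_fraction = 0.4, signature_separation = 6,
  classes = c("PML_RARA", "NPM1", "control"), seed = 7)
bags <- generate_feature_bags(spec)
bags[[1]]
#> <cytomil_bag> patient PML_RARA_p001 | label PML_RARA | 17 cells x 8 features

cfg <- mil_config(embed_dim = 16, attention_dim = 8, lr = 2e-3,
                  patience = 5, max_epochs = 40, seed = 3,
                  classes = c("PML_RARA", "NPM1", "control"))
cv <- cross_validate(bags, cfg = cfg, k = 5, seed = 9)
cv
#> <cytomil_cv> pooled confusion matrix:
#>           predicted
#> true       PML_RARA NPM1 control
#>   PML_RARA       10    0       0
#>   NPM1            0    9       1
#>   control         0    0      10
#> macro F1 (pooled): 0.967
#> per-class F1 over folds: PML_RARA 1.00+/-0.00, NPM1 0.93+/-0.15, control 0.96+/-0.09
```

The pooled confusion matrix counts every patient exactly once (each fold
contributes its held-out test set). Per-class F1 is reported both pooled
and as mean ± s.d. across folds.

```r
pred <- mil_forward(bags[[1]], cv$models[[1]])
pred
#> <bag_prediction> PML_RARA (p=0.997)
#> PML_RARA     NPM1  control
#>   0.9974   0.0003   0.0023

ranked <- rank_by_attention(pred)       # low attention first
head(ranked, 3)
#>   rank                cell_id bag_index   attention
#> 1    1 PML_RARA_p001_cell0015        15 0.001919235
#> 2    2 PML_RARA_p001_cell0012        12 0.002143637
#> 3    3 PML_RARA_p001_cell0002         2 0.004759452

mean(bags[[1]]$planted[tail(ranked$bag_index, 7)])  # top attention quartile
#> [1] 0.5714286
mean(bags[[1]]$planted)                             # base rate
#> [1] 0.2352941
```

The bag is classified as *PML::RARA* with probability 0.997, and the
cells the model attends to are enriched for the generator's planted
(diagnostic) cells — 57% of the top attention quartile versus a 24% base
rate in this bag. `predict_instances()` classifies each cell individually,
`quartile_concordance()` summarizes attention against expert relevance
annotations, and `subsample_robustness()` traces accuracy as a function of
how many cells are available.

A thin command-line front end is installed with the package
(`system.file("cli", "cytomil", package = "cytomil")`) with
`simulate`, `filter`, `train` and `explain` subcommands.

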