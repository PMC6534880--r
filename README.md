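# smilesrl

De novo design of target-focused small molecules in R: a recurrent
SMILES language model fine-tuned by policy-gradient reinforcement
learning against a QSAR activity reward, with a frozen **exploration
network** that stochastically overrides token selection so the generated
library stays chemically diverse instead of collapsing onto a few
high-reward molecules.

Who it is for: computational chemists and method developers who want a
self-contained, fully testable implementation of the
generator + reward + exploration-RL workflow — including dataset
curation, four QSAR backends, library evaluation metrics and
scaffold-space analyses — without any external database dependency.

## The method in brief

* **Generator** `G(y_t | y_1:t-1)`: token embedding (128) → 3 GRU layers
  (512 hidden) → softmax over the SMILES token vocabulary. Pre-trained
  by teacher-forced maximum likelihood (Adam, lr 1e-3, batch 500) on a
  drug-like corpus, optionally fine-tuned on the target's known ligands.
* **Reward** `Q ∈ [0, 1]`: the activity probability of a QSAR classifier
  (RF / SVM / NB / DNN) on 4096-bit ECFP6 fingerprints. Activity tables
  are curated by canonical-SMILES merging, pChEMBL averaging and the
  rule *negative iff mean pChEMBL < 6.5 or annotated "Not Active"*.
* **Reinforcement learning** maximizes

      J(θ) = Σ_t log G_θ(y_t | y_1:t-1) · (Q(y_1:T) − β)

  over sampled, per-epoch-deduplicated batches (β is a reward baseline;
  invalid molecules earn 0). During sampling, each step delegates token
  choice to a frozen copy of the generator `G_φ` with probability ε —
  the exploration strategy that preserves diversity. ε > 0.25 or β > 0.1
  are documented not to converge and trigger a warning.
* **Evaluation**: valid / desired / unique percentages, internal
  diversity `I(A) = |A|⁻² Σ T_d(a,b)` over all ordered fingerprint
  pairs, furan / benzene / fused-ring rates, 19 physicochemical
  descriptors, PCA / t-SNE chemical-space maps, k-means (k = 20)
  scaffold-occupancy comparison, and candidate ranking by score then
  novelty.

Chemistry primitives (RDKit) and the scikit-learn estimators run in a
bundled Python worker reached over a local socket; the GRU and its
backpropagation-through-time gradients are compiled RcppArmadillo code
inside the package.

## Worked example (desk scale)

Everything below runs from synthetic fixtures: a fragment-grammar corpus
whose "active" molecules carry a planted furan motif (prevalence 0.3,
label noise 5%), emulating the real setting where the fingerprint
reward keys on substructures.

```r
library(smilesrl)

fc <- fixture_config(n_molecules = 600, seed = 7, motif_prevalence = 0.3,
                     label_noise = 0.05)
dataset <- curate_activity_dataset(generate_activity_set(fc))
#> QSAR dataset: 410 molecules (129 positive, 281 negative), 4096-bit ECFP6

crossvalidate_predictor(dataset, "RF", k = 5, seed = 101)
#> CV: AUC 0.935 | MCC 0.886 | Sens 0.876 | Spec 0.986 | Acc 0.951
predictor <- train_predictor(dataset, "RF", seed = 1,
                             params = list(n_trees = 300))

corpus <- generate_corpus(fixture_config(n_molecules = 2000, seed = 7))
pre <- pretrain_generator(corpus, epochs = 50, batch_size = 100,
                          embedding_dim = 32, hidden_size = 64, layers = 1,
                          valid_sample_size = 0, seed = 1)

cfg <- rl_config(epsilon = 0.1, beta = 0, epochs = 30, batch_size = 300,
                 seed = 11)
rl <- train_rl(pre$model, freeze_generator(pre$model), predictor, cfg)

batch_report(sample_generator(pre$model, 1000, seed = 5), predictor)
#> Batch of 1000 | valid 94.6% | desired 34.8% | unique 66.7% | unique desired 22.2%
#> Internal diversity (unique_desired): 0.808
batch_report(sample_generator(rl$model, 1000, seed = 5), predictor)
#> Batch of 1000 | valid 93.3% | desired 85.8% | unique 81.7% | unique desired 68.9%
#> Internal diversity (unique_desired): 0.816
```

Reading the numbers: after 30 RL epochs the fraction of generated
molecules the predictor classifies active ("desired") rises from 34.8%
to 85.8% and the unique-desired yield from 22.2% to 68.9%, while
validity (RDKit-parseable) stays above 93% and the internal Tanimoto
diversity of the unique desired set is *maintained* (0.808 → 0.816) —
the point of the exploration network. With ε = 0 the same loop enriches
activity but measurably erodes diversity (see
`tests/testthat/test-acceptance.R`, criterion 8).

`run_pipeline(pipeline_config(seed = 1), "run")` executes the whole
workflow (fixtures → QSAR → pre-train → fine-tune → RL → evaluation)
with per-stage checkpoints and TSV reports, and `inst/cli/smilesrl`
exposes the stages as subcommands (`make-fixtures`, `train-qsar`,
`pretrain`, `finetune`, `train-rl`, `sample`, `evaluate`, `run-all`).

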