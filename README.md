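# triagonist

Multi-task graph-attention modelling and evolutionary design of peptide
triple agonists of the incretin-axis receptors GCGR, GLP1R and GIPR.

Peptides that activate all three receptors (the class that includes
retatrutide) are a leading direction in metabolic-disease therapeutics,
but assay datasets are small, multi-source, and full of missing labels.
`triagonist` provides the full computational design loop for this setting:

* **Sequence handling** — tokenization of peptide strings with bracketed
  non-standard residues (`[dS]`, `[K (yE-C16)]`), activity tables with
  per-receptor EC50 values (high affinity = EC50 < 1000 pM), FASTA I/O.
* **Physicochemical profiling** — ProtParam-compatible molecular weight,
  isoelectric point (Bjellqvist pKa, charge-balance bisection), Guruprasad
  instability index, GRAVY, estimated logP, and polar surface area
  (50 Å² per polar residue).
* **Classifier** — residue chain graphs with 7-channel node features feed a
  shared 4-layer GATv2 encoder (6 heads, 96 hidden) with Set2Set readout
  and three per-receptor heads, trained with a masked multi-task focal
  loss by a three-stage transfer protocol (GCGR/GLP1R first, frozen-encoder
  GIPR head next, unified fine-tuning last). Implemented natively
  (vectorized R + RcppArmadillo kernels, hand-derived backpropagation
  verified against finite differences); no deep-learning framework needed.
* **Evaluation** — stratified 5-fold cross-validation over joint activity
  patterns, Mann–Whitney AUC-ROC, AUC-PR, threshold metrics, fold-model
  ensembling, and similarity-based novelty filtering of validation sets.
* **Design** — a multi-objective genetic algorithm over token sequences
  with fitness `F = H + P + P_min + B + N + D` (receptors hit, mean and
  minimum predicted probability, biological plausibility
  `B = 0.3C + 0.35M + 0.2P + 0.15A`, novelty, diversity), tournament
  selection, single-point crossover, adaptive 70/20/10 mutation,
  elitism and motif-preserving repair.
* **Synthetic data** — a generator that emulates the curated-dataset shape
  (234 sequences; labels for 206/234/56 records; positive fractions
  0.490/0.748/0.571) around a planted, recoverable structure→activity
  rule, so the whole pipeline is testable offline.

## Worked example

Profile a designed candidate and compare it to the packaged reference
panel of 20 published triple-agonist candidates:

```r
library(triagonist)

pep_properties("YAEGTFFTSDYSKLHKEAAEAFINWLIQTKITD")
#> # A tibble: 1 x 8
#>   length mol_weight isoelectric instability_index  gravy est_logP est_psa net_charge_ph7
#>    <int>      <dbl>       <dbl>             <dbl>  <dbl>    <dbl>   <dbl>          <dbl>
#> 1     33      3839.        5.01              20.7 -0.333   -0.333     850          -2.14
```

The 33-mer weighs 3839.22 Da, is mildly acidic (pI 5.01), predicted stable
in vitro (instability index 20.7 < 40), hydrophilic (GRAVY −0.33), and
carries 17 polar residues (850 Å² estimated PSA) — values that match the
published characterization of this candidate exactly.

```r
panel <- reference_candidates()
s <- summarize_report(panel)
s$motif_counts
#> # A tibble: 1 x 3
#>   motif count     n
#>   <chr> <int> <int>
#> 1 EGTF     13    20
```

13 of the 20 reference candidates retain the contiguous EGTF incretin core.

Train and design against synthetic data with a planted rule:

```r
ds  <- generate_dataset(synth_config(seed = 1))
tc  <- train_config(stage1_epochs = 60, stage2_epochs = 30,
                    stage3_epochs = 15, patience = 999,
                    batch_size = 16, seed = 1)
cv  <- crossval(ds$records, gat_config(focal_alpha = 0.5, focal_gamma = 0), tc)
glance(cv)            # per-receptor mean/sd AUC-ROC and F1
autoplot(cv)          # fold-level AUC boxplots

res <- ga_evolve(ga_config(seed = 1), predictor_from_models(cv$models),
                 ga_context(ds$records$tokens))
autoplot(res)         # fitness trajectory
report <- build_report(res$final_population, ds$records,
                       predictor = predictor_from_models(cv$models))
```

A thin command-line wrapper over the same functions ships in
`inst/cli/triagonist` (subcommands `synth`, `train`, `crossval`, `predict`,
`optimize`, `report`; every run writes a JSON manifest with its seed).

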