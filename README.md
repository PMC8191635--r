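# m6ager

Prediction of N6-methyladenosine (m6A) sites in RNA from sequence-derived
features and graph embeddings.

m6A is the most prevalent internal mRNA modification and is involved in
splicing, export, stability and translation. Experimental mapping
(MeRIP-seq, miCLIP) is costly, so sequence-based classifiers that score a
candidate adenosine from its local context are widely used. `m6ager`
implements the m6AGE approach for users who have fixed-length RNA segments
(odd length, candidate A at the center, e.g. the A101/A25/S21/H41 benchmark
sets) and want a tested, reproducible predictor with feature-level
interpretability.

## Method

Each segment is encoded by seven sequence-derived feature families:

| Block | Features | Dimension |
|---|---|---|
| CTD | composition, adjacent-pair transitions, occurrence-position distribution | 30 |
| PseKNC | k-mer frequencies + λ physicochemical correlation tiers, d_u = f_u/(1 + wΣθ) | 4^k + λ |
| NPS | k-spaced pair frequencies C(n1{k}n2)/(L−k−1), k ≤ d_max | 16·d_max |
| NPPS | positional conditional pair probabilities, p_i = p_i⁺ − p_i⁻ | L−k−1 per k |
| NCP-ND | chemical-property bits (A=111, U=010, C=001, G=100) + cumulative density | 4L |
| EIIP | electron-ion interaction pseudopotentials (A 0.1260, C 0.0806, G 0.1335, U 0.1340) | L |
| BPB | interleaved class-conditional positional frequencies (f⁺, f⁻) | 2L |

NPPS and BPB are fitted on the training split only. On top of the fused
sequence features, a sample-similarity network is learned with the fast
linear neighborhood similarity approach (FLNSA): W minimizes

    0.5·‖X − (C⊙W)X‖²_F  s.t. (C⊙W)e = e, W ≥ 0,

with C the c-nearest-neighbor indicator, solved by multiplicative updates.
The thresholded, binarized graph is embedded three ways — SocDim (top
eigenvectors of the modularity matrix B = A − dd<sup>T</sup>/2|E|), Node2Vec
(biased second-order walks + skip-gram with negative sampling), and GraRep
(truncated SVD of k-step log-transition matrices) — and the embeddings are
fused with the sequence blocks as supplementary features. A class-weighted
gradient-boosted decision-tree classifier (xgboost backend; weights
inversely proportional to class sizes) is trained on the 4:1 stratified
split and evaluated with ACC, MCC, SEN, SPE, F1 and rank-based AUC.

## Worked example

```r
library(m6ager)

# synthetic benchmark: 41-nt segments, RRACH consensus planted in positives
d <- generate_dataset(n_pos = 1000, n_neg = 1000, L = 41,
                      motif = "RRACH", motif_strength = 0.9, seed = 1)

run <- run_pipeline(d, pipeline_config(blocks = "auto", seed = 1))
run
#> <m6a_run> 2000 samples, blocks: NPPS, PseKNC, NCP_ND
#> <m6a_metrics> n = 400 (TP 175, TN 179, FP 21, FN 25)
#>   ACC 88.50%  SEN 87.50%  SPE 89.50%  F1 0.8838  MCC 0.7702  AUC 0.9360
```

The held-out 20% of the data is scored by the trained model: 88.5% of the
400 test segments are classified correctly, the Matthews correlation (a
balanced summary in [−1,1]) is 0.77, and the ranking quality (AUC) is 0.94.
`glance(run)` returns these as a one-row tibble, `tidy(run)` the per-sample
predictions, and `autoplot(run)` the ROC curve.

```r
run$importance
#> <m6a_importance> top 20 features (20% from graph embeddings)
```

Feature importance traces every score back to its encoder block; here 4 of
the top-20 features are graph embeddings, showing the network contributes
signal beyond the sequence encoders. Real data are read with
`read_fasta_samples("pos.fa", "neg.fa")`, and the per-dataset block choices
of the published benchmarks ship as presets
(`pipeline_config(blocks = "A101")`, etc.). A thin command-line front end
lives at `inst/cli/m6age.R` (subcommands `synth`, `split`, `run`,
`predict`, `presets`).

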