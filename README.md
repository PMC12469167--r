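# mngsort

Spike-sorting *feasibility* assessment for noisy single-electrode
microneurography recordings of human C-fibres.

## The problem

A microneurography electrode picks up spikes from several C-fibres at once,
at signal-to-noise ratios where conventional unsupervised spike sorters
break down. The *marking method* gives partial ground truth: under
low-frequency background electrical stimulation (0.125–0.25 Hz) each fibre
responds at a near-constant latency, so its spikes form a *track* — the
equivalent of a sorted unit — that can be labelled reliably. `mngsort` uses
those labels to estimate whether a recording is sortable at all, before
anyone tries to sort its unlabelled (spontaneous or naturally evoked)
activity.

Per recording, the package computes:

* **Supervised separability** — stratified 5-fold cross-validated
  classification of the tracks (RBF-SVM with `C = 1`,
  `gamma = 1/(d·Var(X))`, or a random forest) on six waveform feature
  sets: amplitude + FWHM (`simple`), shape/phase/distribution derivative
  features (`SPDF_raw`, 23-dim; `SPDF_FV3`: max f′, max f″, min f″),
  per-recording PCA scores (`W_2PCA`, `W_3PCA`) and the aligned raw
  waveform (`W_raw`). Metrics: accuracy (fraction correct) and
  macro-averaged precision/recall/F1, against the chance level `1/k`.
* **Template similarity** — per-track mean waveforms compared by
  MSE = (1/n)Σ(tᵢ−t̂ᵢ)², MAE = (1/n)Σ|tᵢ−t̂ᵢ|, RMSE = √MSE; small
  distances flag fibre pairs too similar to separate.
* **Unsupervised limitation analysis** — k-means (k fixed to the known
  track count) on each feature space, scored against the labels with ARI,
  NMI and V-measure, quantifying how far the conventional PCA + clustering
  route falls short on this kind of data.
* **Cross-dataset statistics** — paired two-sided Wilcoxon signed-rank
  tests between feature sets with Bonferroni adjustment (α = 0.01/n).

Everything is testable end-to-end through a parametric generator of
marking-method recordings (tracks, activity-dependent slowing, controlled
template distances, controlled SNR).

## Worked example

```r
library(mngsort)

# a two-fibre recording whose templates are exactly 0.6 V apart (RMSE)
pair <- make_template_pair(0.6)
cfg  <- synthetic_config(n_fibers = 2, n_sweeps = 40,
                         templates = list(pair$a, pair$b), seed = 1)
rec  <- generate_recording(cfg)
rec
#> <mng_recording> 160.5 s @ 10000 Hz | 40 stimuli | 80 spikes (80 labeled, 2 tracks)

prep <- extract_waveforms(rec)          # window, resample, align; count exclusions
tpl  <- compute_templates(prep$waveforms)
template_distance(tpl$Track1, tpl$Track2)   # estimated from the noisy trace
#> [1] 0.7138

rep_ <- run_cv(feature_matrix(prep$waveforms, "W_raw"), classifier_spec(seed = 1))
round(rep_$mean, 3); rep_$chance
#> accuracy precision    recall  macro_f1
#>        1         1         1         1
#> [1] 0.5

run_kmeans_eval(feature_matrix(prep$waveforms, "SPDF_FV3"), 2, seed = 1)$ari
#> [1] 0.192
```

Reading the numbers: the two tracks are *perfectly* separable by a
supervised classifier (accuracy 1.0 vs chance 0.5), yet blind k-means on the
three-feature subset barely beats random labelling (ARI 0.19) — the
disconnect between supervised separability and unsupervised cluster
visibility that motivates the package. The template-distance estimate
(0.71) overshoots the generated 0.60 because at this noise level alignment
jitter smears the averaged templates apart; the bias and the conditions
under which the estimator is unbiased are quantified in the methods
vignette (`vignettes/sortability-methods.Rmd`).

The same workflow runs over many recordings at once, with report CSVs:

```sh
exec/mngsort all --config config.yaml --outdir reports/
exec/mngsort simulate --outdir demo_recording/ --fibers 3 --sweeps 80
```

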