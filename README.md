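# jgrs: multi-phase structured pruning for compact neural decoding networks

Decoding behavior from neural activity — for example, classifying a
mouse's fine-motion state from calcium-imaging traces of tens to hundreds
of neurons — increasingly relies on MLP and CNN classifiers. Real-time
uses (closed-loop neuromodulation, brain–computer interfaces) need these
decoders compact, so overparameterized models are *structurally pruned*:
whole nodes or filters are removed together with all dependent weights,
producing a dense smaller network that needs no sparse-kernel support.

`jgrs` implements the **jump greedy-random-selection (JGRS)** multi-phase
pruning schedule and everything needed to study it, for R users in
computational neuroscience and anyone pruning small-to-medium
feed-forward classifiers:

* a model substrate (MLP/CNN build, train, validate) supporting exact
  weight-preserving unit surgery, with parameter and FLOP accounting;
* the JGRS schedule — for hidden layer λ with width *u* and floor μ[λ],
  the *pruning midpoint* is `max(floor((u − μ[λ])/2), 1)`; far subphase 1
  cuts every layer's midpoint per sweep (one retrain per sweep), far
  subphase 2 cuts one layer's midpoint per greedy candidate round, and the
  near phase is per-unit greedy random selection (GRS), all bounded by the
  accuracy floor `ValAcc_min = 𝒯 · OriValAcc` (default 𝒯 = 0.985) and
  the per-layer minimum unit-count vector μ;
* the GRS, RRS (random sensitivity probe) and NWM (weight-magnitude)
  baselines, with full per-step traces and global retrain-call counters —
  the hardware-independent speed proxy;
* comparison metrics (signed accuracy-loss, FLOP- and parameter-count
  improvement differences, runtime ratio) and summary tables;
* seeded synthetic generators emulating calcium-trace decoding data,
  balanced graph-embedding vectors, and parity-planted data whose labels
  provably exceed minimal-network capacity.

See the methods vignette (`vignettes/structured-pruning.Rmd`) for the
model, conventions and design choices.

## Worked example

Prune a 16×16×16 decoder trained on synthetic calcium-like data
(60 neurons, 3000 samples at 10 Hz, binary fine-motion-style labels) down
to a 2×2×2 floor:

```r
library(jgrs)

ds <- generate_msn_like(msn_gen_params(beta = 60, seed = 11))
ds <- split_8_1_1(ds, 11)                     # 2400/300/300
tr <- dataset_split(ds, "train")
va <- dataset_split(ds, "validation")

cfg   <- train_config(epochs = 40, fine_tune_epochs = 6)
model <- build_model(mlp_spec(60, c(16, 16, 16)), seed = 11)
model <- train_model(model, tr, cfg)
model
#> <jgrs_model> mlp; hidden units [16,16,16]; 1554 params, 3008 FLOPs
validate(model, va)
#> [1] 0.94

res <- jgrs(model, tr, va,
            pruning_config(mucv = c(2, 2, 2), seed = 11, train_cfg = cfg))
res
#> <prune_result> hidden [2,2,2]; acc 0.9433 (floor 0.9259); 140 params, 264 FLOPs
#>   5 trace steps; 5 fine-tune, 15 validate calls

head(res$trace[, c("stage", "round", "units_cut", "cr", "val_acc", "accepted")])
#>   stage round units_cut cr   val_acc accepted
#> 1  far1     1        21 21 0.9433333     TRUE
#> 2  far1     2         9  9 0.9400000     TRUE
#> 3  far1     3         6  6 0.9433333     TRUE
#> 4  far1     4         3  3 0.9333333     TRUE
#> 5  far1     5         3  3 0.9433333     TRUE
```

Reading this: the original decoder scores 0.94 validation accuracy with
1554 parameters. Five far-phase sweeps — each removing the sum of the
per-layer midpoints (compression rate 21, then 9, 6, 3, 3) with a single
retrain each — reach the 2×2×2 floor at accuracy 0.9433, above the floor
0.9259 = 0.985 × 0.94, keeping 9% of the parameters after only 5
fine-tune calls. Plain GRS performs a retrain for *every candidate of
every single-unit removal* (typically >100 fine-tunes on this task);
pruning-cost comparisons use these counters via `call_counters()`.

Higher-level drivers: `run_prune()` (one method, artifacts to disk),
`run_compare()` (JGRS vs GRS vs NWM records and summary tables),
`run_phase_trace()` (the RRS far/near sensitivity curve). A thin
command-line front end with verbs `prune`, `compare`, `phase-trace` and
`generate-data` is installed at `inst/cli/jgrs.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/jgrs.R", package = "jgrs"))')" \
  prune --method jgrs --beta 60 --mucv 2,2,2 --tolerance 0.985 --out out/
```

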