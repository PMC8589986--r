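# echoclass

Acoustic differentiation and classification of beluga
(*Delphinapterus leucas*) and narwhal (*Monodon monoceros*) echolocation
clicks, for passive acoustic monitoring (PAM) work where the two species
co-occur and must be told apart from their biosonar alone.

The package implements the full analysis chain:

1. **Synthesis** — a calibrated synthetic world: Gabor-component click
   templates (beluga: smooth spectrum peaking at 68.7 kHz; narwhal:
   notched spectrum peaking at 43.7 kHz), log-normal inter-click
   intervals, 81 events across 7 encounters, white-noise recordings at
   500 kHz.
2. **Detection** — 4 kHz Butterworth high-pass, smoothed Teager–Kaiser
   energy, 14 dB SNR threshold over a median noise floor, 800-sample
   snippets, and detector codes 0–6 by peak-frequency band.
3. **Click parameters** — the twenty standard measures per click:
   spectral peaks/troughs, −3/−10 dB band edges with bandwidth, centre
   frequency and Q, Teager–Kaiser duration, inter-click interval.
4. **Events** — clicks tiled into 1-min (beluga) / 2-min (narwhal)
   windows; event features are per-parameter means plus the modal ICI.
5. **Statistics** — z-scored Euclidean distances, perMANOVA and PERMDISP
   (999 permutations), PCA on the correlation matrix with sequential
   broken-stick significance.
6. **Classifiers** — a balanced random forest (equal per-class samples
   drawn *without replacement* per tree; OOB confusion with exact
   binomial inference, permutation importance, proximity MDS, sensitivity
   grid) and a two-stage call/event classifier with encounter-similarity
   validation.  The forest is compiled (Rcpp) so the published
   10 000–20 000-tree models fit in seconds.

## Worked example

```r
library(echoclass)

cfg <- sim_config(seed = 3)               # 19 beluga + 62 narwhal events
ds  <- generate_dataset(cfg)
cl  <- pipeline_click_features(ds)        # render -> detect -> measure
ev  <- build_event_table(cl)

aggregate(cbind(peak, fmin_3dB) ~ species, ev, mean)
#>   species     peak fmin_3dB
#> 1  beluga 66.44862 62.76172
#> 2 narwhal 43.83886 40.66103

d <- zscore_and_distance(ev)
set.seed(1)
permanova(d, ev$species)
#> pseudo-F(1, 79) = 203.614, p = 0.001 (999 permutations)

set.seed(1)
permdisp(d, ev$species)$group_dispersion   # beluga events more dispersed
#>   beluga  narwhal
#> 2.290168 1.540140

rf <- fit_balanced_forest(ev[, feature_names()], ev$species,
                          mtry = 4, sampsize = 9, ntree = 10000)
rf$confusion
#>          predicted
#> observed  beluga narwhal
#>   beluga      19       0
#>   narwhal      0      62

bt <- fit_banter(cl)                      # two-stage classifier
bt$call_stage$detectors                   # 2 3 4 5
summary_row <- bt$event_stage$summary
summary_row[summary_row$class == "Overall", "rate_pct"]
#> [1] 100
```

The event-mean peak frequencies recover the calibrated species values
(68.7 / 43.7 kHz) up to the event-to-event spread (±10.1 / ±7.8 kHz over
19 / 62 events — the single-seed beluga mean above is 2.3 kHz low for
exactly that reason); the perMANOVA separates the species at the
permutation floor p = 0.001; and both classifiers sit at their ceiling on
this well-separated synthetic world (the field-data reference points are
92.6% for the single forest and 97.5% for the two-stage model).

A subcommand CLI wraps the same pipeline:

```sh
Rscript -e 'echoclass::cli_main()' run-all --seed 1 --out-dir out/
```

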