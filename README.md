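# sceneprobe

Tools for studying how local image reconstruction in natural scenes is
controlled by object-segmentation structure ("top-down": where human
annotators agree an object boundary lies) versus raw edge energy
("bottom-up": where the physical image has strong luminance gradients).

The experimental logic the package implements: every scene gets two
co-registered maps —

* a **bottom-up map**: Sobel gradient energy, RMS-pooled over a 0.9° disc
  and max-normalized to [0, 1];
* a **top-down map**: the proportion of annotators whose (0.5°-thickened)
  boundary drawing covers each pixel.

Four probe insertion points per scene cross rich/poor values on the two
maps while holding the other map matched: the top-down-rich point with the
*smallest* bottom-up value v, the top-down-poor point closest to v, the
top-down-poor point with the *largest* bottom-up value V, and the
top-down-rich point closest to V (eligibility: local boundary elongation
≥ 0.9, bottom-up ≥ 0.1, ≥ 2° from the edge; points ≥ 1.6° apart). A probe
— 16 superimposed Gabor wavelets spanning orientation, with a target of
intensity ρ on the congruent (channel 5) or incongruent (channel 13)
orientation plus Gaussian orientation noise (mean 3%, SD 0.7% contrast,
clipped at ±4 SD) — is grafted into the scene, and the observer reports
congruent vs incongruent.

From trial records the package computes sensitivity d′ = z(H) − z(F) and
criterion c = −(z(H)+z(F))/2, rich/poor effects as natural-log ratios
ln(d′_rich/d′_poor) with Wilcoxon group tests, reverse-correlation
orientation tuning functions

p = ⟨n[1,1]⟩ + ⟨n[0,0]⟩ − ⟨n[1,0]⟩ − ⟨n[0,1]⟩,

the retuning index (p(13) − p(5))² / Σp², and double-pass internal-noise
estimates by inverting a two-pass late-noise SDT model on percent correct
and percent agreement. It also ships the quadrature-pair gain-control
observer with Poor/Rich filter states, the full set of scene
manipulations (lowpass/highpass filtering, swirl/lens warping,
cut-out/lines, phase/power scrambling, gap stimuli), a lateralized ERP
stage (contra-minus-ipsi differencing, rich-minus-poor modulation maps
with across-subject Z scores, occipital window pooling), and synthetic
generators for annotated scenes, observer cohorts and ERP epochs so the
whole pipeline runs and validates without external data.

See `vignette("sceneprobe-methods")` for the model details and design
decisions.

## Worked example

```r
library(sceneprobe)

## a synthetic annotated scene -> maps -> the four insertion points
gen <- generate_scene(scene_generator_config(), seed = 7)
sel <- scene_to_points(gen)
insertion_points_df(sel$points, scene_id = 7)
#>           scene_id row col td_label bu_label congruent_theta matched_value
#> rich_poor        7  62 172     rich     poor           2.770         0.218
#> poor_poor        7 104 153     poor     poor           1.338         0.218
#> poor_rich        7  48 106     poor     rich           0.746         0.838
#> rich_rich        7  27 178     rich     rich           0.863         0.838

## simulate a cohort whose top-down-rich insertions engage the sharper
## observer state, then analyze it
trials <- simulate_experiment(insertion_points_df(sel$points, 7),
                              cohort_config(n_subjects = 8,
                                            trials_per_cell = 150),
                              seed = 1)
summarize_experiment(trials)
#> <experiment_summary> 8 observers
#>   top-down  log-ratio: median 0.5797, 95% CI [0.3432, 0.7177], Wilcoxon p = 0.007813 (n=8)
#>   bottom-up log-ratio: median -0.0838, 95% CI [-0.1569, 0.0375], Wilcoxon p = 0.25 (n=8)
```

The top-down rich/poor log-ratio is positive (rich insertions roughly
e^0.58 ≈ 1.8× more sensitive) with a significant group test, while the
bottom-up contrast straddles zero — exactly the ground truth built into
the simulated cohort. The reverse-correlation kernels show the same
dissociation as tuning sharpness:

```r
tr <- symmetrize(reverse_correlation(trials[trials$td_label == "rich", ]))
tp <- symmetrize(reverse_correlation(trials[trials$td_label == "poor", ]))
retuning_index(tr)   # 0.874  (sharp kernel at rich insertions)
retuning_index(tp)   # 0.533  (broader kernel at poor insertions)
```

A command-line wrapper over the same functions lives at
`inst/cli/sceneprobe.R` (subcommands `synth`, `simulate`, `analyze`,
`run`).

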