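# licklock

Analysis of cerebellar Purkinje-cell spike trains recorded during rhythmic
licking.

When head-fixed mice drink from a water spout they lick in bouts at roughly
6 Hz. Purkinje cells of the cerebellar vermis and adjacent hemispheres fire
two kinds of spikes during this behaviour — high-rate simple spikes (SS,
tens of Hz) and sparse climbing-fibre-driven complex spikes (CS, ~1 Hz,
each followed by a pause in simple-spike firing) — and both can carry
information
about the lick rhythm, the start and end of bouts, the direction of tongue
protrusion, and adaptation to a moving target. `licklock` implements the
full analysis chain for such recordings, for electrophysiologists and
computational neuroscientists working with paired spike/behaviour event
tables:

- **Bout segmentation** — maximal runs of licks with inter-lick intervals
  below 500 ms (`segment_bouts()`), plus cell-inclusion checks (every CS
  followed by a ≥ 8 ms SS pause, ≥ 20 analysable trials;
  `validate_cell()`).
- **PSTHs and Z-scoring** — 10 ms peri-stimulus time histograms with
  Z = (value − baseline mean)/baseline SD under the three baseline
  conventions (−1000..−500 ms before bout start, +500..+1000 ms after bout
  end, −1000..−250 ms before the licks of interest), modulation depth
  (max − min within a 200 ms window), and CS responses at bout transitions
  (`compute_psth()`, `zscore_psth()`, `bout_transition_response()`).
- **Phase-transform coherence** — spike times are warped onto the lick
  cycle (phase 0 = protrusion start, π = maximal protrusion, 2π = end of
  retraction) and the magnitude-squared coherence between the spike–lick
  cross-correlogram and the lick autocorrelogram is read at the lick
  fundamental; cells with msc > 0.5 are classed coherent
  (`build_phase_map()`, `lick_coherence()`). Autocorrelogram power inside
  versus outside bouts quantifies whether rhythmicity is confined to licking
  (`autocorr_power()`), and `grid_summary()` reduces per-cell values on the
  8×4 electrode grid to the interpolated 7×3 map.
- **Endpoint kinematics** — per-session tertile "rosette" over tongue
  endpoints, SS Z-maps in the two pre-protrusion windows (−150..−75 and
  −75..0 ms before maximal protrusion), and ipsiversive vs contraversive
  comparisons (`build_rosette()`, `zone_ss_map()`, `lateral_comparison()`).
- **Decoding** — 200 ms snippets (10 ms overlap) featurised as SS rate, SS
  CV2 (CV2 = 2|ISIₙ₊₁ − ISIₙ|/(ISIₙ₊₁ + ISIₙ)) and CS rate; balanced
  training sets (two thirds of the smaller class per class); an XGBoost
  classifier (histogram split finding, 4096 trees of depth 8 by default)
  with per-class accuracies, the predictive (>55%) / strongly predictive
  (>65%) classification, and mean |SHAP| feature attribution
  (`extract_windows()`, `balanced_split()`, `train_eval()`).
- **Perturbation trials** — closed-loop lick-port displacements (3 mm
  rightward, onset 40 ms after a trigger lick, return after 750 ms) and
  optogenetic stimulation: lick indexing around movements, normalization to
  pre-movement coordinates, CS movement responses and direction
  selectivity, SS adaptation peaks, and opto effect estimation
  (`index_trial_licks()`, `cs_move_response()`, `opto_effect()`).
- **Synthetic sessions** — a seeded generative model
  (`generate_session()`) with von Mises phase-locked SS, bump-modulated CS,
  enforced CS pauses, endpoint coupling, port-following and opto effects,
  returning the full ground truth so every stage is validated by parameter
  recovery.

## Worked example

```r
library(licklock)

gen <- generate_session(behaviour_spec(),
                        list(pc1 = cell_spec(ss_kappa = 4, ss_phase_pref = pi,
                                             cs_bout_start_gain = 5)),
                        duration = 300, seed = 42)
sess  <- gen$session
bouts <- segment_bouts(sess$licks)          # 107 bouts from 752 licks
cell  <- sess$cells$pc1

validate_cell(cell, n_trials = n_licks(sess$licks))
#> <validity_report> pc1: pause ok (0 offenders), trials ok (752), PASS

pm <- build_phase_map(sess$licks, bouts)
lick_coherence(cell$ss_times, pm)
#> <coherence> msc 0.999, phase 3.08 rad, coherent (8023 spikes)

bout_transition_response(cell$cs_times, bouts, "start", session_duration = 300)
#> <modulation> depth 9.20 Z, peak Z 8.87, significant

decode_cell(cell, sess$licks, seed = 1, nrounds = 256)
#> <decoder> bout 64.7%, inter-bout 62.9% -> predictive
#>   mean |SHAP|: ss_rate 0.897, ss_cv2 2.053, cs_rate 0.385
```

The cell was generated with strong phase locking (κ = 4) at preferred phase
π, so the coherence is near 1 and the recovered phase (3.08 rad) matches
the ground truth; the bout-start complex-spike gain produces a significant
(Z > 3) transition response. The decoder classifies 200 ms windows as
lick/no-lick well above chance, with CV2 the most informative feature for
this purely phase-locked cell (locking reshapes spike patterning more than
the window-averaged rate).

`run_pipeline(pipeline_config(...))` chains every stage over a whole
session (simulated or read from CSV event tables via `read_session()`) and
returns a per-cell summary table plus population fractions.

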