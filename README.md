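# trackvalidatr

Validated overlap-based tracking of unlabeled cells in time-lapse
microscopy.

## The problem

Label-free time-lapse imaging is the only way to watch large numbers
of living cells proliferate without disturbing them, but turning an
image stack into biology requires following every cell through every
frame, across divisions, into genealogic trees. Tracking errors
propagate fatally: with a per-frame success probability *p*, an
*n*-frame path survives with probability *p*ⁿ — 95% detection leaves
only 7.7% of 50-frame paths intact. Detectors cannot be made good
enough to fix this; the output has to be **validated**.

trackvalidatr implements an automated validation layer on top of a
deliberately simple tracker:

* **Detection** — high-pass illumination correction, Otsu global
  threshold, morphological refinement; each 8-connected bright region
  is a detected cell ("cell mask").
* **Overlap tracking** — cells are linked between frames when their
  forward overlap (intersection / own area) and backward overlap
  (intersection / candidate area) both exceed thresholds and the link
  is unambiguous; maximal unambiguous chains form *path fragments*,
  and all concurrent candidates are kept in a fragment adjacency
  relation.
* **Mitosis detection** — a division must be a Y-junction (one
  fragment, exactly two successors) *and* show the morphological
  division pattern (the cell shrinks, rounds and brightens), scored
  as a multivariate-normal density of the terminal feature-difference
  vector, Prob(d) > t_mit.
* **Validation** — every fragment terminus is explained by an error
  decision tree (movie boundary → image border → merged cells →
  mitosis → vanished/recovered → cell death → debris → unresolved).
  Only *complete paths* — whole cell lives from one mitosis to the
  next, touching no merge, border or unresolved terminus — are
  accepted. If in doubt, the path is excluded.
* **Evaluation** — detection FAR/FRR with dual 30%-overlap matching,
  tracking and mitosis *trustworthiness* (100 × correct/returned),
  and genealogic degree-of-relation error rates, plus the unvalidated
  `naive_track()` baseline to quantify what validation buys.
* **Biology** — proliferation curves, confluency and mean cell area,
  division probability per time window, life-time (cell-cycle)
  distributions, sibling division symmetry and lineage-tree
  summaries, all as tidy tibbles.
* **Simulator** — a seeded synthetic time-lapse generator with
  pixel-exact ground-truth masks, lineage and an event log, which
  reproduces the division pattern and all four error scenarios
  (merges, dropouts, border crossings, debris) for calibration and
  benchmarking.

## Worked example

```r
library(trackvalidatr)

# a small synthetic culture: 12 cells, 50 frames of 400 x 400 px,
# cell-cycle time 240 +/- 60 min at 15 min/frame
movie <- simulate_movie(simulation_config(
  width = 400, height = 400, n_frames = 50, n_initial = 12,
  life_mean = 240, life_sd = 60, seed = 9))

# calibrate the mitosis pattern model on an independent movie
cal <- simulate_movie(simulation_config(
  width = 400, height = 400, n_frames = 50, n_initial = 12,
  life_mean = 240, life_sd = 60, seed = 42))
model <- fit_mitosis_model(cal)

tracks <- track_movie(movie$frames, run_config())
result <- validate_tracks(tracks, model)
result
#> Validated tracking result
#>   fragments: 121  chains: 121
#>   detected mitoses: 41  merges: 4
#>   accepted complete paths: 28

classification_counts(result, movie$truth, tracks$masks)
#> # A tibble: 1 x 7
#>   paths detected_mitoses correct_mitoses mitosis_trustworthiness
#> 1   121               41              41                     100
#>   complete_paths correct_complete_paths tracking_trustworthiness
#>              28                     28                      100

classification_counts(naive_track(tracks$masks), movie$truth, tracks$masks)
#> # A tibble: 1 x 7
#>   paths detected_mitoses correct_mitoses mitosis_trustworthiness
#> 1   117               50              48                      96
#>   complete_paths correct_complete_paths tracking_trustworthiness
#>              38                     36                     94.7
```

Even on this small, clean movie the validated output is error-free
while the greedy baseline already returns wrong mitoses and wrong
complete paths; on an error-injected benchmark (50 starting cells,
150 frames, seeded optical merges, dropouts, border traffic and
debris — the configuration exercised in the test suite) the validated
tracker stays at 100% tracking trustworthiness (166/166 accepted
complete paths correct) while the naive baseline drops to 92.8%
(192/207) with 97.0% mitosis trustworthiness against the validated
100%. The ordering — fewer paths, far fewer errors — is the
package's central point. Downstream statistics come straight off the
accepted set:

```r
lifetime_distribution(result$complete, frame_interval = 15)
sibling_symmetry(result$forest, result$accepted)
confluency_and_mean_area(tracks$masks, pixel_size = 1.6)
```

`plot_*()` helpers and `autoplot()` render the standard figures
(proliferation curve, detection error rates, life-time histogram,
symmetry histogram). A thin command-line interface
(`inst/cli/trackvalidatr.R`, or `run_cli()`) chains the stages as
`simulate`, `detect`, `track`, `validate`, `evaluate`, `stats` and
`pipeline` subcommands.

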