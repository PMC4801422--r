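# nmjmorph

Quantitative morphometry of *Drosophila* larval neuromuscular junctions
(NMJs) from two-channel fluorescence z-stacks, as a scriptable R package.

Synapse-morphology screens score the larval NMJ — a branched chain of
synaptic boutons on the muscle surface — by hand, feature by feature.
`nmjmorph` re-implements that measurement as a headless batch pipeline:
from a terminal-marker channel (Dlg1, Hrp, Syt or Csp), an active-zone
channel (Brp) and one polygon region of interest per specimen, it derives
three intermediate structures and nine per-NMJ features:

| structure | features |
|---|---|
| NMJ outline (rolling-ball background subtraction, Renyi-entropy auto-threshold, within ROI) | area (µm²), perimeter (µm), bouton count (distance-transform watershed, 100-px floor) |
| NMJ skeleton (wider Li auto-threshold, Guo–Hall thinning, branch graph) | total length, longest branch length, islands, branches, branching points |
| 3D active zones (grey closing, 26-neighbour local maxima, prominence + intensity floor, inside the outline) | active-zone count |

A second variant (`run_bouton_variant()`) counts boutons on
synaptic-vesicle markers (Syt/Csp) with a moments threshold, a dilation
step before the watershed and 10-px floors — the configuration that makes
bouton counts reliable, because vesicle markers leave interbouton regions
dark. Method-agreement statistics (Lin's concordance correlation with
confidence interval, percent deviation, object-level
sensitivity/specificity) and a synthetic NMJ generator with complete
ground truth complete the toolkit, so the entire pipeline is testable
without any real data.

## Worked example

Generate three synthetic NMJs in the package's per-plane file dialect,
assemble them into hyperstacks, and run the nine-feature analysis:

```r
library(nmjmorph)

dir <- tempfile("nmj_demo_")
syn <- lapply(1:3, function(sd)
  generate_nmj(synth_spec(seed = sd, defocus = 0)))  # in-focus, noiseless
write_fixture_directory(syn, dir)

run_convert(dir, nmj_config())          # per-plane TIFFs -> stacks + flats
res <- run_analyze(dir, nmj_config())   # outline -> skeleton -> spots
res[, c("nmj_id", "area_um2", "perimeter_um", "n_boutons",
        "total_length_um", "n_islands", "n_branches",
        "n_branching_points", "n_active_zones")]
```

```
  nmj_id area_um2 perimeter_um n_boutons total_length_um n_islands n_branches n_branching_points n_active_zones
1 SYN001    74.44       115.83        15           43.06         2          6                  2             25
2 SYN002    60.79        97.29        11           36.44         2          6                  2             25
3 SYN003    67.93       104.26        14           38.22         2          6                  2             25
```

Each row is one NMJ. The counts — 2 islands, 6 branches, 2 branching
points, and per-specimen bouton (15/11/14) and active-zone (25) numbers —
equal the planted ground truth exactly on these in-focus noiseless
fixtures (compare `syn[[1]]$truth`); area, perimeter and lengths are
calibrated to µm via
the acquisition geometry (6.932 px/µm, 0.3 µm z-step, 42 planes). The
run also writes a tab-separated `nmj_results.txt` and one annotated
image per NMJ (outline in yellow, skeleton in blue, active zones as
white foci).

Agreement between two measurement series (e.g. pipeline vs manual) uses
the validation module:

```r
manual <- c(403, 286, 509, 352, 441, 310)   # e.g. NMJ areas, two raters
macro  <- c(392, 291, 498, 360, 452, 300)
concordance_correlation(manual, macro)       # ccc 0.992, 95% CI [0.945, 0.999]
percent_deviation(manual = 25, macro = 16)   # 36: manual-larger is positive
```

A thin command-line wrapper ships in `inst/cli/nmj-morph`
(`nmj-morph convert <dir>`, `nmj-morph analyze <dir> --marker dlg1
--preset widefield`, `nmj-morph boutons <dir>`, `nmj-morph synth <dir>
--seed 1`, `nmj-morph validate <paired.tsv>`).

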