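# nbaxis — division-axis quantification for neuroblast time-lapse microscopy

*Drosophila* larval brain neuroblasts (NBs) are stem cells that divide
asymmetrically over many cycles, budding a small ganglion mother cell
(GMC) from their basal pole each time, and they maintain the orientation
of that division axis from one cycle to the next. Quantifying this
maintenance means extracting 3D division axes from anisotropic confocal
time-lapse stacks (0.8 µm z-sections, ~0.26 µm xy pixels) and measuring,
in physical space, the angle between successive axes (**α**) and between
an axis and the direction of the last-born daughter (**β**):

&nbsp;&nbsp;&nbsp;&nbsp;α = arccos( v₁·v₂ / (|v₁||v₂|) ),&nbsp;&nbsp; v = B − A,

with A the apical and B the basal pole, reported in degrees on [0°, 180°].

`nbaxis` implements the full quantification as a tested R pipeline, for
people analysing such recordings or benchmarking methods against them:

* exact inter-axis geometry in physical coordinates (`axis_angle`,
  `voxel_to_physical`);
* division-axis extraction from the telophase dumbbell shape
  (three-step pole finding with neck-based apical/basal assignment;
  `find_poles_from_shape`, `segment_cell`) or from the two spindle-pole
  centrosomes (`centrosome_axis`);
* mitotic-rounding detection by 3D sphericity and the NB→daughter cue
  axis through the contact interface (`detect_rounding_onset`, `gmc_axis`);
* NB/cortex-glia surface-contact fraction by marching-tetrahedra
  isosurface triangulation (`isosurface_area`, `contact_fraction`) and
  EdU proliferation volumes from probability maps (`edu_volume`);
* condition comparisons with exact two-tailed Mann–Whitney U tests and
  boxplot-convention summaries (`mann_whitney_u`, `compare_conditions`);
* a synthetic 4D scene generator with exact ground truth
  (`sample_division_series`, `render_stack`), whose presets carry the
  published per-condition angle summaries (e.g. control α 24 ± 15°,
  β 14 ± 7°, GMC ablation 36 ± 20°, contact 79 ± 5% vs 71 ± 9%), so that
  every stage is verifiable by parameter recovery.

Stacks are read/written as TIFF (OME-TIFF spacing metadata is parsed on
read) with a JSON sidecar; all tabular outputs are CSV with `#` comment
headers declaring their conventions.

## Worked example

Simulate one control neuroblast over three cycles, measure every
division through the full render → segment → pole-extraction pipeline,
and compare conditions:

```r
library(nbaxis)

truth <- sample_division_series("control", n_cycles = 3, seed = 42)
truth
#> <scene_truth> preset 'control' (24 +/- 15 deg), 3 cycles, seed 42, fov 25.0 um

q <- quantify_scene(truth, noise = TRUE)
q$angles
#>   nb_id  kind cycle_ref angle_deg
#> 1   nb1 alpha         2  32.41026
#> 2   nb1 alpha         3  43.11005
round(q$axis_errors_deg, 2)
#> [1] 0.48 1.04 0.88
```

The two α values are this cell's measured cycle-to-cycle deviations (its
true deviations were 33.5° and 43.7°); `axis_errors_deg` shows each
measured axis lies within ~1° of the known truth despite shot noise and
the 3× anisotropic grid. Comparing 35 measured deviations per condition
reproduces the ablation effect:

```r
alphas <- data.frame(
  condition = rep(c("control", "gmc_ablation"), each = 35),
  value = c(vapply(1:35, function(i)
              truth_angles(sample_division_series("control", 2, seed = i))$alpha_deg, 1),
            vapply(1:35, function(i)
              truth_angles(sample_division_series("gmc_ablation", 2, seed = 100 + i))$alpha_deg, 1)))
compare_conditions(alphas, pairs = list(c("control", "gmc_ablation")))
#> <condition_summary> control: 23.5 +/- 14.7 (SD), n = 35; median 21.6 [13.4, 35.3], 0 outliers
#> <condition_summary> gmc_ablation: 42.7 +/- 20 (SD), n = 35; median 37.7 [32.6, 56.1], 0 outliers
#>
#> Pairwise two-tailed Mann-Whitney U tests (raw p, no multiplicity correction):
#>  condition1   condition2   U     p_value               method
#>     control gmc_ablation 285 0.000122548 normal-approximation
```

The methods vignette
(`vignettes/division-axis-quantification.Rmd`) documents the model, the
generator's assumptions, and every tunable parameter.

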