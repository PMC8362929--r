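# coolwedge

Quantitative tools for studying what *cooling* does to the myocardium of
dialysis patients, in two coupled halves:

1. **Perfusion heterogeneity.** 3D myocardial blood-flow maps
   (mL/min/100 g on a 0.5 × 0.5 × 5 mm grid with a left-ventricular
   mask) are summarized by the **relative-dispersion fractal
   dimension**: voxels are pooled into growing in-plane blocks of `m`
   voxels, the relative dispersion `RD(m) = SD/mean` of block means is
   computed per scale, and

   `FD = 1 − slope of log RD vs log m`,

   so FD = 1.0 is perfectly homogeneous perfusion and FD = 1.5 the
   spatially uncorrelated (completely heterogeneous) limit. Alongside:
   six-segment per-slice statistics, myocardial perfusion reserve
   (stress mean / rest mean), and exact Wilcoxon signed-rank
   comparisons of paired normothermic (NT, 37 °C) vs therapeutic
   hypothermia (TH, 32 °C) visits.

2. **Electrophysiology.** A human ventricular cardiomyocyte model
   (2006 ten Tusscher–Panfilov-type; epi/M/endo variants, compiled via
   Rcpp) with two configurable stressors — Q10 temperature scaling for
   hypothermia, and an acute-ischemia triad (hyperkalemia, ATP-sensitive
   K⁺ current, Na⁺/Ca²⁺ conductance block) for the dialysis "ischemic"
   state — embedded in a monodomain transmural wedge that produces a
   unipolar pseudo-ECG (dipole-source sum at an electrode 3 cm beyond
   the epicardium), plus QRS/ST/QT/T-wave feature extraction and an
   S1–S2 cross-field re-entry assay on heterogeneous sheets.

A synthetic-data module generates LV-shell-shaped flow volumes with a
*prescribed* mean flow and fractal dimension (spectral synthesis with an
estimator-calibrated exponent) and paired 7-subject NT/TH cohorts, so
the entire analysis is reproducible without patient data.

## Worked example

```r
library(coolwedge)

# a synthetic LV perfusion map with FD 1.30 and mean flow 133
map <- generate_perfusion_map(synth_map_spec(target_fd = 1.3,
                                             mean_bf = 133, seed = 7))
fd <- estimate_fd(map)
fd
#> <fractal dimension> FD = 1.2914 (7 scales, R^2 = 0.9999)
glance(fd)            # one-row tibble; tidy(fd) gives the RD curve
#> # A tibble: 1 x 4
#>      fd fit_r2 n_scales_used in_range
#>   <dbl>  <dbl>         <int> <lgl>
#> 1  1.29  1.000             7 TRUE

# a paired NT/TH cohort and the study's headline statistic
cohort <- generate_cohort(cohort_spec(seed = 1), keep_maps = FALSE)
summarize_paired(cohort, fd, state = "rest")[
  , c("median_nt", "median_th", "percent_change", "p_value")]
#> # A tibble: 1 x 4
#>   median_nt median_th percent_change p_value
#>       <dbl>     <dbl>          <dbl>   <dbl>
#> 1      1.30      1.10          -15.2  0.0156
```

The FD of 1.29 recovers the prescribed 1.30; the cohort realizes
the designed −14% drop (−15.2% in this seed) in heterogeneity under cooling, significant by
the exact signed-rank test at n = 7 (p = 2/2⁷ ≈ 0.016 when all seven
subjects move the same way).

Cell and tissue level:

```r
glance(run_paced(cell_params("epi")))$apd90                  # 306.6 ms
glance(run_paced(cell_params("epi", temperature_c = 32)))$apd90  # 471.5 ms
glance(run_paced(cell_params("epi", ischemia_severity = 1)))$apd90  # 181.0 ms

run_condition("control", wedge_config(dx_mm = 0.5, mode = "2d"))
#> <wedge control> QRS 26 ms, QT 352 ms, ST 270 ms, T positive (0.000444)
run_condition("NT_PD", wedge_config(dx_mm = 0.5, mode = "2d"))
#> <wedge NT_PD> QRS 80 ms, QT 251 ms, ST 78 ms, T negative (-0.000234)
run_condition("TH_PD", wedge_config(dx_mm = 0.5, mode = "2d"))
#> <wedge TH_PD> QRS 102 ms, QT 403 ms, ST 179 ms, T negative (-0.000228)
```

The ischemic wedge inverts the T wave and abbreviates ST/QT; cooling it
widens QRS, prolongs ST and QT and softens the inversion — the
simulated signature of hypothermic cardioprotection. `run_pipeline()`
chains all stages (cohort → FD/MPR → paired statistics → wedge
conditions → ECG features) into a JSON + markdown report under one
seed.

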