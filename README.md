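# neutrofun

Quantitative analysis of neutrophil function assays for two-group cohort
studies of community-acquired pneumonia (CAP). Neutrophils from patients
with CAP-associated sepsis show altered effector function — less accurate
chemotaxis toward CXCL8, slower oxidative-burst kinetics, an immature
surface phenotype — while glycolytic metabolism is largely preserved.
`neutrofun` implements the computational side of such a study as a tested,
reusable pipeline for anyone analysing migration time-lapses,
extracellular-flux plates or subject-level cytometry/clinical tables.

## What it computes

**Chemotaxis track metrics.** A track is a cell's positions
\((x_i, y_i)\) at times \(t_i\) (the assay images every 20 s for 12 min,
37 frames). With step vectors \(\mathbf{s}_i\) and a unit gradient
direction \(\mathbf{g}\) toward the chemoattractant:

- chemotactic index \(\mathrm{CI} = \frac{1}{n}\sum_i
  \cos\angle(\mathbf{s}_i, \mathbf{g})\) — per-frame accuracy, 1 directly
  toward the source, −1 directly away;
- directness \(= |\mathbf{x}_{end}-\mathbf{x}_{start}| / \sum_i
  |\mathbf{s}_i|\) — straightness of the whole path, 1 for a straight line;
- speed \(= \sum_i |\mathbf{s}_i| / \Delta t\) (µm/min, any direction) and
  velocity \(= (\mathbf{x}_{end}-\mathbf{x}_{start})\cdot\mathbf{g} /
  \Delta t\) (signed, toward the source), plus displacement and total
  distance.

Cells are summarised per subject (unweighted mean over cells with at least
`min_steps` steps), one dot per participant.

**Extracellular-flux kinetics.** ECAR (mpH/min) is converted to proton
efflux rate \( \mathrm{PER} = \mathrm{ECAR} \times BF \times V \times
K_{vol} \) (pmol H⁺/min) to account for medium buffering. Basal glycolysis
is the last measurement before the PMA injection; fold change is the
post-PMA peak PER (before oligomycin) over basal. Oligomycin and
2-deoxyglucose responses are checked as QC (mitochondrial contribution,
incomplete inhibition). The oxidative burst is summarised from the post-PMA
OCR curve: total O₂ (trapezoidal area under the curve), peak OCR, and time
to peak.

**Cytometry summaries.** Annexin V / propidium iodide quadrants (viable
AnV−/PI−, early apoptotic AnV+/PI−, late apoptotic AnV+/PI+, necrotic
AnV−/PI+), isotype-gated percent-positive and MFI per marker, and the
CD66b+/CD10+ mature-neutrophil fraction.

**Cohort statistics.** Shapiro–Wilk gates each continuous variable to
Student's t (mean (SD) summaries) or Mann–Whitney (median (IQR));
categorical variables get two-sided Fisher's exact tests; optional
Benjamini–Hochberg adjustment. A normal-approximation sample-size
calculator for a fractional reduction in a mean,
\(n = 2\sigma^2 (z_{1-\alpha/2}+z_{power})^2/\Delta^2\), is included.

**Synthetic data.** Seeded generators emulate every input: von Mises-biased
random-walk tracks (expected CI is the Bessel ratio
\(I_1(\kappa)/I_0(\kappa)\)), phased glycolysis curves, gamma-pulse burst
curves, and two-group cohorts at specified means/SDs or median/IQRs.

## Worked example

```r
library(neutrofun)

# 50 biased tracks at kappa = 2; expected CI = I1(2)/I0(2) = 0.698
tracks <- simulate_tracks(n_cells = 50, kappa = 2, seed = 7)
summarize_tracks(tracks, gradient_spec(0, 1), min_steps = 10)$subject
#>   speed velocity chemotactic_index directness displacement distance n_cells_used
#> 1 3.001    2.087             0.699       0.71       25.511   36.018           50

# glycolysis well at the control-group scale (basal 114 pmol/min, fold 3.4)
fs <- simulate_flux(basal_per = 114, fold = 3.4, noise_sd = 5, seed = 7)
basal_glycolysis(fs)        # 114.3 pmol/min
fold_change_glycolysis(fs)  # 3.45

# cohort at the observed chemotactic-index separation, then the test harness
cohort <- simulate_cohort(
  c(control = 23, CAP = 14),
  list(chemotactic_index = list(
    type = "normal",
    mean = c(control = 0.31, CAP = 0.14),
    sd   = c(control = 0.13, CAP = 0.03))),
  seed = 7)
run_comparison_table(cohort)$results
#>            variable test_used statistic p_value     summary_a     summary_b n_a n_b
#> 1 chemotactic_index student_t      6.08 6.1e-07 0.359 (0.139) 0.13 (0.0284)  23  14

fisher_exact_2x2(0, 32, 4, 21)           # 0.032 (0/32 vs 4/25 affected)
sample_size_two_means(0.30, 0.13, 0.62)  # 10 per arm (unrounded 10.27)
```

The subject CI of 0.699 matches the von Mises closed form; the simulated
cohort recovers a highly significant group difference, as expected at this
effect size (Cohen's d ≈ 1.8); the Fisher and sample-size values match the
published cohort's comparisons.

A command-line wrapper is installed with the package
(`system.file("scripts", "neutrofun", package = "neutrofun")`) with
subcommands `simulate-tracks`, `simulate-flux`, `simulate-cohort`,
`analyze-tracks`, `analyze-flux`, `compare-groups` and `report
--show-config`; every simulation writes a JSON provenance sidecar.

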