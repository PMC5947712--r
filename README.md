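# qitscreen

Kinetic analysis for **quantitative irreversible tethering (qIT)** —
high-throughput screening of covalent (electrophilic) fragments against
protein cysteines, ranked by *kinetic selectivity* instead of raw
reactivity.

## The problem and the model

In a qIT screen each fragment reacts with a target thiol under
pseudo-first-order conditions (fragment in large excess), so free thiol
decays as a single exponential. Residual thiol is read out over time with
a fluorogenic maleimide probe:

```
F(t) = B + S · exp(−(k_obs + k_ox)·t) · (1 + ε)
```

Sample fluorescence is normalized against matched DMSO-control wells
(which cancels the background drift and any shared aerobic-oxidation
channel `k_ox`), and `k_obs` is estimated per fragment × target by
exponential regression. Fits are graded by half-life: the assay resolves
kinetics reliably for `t½ = ln2/k` between 1 and 500 h (optimally
1–200 h).

The screening statistic is the **rate enhancement factor**

```
REF = k_protein / k_GSH
```

which cancels intrinsic warhead electrophilicity: REF ≈ 1 for
non-binders, REF > 3 calls a rate-*accelerated* fragment (protein-
templated, binding-driven reactivity) and REF < 0.3 a rate-*retarded*
one — strict fold-change cutoffs chosen to keep the screen's
false-discovery rate under 2.5%. Assay robustness is scored with
time-resolved Z′ factors over positive/negative control wells,
`Z′ = 1 − 3(σ₊+σ₋)/|μ₊−μ₋|`.

The package provides, as composable tibble-in/tibble-out functions:

| stage | functions |
|---|---|
| synthetic screens with planted ground truth | `qit_config()`, `simulate_truth()`, `simulate_timecourses()`, `simulate_qc_plate()`, `simulate_screen()` |
| normalization & kinetics | `normalize_screen()`, `normalize_to_control()`, `fit_first_order()`, `fit_kinetics()`, `half_life()`, `classify_fit_quality()` |
| screening statistics | `compute_ref()`, `call_hits()`, `derive_thresholds()`, `average_reactivity()`, `correlate_reactivity()` |
| assay QC | `zprime()`, `zprime_timecourse()` |
| IO & pipeline | `read_timecourses()`, `write_timecourses()`, `read_screen_config()`, `run_pipeline()` |

Fitted objects support `tidy()`, `glance()` and `autoplot()`. A thin
command-line wrapper (`inst/cli/qit.R`; subcommands `simulate`, `fit`,
`screen`, `qc`, `run`) drives the same functions from a shell.

## Worked example

A simulated screen of 138 fragments against seven protein thiol targets
plus the glutathione control (1104 fitted rate constants), duplicate
wells, 5% reader noise:

```r
library(qitscreen)

cfg  <- qit_config(seed = 7, n_fragments = 138, n_protein_targets = 7)
sim  <- simulate_screen(cfg)
fits <- sim$timecourses |>
  normalize_screen(cfg$background_au) |>
  fit_kinetics()
glance(fits)
#>   n_fits n_optimal n_acceptable n_out_of_range n_failed mean_r_squared_reliable
#> 1   1104       761          223            120        0                   0.894

calls <- call_hits(fits)          # fixed REF > 3 / < 0.3 policy
glance(calls)
#>   n_pairs n_accelerated n_retarded n_neutral upper lower mode
#> 1     888            49         45       794     3   0.3 fixed

correlate_reactivity(fits)        # k_GSH vs mean protein reactivity, log-log
#>   pearson_r spearman_rho slope intercept     n
#> 1     0.964        0.970 0.922    -0.153   138

zprime_timecourse(sim$qc_plate)   # time-resolved assay robustness
#> screen verdict: excellent (Z' range 0.78 to 0.87)
```

Reading: 984 of 1104 fits land inside the reliable 1–500 h half-life
window (mean R² 0.894 there); the 49 accelerated calls are exactly the
49 planted binders (7 per protein target) and the glutathione control
tracks mean protein reactivity tightly (r = 0.96) for this mostly-null
library, which is what licenses REF as a binding-specific ranking.
Single REF values reproduce, e.g. `format_ref(compute_ref(0.233, 0.089))`
→ `2.6`.

`run_pipeline(read_screen_config("config.yaml"))` runs all stages and
writes `fits.csv`, `ref_calls.csv`, `matrix_summary.csv`,
`correlation.csv`, `qc_report.csv` and a seeded `manifest.json`; an
example config ships in `inst/extdata/example_screen_config.yaml`.

## Documentation

The methods vignette (`vignettes/qit-methods.Rmd`) describes the
measurement model, the one-parameter linear-space fitter and its bounded
deterministic search, the half-life quality windows, the REF gating and
FDR-bounded threshold derivation, the Z′ conventions, and what the
synthetic-screen generator does and does not emulate.
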