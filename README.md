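# calyx

Desk-scale analysis machinery for ligand unbinding from lipocalin binding
pockets, modelled on the apolipoprotein M (apoM) / sphingosine-1-phosphate
(S1P) system: an HDL-associated beta-barrel carrier whose calyx anchors the
charged S1P headgroup at a hydrophilic opening and buries the hydrocarbon
tail in a hydrophobic lower cavity gated by two tyrosines.

The package is for computational structural biologists who need the
*analysis chain* of an enforced-unbinding / umbrella-sampling study as
tested, reusable code — together with a synthetic-data generator that
produces inputs with known ground truth, so every estimator can be
validated end to end without cluster-scale simulation.

## What it computes

* **Model landscapes and Langevin sampling** — analytic 1-D unbinding
  profiles U(&xi;) (bound shelf at 0, smooth rise, plateau at the barrier,
  optional metastable shoulder) sampled by overdamped Euler–Maruyama
  dynamics: unbiased, umbrella-biased (k = 1000 kJ/mol/nm&sup2;), or pulled
  by a constant-velocity spring (k = 100 kJ/mol/nm&sup2;, v = 0.01 nm/ns),
  with rupture forces read off force–extension traces.
* **WHAM** — the weighted histogram analysis method: self-consistent
  iteration of

  P(&xi;<sub>b</sub>) = &Sigma;<sub>i</sub> h<sub>i</sub>(b) /
  &Sigma;<sub>i</sub> N<sub>i</sub> exp((f<sub>i</sub> −
  w<sub>i</sub>(&xi;<sub>b</sub>))/k<sub>B</sub>T),&nbsp;&nbsp;
  f<sub>i</sub> = −k<sub>B</sub>T log &Sigma;<sub>b</sub>
  P(&xi;<sub>b</sub>) exp(−w<sub>i</sub>(&xi;<sub>b</sub>)/k<sub>B</sub>T),

  with W = −k<sub>B</sub>T log P, window-level bootstrap errors
  (200 replicates), and barrier / &Delta;G / plateau summaries.
* **Force distribution analysis** — aggregation of atom-pairwise
  ligand–protein force vectors into time-averaged residue profiles (pN),
  key-residue thresholds (>70 / >40 pN) and pulling-vs-equilibrium
  contrasts.
* **Protonation bookkeeping** — effective pKa from perturbation terms,
  Henderson–Hasselbalch fractions, net proton exchange between bound and
  free states, isoelectric points, and per-frame time series.
* **Pocket geometry** — PDB reading/writing, C&alpha; opening distances,
  Kabsch RMSD, block-averaged RMSF, tyrosine-gate metrics, hydrogen-bond
  occupancy, and grid/probe cavity volumes split at the gate plane into
  upper and lower sub-pockets.
* **Pipeline** — a validated, seeded, configuration-driven driver
  (`run_pipeline()`) plus a thin CLI wrapper in `inst/cli/calyx.R`.

## Worked example

```r
library(calyx)

## a 64 kJ/mol unbinding landscape, 47 umbrella windows, WHAM
ls64 <- make_unbinding_landscape(barrier = 64, bound_min = 1.0, plateau_start = 2.3)
ds <- generate_umbrella_dataset(ls64, centers = seq(1.0, 3.3, by = 0.05),
                                spring_k = 1000,
                                params = langevin_params(seed = 11),
                                n_samples = 1e4)
profile <- solve_wham(ds, wham_config())
profile
#> PMF profile: 266 bins (266 populated), xi 0.825..3.47 nm
#>   WHAM: converged after 2869 iterations
#>   max W: 67.17 kJ/mol
unlist(pmf_summary(profile))
#>  dG_unbind    barrier     xi_min xi_plateau no_plateau
#>   64.48891   64.75209    0.91500    2.14500    0.00000

## net proton exchange of S1P at pH 7 from the reported pKa values
bound <- s1p_titratable_set(c(4, 4), 14, "S1P bound")
free  <- s1p_titratable_set(c(6, 6), 11, "S1P free")
net_proton_exchange(bound, free, pH = 7)$magnitude
#> [1] 0.1797203

## grid cavity volume of a toy calyx with known analytic volume
st <- make_toy_calyx(cavity_radius = 4, cavity_depth = 10)  # pi r^2 d = 502.7 A^3
cavity_volumes(st, attr(st, "gate"),
               cavity_config(seed_point = attr(st, "upper_seed")))
#> Cavity volumes (grid 0.50 A, probe 1.40 A):
#>   total 505.9 A^3 = upper 252.9 + lower 253.0 A^3 (4047 points)
```

Reading the numbers: the WHAM reconstruction recovers the generator's
64 kJ/mol input barrier to within 0.8 kJ/mol at 10<sup>4</sup> samples per
window (the plateau mean `dG_unbind` is the robust estimate; `xi_plateau`
marks where the profile flattens).  The proton-exchange magnitude 0.18 is
what the printed pKa set (phosphate oxygens 4&rarr;6, amine 14&rarr;11)
implies at pH 7 — consistent with a reported ~0.16 given the rounded
inputs.  The grid volume lands within 1% of the analytic cylinder.

## Layout

* `R/` — landscapes and samplers, WHAM, FDA, protonation, structure and
  cavity analytics, pipeline.
* `src/` — Rcpp cores for the Langevin integrator and the WHAM fixed
  point.
* `vignettes/calyx-methods.Rmd` — the methods vignette: model
  assumptions, numerical choices, and what the synthetic data do and do
  not demonstrate.
* `inst/cli/calyx.R` — command-line wrapper (`simulate`, `wham`, `fda`,
  `protonation`, `pocket`, `run-all`, `validate`).
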