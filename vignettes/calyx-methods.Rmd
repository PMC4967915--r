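---
title: "Methods: unbinding energetics and pocket analytics in calyx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unbinding energetics and pocket analytics in calyx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`calyx` is a desk-scale analysis toolbox for the energetics and geometry of
ligand unbinding from a lipocalin binding pocket.  The motivating system is
sphingosine-1-phosphate (S1P) leaving the calyx of apolipoprotein M (apoM):
a zwitterionic lysolipid whose charged headgroup is anchored by arginines,
a tryptophan and a glutamate at the hydrophilic opening of an
eight-stranded beta-barrel, while its hydrocarbon tail occupies a
hydrophobic lower cavity gated by two tyrosines (positions 102 and 147).
The package does not run atomistic molecular dynamics.  Instead it
implements, with full tests, the *analysis machinery* such a study rests
on, together with a synthetic-data generator that produces inputs with
known ground truth so that every estimator can be validated end to end.

## The model landscape and its sampler

The reaction coordinate $\xi$ is the ligand-protein separation in nm
(bound state near 1 nm, free state at 3.3 nm).  `make_unbinding_landscape()`
builds an analytic free-energy profile $U(\xi)$: zero on a bound shelf up
to `bound_min`, a monotone cubic spline through quintic-smoothstep knots up
to `plateau_start`, and exactly the barrier height beyond it.  An optional
*shoulder* subtracts a compact-support bump
$d\,\exp(1 - 1/(1-u^2))$ from the flank, creating a metastable
intermediate of depth $d$ whose support is strictly inside the flank, so
the boundary invariants ($U(\text{bound}) = 0$, $U = $ barrier on the
plateau) hold exactly.

`simulate_overdamped()` integrates the overdamped Langevin equation with
the Euler--Maruyama scheme,

$$\xi_{t+\Delta t} = \xi_t - \frac{D}{k_BT}\,
  \partial_\xi\!\left(U + w_{\text{bias}}\right)\Delta t
  + \sqrt{2D\Delta t}\,\eta_t,$$

with reflecting boundaries at the domain edges.  Defaults: $T = 310$ K
(so $k_BT = 2.577$ kJ/mol with $k_B = 0.0083145$ kJ/mol/K), $D = 1$
nm$^2$/ns, $\Delta t = 10^{-5}$ ns.  Two guards run at startup: the
expected per-step displacement must stay below 0.1 nm (hard error), and
$\Delta t < 0.1\,k_BT/(D\,\max|U''|)$ (warning).  Setting $D = 0$ is
interpreted as the noiseless limit: thermal kicks are switched off while
the drift keeps unit mobility, giving a deterministic gradient descent.
All randomness flows through R's RNG, so a seed fixes the trajectory
bitwise.

Three bias modes mirror the simulation protocols being emulated: none,
a fixed umbrella restraint $w(\xi)=\tfrac{k}{2}(\xi-c)^2$ with
$k = 1000$ kJ/mol/nm$^2$, and a spring whose anchor moves at constant
velocity ($k = 100$ kJ/mol/nm$^2$, $v = 0.01$ nm/ns by default) for
enforced-unbinding pulls.

### Umbrella datasets

`generate_umbrella_dataset()` runs one biased simulation per window
centre.  Window spacing defaults to 0.05 nm, which over 1.0--3.3 nm gives
47 windows -- inside the 41--88 window range such studies report; the
spacing itself is a package decision, as is everything else in this
paragraph.  Each window starts at its centre, discards the first 10% of
recorded samples as burn-in (the fraction-based analogue of discarding an
equilibration prefix), and retains `n_samples` positions.  Retained
samples are spaced one harmonic relaxation time
$\tau = k_BT/(Dk)$ apart (in integrator steps), the conventional spacing
at which successive samples of an overdamped harmonic degree of freedom
are treated as statistically independent; the window-level bootstrap
below assumes exactly this.  Adjacent windows are checked for histogram
overlap and a warning names any gap.  Per-window seeds derive
deterministically from the dataset seed.

### Rupture forces

`run_constant_velocity_pull()` reports the rupture (unbinding) force as
the maximum of the spring-force trace *after* smoothing with a running
mean spanning 0.05 nm of anchor displacement.  The instantaneous spring
force fluctuates with amplitude $k_{\text{spring}}\sqrt{k_BT/k_{\text{eff}}}$
(tens of pN); the maximum of the raw trace therefore grows with trace
length (extreme-value statistics) rather than with the rupture event, and
slower pulls would paradoxically report larger forces.  Smoothing over a
fixed pulled distance makes traces at different velocities comparable;
the raw maximum is still reported as `f_max_raw_pN`.  With this
convention the median rupture force increases with pulling velocity
across 0.01--1 nm/ns, the expected loading-rate dependence.

## WHAM

`solve_wham()` iterates the standard self-consistency equations on
histogrammed window data,

$$P(\xi_b) = \frac{\sum_i h_i(b)}
 {\sum_i N_i\,e^{(f_i - w_i(\xi_b))/k_BT}},\qquad
 f_i = -k_BT\,\log \sum_b P(\xi_b)\,e^{-w_i(\xi_b)/k_BT},$$

until $\max_i|\Delta f_i|$ falls below the tolerance, then reports
$W = -k_BT\log P$ shifted to minimum zero.  Numerical choices (none of
which are dictated by the emulated protocol): bin width 0.01 nm,
tolerance $10^{-6}$ kJ/mol on the $f_i$, at most $10^5$ iterations,
$f_i$ initialised at 0 with a deterministic iteration order and the
gauge fixed by $f_1 = 0$ during iteration.  Bins inside the sampled range
that receive no counts keep $W = +\infty$ and are excluded from the
minimum shift; they are never interpolated.  A disconnected chain of
windows (adjacent windows sharing no populated bin) is an error naming
the break; the implementation is verified against an independent
brute-force fixed-point iteration on hand-countable toy problems.

Two estimator details matter for noisy profiles and are deliberate:

* **Summaries ignore sparse bins.**  `pmf_summary()` drops bins holding
  fewer than 50 counts.  A bin with $n$ counts carries free-energy noise
  of order $k_BT/\sqrt{n}$; the barely-visited bins at the edges of the
  sampled range would otherwise dominate both the barrier (a maximum
  statistic) and the plateau-slope detection.  The plateau is the longest
  terminal stretch whose local slope, measured over a 0.1 nm scale rather
  than bin-to-bin, stays below 10 kJ/mol/nm and extends at least 0.2 nm;
  $\Delta G_{\text{unbind}}$ is the plateau mean relative to the
  well-sampled minimum.  Without a plateau the maximum is reported with a
  flag.
* **Bootstrap replicates are aligned on well-sampled bins.**
  `bootstrap_pmf_error()` resamples complete windows with replacement
  (histograms as independent data points, 200 replicates by default),
  re-solves WHAM per replicate warm-started from the full solution, and
  reports the per-bin standard deviation.  Each replicate is shifted by
  its minimum over bins holding at least 50 counts; anchoring on the
  global minimum would add the order-$k_BT$ noise of one sparse bin to
  every bin of the replicate as a spurious global offset.  Replicates
  whose resampled chain is disconnected are discarded and counted, with a
  warning past 20%.

At the study conditions used in the tests (47 windows, $10^5$ retained
samples per window, fixed seed) the recovered barrier of a 64 kJ/mol
template is reproduced within 2 kJ/mol, as are 20, 40 and 75 kJ/mol
templates; there is a small positive bias (a few tenths of kJ/mol) from
the reflecting boundary below the bound shelf, well inside that band.

## Force distribution analysis

`aggregate_residue_profile()` turns per-frame atom-pairwise force vectors
between ligand and protein into a residue-wise profile: per frame, all
pair vectors into one residue are vector-summed; the profile value is the
time average of that sum's magnitude, in pN (1 kJ/mol/nm = 1.66054 pN).
The emulated analysis does not state whether "summing" is a vector or a
scalar operation; the vector-sum-magnitude convention was chosen because
it preserves the cancellation semantics of opposing atomic forces and is
what published force-distribution implementations aggregate.  Records may
arrive in either orientation ($F_{ij} = -F_{ji}$ exactly), frames with no
record for a residue contribute zero, and aggregation is linear and
permutation-invariant -- all property-tested.

Key binding residues are those with mean force strictly above a
threshold (70 pN for equilibrium anchors, 40 pN for pulling
contributors), sorted descending.  "Markedly increased during pulling"
has no quantitative definition in the emulated analysis; the package
flags residues whose pulling force exceeds 40 pN *and* whose
pulling/equilibrium ratio exceeds 2 (zero equilibrium force counts as an
infinite ratio).

## Protonation bookkeeping

Each titratable site carries its water pKa plus four environmental
perturbation terms (desolvation, hydrogen bonding, electrostatic
reorganization, Coulombic), consumed as numeric inputs -- the
structure-based estimation of those terms is explicitly out of scope.
The effective pKa is their sum; protonated fractions follow
Henderson--Hasselbalch, $\theta = 1/(1+10^{\,\text{pH}-\text{p}K_a})$.

The net proton exchange between the bound and free context is
$n = \sum_g \theta(\text{p}K_a^{\text{free}}) -
\theta(\text{p}K_a^{\text{bound}})$ over label-matched groups.  Sign
convention: positive $n$ means protons *gained* by the ligand upon
unbinding; the headline quantity is the magnitude with the direction in
metadata.  With the reported S1P values (two phosphate oxygens 4 bound /
6 free, amine 14 bound / 11 free, pH 7) the magnitude evaluates to
0.1797; the published 0.16 is recovered exactly only at an unrounded
free-phosphate pKa near 5.95, so agreement is expected at the $\pm 0.03$
level given the rounded inputs.  The two phosphate oxygens are treated as
independent one-proton sites, not as coupled macroscopic pKas, matching
how the sites are enumerated in the emulated analysis.

The isoelectric point solves $Q(\text{pH}) = 0$ with
$Q = \sum_{\text{bases}}\theta - \sum_{\text{acids}}(1-\theta)$ by
bisection on pH 0--14 to $|Q| < 10^{-6}$; a set without both an acid and
a base has no zero crossing and errors.  `protonation_timeseries()`
applies both per frame against the first frame's schema, skipping and
logging frames with missing groups.

## Structure analytics

Structures are atom tables plus an $n_{\text{models}}\times 3n$
coordinate matrix (multi-model PDB = trajectory).  PDB parsing is
delegated to bio3d with two package-side policies: coordinates are
pre-scanned so an unparseable field errors with its line number, and
alternate locations resolve to the highest-occupancy copy.  Van der
Waals radii come from a bundled table (C 1.70, N 1.55, O 1.52, S 1.80,
P 1.80, H 1.20 A; unknown elements 1.70 with a warning), overridable.

Superposition uses the Kabsch SVD solution with determinant correction,
so mirror images are never matched; collinear selections are flagged.
`windowed_rmsf()` implements block-averaged fluctuations: the trajectory
splits into equal windows (remainder frames dropped and logged), each
window's frames are superposed onto the window mean (two refinement
passes from a first-frame seed), and the across-window mean and standard
error are reported -- the scheme behind "averaged over $N$ windows,
error bars show the standard error" analyses.  A single window reports
SE 0 by convention.

Hydrogen bonds use donor--acceptor distance $\le 3.5$ A and
D--H$\cdots$A angle $\ge 150^\circ$ when hydrogens are available, with a
documented distance-only fallback for hydrogen-free crystal structures.

### Cavity volumes

`cavity_volumes()` counts grid points (0.5 A spacing, 1.4 A water probe
by default) that are simultaneously (i) outside every probe-inflated
atom sphere, (ii) *buried* -- at least 18 of the 26 cubic-lattice ray
directions hit protein within 12 A -- and (iii) 26-connected to a seed
point by flood fill.  The volume is the point count times the cell
volume.  A partition plane through the midpoint of the two gate
side-chain oxygens, normal to the barrel axis (first principal axis of
the C$\alpha$ atoms), splits the cavity into upper and lower sub-pockets
with `total = upper + lower` exact in point counts; points on the plane
count as upper.  The upper side is oriented by an explicit `up_point`
when given, else by the seed's side of the plane, else by the side
holding more points.  A flood fill that exceeds the hard point cap means
the pocket leaks to solvent and errors ("pocket not enclosed"); a seed
inside an atom errors immediately.  These parameters are package
decisions -- the emulated study names neither tool nor settings -- chosen
as the field's standard probe/grid conventions plus an enclosedness
criterion strict enough to report a closed lower pocket as exactly zero.

Grid-based volumes are rotation-invariant only up to discretisation
(about 1--3% at 0.5 A), unlike the distance and RMSD outputs which are
invariant to numerical precision; the tests assert exactly that.

### The toy calyx

`make_toy_calyx()` builds the ground-truth fixture: a cylindrical cavity
(radius $r$, depth $d$, analytic volume $\pi r^2 d$) enclosed by carbon
pseudo-atom walls whose centres sit at $r + r_C + \text{probe}$ from the
axis, so the probe-inflated wall surface coincides with the analytic
cylinder.  Two "tyrosine" gate residues (numbered 102 and 147) face each
other across the mid-plane at a controllable gap; `gate_gap = 0` seals
the lower chamber completely (a constriction ring plus touching tips),
and the default fully retracts the tips into the wall so the analytic
volume is exact.  At intermediate gaps the protruding tips occlude part
of the cylinder, so the analytic value is exact only at the extremes --
the fixture is a volume oracle, not a morphing model.  At 0.5 A grid the
measured volume lands within 1% of $\pi r^2 d$ for the default fixture,
against the 5% band the tests assert.

## What the synthetic data do and do not show

The generator reproduces the *statistical structure* the estimators rely
on: Boltzmann-distributed biased samples with known ground truth
(verified by chi-squared screens and a double-well occupancy check),
velocity-dependent rupture events, pairwise force records with designed
residue means and exact antisymmetry, and cavities with closed-form
volumes.  It deliberately omits everything atomistic: there is no
orthogonal degree of freedom (real umbrella windows sample orthogonally
to the pull axis), no force field, no solvent, no protein flexibility
coupling to the reaction coordinate, and the 1-D landscape is smooth
where a real unbinding free-energy surface is rugged.  Passing tests
therefore certify the analysis chain -- sampling in, numbers out -- not
the biology; the atomistic barrier heights (tens of kJ/mol with
mutant shifts of 4--20 kJ/mol) and hydrogen-bond occupancies of the real
system require cluster-scale simulation and are used here only as shape
templates and thresholds.

## Problem sizes

The shipped tests run the full synthetic study at 47 windows with $10^5$
retained samples per window (and $2\times 10^5$ for the
error-convergence check), 200 bootstrap replicates, 15 pulling runs
across three velocities, and cavity grids of roughly $10^5$--$10^6$
points -- sizes chosen so the complete suite exercises the stated study
conditions on a single CPU in minutes.

## Known limitations

* 1-D WHAM only; no multidimensional reaction coordinates, no MBAR, and
  no autocorrelation-based inefficiency weighting (samples are instead
  decorrelated at the source by the relaxation-time stride).
* The bootstrap treats windows as the unit of resampling; resampling
  histogram contents within windows is a different (smaller) error
  estimate and is not implemented.
* Cavity buriedness uses the 26 lattice rays only; very wide pocket
  mouths can count as buried if the mouth subtends few ray directions.
* The barrel axis is a principal axis of C$\alpha$ positions (or of all
  atoms for pseudo-structures); strongly bent barrels would need an
  explicit axis selection.
* No secondary-structure assignment, no interaction-energy computation,
  and no structure repair.
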