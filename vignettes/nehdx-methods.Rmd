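---
title: "Analyzing nonequilibrium HDX-MS: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing nonequilibrium HDX-MS: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nehdx)
```

## The measurement and the question

Hydrogen/deuterium-exchange mass spectrometry (HDX-MS) reads out the
hydrogen-bonding and solvent exposure of backbone amides as a mass increase of
peptic peptides incubated in D2O. In the *nonequilibrium* variant, labeling
starts milliseconds after a ligand is rapidly mixed with the protein, while
the population is still relaxing from its starting conformation (apo) toward
the ligand-bound end state. Repeating the labeling time course in three
conditions — apo, fully equilibrated end state, and the nonequilibrium
transient — asks, for every resolvable position in the protein: *does the
path between the two end points pass through structures that neither end
point contains?*

A region that simply interpolates between the end states stays inside the
envelope of the apo and end-state uptake curves. A region that transiently
unfolds (or transiently rigidifies) leaves that envelope: the hallmark
observable of the experiment, seen for example in the tower helix of glycogen
phosphorylase during both allosteric activation and inhibition.

## From peptides to residues

Input tables carry one row per peptide x state x replicate x exposure, with
centroided uptake in Daltons. The pipeline:

1. **Normalizes** uptake to the maximum exchangeable amide count: peptide
   length minus `n_term_exclusions` N-terminal residues minus prolines, times
   the buffer deuterium fraction and an optional back-exchange recovery
   factor. We default to one excluded N-terminal residue (the first backbone
   amide of a peptic fragment is not observable after digestion); two is a
   config option since conventions differ. The back-exchange factor defaults
   to 1 (no correction) — applying one requires a deuterium-recovery
   calibration that the input tables may not carry. Values above 1.05 after
   normalization are flagged suspect but never clipped, so downstream sums
   stay unbiased.
2. **Averages replicates** (arithmetic mean, sample SD; a single replicate
   reports SD as missing, never 0).
3. **Averages peptides to residues**: each non-proline residue receives the
   unweighted mean of all covering peptides, excluding peptides in which the
   residue falls on an excluded N-terminal position. Unweighted, because the
   simplest reading of residue-level averaging treats each peptide as one
   observation of the residue; a length-weighted variant is available as an
   ablation (`norm_config(length_weighted = TRUE)`). The propagated SD is the
   root-mean-square of the contributing peptide SDs over the square root of
   the peptide count.

Exposure grids are matched across states with a relative tolerance of 1e-6;
times present in only some states are dropped from difference computations.

## Exchange kinetics

Each time course is fit with the stretched exponential

$$D(t) = A\,\bigl(1 - e^{-(k_{\mathrm{obs}} t)^{\beta}}\bigr),$$

where $A$ is the plateau, $k_{\mathrm{obs}}$ the observed rate and
$\beta \in (0, 1]$ absorbs rate heterogeneity among the amides contributing
to one envelope ($\beta = 1$ is a single exponential). The fit is
Levenberg-Marquardt least squares with multi-start over
$k \in \{10^{-6}, 10^{-4}, 10^{-2}, 1, 10^{2}\}$ s$^{-1}$ and
$\beta \in \{0.5, 1\}$ — a four-decade time window demands log-scale starts —
optimizing $\log_{10} k$ for conditioning, with bounds $A \le 1.2$,
$k \in [10^{-8}, 10^{3}]$ s$^{-1}$. Ties in RSS break toward the lower rate.
Weighted fitting ($1/\mathrm{SD}^2$) is off by default because replicate SDs
near zero would otherwise dominate the objective.

A series is classified *slow* when $k_{\mathrm{obs}} < 10^{-5}$ s$^{-1}$,
when the fit fails on a flat series, or when the fitted plateau is below
0.05 relative-uptake units. The amplitude floor exists because least squares
on a noisy flat series happily explains the noise with a tiny, fast
exponential; a rate is meaningless when essentially no exchange occurred
within the window.

## Sum-difference coordinates, archetypes, clusters

For every residue present in all three states the pipeline computes

$$x = \sum_t \bigl(D_{\mathrm{ne}}(t) - D_{\mathrm{apo}}(t)\bigr), \qquad
  y = \sum_t \bigl(D_{\mathrm{ne}}(t) - D_{\mathrm{end}}(t)\bigr)$$

over the shared time grid (a per-time mean is a config option for comparing
experiments with unequal grids), with uncertainties summed in quadrature.
Each axis is then three-valued — negative, zero, positive — where "zero"
means $|v| \le z\sigma$ with $z = 2$ by default; the 3 x 3 grid gives nine
archetypes. $(0,0)$ is unchanged; $x>0, y>0$ is exchange beyond both states
(transient deprotection); $x \ne 0, y = 0$ are on-pathway completions sitting
on the $y = 0$ axis; the mixed-sign cells are interpolating behavior and the
$x = 0, y \ne 0$ cells lagging behavior. The archetype names are descriptive
choices of this package.

Residues are grouped by k-means on the raw $(x, y)$ — both axes share units,
so standardization would distort the geometry — with 25 restarts under a
recorded seed, $k = 7$ by default and `k = "auto"` selecting
$k \in [2, 12]$ by maximum mean silhouette width. Average-linkage
hierarchical clustering of the k centroids (Euclidean distance) gives the
cluster dendrogram, exported as Newick.

The dead-time saturation check compares normalized uptake of reporter
peptides at the earliest exposure between the nonequilibrium and end states
(Welch test) and additionally requires the absolute mean difference to stay
below 0.05 relative-uptake units: with two or three replicates a p-value
alone is meaningless, so an effect-size gate is mandatory.

## The forward simulator

`simulate_experiment()` is a mechanistic stand-in for instrument data, with
complete ground truth. Its physics:

- The population relaxes apo → transient → end with first-order rates
  $k_1 = 0.5$, $k_2 = 0.2$ s$^{-1}$ (closed form, equal-rate limit handled
  analytically), chosen so the transient is appreciably populated inside the
  0.05–300 s window. Ligand mixing happens one dead time (50 ms) before the
  first exposure.
- Exchange follows the EX2 limit: a residue's instantaneous rate is the
  population-weighted sum of $k_{\mathrm{int}}/P_s$ over states $s$, where
  $P_s \ge 1$ are protection factors. Centroided (single-envelope) uptake is
  therefore the correct measurement model; EX1 bimodality is out of scope by
  construction. Uptake is the exact closed-form integral of this hazard —
  the occupancies are sums of exponentials, so no numerical quadrature is
  needed (adaptive quadrature serves as the independent oracle in the tests).
- Seven contiguous regions carry seven behavior classes. Each class is a
  signature of *observed* rates (apo, transient, end); per-residue protection
  factors are derived as $P_s = k_{\mathrm{int}}/k_s$, with
  $k_{\mathrm{int}}$ log-uniform up to 10 s$^{-1}$ and bounded below so that
  every $P_s \ge 1$. This construction is deliberate: residues within one
  structural element share *correlated observed kinetics* — which is exactly
  what the clustering is designed to find — while intrinsic rates still vary
  over decades between residues. A shared lognormal jitter (SD 0.15) scales
  all three rates of a residue together, with a small state-specific jitter
  (SD 0.05) on top.
- Classes: `unchanged`; `interpolating` (transient rate between the end
  points); `transient_deprotection` and `transient_protection` (transient
  rate outside the end-point range — these escape the envelope);
  `on_pathway_deprotected`, `on_pathway_protected` and `binding_site`
  complete their local change within the dead time, so they sit exactly on
  $y = 0$ (the binding site on the protected side, with moderate contrast).
- Peptide maps (length 6–18, overlap ≥ 3) are tiled *within* regions. Real
  peptic maps cross structural boundaries, which genuinely blends classes in
  residue-averaged data and makes residue-level ground truth ill-defined near
  edges; the fixture trades that realism away so that every residue's
  generating class is identifiable. Passing tests therefore demonstrate
  correctness of the pipeline's arithmetic and clustering, not robustness to
  boundary-spanning peptides in real data.
- Replicate noise is i.i.d. Gaussian on the Dalton scale with SD
  `noise_sd * n_exchangeable` (default 0.01 relative-uptake units), truncated
  at zero because a centroided mass increase cannot be negative; truncation
  slightly shrinks the apparent SD of unexchanged peptides.
- Presets: activation = 31 log-spaced exposures from 0.05 to 300 s;
  inhibition = 20 points over the same span. Protein length defaults to 120
  residues — large enough for seven regions of ~17 residues, small enough
  that the full pipeline runs in seconds.

With these defaults the full pipeline recovers the generating regions
essentially perfectly (adjusted Rand index 1.0 in our tests), and
silhouette-based `k = "auto"` selects 7 in most seeds; occasional seeds
split one elongated cluster into subclusters (8–9) — a known behavior of
silhouette selection on anisotropic clusters, not an arithmetic error.

## Structural trajectory analysis

Multi-model PDB series (e.g. morphing/interpolation output) are analyzed
with:

- **Backbone H-bonds** by the DSSP electrostatic criterion
  ($E = 0.084 \cdot 332 \,(1/d_{ON} + 1/d_{CH} - 1/d_{OH} - 1/d_{CN})$
  kcal/mol, bond if $E < -0.5$), chosen over purely geometric cutoffs
  because interpolated structures have strained geometries; a geometric
  criterion (H···O < 2.5 Å, N–H···O angle > 120°) is available. Amide
  hydrogens are always re-placed geometrically (1.02 Å from N, in-plane,
  opposite the C(i−1)/CA bisector), even when present in the file, so the
  criterion is applied consistently. Prolines are never donors.
- **Event matrices**: presence of each donor→acceptor pair per trajectory
  step; breaking events are present→absent transitions between adjacent
  steps.
- **Pairwise RMSD** over a residue window, after least-squares (Kabsch)
  superposition on that same window — the simplest reading of a
  region-restricted RMSD; superposing on a different selection is a config
  option. Optionally normalized to the matrix maximum.
- **Label painting** writes small integer labels (cluster assignments,
  archetype codes) into the B-factor column, sentinel −1 for unlabeled
  residues, for rendering in any structure viewer.

A dihedral-built ideal helix (φ = −57°, ψ = −47°) and a
helix→unwound→helix trajectory generator serve as geometry fixtures; the
morphing algorithm itself is out of scope — the module consumes any ordered
model series.

## Numerical and design notes

- Degenerate inputs: all-zero uptake series return a flagged non-converged
  fit, not an error; peptides with zero exchangeable amides are excluded with
  a warning; all-identical coordinates return a single cluster with a
  warning; missing sigmas classify by sign alone and are flagged.
- Determinism: simulation and clustering seeds are independent, always
  recorded in outputs, and fixed seeds give byte-identical result bundles
  (verified by MD5 in the run manifest).
- Problem sizes in the test suite (70–120 residues, 8–31 time points, 2–3
  replicates, 100 Monte Carlo fit draws) were chosen so the whole suite runs
  in about two minutes while every statistical check retains adequate power.
- Known limitations: no EX1/bimodal simulation; no vendor-specific export
  dialects (a column-rename map adapts other exports); no correction for
  sequence-specific intrinsic rates (the pipeline consumes relative uptake
  only); region-aligned synthetic peptide maps as discussed above; the
  saturation check requires ≥ 2 replicates at the earliest exposure.
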