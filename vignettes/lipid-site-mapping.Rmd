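---
title: "Mapping lipid binding sites from MD trajectories: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping lipid binding sites from MD trajectories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LipidSites)
```

# The problem

Amphiphilic ligands such as free fatty acids partition into the membrane and
meet their protein target by lateral diffusion. In a simulation of a channel
in a mixed bilayer, every lipid produces thousands of transient protein
contacts; a binding *site* is distinguished not by the existence of contacts
but by their statistics — how much total time a residue spends in contact and
how long the longest uninterrupted episode lasts. `LipidSites` turns those
two statistics, plus spatial-density and pose-clustering views of the same
trajectory, into site calls, and adds the electrophysiology fits used to test
candidate sites experimentally.

# Contact statistics and site calling

A contact is any lipid atom (or any head-group atom, in `headgroup_only`
mode) within the contact cutoff of any residue atom under the orthorhombic
minimum-image convention. The 6 Å default is the customary coarse-grained
contact distance (it brackets the first Lennard-Jones minimum of standard CG
force fields); 4.0 Å is used for all-atom heavy-atom (hydrophobic) contact,
3.5 Å for hydrogen-to-acceptor hydrogen bonds, and 4.0 Å for N–O salt
bridges. All cutoffs live in one `analysisConfig()` object and are echoed in
every output.

Two per-residue statistics are computed from the boolean presence tensor
(frame × lipid × residue):

* **Total interaction time** — `dt ×` the number of frames in which at least
  one lipid is in contact. This is a *union* over lipids: a residue touched
  by two lipids simultaneously accrues one frame, not two, so a residue's
  total can never exceed the trajectory duration. A sum-over-lipids variant
  (`sumOverLipids = TRUE`) is provided for users who want multiplicity.
* **Longest lifetime** — `dt ×` the longest run of consecutive contact frames
  against any single lipid. A single absent frame breaks the run
  (`gapTolerance = 0`); a gap-tolerance parameter exists for sensitivity
  analysis. An episode of k frames contributes `k·dt` with no half-frame end
  corrections — the simplest convention consistent with frame-sampled data.

Both statistics are averaged positionally across the channel's symmetric
subunits (`symmetryAverage()`), which requires equal residue counts per
subunit and reports against the first subunit's numbering. Residues strictly
above the Tukey fence `Q3 + 1.5·IQR` — computed over all residues with the
linear-interpolation quantile convention (R type 7; the convention is
recorded in the output because different tools disagree here) — are called
*high-contact* (from total time) and *stable-contact* (from longest
lifetime). Strict inequality means ties at the fence are excluded; in the
degenerate all-equal case nothing is called.

At the lipid level the same run-length machinery yields *UQ binders* (total
interaction time ≥ Q3 across lipids — inclusive, since "upper quartile"
includes its boundary) and *constant binders* (longest lifetime equal to the
full duration, i.e. contact in literally every frame; a maximum-missing-frames
tolerance is exposed but defaults to 0). A full-duration binder necessarily
has maximal total time, so constant binders are always a subset of UQ
binders.

For a chosen bound lipid, residues are discriminated into *binder* residues
(direct contact — any heavy-atom pair within 4.0 Å, or a hydrogen-bond or
salt-bridge event — in at least a fraction θ of frames) and *proximal*
residues (within the 6 Å contact shell for ≥ θ of frames without direct
contact). θ = 0.5 is a declared package default, always reported: the
literature distinguishes the two classes qualitatively but states no numeric
persistence rule, so the threshold is a design decision here, not an
inference of anyone's intent.

# Spatial enrichment

Voxel occupancy is *binary per frame per voxel*: the fraction of frames in
which at least one selected atom lies in the voxel, so 0.03 reads as
"present in 3% of frames". This matches how volumetric occupancy maps are
conventionally thresholded (10/15/20/30% contours, monotonically nested); an
atom-count-weighted mode exists for densities. Grids are axis-aligned,
origin at the box corner, half-open voxels.

Slab profiles count (frame, head-group atom) events within a 3 Å shell of a
reference residue set, binned into 0.5 Å z-slabs, per consecutive time
interval; the per-interval totals equal the unbinned event counts by
construction. Fold enrichment between two species is the per-bin count
ratio, with explicit `numerator_only` and `empty` flags instead of silent
division by zero.

The radial distribution function is *lateral* by default: distance in the
membrane plane from the protein's centre-of-geometry axis, normalised by the
uniform-density expectation over annular areas, so g(r) → 1 for an ideal
gas. This choice reflects that the reference object is a membrane-spanning
channel, where density varies laterally; a 3-D minimum-distance-to-surface
variant is available (`mode = "surface"`) and labelled in the output, since
either convention appears in practice. Radial bins beyond half the smaller
lateral box length are truncated with a warning.

# Pose clustering

Two clustering algorithms operate on a pose RMSD matrix:

* **Jarvis–Patrick**: neighbour lists from a distance cutoff; two poses link
  when each is in the other's list and they share at least `commonNeighbors`
  neighbours (default 3); clusters are connected components; singletons are
  reported in an explicit "unclustered" bin so populations still sum to 1.
  The "number of neighbours" parameter is read as the required
  common-neighbour count, with the fixed-size-M nearest-neighbour list
  variant available as an option.
* **GROMOS**: iteratively take the pose with the most within-cutoff
  neighbours as a centroid and remove it with all its neighbours —
  permanently, so the output is a partition. Ties break toward the lowest
  pose index everywhere, making both algorithms deterministic.

The representative pose of a cluster is the member with the smallest mean
RMSD to the other members. By default poses are compared without
superposition — appropriate when the protein is positionally restrained, as
in typical coarse-grained production runs — and a Kabsch least-squares
superposition is applied per pair when requested.

# Electrophysiology fits

Tail-current amplitudes against the preceding activation voltage give the
G(V) curve; when raw traces are supplied the amplitude is the mean over a
configurable window (default 5–20 ms) after the capacitive blank, and the
window is always reported since "shortly after the step" is not a number.
The Boltzmann model is implemented exactly as
`G(V) = Gmin + (Gmax − Gmin)/(1 + exp[(V50 − V)·s])` with the slope factor
`s` in 1/mV multiplying the voltage difference (not dividing it): in this
form a positive `s` yields an activating curve and `G(V50)` is exactly the
half-range. Per-cell effects are `ΔV50 = V50(treated) − V50(control)` and
`ΔGmax = Gmax(treated)/Gmax(control) − 1` in percent.

The concentration–response model is the standard Hill form
`ΔEffect = ΔEffect_max / (1 + (L50/[L])^|H|)`. The printed source form of
this equation is typographically ambiguous, but both reported effect types
grow in magnitude and saturate with concentration, which forces the standard
reading; the Hill coefficient's sign is treated as a recorded direction
convention (|H| is constrained to 1 for robustness over sparse dose ranges,
optionally with ΔEffect_max fixed too, leaving L50 as the single free
parameter). Relaxation kinetics are fitted as `I(t) = A·exp(−t/τ) + C` over
a window after the capacitive blank.

All fits are unweighted Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) with analytic initial guesses (half-range crossing for
V50, the 25–75% rise span for s, the concentration nearest half-max for
L50), so convergence needs no user tuning; noiseless data are recovered to
10⁻⁶ from initial guesses perturbed by factors 0.5–2, and the Boltzmann fit
is exactly equivariant under voltage translation.

# The synthetic generator: what it emulates and what it does not

`simulateLipidTrajectory()` builds a four-fold symmetric ring of one-bead
pseudo-residues ("the channel") at the membrane midplane of a periodic box,
with three-bead lipids (charged head + two tails) of two species. Free
lipids random-walk laterally at leaflet height (|z| = 17 Å from the
midplane); an outer-leaflet lipid within 5 Å (lateral) of a planted anchor
binds with probability `pOn` per frame and is held with its head pinned
2.5 Å lateral / 1.5 Å above its anchor; a bound lipid releases with
probability `kOff` per frame and is emitted just outside the capture zone.
Dwell times are therefore geometric with mean exactly `1/kOff` frames — an
exact oracle for the run-length statistics — and emitting released lipids
outside the zone keeps long-run occupancy tied to the planted on/off rates
(releasing in place would let the high-affinity species instantly re-bind in
bursts and decouple occupancy from `pOn`). The stationary balance
`P(bound)·kOff = P(free-in-zone)·pOn/(1−pOn)` holds exactly and is verified
in the tests, as is the 3-fold planted affinity ratio between the default
species (pOn 0.15 vs 0.05 at equal kOff 0.05, the mean dwell of 20 frames =
10 ns at the 0.5 ns frame spacing).

The geometry is deliberately arranged so that ground truth is unambiguous:
free lipids ride 17 Å above/below the midplane ring and so never enter the
6 Å contact shell, the 7 Å residue spacing keeps a pinned head (2.9 Å from
its own anchor) more than 6 Å from the anchor's neighbours, and the pinned
head sits inside the 3 Å slab-profile shell and the 4 Å direct-contact
cutoff. Consequently every protein contact arises from a planted binding
event and the anchor sets are recovered exactly by the Tukey-fence
classifier. One lipid can be planted as a permanent binder (`kOff = 0`) to
give the constant-binder logic a unique known answer. Setting `pOn = 0`
yields a pure-diffusion bilayer, used to verify leaflet assignment against
planted leaflets.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: there are no forces or excluded volume (lipids can
overlap the protein laterally at leaflet height), no membrane elasticity or
curvature, no tail conformational dynamics (tails hang rigidly below the
head), no inner-leaflet binding, no specific lipid chemistry, and binding is
a teleporting two-state process rather than a diffusive approach with an
energy landscape. The generator validates the *analysis* — contact
bookkeeping, run-length statistics, outlier calling, density normalisation,
clustering, fitting — under known kinetics; it says nothing about whether a
particular force field or sampling time suffices for a real channel. In
real trajectories, non-site residues accrue background contact time and the
Tukey fence is then a genuine statistical call rather than an exact one; the
quantile-oracle tests cover that regime on random data.

The validation problem sizes (chosen to keep the full suite around three
minutes): 20,000-frame runs (10 µs at 0.5 ns spacing) for site recovery and
kinetics, with 24 lipids in a 200 × 200 × 60 Å box; 2,000-frame runs for
pipeline-level checks; 10⁶ samples for the uniform-g(r) check; 100 seeds per
curve-fit noise study.

# Numerical choices, degenerate inputs, limitations

* Coordinates are Å internally, time ns; GRO files (nm) are converted on
  read. Only orthorhombic boxes are supported; triclinic input is rejected
  with a clear error, since every operation here needs only minimum-image
  distances and bilayer systems are conventionally built orthorhombic.
* Trajectories are assumed molecule-wrapped; when a bond list is available,
  a make-whole pass shifts atoms by box lengths to restore molecular
  integrity before centroid or grid analyses.
* Residue indices are reported exactly as in the topology. A constant-offset
  map (`mapResidueNumbering()`, default +10) converts between a structure's
  numbering and the homologous human-construct numbering.
* Quantiles: R type 7 everywhere, recorded in outputs.
* Leaflet assignment uses the head-group-z midplane; with unequal leaflet
  populations the estimate is biased toward the more populated leaflet, and
  all-equal z triggers a warning with a one-leaflet assignment.
* The hydrogen-bond criterion is distance-only by default (hydrogen to
  acceptor ≤ 3.5 Å, donors identified from the bond list or a ≤ 1.2 Å
  covalent heuristic, electronegative = N/O/S); an angle term can be added
  but is off by default. Coarse-grained systems without hydrogens get a
  clear error pointing to bead-level contact analysis.
* Running averages are centred; edges where the window is incomplete are NA
  rather than silently shortened.
* XTC input is not supported (no reader available to R); use DCD or
  multi-model PDB. DCD files carry no box, which is taken from the topology
  file or supplied explicitly.
* The interval windowing for slab profiles defaults to a single
  whole-trajectory interval; consecutive fixed-length windows (e.g. 1 µs)
  are a parameter, since published analyses vary in how they stride
  trajectories between analysis windows.

# The pipeline

`runSiteMapping()` composes the stages — load/generate, contact tensor,
residue statistics with symmetry averaging and classification, lipid
statistics with binder classes, binder-residue roles, occupancy grid,
slab/fold-enrichment profiles, lateral RDF, pose clustering — from a single
`runConfig()` (optionally read from YAML), writes CSV/OpenDX/PDB outputs and
a JSON report, and is byte-identical across reruns at a fixed seed
(timestamps are written to a separate file). `validateConfig()` returns an
aggregated error list (paths, species names, parameter ranges) before any
computation starts. Every stage is an exported function, and the pipeline is
pure composition, so pipeline results always equal standalone invocations.
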