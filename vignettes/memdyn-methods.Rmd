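---
title: "Methods: bilayer maps, ensemble motions and smFRET recurrence in memdyn"
author: "memdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bilayer maps, ensemble motions and smFRET recurrence in memdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memdyn)
```

memdyn collects the quantitative analyses used to characterise a
membrane-protein complex reconstituted in lipid nanodiscs, across three
kinds of evidence: molecular-dynamics coordinate frames (bilayer thickness
and scaffold planarity), ensembles of fitted atomic models (domain
centre-of-mass motions), and single-molecule FRET photon streams
(recurrence analysis of bursts), together with a forward model that
predicts FRET efficiencies from structures and a contact classifier for
crystal-packing analysis. This vignette records the models, the tunable
parameters and the numerical decisions, so that results can be interpreted
and reproduced without reading the source.

## Coordinate model

All structure-facing functions consume a `StructureModel`: an ordered atom
table with author residue numbering preserved verbatim. This matters
because domain definitions (e.g. POTRA1 = BamA residues 24–92) are given in
author numbering; any renumbering would silently shift them. On reading PDB
files, alternate locations other than blank or "A" are dropped so centroid
and RMSD computations never double-count an atom; hydrogens are kept at
this level and excluded where the analysis requires it (contacts,
accessible volumes). The writer always emits `MODEL`/`ENDMDL` pairs, also
for single models, so the multi-model dialect is uniform and round trips
preserve atom identity exactly and coordinates to the PDB's three decimals.

## Bilayer thickness maps

Each lipid is represented by its phosphate: the analysis operates on one
phosphorus position per lipid and deliberately ignores acyl chains. Per
frame:

1. A total-least-squares plane is fitted to all phosphates (SVD of the
   centred coordinates; the normal is oriented into the +z hemisphere, with
   a deterministic tie-break).
2. Lipids are assigned to leaflets by the sign of their distance from this
   plane; planes are then fitted to each leaflet and averaged (midpoint and
   renormalised mean normal) to give the central plane. Assignment is
   re-checked against the central plane and iterated to stability (at most
   10 iterations; one pass almost always suffices). If the mean separation
   between the two leaflets along the central normal is below 2 Å the input
   is rejected — a single noisy sheet would otherwise be "split" about its
   own fit plane and produce meaningless thicknesses.
3. Every phosphate is projected onto the central plane; its height is the
   absolute orthogonal distance. The plane is sampled on a square grid
   (default 1 Å); the height of a cell, per leaflet, is the mean height of
   the `k = 3` nearest projected headgroups (2D Euclidean distance, ties
   broken by lipid index), and thickness is the sum of the upper and lower
   heights.
4. "Inside the nanodisc" is not self-defining on a point set; we take the
   convex hull of the projected phosphates eroded inward by one grid
   spacing.

Aggregation over frames reports the per-cell mean and *population* standard
deviation (a descriptive map statistic, not an inferential one). Each frame
is analysed in its own best-fit central plane — the nanodisc tumbles during
a simulation, and a fixed lab frame would smear the map with rigid-body
motion. Cell indexing must nevertheless be consistent across frames: the
in-plane axes of the first frame are defined by the principal axes of its
projected phosphates (each axis sign-fixed by its third central moment, so
the basis co-rotates with the content under rigid motion) and are then
carried onto every later frame's plane by projection and
re-orthonormalisation. Carrying the axes, rather than recomputing principal
axes per frame, is essential: for a nearly isotropic disc the principal
directions are degenerate and would rotate freely between frames,
azimuthally averaging away genuinely asymmetric features such as a
one-sided thinning.

## Scaffold-belt planarity

The membrane-scaffold belts are analysed from their Cα traces. Per frame, a
plane is fitted to the belt's Cα atoms and each Cα `(x, y, z)` is projected
to `(x_p, y_p, z_p)`; the per-residue score is

$$\log_{10}\left(\sum_{n} \sqrt{(x - x_p)^2 + (y - y_p)^2 + (z - z_p)^2}\right)$$

with the sum running over however many frames are supplied (the frame count
is taken from the input, never hard-coded). Two numerical choices: the
logarithm base is 10 (the plotting convention for this score; the defining
expression leaves the base unstated), and the inner sum is floored at
1e-12 Å before the logarithm, because a perfectly planar belt would
otherwise score negative infinity. The floor gives the sentinel score -12,
which is what "planar to machine precision" looks like in this package's
output. Note that the plane is fitted to *all* belt residues, so a single
residue displaced by `h` pulls the fit towards itself and scores slightly
less than `h` per frame (a ~3/n effect for a circular belt of n residues);
this is a property of the defining formula, not an artefact.

## Ensemble domain motions

Models fitted into related maps, or drawn from the literature, rarely share
a residue set, so ensembles are first pruned to the (chain, residue)
positions whose Cα exists in every model. Superposition is least-squares
rigid-body (Kabsch, with the determinant correction that guarantees a
proper rotation), computed on an explicit alignment selection — the back of
the β-barrel opposite the lateral gate for barrel-relative motions, or the
preceding domain for inter-domain relationships. The centre of mass of a
domain is the unweighted centroid of its Cα atoms (all trace atoms have the
same mass). Every model is superposed onto the first model of the ensemble;
this choice is immaterial because pairwise COM distances are invariant to
the reference model and to any global rigid transform (both properties are
tested). Domain boundary residues that appear in two printed ranges (e.g.
residue 92 in both POTRA1 and POTRA2) are kept in both domains, following
the printed definitions literally. Displacement matrices are reported raw,
in Å, without normalisation.

## smFRET recurrence analysis

Transfer efficiency relates to interdye distance through the Förster
equation $E = 1/(1 + (R/R_0)^6)$, with $R_0 = 60$ Å for the dye pair this
package's defaults emulate.

**Burst detection** is an all-photon sliding-window search: a photon
qualifies when it starts a run of `m = 10` photons spanning at most
`t = 500` µs; contiguous qualifying photons form a burst, and bursts with
fewer than 20 photons in total are discarded. The (m, t) defaults are the
conventional sliding-window values and are exposed as configuration; the
20-photon floor is the analysis threshold. Background rates are a property
of the simulator and of reporting; no count-level background subtraction is
applied to bursts.

**Corrections.** Three corrections are applied to each burst's counts, with
the standard accurate-FRET algebra for alternating-laser excitation:
`Fcorr = FDA − leakage·FDD − direct·FAA`, then
`E = Fcorr / (Fcorr + γ·FDD)` and `S = (Fcorr + γ·FDD) / (Fcorr + γ·FDD +
FAA)`. With γ = 1 and zero leakage/direct excitation, E reduces to the raw
proximity ratio. Bursts with a vanishing denominator are flagged invalid
and excluded.

**Filtering** keeps bursts with stoichiometry in the closed interval
[0.25, 0.75] and at least three acceptor-channel photons during donor
excitation. The S-range filter stands in for photon-distribution-based
double-labelling filters whose internals live in external methods; it is
the fully specified filter of the two and removes the same single-labelled
populations.

**Recurrence.** Bursts from distinct molecules are uncorrelated, so the
burst-time autocorrelation `g(t)` — a histogram of pairwise forward time
differences normalised by the homogeneous-Poisson expectation for the same
mean rate and span — equals 1 for unrelated bursts and exceeds 1 when
molecules re-enter the confocal volume. The same-molecule probability is
`P_same(t) = 1 − 1/g(t)`, clamped to [0, 1] because finite-sample g can dip
below 1. Consecutive filtered bursts whose end-to-start gap is below 30 ms
form (E0, E1) pairs; "consecutive with a dt window" is read as the gap
between bursts, not the start-to-start interval (configurable). Pairs can
optionally be restricted to lags whose P_same exceeds a threshold; this is
off by default. The pair density is a 2D Gaussian kernel density with
bandwidth 0.012 (kernel standard deviation in E units) evaluated on a
0.002-step grid over the unit square; density on the diagonal indicates
persistent states, off-diagonal density indicates millisecond-scale
transitions.

## The ALEX photon simulator

The simulator emulates burst-level statistics, not diffusion paths: primary
bursts arrive as a Poisson process, draw a state from the stationary
occupancy, an exponential duration (mean 1 ms) and a Poisson photon count,
and place photons into the alternation structure (40 µs period, 40% duty
cycle). During donor excitation, a photon lands in the acceptor channel
with exactly the probability that makes the correction algebra above, run
forward, recover the true state efficiency — so the generator and the
corrections are inverse functions by construction, and any disagreement in
tests indicts the analysis, not the fixture. Recurrence is modelled
explicitly: with probability `recurrenceProb` a molecule emits one paired
burst after a uniform gap (default 1–25 ms), keeping its state unless a
jump is drawn from its exponential dwell time, in which case the new state
comes from the transition matrix (self-transitions zeroed). The ground
truth records every burst interval, true state and pairing, which is
sufficient to predict every downstream result without rerunning the
generator.

One deliberate regime choice: the default burst brightness (mean 1500
photons) puts the shot-noise width of a per-burst E at about 0.016 — small
enough that states 0.05 apart in E remain separable by a 0.012-bandwidth
density estimate. Dimmer, more typical bursts (tens of photons) carry shot
noise of ~0.05 in E, and *no* density estimate can resolve states 0.05
apart from such bursts; resolving closely spaced states experimentally
relies on exactly this kind of high-photon-count information. Simulated
streams therefore represent the information content needed by the analysis,
not the brightness distribution of any particular instrument.

## Forward FRET prediction

Dye positions are modelled by a single-sphere accessible volume: candidate
dye centres on a deterministic 1 Å cubic grid within the linker length of
the attachment atom (CB by default — maleimide dyes attach at the cysteine
side chain — with CA as the glycine fallback), rejecting positions that
clash with any non-hydrogen atom (distance < vdW + dye radius) or that
cannot be reached from the attachment along a straight segment sampled at
1 Å steps with probe radius half the linker width. This is a documented
simplification of three-radius accessible-volume models; the dye geometry
defaults (linker 20 Å, width 4.5 Å, radius 3.5 Å) are Alexa-488-like and
fully configurable, since published parameter sets for specific dyes are
tied to particular software manuals. Van der Waals radii are the Bondi set.
Interdye distance distributions are histograms over all inter-cloud point
pairs (uniformly subsampled at one million pairs with a fixed seed when the
cross product is larger); bins are centred on multiples of the bin width so
a degenerate distribution at an integer distance reports that distance
exactly. The predicted efficiency is the histogram-weighted mean of the
Förster curve, and the implied E distribution is also summarised by a
least-squares single-Gaussian fit (mu, sigma), since different studies
report the mean or the mode.

## Crystal-packing contacts

Contacts between two positioned coordinate sets are atom pairs whose Bondi
van der Waals spheres interpenetrate by more than 0.4 Å (hydrogens
excluded). Salt bridges are Lys NZ or Arg NE/NH1/NH2 against Asp OD1/OD2 or
Glu OE1/OE2 — Arg NE is included with the terminal nitrogens, reading
"side-chain amides" inclusively — and hydrophobic contacts are
carbon–carbon pairs. Symmetry-mate generation is out of scope: the module
consumes coordinate sets that have already been positioned (e.g. exported
from a crystallographic viewer), which keeps the classification independent
of any space-group machinery.

## Synthetic study conditions and what passing tests show

The generators' defaults describe the emulated study: an MSP1D1-scale disc
(97 Å diameter) with phosphate planes at ±20 Å, a 70:25:5 PVPE:PVPG:PVCL
headgroup composition apportioned by largest remainder, two 90-residue
poly-alanine belts, and the ALEX parameters above. The test and acceptance
problem sizes are chosen for desk-scale determinism: 400 lipids per leaflet
over 10 frames for the flat-bilayer recovery, 150 per leaflet over 5 frames
for the thinned-wedge recovery, a 16-model articulated ensemble for COM
bookkeeping, and a ~320 s simulated stream (~2000 filtered bursts) for the
three-state recurrence analysis.

Passing these tests shows that the implementations compute their defining
formulas exactly (against brute-force oracles), respect the symmetries the
quantities must have (rigid invariance, reference invariance, leaflet
exchange), and recover planted ground truth under the generators'
idealisations. It does not show robustness to what the generators omit:
lipid acyl-chain structure, correlated lipid motion, dye photophysics
(blinking, bleaching), diffusion-path-dependent burst shapes, detector
artefacts, or model error in fitted coordinates. Conclusions about real
data inherit those caveats.

## Known limitations

- The thickness grid mask is a convex proxy for "inside the nanodisc";
  strongly non-convex phosphate arrangements would be masked too
  generously.
- `P_same` is estimated per lag bin from the pooled autocorrelation, not
  per pair from a model fit.
- The accessible-volume model is single-sphere; dyes with strongly
  anisotropic linkers are approximated.
- The contact classifier knows the twenty standard residues' side-chain
  atom names only; modified residues fall into "other".
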