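# memdyn

Quantitative analyses for integrative structural studies of membrane-protein
complexes in lipid nanodiscs — written for structural biologists and
biophysicists who have molecular-dynamics frames, ensembles of fitted atomic
models, or single-molecule FRET photon streams of the same system and want
the bespoke statistics those data support:

- **Bilayer thickness maps** from phosphate positions: per-frame
  total-least-squares leaflet assignment, central-plane projection, and a
  1 Å grid whose cell height is the mean height of the 3 nearest projected
  headgroups per leaflet; per-cell mean and population SD over frames.
- **Scaffold-belt planarity**: per-residue score
  log₁₀ Σₙ √((x−x_p)² + (y−y_p)² + (z−z_p)²), the summed deviation of each
  belt Cα from its per-frame best-fit plane.
- **Ensemble domain motions**: pruning to the common Cα set, Kabsch
  superposition on an explicit alignment selection, and pairwise
  centre-of-mass displacement matrices per domain with maxima.
- **smFRET recurrence analysis**: sliding-window burst detection,
  accurate-FRET ALEX corrections (γ, leakage, direct excitation),
  stoichiometry/acceptor-count filtering, burst-time autocorrelation g(t),
  same-molecule probability P_same(t) = 1 − 1/g(t), consecutive
  (E0, E1) burst pairs with dt < 30 ms, and their 2D Gaussian kernel
  density (bandwidth 0.012).
- **Forward FRET prediction**: single-sphere accessible-volume dye clouds,
  interdye distance distributions, and the mean of
  E = 1/(1 + (R/R₀)⁶) with R₀ = 60 Å, plus a single-Gaussian summary.
- **Crystal-packing contacts**: van der Waals overlaps > 0.4 Å (Bondi
  radii), classified into salt bridges (Lys/Arg side-chain N against
  Asp/Glu carboxylate O) and hydrophobic carbon–carbon contacts.

Every analysis has a matching synthetic-data generator
(`makeNanodiscFrames`, `makeArticulatedEnsemble`, `simulateALEXPhotons`,
`makeDyeFixture`) that emits a ground-truth record alongside the data, so
the whole pipeline runs and validates at desk scale with no downloads.

## Worked example

An asymmetrically thinned nanodisc (30 Å thick in one quadrant, 40 Å
elsewhere) plus a three-state smFRET stream:

```r
library(memdyn)

spec <- bilayerSpec(nLipidsPerLeaflet = 150,
                    surfaceUpper = function(x, y)
                      ifelse(atan2(y, x) > 0 & atan2(y, x) < pi/2, 10, 20),
                    surfaceLower = -20, positionalNoiseSd = 0.5, seed = 42)
gen <- makeNanodiscFrames(spec, nFrames = 5)
aggregateThickness(gen$frames)
#> ThicknessGrid: 100 x 97 cells at 1 A spacing, 6875 in-disc cells, 5 frame(s)
#>   mean thickness 37.68 A (range 29.35-40.65)

planarityProfile(gen$frames, chain = "M")
#> PlanarityProfile: chain M, 90 residues over 5 frame(s); score range -12.000 to -12.000
```

The map's range spans the planted 30 Å quadrant (cells near 29–30 Å) and
the 40 Å remainder; the overall mean (37.7 Å) sits between them because one
quadrant is thinned. The belts were generated with zero out-of-plane
deviation, so every residue reports the sentinel floor −12 (log₁₀ of the
1e-12 Å zero-deviation clamp).

```r
sim <- simulateALEXPhotons(photonStreamSpec(
  states = data.frame(E = c(0.13, 0.20, 0.25), dwellMs = c(10, 10, 10)),
  durationS = 60, seed = 42))
bt <- filterBursts(correctBursts(detectBursts(sim$photons)))
bt
#> BurstTable: 427 burst(s), corrected (gamma=1)

pairs <- recurrencePairs(bt, dtMaxMs = 30)
head(round(pairs[, 1:3], 3), 3)
#>      E0    E1     dt
#> 1 0.133 0.212 10.365
#> 2 0.199 0.273 19.088
#> 3 0.270 0.208 20.067

pSame(20)
#> [1] 0.95
```

Each pair row is a consecutive burst pair within the 30 ms recurrence
window: the first pair sat in the E ≈ 0.13 state and then jumped towards
E ≈ 0.20/0.25 — exactly the off-diagonal density that
`pairDensity(pairs, bandwidth = 0.012)` renders as transition lobes beside
the three on-diagonal state peaks. `pSame(20) = 0.95` is the same-molecule
probability at an autocorrelation amplitude of 20.

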