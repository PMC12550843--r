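# glycophase

Conformational phase-space analysis of N-glycans from molecular-dynamics
trajectories.

Glycoside hydrolases frequently bind their substrate with the ring in
subsite −1 distorted away from the relaxed ⁴C₁ chair, and that ring
distortion travels together with a specific global conformation of the
glycan's linkages. Quantifying this requires several pieces of machinery,
which this package provides as tested, reusable components:

* **Ring puckering** — Cremer–Pople coordinates (Q, θ, ϕ) of
  six-membered rings (`cremerPople()`), an exact inverse constructor
  used as the oracle (`buildRing()`), canonical IUPAC shape naming over
  the 38-entry reference sphere (`canonicalName()`), and the equal-area
  Mollweide projection for pucker landscapes (`mollweide()`,
  `plotMollweideFES()`).
* **Conformer strings** — per-frame letter strings over glycosidic
  dihedrals (C, G±, A±, T; gg/gt/tg for ω) with free-energy-basin
  inheritance (`basinMap()`, `findBasins()`), branch-aware traversal
  from the free reducing end (`assignConformers()`), and population
  analysis with #1, #2, … short labels (`conformerDistribution()`).
* **Free energies** — ΔG = −k_B T ln P with block-averaged standard
  errors (`feProfile1D()`, `feSurface2D()`, `blockStats()`); 200×200
  pucker surfaces and 35×35 latent-space surfaces.
* **Latent spaces & correlation** — PCA over periodicity-aware
  sin/cos dihedral features with dataset concatenation (`featurize()`,
  `fitLatent()`, `latentFES()`) and conformer↔pucker Pearson analysis
  via one-hot encoding (`oneHot()`, `correlatePhase()`).
* **Replica-ladder planning** — λ/γ ladders for combined
  solute-tempering + well-tempered-bias sampling, hill heights
  h = (k_B ΔT/τ)·τ_G, restraint tables, bias-config emission and
  exchange diagnostics (`buildLadder()`, `hillHeight()`,
  `exchangeDiagnostics()`).
* **Synthetic trajectories** — a generator with known ground truth
  (Markov conformer states, pucker states on the sphere, tunable
  conformer↔pucker coupling c) so that every stage of the pipeline is
  testable without running MD (`simulateTrajectory()`,
  `solutionPreset()`, `boundPreset()`).

## Worked example

Simulate a bound-regime trajectory (two conformer states coupled to
chair / half-chair pucker states), classify conformers, and correlate
them with the ring pucker:

```r
library(glycophase)

tr  <- simulateTrajectory(boundPreset(), nFrames = 10000, seed = 1)
bm  <- basinMap(tr@colvar)                       # per-dihedral FE basins
ser <- assignConformers(tr@colvar, bm, presetTopology())
conformerDistribution(ser)
#> ConformerDistribution: 4 conformers, 10000 frames, minProb 0.05
#>                string count probability shortLabel
#>    6- C T gt 3- C G-  6299      0.6299         #1
#>  6- A+ A- tg 3- C G-  3623      0.3623         #2
#>   6- A+ T tg 3- C G-    59      0.0059      other
#>   6- C A- gt 3- C G-    19      0.0019      other

oh <- oneHot(ser)
cm <- correlatePhase(oh, theta = tr@colvar@values[, "theta"])
round(cm@r[, "theta"], 3)
#> 6- A+ A- tg 3- C G-   6- C T gt 3- C G-               theta
#>               0.866              -0.872               1.000
```

The two dominant conformers correlate with θ with opposite signs
(+0.87 / −0.87): frames in conformer #2 carry the distorted
(half-chair, larger θ) ring while #1 keeps the chair — the designed
coupling of the generator, recovered end-to-end through the
classification and correlation machinery. In the solution regime
(`solutionPreset()`, coupling 0) the same pipeline yields |r| < 0.03,
i.e. no spurious coupling.

Pucker naming and free-energy profiles work the same way:

```r
pc <- cremerPople(buildRing(Q = 0.57, theta = 0.95, phi = 5.76))
canonicalName(pc)
#> [1] "OH5"

prof <- feProfile1D(tr@colvar@values[, "theta"], bins = 72,
                    nBlocks = 10, range = c(0, pi))
plotProfile(prof, xlab = expression(theta ~ "(rad)"))
```

A thin command-line front end over the same functions is installed at
`system.file("cli", "glycophase.R", package = "glycophase")`, with
subcommands `simulate`, `pucker`, `conformers`, `fes`, `pca`,
`correlate`, `restrect` and `diagnose`; every command accepts
`--seed`, `--temperature` and `--out`, and fixed seeds give
byte-identical outputs.

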