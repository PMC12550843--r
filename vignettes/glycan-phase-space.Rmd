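---
title: "Analysing the conformational phase space of glycans"
author: "glycophase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing the conformational phase space of glycans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycophase)
```

## Scope and model

N-glycans explore two coupled kinds of conformational freedom: the
torsions of their glycosidic linkages (phi, psi, and omega for 1-6 /
2-6 linkages) and the out-of-plane pucker of each pyranose ring. In
glycoside hydrolases the catalytically competent substrate is often
ring-distorted, and the distortion of the ring in subsite -1 tends to
travel together with a specific global linkage conformer. This package
implements the analysis layer for that problem: classifying the global
linkage conformer per trajectory frame, quantifying the ring pucker on
the Cremer-Pople sphere, reconstructing free-energy profiles and
surfaces from sampled frames, and measuring the statistical coupling
between conformers and pucker. It operates on sampled collective
variables (or on coordinates via a selection config); it does not run
molecular dynamics.

## Ring puckering

A six-membered ring with atoms ordered O5, C1, C2, C3, C4, C5 is
reduced to the Cremer-Pople triplet (Q, theta, phi): the ring is
translated to its geometric centre, a mean plane is defined through
the two weighted coordinate sums, and the out-of-plane displacements
z_j are Fourier-decomposed into an m = 2 pair (q2, phi) and the
alternating m = 3 sum q3, with Q^2 = q2^2 + q3^2 and
theta = acos(q3/Q). Under this atom order the 4C1 chair of
D-pyranoses sits at theta = 0 and 1C4 at theta = pi; that orientation
convention is not universal in the literature, so it is fixed here
once and asserted by tests (the inverse constructor `buildRing()`
serves as the independent oracle: forward of inverse must be the
identity to 1e-8 over the sphere).

Canonical shape names are assigned by nearest great-circle distance to
a 38-entry reference table (`canonicalShapes()`): chairs at the poles,
boats and skew-boats alternating every 30 degrees of phi on the
equator, envelopes and half-chairs alternating on the tropics at
theta = 54.74 / 125.26 degrees. The phi anchor places 3,OB at phi = 0
and OS2 at phi = 330 degrees; the table order is the documented
tie-break. Frames with sin(theta) < 1e-6 have a degenerate azimuth and
are flagged (`definedPhi = FALSE`, phi reported as 0) and excluded
from phi statistics; planar rings (Q < 1e-8 A) receive the sentinel
label "planar" rather than an arbitrary shape.

Pucker landscapes are drawn with the Mollweide projection, a
pseudocylindrical equal-area map: latitude pi/2 - theta, longitude
phi - centerPhi, and an auxiliary angle t solving
2t + sin(2t) = pi sin(lat). The solver uses vectorized bisection (the
equation's derivative vanishes at the poles, where Newton iteration
stalls) polished by two Newton steps, to a residual below 1e-12.
Equal area matters because cell densities, and hence free energies,
are preserved by the map. The default central meridian is 180 degrees
so the B2,5 / OS2 sector of the equator — where distorted states of
mannosidase substrates concentrate — is not cut by the seam.

```{r pucker}
ring <- buildRing(Q = 0.57, theta = 0.12, phi = 1.0)
cremerPople(ring)
canonicalName(0.12, 1.0)
```

## Conformer strings

Each frame's global conformer is a letter string over the glycan's
dihedrals. The letters follow the IUPAC intervals: for phi/psi,
C = (-0.52, +0.52), G+ = (+0.52, +1.57), A+ = (+1.57, +2.62),
T = [+2.62, pi] or (-pi, -2.62), A- = (-2.62, -1.57),
G- = (-1.57, -0.52); for omega, gg = (-2.62, 0), gt = (0, 2.62),
tg = [2.62, pi] or (-pi, -2.62]. Printed interval brackets are
inconsistent across sources, so one audited ownership convention is
applied everywhere: intervals are half-open and closed at the lower
bound, with T (and tg) owning both +/-2.62 endpoints and 0 belonging
to gt.

Letters are not assigned from raw intervals but inherited from
free-energy basins: a 1D periodic free-energy profile (-kB T ln P of
the binned marginal, 72 bins = 5-degree resolution by default) is
computed per dihedral, its local minima are labelled by their interval
letter, and every angle between the flanking barriers inherits that
letter. Shallow minima are merged watershed-style under a prominence
threshold of 1 kBT. Neither the resolution nor the threshold is a
published constant; 72 bins resolve the narrowest letter interval
(about 1 rad) by an order of magnitude while the 1 kBT prominence
rejects minima indistinguishable from sampling noise, and both are
arguments of `basinMap()`. Basins whose minima share a letter merge
into one label; this is the simpler of the two defensible readings of
basin labelling and is stated here because it changes the conformer
count on multimodal profiles.

The string starts at the free reducing end and lists phi, psi (and
omega if present) per linkage; at a branching junction a separator
named for the branch-origin carbon (e.g. `6-`) is emitted and the
higher-carbon branch is traversed to its terminus before the lower
one, recursively — the recursion generalises the two-way rule to
nested junctions. Distributions over strings get short labels #1, #2,
... by descending probability (lexicographic tie-break), with a 5%
reporting threshold folding rare conformers into "other".

```{r conformers}
tr <- simulateTrajectory(boundPreset(), nFrames = 4000, seed = 1)
bm <- basinMap(tr@colvar)
ser <- assignConformers(tr@colvar, bm, presetTopology())
conformerDistribution(ser)
```

## Free energies and block errors

Free energies come from ground-replica (unbiased) probabilities via
deltaG = -kB T ln(P), kB = 0.0083144626 kJ/(mol K), default
temperature 310.15 K. Empty bins are masked, never zero. Profile
errors use block averaging: the series is cut into N contiguous,
equally sized blocks (5-10 in practice), a free-energy value is
computed per block and bin, and the sampling variance of the block
means is var = (N/(N-1)) (mean(X^2) - mean(X)^2) with
SEM = sqrt(var/N). Two choices here were genuinely open. First, the
per-block statistic is the block's own free energy (not its
probability); the SEM therefore applies to deltaG directly, which is
what the error bars decorate. Second, a bin empty in some block
contributes a masked block value: it is dropped and the effective
block count recorded, rather than imputed as zero probability (which
would inject infinities). Blocks are treated as independent —
within-block correlation is the user's responsibility through the
block count. Surfaces use 200 x 200 bins for (theta, phi) pucker
landscapes and 35 x 35 for latent spaces; a surface with a single
populated cell is legal (deltaG = 0 there, everything else masked).

## Latent spaces and conformer-pucker correlation

For dimensionality reduction every dihedral enters as its (sin, cos)
pair, which respects angular periodicity; PCA is computed on the
column-centred concatenation of whatever datasets are being compared,
so that, e.g., bound and unbound ensembles share one latent space.
Features are centred but not variance-scaled — sin/cos features are
already commensurate, and scaling would inflate near-constant
features; centring happens on the concatenated matrix, consistent
with concatenation-before-PCA. Component signs are fixed (largest
loading positive) to make runs comparable.

Conformer labels are ordinal, so correlation with pucker uses one-hot
encoding followed by pairwise Pearson coefficients. Theta enters in
radians — it lives on [0, pi], so linear correlation is meaningful —
while the pucker azimuth phi is excluded from Pearson analyses by
default because of its circularity. Constant columns give NA entries
(rendered blank, never 0), and a 1% population filter removes
conformers whose correlations would be noise-dominated.

## Replica-ladder planning and diagnostics

The planning module encodes the enhanced-sampling bookkeeping:
per-replica Hamiltonian scaling lambda (effective temperature
T0/lambda), well-tempered bias factor gamma, boosting temperature
dT = T0 (gamma - 1), and hill height h = (kB dT / tau) tauG (tau = 4
ps, tauG = 1 ps, 0.35 rad hills by default). `boundLadder()` carries
the explicit 16-replica ladder (lambda 1..0.55, gamma 1..6);
`solutionLadder()` builds 12-replica geometric progressions (lambda
1..0.42, gamma 1..14). Nominal temperature spans quoted for such
ladders are sometimes approximate: 310.15/0.55 = 563.9 K, not 570 K,
and `validateLadder()` surfaces that as a warning instead of silently
adjusting either number. Exchange diagnostics compute neighbour-pair
acceptance and per-walker round-trip times from an index trace;
`randomWalkTrace()` provides the analytic benchmark — for a half-lazy
reflecting symmetric walk on n rungs the mean round trip is
2 n (n-1) attempts — against which the round-trip bookkeeping is
validated.

## The synthetic generator

`simulateTrajectory()` produces desk-scale trajectories with known
ground truth: a Markov chain over conformer states; per-state circular
dihedral distributions; pucker states on the sphere; and a coupling
c in [0,1] — the probability that a frame's pucker state is the
partner of its conformer state rather than a background draw.
Dihedral noise is wrapped-normal (any correctly wrapped unimodal
family would do; the choice is recorded in the trajectory metadata)
with concentration kappa mapping to sd = 1/sqrt(kappa). Theta noise
is reflected at the poles, phi noise wraps periodically; a
spherical-normal model is deliberately out of scope.

The presets encode the two regimes of interest. `solutionPreset()`:
four exchanging conformer states, kappa = 40 (about 9-degree angular
sd, typical of a well-defined rotamer), persistent chain (0.98
self-transition, dwell about 50 frames), a single chair pucker state
(theta = 5 degrees, 6-degree spread) and c = 0 — conformers and
pucker uncorrelated. `boundPreset()`: two conformer states differing
in the designated linkage's psi/omega, paired with chair and
equatorial-band half-chair (theta = 54.7 degrees, phi = 330 degrees,
the OH5 sector) pucker states at c = 0.9; one-hot correlations of the
two states against theta then have opposite signs, the qualitative
signature of a distortion-coupled bound glycan. Default length is
10^4 frames at 10 ps spacing; these sizes make each analysis stage
statistically decisive (binomial error well below the effects being
asserted) at interactive runtimes.

What the generator does *not* emulate matters for interpreting green
tests: there are no energetics or sterics, no correlation between
dihedral noise across linkages beyond the shared hidden state, no
slow pucker kinetics (pucker draws are conditionally independent
given the state), and no replica-exchange dynamics. Passing tests
demonstrate the correctness of the estimators and classification
machinery — not that any particular real glycan behaves like the
presets.

```{r coupling}
oh <- cbind(s1 = as.numeric(tr@conformerState == "s1"),
            s2 = as.numeric(tr@conformerState == "s2"))
round(correlatePhase(oh, theta = tr@colvar@values[, "theta"])@r["theta", 1:2], 3)
```

## Numerical choices and degenerate inputs

* Angles are wrapped once at ingest to (-pi, pi], half-open at -pi;
  all downstream code assumes it. Pucker theta (and amplitude Q) are
  exempt.
* Missing values are explicit NA: excluded from histograms and
  distributions, never imputed; a frame with any missing angle has no
  conformer string.
* Collinear atom quadruples have no defined torsion and yield NA;
  planar rings yield Q = 0 with undefined angles rather than an
  exception.
* Probability 0 maps to a masked free energy, never to Inf inside a
  profile; profiles are shifted so their minimum is exactly 0.
* Ties: canonical shape ties resolve to the earlier table entry;
  conformer-probability ties resolve lexicographically; letter-interval
  boundaries belong to the interval closed at that bound.
* Atom identifiers in selection configs are 1-based (PDB serial
  convention) and converted internally once.

## Limitations

Furanose (five-membered) pseudorotation, amplitude (Q) free-energy
analysis, WHAM-style reweighting of biased replicas, automatic
topology inference from 3D structure, and nonlinear embeddings are
all out of scope. The Pearson machinery correlates theta only; a
circular-circular correlation for phi would need different
statistics. Block averaging treats blocks as independent — for
strongly autocorrelated series the block count must be chosen so that
blocks exceed the correlation time, or the SEM will be optimistic.
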