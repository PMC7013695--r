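---
title: "Activation hallmarks of GPCR/G-protein trajectories: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activation hallmarks of GPCR/G-protein trajectories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchmd)
```

## The scientific problem

Class A G-protein-coupled receptors (GPCRs) transmit an extracellular
agonist signal to an intracellular G protein through a small set of
conserved conformational changes, often called molecular switches or
microswitches. For the dopamine D2 receptor, which exists as a short (D2S)
and a long (D2L) isoform differing by 29 residues in the third
intracellular loop (ICL3), a question of pharmacological interest is which
inhibitory G-alpha subtype (Gi1 vs Gi2) each isoform prefers. Microsecond
molecular-dynamics (MD) simulations address this by watching a battery of
residue-level observables:

* the distance between the receptor's intracellular cavity and the
  C-terminal alpha5 helix of G-alpha, and its **trend** over the run
  (approach = coupling maintained, retreat = G protein sliding out);
* the **chi1 rotamers** of the microswitch residues W6.48 (toggle switch,
  CWxP motif), F6.44 (transmission switch), H6.55 and Y7.53 (NPxxY motif);
* the **ionic lock** R3.50-E6.30 between TM3 and TM6, formed in inactive
  receptors (about 3.0 angstrom in the inactive D2 crystal structure) and
  broken on activation;
* the **TM5-TM7 distance** at the conserved tyrosines Y5.58/Y7.53 (about
  19.4 angstrom in the inactive crystal structure; smaller when TM6 bends
  in active-like conformations);
* the **TM6 kink** at the 6.48 toggle position (bent in active, straight
  in inactive structures);
* a **continuous internal water channel** past the hydrophobic barrier
  L2.42/I2.43/L3.43/I3.46/M6.36, whose wetting marks activation;
* **C-alpha principal component analysis** of helix subsets and the
  normalized **covariance overlap** between simulations.

This package implements that battery as reusable, tested functions over
multi-model PDB trajectories, addressed throughout in Ballesteros-Weinstein
(BW) `h.p` notation so the same analysis runs on any author numbering.

## Residue mapping

A `bw_map` holds one anchor residue per helix (the `x.50` position) and a
helix span; `resolve_bw()` is plain arithmetic,
`resno = anchor + (p - 50)`, validated against the span. Anchors are meant
to be supplied explicitly in a config and merely *suggested* by
`detect_motifs()`, which scans for DRY (the arginine is 3.50), CWxP (the
tryptophan is 6.48, so `6.50` is two residues later) and NPxxY (the
tyrosine is 7.53, so `7.50` is three residues earlier). Autodetection must
be confirmed by the user: helix boundaries differ between isoforms and the
published analyses never state their spans, so span validation is
deliberately a soft, configurable guard (default anchor +/- 25, clipped).
ICL3 residues carry no BW label and are addressed as (chain, residue id).

## Geometry conventions

* **Dihedrals** are reported in degrees in (-180, 180], IUPAC sign
  (checked against an independent implementation and against
  `bio3d::torsion.xyz` in the test suite). chi1 is N-CA-CB-gamma with the
  gamma atom chosen by residue type (CG; CG1 for Ile/Val; OG/OG1 for
  Ser/Thr; SG for Cys); Gly and Ala are rejected.
* **Rotamer states** use half-open 120-degree bins: gauche- on (-120, 0],
  gauche+ on (0, 120], trans otherwise, so the canonical -60/+60/180
  states sit at bin centres and -120 falls in trans.
* **Centers of mass are unweighted centroids.** The published selections
  are all-C-alpha or all-heavy-atom sets, where mass weighting is either
  irrelevant (identical atoms) or irreproducible without a mass table;
  side-chain centroids for the interface distances are likewise unweighted
  heavy-atom means, with a logged C-alpha fallback for glycine.
* **Superposition** is the Kabsch least-squares fit with the proper
  rotation enforced; it is implemented in-package because downstream code
  needs the rotation/translation pair itself, and is cross-checked against
  `bio3d::fit.xyz` and a random-rotation optimality bound in the tests.
* **Contacts** on residue-pair minimum-distance maps use heavy atoms only
  (hydrogens are often absent from PDB dumps) and a 3.0 angstrom
  threshold, the convention used for marking contacts on published
  distance maps. Time-averaged maps average the per-frame minima over the
  window first and threshold afterwards.
* **Coordinates are assumed pre-imaged.** No periodic-boundary unwrapping
  is attempted; inputs must contain whole molecules.

### Helix axes and the TM6 kink

The TM6 kink is the angle between the axes of the segments 6.30-6.47 and
6.49-6.60, split at the 6.48 bend locus and clipped to the mapped span.
Axes come from `helix_axis()`: a principal-axis fit applied to
*turn-averaged* points. A raw principal axis of a short helix segment
tilts by several degrees when the segment covers a non-integer number of
helical turns (the centroid of the surface spiral is off the centerline);
averaging each point with its neighbours using a 5-point kernel whose
weights cancel the 100 degrees/residue harmonic removes this wobble
exactly for an ideal helix. Runs shorter than 7 residues (including
exactly collinear point sets) fall back to the raw principal axis.

Per-frame kink angles of a *straight* helix still fold coordinate noise
into a small positive angle (an angle magnitude cannot average to zero),
so `tm6_kink(..., average = TRUE)` also offers the kink of the
superposed mean structure, which is the estimator used when recovering a
planted bend; the per-frame series remains what the report tabulates. The
report's bent/straight call uses a 15-degree threshold on the mean
per-frame kink - published bending calls are qualitative, so the
threshold is a documented config knob, not a literature constant.

## The coupling trend classifier

The receptor/G-alpha approach series is the per-frame distance between
the centroid of five conserved intracellular receptor C-alphas (Y7.53,
L2.46, I3.46, T5.54, V6.40) and the centroid of the C-alphas of the five
C-terminal alpha5 residues of G-alpha (D351-F355 in Gi1 numbering; the
residue ids are config entries because G-alpha subtypes number
differently). The trend is an ordinary least-squares line of distance
against time - published work draws a best-fit line and reads its sign;
OLS is the natural formalisation. Classification uses a dead-band
`threshold` (default 0.0005 angstrom/ns, i.e. 0.5 angstrom over 1
microsecond): slopes below `-threshold` are "approaching", above
`+threshold` "receding", otherwise "flat". The dead-band exists purely to
avoid classifying noise as drift and is configurable; fits can be
restricted to a time window (e.g. the last 100 ns) since some published
summaries use windows. Each trajectory (replica) is fitted separately.

## Hydrogen bonds and the ionic lock

The ionic-lock distance is the minimum over the six R3.50 guanidinium
nitrogen (NE/NH1/NH2) to E6.30 carboxylate oxygen (OE1/OE2) pairs - the
published 3.0 angstrom inactive-state value does not state its atom
convention, so the charged-group minimum is assumed and documented.
`hbond_present()` uses a heavy-atom N/O-to-N/O distance criterion of
3.5 angstrom with no angle term, again because hydrogens may be absent.

## Water-channel detection

Published open/closed channel calls are made by visual inspection of
rendered waters; a reusable implementation needs numeric criteria, which
are therefore package-defined, recorded in every output header, and
config-exposed in `channel_spec()`:

| parameter | default | meaning |
|---|---|---|
| `top_ref`, `bottom_ref` | 3.32, 7.53 | axis endpoints: orthosteric-site locus to NPxxY gate |
| `cylinder_radius` | 8 A | lateral capture radius around the axis |
| `link_cutoff` | 3.5 A | O-O distance linking two waters (H-bond heavy-atom distance) |
| `attach_cutoff` | 4.0 A | water-to-endpoint attachment |
| `axial_margin` | 3 A | axial slack beyond the endpoints |

A frame is "open" when the graph of linked channel waters connects some
water attached to the top endpoint with one attached to the bottom
endpoint (connectivity via igraph; validated against a hand-written
breadth-first search). `barrier_occupancy()` counts water oxygens within
4 angstrom of any heavy atom of the five barrier residues. Only water
oxygens are used; hydrogens are ignored throughout.

## PCA and the covariance overlap

`build_covariance()` superposes frames on a fit selection in two passes
(fit to the first frame, form the average structure, re-fit to the
average) and accumulates the *non-mass-weighted* covariance of the
analysis C-alphas - non-mass-weighting follows the published analysis
choice explicitly. The canonical selections mirror that analysis: fit on
all receptor C-alphas; analyse TM6, or TM5+TM7 sub-spans around
Y5.58/Y7.53 (default `x.50 +/- 8`, config-overridable, since the exact
published sub-spans are unstated). Concatenated replicas can be analysed
by concatenating frames before `build_covariance()`; projections keep
their provenance through the per-trajectory report tables.

Two simulations are compared by the normalized covariance overlap

$$\Omega(A,B) = 1 - \sqrt{\frac{\mathrm{tr}\left[(A^{1/2}-B^{1/2})^2\right]}{\mathrm{tr}\,A + \mathrm{tr}\,B}},$$

the standard trace metric in MD analysis tools, consistent with its two
defining anchors: 1 for identical matrices and 0 for sampled subspaces
with orthogonal support. Matrix square roots use symmetric
eigendecomposition with negative eigenvalues clipped to zero; the value
is clamped to [0, 1] against rounding. The population (divide-by-N)
covariance is used; the tests carry the explicit N/(N-1) factor where
they cross-check against `bio3d::pca.xyz`.

## The synthetic-trajectory generator

No trajectory data are deposited for the study conditions this battery
targets, so `generate_trajectory()` builds toy systems with *known ground
truth* for every observable:

* seven ideal alpha-helices (rise 1.5 angstrom/residue, twist 100
  degrees/residue, C-alpha radius 2.3 angstrom) on a 12-angstrom circle,
  each spanning BW positions 30-70 with planted DRY/CWxP/NPxxY motifs;
* TM6 bent by a requested angle about the 6.48 C-alpha;
* full N/CA/CB/gamma internal-coordinate side chains for the four switch
  residues, so the planted chi1 is exact, evolved by a two-state Markov
  flip rule per frame;
* an R3.50/E6.30 charged pair built at the requested minimum distance;
* an 8-residue alpha5 mimic placed collinearly below the receptor probe
  centroid, so a drift slope `s` makes the probe distance *exactly*
  `d0 + s t` before noise;
* a water column along the 3.32-7.53 axis (five oxygens per 1.5-angstrom
  level) that is open, blocked (middle third displaced far off-axis), or
  alternating per frame;
* finally i.i.d. Gaussian noise on every coordinate.

Defaults represent the emulated study conditions: 1000 frames at
1 ns/frame (a 1-microsecond run sampled at 1 ns), coordinate noise 0.5
angstrom per axis (C-alpha-fluctuation scale for a stable transmembrane
bundle), drift slopes of +/-0.003 angstrom/ns for clearly coupled or
decoupled runs (a 3-angstrom approach over 1 microsecond), and a
12-angstrom initial probe separation. One seeded stream drives first the
rotamer chains (in switch-label order) and then the noise, so output is
bit-reproducible; the pre-noise planted values are emitted as per-frame
truth labels.

What the generator does **not** emulate: force-field physics, membranes
and lipids, correlated collective motions, water residence dynamics,
sodium binding, or realistic side-chain packing. Passing recovery tests
therefore demonstrates that the *analysis* is correct and well-calibrated
on data with the right statistical shape (linear trends plus isotropic
noise, two-state torsions, percolating water columns), not that the
science of any particular MD system is reproduced.

## Numerical and degenerate-input choices

* Degenerate dihedrals (collinear triples) raise a geometry error rather
  than returning an arbitrary angle.
* `coupling_trend()` on fewer than two distinct time points raises a
  degenerate-input error; `build_activation_report()` converts that into
  a "degenerate" classification so single-frame reports still carry all
  instantaneous distances.
* Altloc records keep the highest occupancy (ties: first encountered);
  insertion codes are rejected outright - renumber first.
* Eigenvalues are clipped at zero before square roots; overlap values are
  clamped to [0, 1].
* Report metrics fail independently: every failure is caught and recorded
  in the report's error slot while the rest of the battery completes, and
  the pipeline isolates whole-trajectory failures the same way, mirroring
  a replicas-plus-control study layout.

## Problem sizes in the test suite

The suite validates at the scale the battery targets: slope recovery and
classification accuracy use 1000-frame runs at noise 0.5 angstrom over
100 seeds per planted slope; oracle-equivalence checks run 100 random
fixtures per metric; preset discrimination analyses four 1000-frame
presets end to end. Property tests that only probe invariances use
smaller sizes (30-300 frames) chosen to keep the default run quick while
leaving the statistical conclusions unchanged.

## Known limitations

* The canonical input dialect is multi-model PDB; binary trajectory
  formats need conversion (the reader interface is a single function, so
  an adapter is straightforward).
* BW assignment is sequence/config-based; structure-based assignment
  against a template is out of scope.
* Water-channel criteria are geometric, not energetic, and the channel
  axis is a straight segment - strongly curved pathways would need a
  curved probe.
* The H-bond test has no angular term, trading specificity for
  robustness to missing hydrogens.
* Interaction energies, docking and free-energy estimates are explicitly
  out of scope.
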