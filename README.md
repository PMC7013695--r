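# switchmd

Activation-hallmark analysis for class A GPCR molecular-dynamics
trajectories, with a ground-truth synthetic-trajectory generator.

## What problem this addresses

Deciding whether a receptor/G-protein complex stays coupled in an MD
simulation — and whether the receptor drifts toward its active or
inactive state — is usually read off a battery of residue-level
observables rather than any single number: the trend of the distance
between the receptor's intracellular cavity and the α5 helix of Gα, the
χ1 rotamers of the conserved microswitches (W6.48, F6.44, H6.55, Y7.53),
the TM3–TM6 ionic lock (R3.50–E6.30), the TM5–TM7 tyrosine distance
(Y5.58–Y7.53), the TM6 kink at the CWxP motif, the formation of a
continuous internal water channel past the hydrophobic barrier
(2.42/2.43/3.43/3.46/6.36), and Cα principal-component analysis with the
covariance overlap between runs. `switchmd` implements this battery as
tested R functions over multi-model PDB trajectories, addressed in
Ballesteros–Weinstein `h.p` notation so the same script runs on any
author numbering. It is aimed at structural bioinformaticians analysing
GPCR (e.g. dopamine D2 isoform / Gi subtype) simulations, and at method
developers who need a trajectory battery with known-truth test data.

## The statistics at the core

* **Coupling trend**: ordinary least-squares fit of the probe distance
  *d(t)* (centroid of Y7.53/L2.46/I3.46/T5.54/V6.40 Cα vs centroid of the
  five C-terminal α5 Cα); classification by the slope sign outside a
  dead-band (default 5×10⁻⁴ Å/ns): *approaching*, *receding* or *flat*.
* **Rotamer states**: χ1 = N–CA–CB–γ dihedral, binned gauche⁻ (−120, 0],
  gauche⁺ (0, 120], trans otherwise.
* **Channel continuity**: water oxygens within 8 Å of the 3.32→7.53 axis
  form a graph with edges at O–O ≤ 3.5 Å; a frame is open when a path
  connects waters attached (≤ 4 Å) to both endpoints.
* **Covariance overlap** between two runs with Cα covariances A, B:

      Ω(A, B) = 1 − sqrt( tr[(A^1/2 − B^1/2)²] / (tr A + tr B) )

  Ω = 1 for identical matrices, Ω = 0 for orthogonal-support subspaces.

See `vignettes/activation-hallmarks.Rmd` for every convention, default
and design choice.

## Worked example

```r
library(switchmd)

# a 300 ns study-like system with known ground truth
spec <- synthetic_preset("active-coupled", n_frames = 300, seed = 42)
gen  <- generate_trajectory(spec)          # $traj, $map, $truth
report <- build_activation_report(gen$traj, gen$map)
print(report)
```

```
activation_report: synthetic (300 frames)
  receptor/alpha5 trend : -0.00279 A/ns -> approaching
  ionic lock R3.50-E6.30: 11.80 A (mean)
  Y5.58-Y7.53 (CA)      : 17.80 A (mean)
  TM6 kink at 6.48      : 30.2 deg (mean) -> bent
  water channel open    : 1.00 of frames
  chi1 6.48             : gauche- (modal state)
  chi1 6.44             : trans (modal state)
  chi1 6.55             : trans (modal state)
  chi1 7.53             : gauche- (modal state)
```

The preset plants a −0.003 Å/ns α5 approach, a 30° TM6 bend, a broken
ionic lock (12 Å) and a continuously open water channel under 0.5 Å
coordinate noise; the report recovers each one: the fitted slope −0.00279
is the planted drift within noise, the 30.2° mean kink and "bent" call
match the planted bend, and the open fraction is exactly 1. Comparing two
presets by TM6 covariance overlap:

```r
cv <- function(g) build_covariance(g$traj, receptor_ca_selection(g$traj, g$map),
                                   tm_ca_selection(g$traj, g$map, 6L))
g2 <- generate_trajectory(synthetic_preset("inactive-decoupled", n_frames = 300, seed = 42))
round(overlap_matrix(list(active = cv(gen), inactive = cv(g2))), 3)
```

```
         active inactive
active    1.000    0.992
inactive  0.992    1.000
```

(The two toy systems share the same noise structure, hence the high
off-diagonal overlap; distinct sampled motions drive it toward 0.)

Real trajectories enter the same way: `read_trajectory("run.pdb")` plus a
residue-mapping YAML (`read_map_config()`), or batch runs via
`run_analysis(run_config(...))`, which writes per-trajectory TSV report
tables and the pairwise overlap matrix. A thin CLI wrapper is installed at
`inst/cli/switchmd` (`analyze`, `simulate`, `map` subcommands).

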