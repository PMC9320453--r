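---
title: "Models and methods behind mdhinge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mdhinge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mdhinge)
```

`mdhinge` analyses molecular-dynamics trajectories of proteins built from
a few quasi-rigid domains joined by flexible linkers — the architecture of
many ribosome-assembly factors, whose function depends on an equilibrium
between a compact ("closed") and an extended ("open") arrangement of the
flanking domains about a central one. This vignette explains each model,
its assumptions, the tunable parameters, and the design choices made where
the field's conventions leave room.

## Residue numbering

All user-facing residue numbers are *sequence* numbering. Reference PDB
files sometimes number a construct with a leading tag so that sequence
position $x$ appears as file residue $x + \mathrm{offset}$; the offset is
part of the domain configuration (default 0) and is applied exactly once,
when selections are resolved against the file. This avoids the classic
off-by-a-tag trap when naming mutation sites.

Domains are named inclusive residue ranges. Linker residues belong to no
domain: they are excluded from per-domain metrics but included in
whole-protein metrics. Whether whole-protein statistics should exclude
linkers is a matter of taste; we include them, and per-domain series are
available whenever the distinction matters.

## Superposition

Rigid-body least-squares superposition uses the SVD form of the Kabsch
algorithm with the standard sign correction of the smallest singular
vector, so the returned rotation always has determinant $+1$: a mirror
image that would fit better is never used, because protein chirality must
be preserved. The fit is unweighted, matching the unweighted RMSD
definition used throughout.

Fits require at least three non-collinear points, because the optimal
transform is otherwise not unique. The RMSD *minimum* is still unique for
degenerate sets, so `kabsch_superpose(..., allow_degenerate = TRUE)`
accepts them and returns one valid minimiser — this is how the textbook
two-atom RMSD example (reference atoms 2 Å apart, frame atoms 4 Å apart,
post-fit RMSD exactly 1 Å) is reproduced. Default fit and measure
selection is Cα; a backbone (N, CA, C, O) fit is available through the
selection language, since published protocols vary on this point while
reporting Cα-based metrics.

## Stability metrics

*RMSD.* Each frame is superposed onto the reference (by default the first
frame) over the fit selection and the deviation is measured over the
measure selection:
$\mathrm{RMSD}(t) = \sqrt{\tfrac1N \sum_i |r_i(t) - r_i^{\mathrm{ref}}|^2}$.
Per-domain RMSD fits *and* measures on that domain's Cα only, with an
independent superposition per domain. A globally fitted per-domain RMSD
would mix internal domain deformation with inter-domain rigid motion; the
per-domain fit isolates internal stability, which is what per-domain
traces are meant to show.

*RMSF.* The per-residue fluctuation is taken about the trajectory-average
structure: the trajectory is aligned to its first frame, averaged,
re-aligned to that average once, and
$\mathrm{RMSF}(i) = \sqrt{\tfrac1T \sum_t |r_i(t) - \bar r_i|^2}$
is evaluated. The average-structure/alignment pair is a fixed point only
in the limit of infinitely many iterations; one iteration is the standard,
deterministic choice and further iterations change the profile by far less
than thermal noise. An optional separate fit selection lets fluctuations
of mobile atoms be measured relative to a stable scaffold. With $n$
aligned atoms over $T$ frames, estimating the mean and the 6 rigid degrees
of freedom biases the measured RMSF downward by a factor of roughly
$\sqrt{1 - 1/T - 2/n}$; at the problem sizes used in the tests (72 atoms,
2000–5000 frames) this is a 1–2% effect, well inside the 5% recovery
tolerance asserted against the isotropic-noise expectation
$\mathrm{RMSF} \to \sqrt{3}\sigma$.

*Equilibration.* Published analyses usually set equilibration points by
eye. We operationalise the same judgement reproducibly: scan candidate
start frames at window boundaries and accept the earliest start after
which every full window of the series has least-squares slope within
`slope_tol` and window means within twice the pooled within-window
standard deviation. Defaults are a window of 10% of the series and
`slope_tol = 0.02` Å/ns, appropriate for production-scale series
(hundreds of ns at 0.1 ns/frame). Short synthetic series carry
proportionally larger slope-estimation noise, so the desk-scale analyses
in the tests and the acceptance script use `slope_tol = 0.2` Å/ns with
40-frame windows — a property of the series length, chosen once from the
noise model, not tuned. A series that never qualifies (a monotone drift)
returns the "not equilibrated" sentinel `NA`.

## Domain-motion geometry

The radius of gyration is the standard mass-weighted root-mean-square
form, $R_g(t) = \sqrt{\tfrac1M \sum_i m_i |r_i(t) - R(t)|^2}$. (The
root-mean-square form is the only one consistent with the ~19–27 Å values
quoted for ~250-residue proteins; a linear average has no such
interpretation.) Masses come from a standard atomic-mass table by element;
Cα-only coarse models carry the carbon mass, 12.011 amu.

Inter-domain distances use mass-weighted centres of mass of each domain's
Cα atoms; hinge angles use unweighted centres of geometry, with
$\theta = \arccos(\widehat{BA} \cdot \widehat{BC})$ at the central domain
$B$. The two flavours are kept distinct because both conventions are in
use; for Cα-only selections of equal-mass atoms they coincide. All three
observables are rigid-invariant, so no superposition is involved.

## The ΔRMSD progress variable

$\Delta\sigma(t) = \sigma_{\mathrm{closed}}(t) - \sigma_{\mathrm{open}}(t)$,
where each $\sigma$ is the RMSD of the frame to one reference after its
*own* independent superposition. A shared fit would bias $\Delta\sigma$
toward whichever reference supplied the fit. Because post-fit RMSD is a
metric on shapes, $|\Delta\sigma| \le D$ always, with $D$ the
inter-reference RMSD — a bound the test suite verifies on random frames,
along with exact antisymmetry under swapping the references and
monotonicity along the closed→open interpolation path.

Frames are classified closed / intermediate / open by whether
$\Delta\sigma$ lies below $-fD$, inside $\pm fD$, or above $+fD$. The
intermediate band fraction $f$ defaults to 0.2: "close to zero" is
inherently a judgement call, and one fifth of the inter-reference
separation is conservative while still leaving the band wide enough that
genuinely parked-halfway systems fall inside it. The per-system call is
the majority frame label over the production run. Transition onsets are
detected by departure from an initial-segment baseline by more than 6
baseline standard deviations sustained for 3 frames; on a hinge ramp the
first post-onset frames move many baseline deviations at once, so the
detected frame tracks the programmed onset to a frame or two.

## Protein structure networks

Three interaction classes are detected geometrically per frame: salt
bridges (SB), hydrogen bonds (HB) and hydrophobic contacts (HC). In
all-atom mode the defaults are: SB — minimum distance between charged-group
atoms of oppositely charged residues (Asp/Glu carboxylates vs Lys/Arg/His
amine and guanidinium nitrogens) ≤ 4.5 Å, with histidine treated as
protonatable-positive by default since simulation protocols typically
assign its protonation at physiological pH; HB — donor–acceptor heavy-atom
distance ≤ 3.5 Å, plus a D–H···A angle ≥ 120° when hydrogens are present;
HC — distance between side-chain heavy-atom centres ≤ 5.0 Å for residues
in {Ala, Val, Leu, Ile, Met, Phe, Trp, Pro}. These are the published
defaults of the interaction-analysis tools in common use and every cutoff
is configurable. Residue-centre mode applies the per-class cutoff to
representative points (Cα, or the residue centroid) with the same identity
rules, and is the natural mode for coarse-grained models. Pairs fewer than
2 positions apart in sequence are excluded in all classes, removing
trivially covalent-adjacent contacts.

*Persistence* is the exact fraction of production-run frames in which a
pair satisfies its class constraints. The per-class persistence threshold
$p_{crit}$ is set by the largest-hydrophobic-cluster criterion: scan
thresholds from 0 to 1 in steps of 0.02, record the size of the largest
connected component of the HC graph at each threshold, and take the
threshold at the largest single-step drop of that size. Ties resolve to
the smallest qualifying threshold, for determinism; if the size never
drops inside the scan (a degenerate system whose contacts all persist
equally), the final boundary 1.0 is returned. Systems with no hydrophobic
contacts at all must supply an explicit threshold — the criterion is
simply undefined there, and the pipeline then falls back to 0.5.

The merged network keeps class-edges with persistence at or above their
class threshold. Node degree counts *distinct interacting partners* by
default: a pair linked by both an SB and an HB contributes one, not two,
which keeps degrees comparable across residues with different chemistry;
per-class counting is available by flag. Hubs are residues whose degree
strictly exceeds `k_min` in at least one analysed system (strict, so a
degree exactly at the threshold is not a hub), and
$\Delta\mathrm{Degree}_i = k_i^{\mathrm{open}} - k_i^{\mathrm{closed}}$
compares open and closed networks, with absent residues counted at degree
0. Inter-domain tables list cross-domain records whose persistence
strictly exceeds the class threshold, sorted by persistence.

## The synthetic hinge generator

The generator emulates the geometry of a three-domain hinge protein at
desk scale: domains are rigid shells of pseudo-Cα beads on a Fibonacci
sphere (deterministic, no randomness before noise), flanking-domain
centres sit at `arm_length` from the central domain with the programmed
hinge angle between the arms, and linkers are straight bead chains
re-anchored each frame. The hinge path is closed until
`transition_frame`, ramps linearly over 10% of the frames to
`theta_closed + park_fraction (theta_open − theta_closed)`, and parks.
Isotropic i.i.d. Gaussian noise of `noise_sigma` per coordinate is added
to every bead, giving closed-form expectations (e.g.
$\mathrm{RMSF} \to \sqrt3\,\sigma$) against which recovery is tested. All
stochasticity flows from one integer seed through a single stream, so
equal parameters give bit-identical trajectories.

Default conditions were chosen once to resemble a mid-size three-domain
protein at equilibrium: 40 beads per domain on 8 Å shells, 25 Å arms,
hinge 60° (closed) to 110° (open), 6-residue linkers, 0.3 Å noise, 400
frames at 0.1 ns/frame. Bead identities alternate Leu/Ser inside domains
(providing a hydrophobic scaffold so the HC network and the
largest-cluster criterion are exercised) with Gly linkers.

Designed contacts emulate closed-state-only salt bridges between domains
I and III: the named residue pair is assigned Asp/Lys identities, sits on
the two domain surfaces facing each other, and while the hinge angle is
at or below `theta_contact` (default θ_closed + 5°) the two beads are
pulled symmetrically to 3.5 Å separation. The enforcement is a small
(≈3 Å) perturbation of two beads, so it leaves the global geometry
essentially untouched; it does mean that in contact-bearing fixtures the
contact beads are not rigid members of their shells, and the centre of
geometry of a 40-bead domain shifts by a few tenths of an Ångström.
Tests that assert exact hinge-angle recovery or per-domain rigidity
therefore use contact-free parameters, and contact-bearing fixtures are
used where the contacts themselves are the point (persistence,
inter-domain tables, state calls).

What the generator does *not* emulate: force-field energetics, solvent,
side-chain chemistry beyond residue identity, anisotropic or correlated
fluctuations, and realistic linker dynamics. Passing the recovery tests
therefore demonstrates that the analysis stages measure what they claim
on data with known answers — not that any particular biological system
behaves this way.

## The pipeline

`run_pipeline()` runs the stages in a fixed order per system:
equilibration first (on the whole-protein RMSD), then every later
statistic on production frames only; then per-domain RMSD, RMSF, $R_g$,
I–III distance and I–II–III angle, $\Delta\sigma$ with the state call,
interaction persistence, $p_{crit}$, the merged PSN, hubs at each
requested `k_min`, ΔDegree between the systems labelled open and closed,
and the inter-domain I–III table. A failing stage is recorded in the
report's error log with its system and stage name, and independent stages
continue. No stage is stochastic, so rerunning a configuration produces
byte-identical outputs — the test suite checks this at the file level.

Outputs are CSV per metric series (`time_ns,value` with a metadata comment
line), JSON summaries, and GraphML for the networks. The thin command-line
wrapper in `inst/cli/mdhinge-run.R` exposes `run` plus per-stage
subcommands over the same functions.

## Numerical choices and limitations

- Arc-cosine arguments are clamped to $[-1, 1]$; angle range is
  $[0°, 180°]$.
- Collinearity in superposition is declared when the second singular
  value falls below $10^{-8}$ of the first.
- Persistence ratios are exact frame-count divisions stored as doubles.
- The equilibration estimator assumes the metric is stationary after
  equilibration; oscillatory series with period comparable to the window
  can fail the mean-consistency check and report later equilibration than
  an eye would.
- Multi-model PDB is the only trajectory format; binary formats (DCD/XTC)
  would enter as adapters producing the same trajectory object, and PDB's
  fixed-point format limits coordinate round-trips to $10^{-3}$ Å.
- Problem sizes in the tests (up to 5000 frames × 72 atoms, and a
  three-system pipeline of 400-frame trajectories) were chosen so the
  whole suite exercises every stage at statistically meaningful sizes on
  a single CPU.
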