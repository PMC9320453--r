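# mdhinge

Comparative molecular-dynamics trajectory analysis for multi-domain hinge
proteins.

Many ribosome-assembly factors and other multi-domain proteins function by
swinging rigid domains about flexible linkers, interconverting between a
"closed" and an "open" arrangement. Point mutations far from any binding
site can shift the balance between these conformations and thereby break
function. `mdhinge` implements the standard battery of observables used to
characterise such behaviour across a panel of simulated systems
(wild-type and mutants, started from closed and open conformers):

- **Stability**: per-frame RMSD (whole protein and per domain, each domain
  fitted independently), per-residue RMSF about the trajectory-average
  structure, and a sliding-window equilibration-point estimate that
  separates the equilibration transient from the production run.
- **Domain-motion geometry**: mass-weighted radius of gyration
  `Rg(t) = sqrt((1/M) Σ m_i |r_i − R|²)`, inter-domain centre-of-mass
  distances over Cα atoms, and the I–II–III hinge angle
  `θ = arccos(BA·BC / |BA||BC|)` between centres of geometry.
- **Conformational progress**: the ΔRMSD variable
  `Δσ(t) = σ_closed(t) − σ_open(t)`, where each σ is an independently
  superposition-fitted RMSD to a closed or open reference structure;
  negative values are closed-like, positive open-like, near-zero
  intermediate. Frames and systems are classified accordingly, and
  transition onsets detected.
- **Protein structure networks**: per-frame geometric detection of salt
  bridges, hydrogen bonds and hydrophobic contacts; interaction
  *persistence* (the fraction of production frames in which a contact's
  constraints hold); a per-class persistence threshold chosen by the
  largest-hydrophobic-cluster criterion; the merged residue network with
  hubs (degree `k` strictly above a threshold in at least one system),
  per-residue ΔDegree = k_open − k_closed, and inter-domain interaction
  tables.
- **Synthetic ground truth**: a coarse-grained three-domain hinge-protein
  generator (rigid bead-shell domains, straight linkers, programmable
  hinge angle θ(t) with closed→open transitions, Gaussian thermal noise,
  and designed domain I–III contacts that exist only while the hinge is
  closed), so every analysis stage can be validated without
  production-scale trajectories.

All superpositions use an SVD-based Kabsch fit restricted to proper
rotations (det = +1), so chirality is never inverted.

## Worked example

```r
library(mdhinge)

# synthetic three-domain system: hinge closed at 60 deg, opening to 110 deg
# at frame 200, 0.3 A thermal noise
p <- hinge_params(theta_closed = 60, theta_open = 110, n_frames = 400,
                  noise_sigma = 0.3, transition_frame = 200, seed = 23)
gen  <- generate_trajectory(p)
refs <- generate_references(p)
dset <- hinge_domain_set(p)

ang <- hinge_angle(domain_centers(gen$trajectory, dset, "cog"), "I", "II", "III")
round(c(closed = mean(ang$values[1:199]), open = mean(ang$values[241:400])), 2)
#> closed   open
#>  59.99 109.98

d <- delta_rmsd(gen$trajectory, refs$closed, refs$open)
detect_transition(d)
#> [1] 200
classify_state(d, production_start = 241)$system_label
#> [1] "open"
```

The per-phase hinge-angle means recover the programmed 60° and 110° to a
hundredth of a degree, the ΔRMSD series pinpoints the programmed
transition frame exactly, and the production run is classified as open.
`run_pipeline()` chains all stages over a set of systems described in a
YAML config and writes CSV/JSON/GraphML outputs; see
`vignette` source `vignettes/mdhinge-methods.Rmd` for the full model
description and `inst/cli/mdhinge-run.R` for the command-line wrapper.

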