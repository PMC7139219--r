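---
title: "LipoCG: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LipoCG: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LipoCG)
```

# Scope

LipoCG prepares coarse-grained (CG) lipoprotein systems for molecular
dynamics and analyses the ensembles such simulations produce. It covers the
four maturation states of a bacterial lipoprotein (SP, SP + Di, Di, Tri),
the CG parameters of the lipid-modified cysteine, membrane and
umbrella-sampling protocol specification, contact and deformation analysis,
WHAM free-energy estimation, and the thermodynamic cycle of Lol-pathway
transfer. It never executes an MD engine; all simulation-scale results
enter the package as trajectories or window samples.

# Sequence model

Lipoproteins are recognised by the lipobox `[LVI][ASTVI][GAS][C]`, whose
cysteine (the +1 residue relative to the signal-peptidase cleavage site)
receives the lipid. `scanLipobox` reports **every** matching 4-residue
window, overlapping ones included, in sequence order; a biological
precursor has one annotated site, so `selectLipoboxMatch` prefers the match
whose signal-peptide length falls in the physiological 15--40 band and
otherwise takes the first. Nonstandard residue codes (X, U, B, ...) are
rejected with the offending position rather than coerced: downstream tether
building needs defined per-residue geometry. All residue numbering is
1-based, matching PDB author numbering, because models are cross-referenced
against deposited structures.

# Tether geometry

The experimentally resolved core is reoriented so the backbone beads of its
first two residues lie on the z-axis with the N terminus below the core
centroid — the pose from which the tether extends toward the membrane. The
transform is rigid (rotation of determinant +1 plus translation); internal
geometry is preserved to better than 1e-6 Å and the operation is
idempotent. Two degenerate inputs error: fewer than two residues, and
coincident first/second backbone positions (no definable axis).

For SP-bearing states the signal peptide is built as an ideal α-helix from
residue 1 to the lipobox cysteine: 1.5 Å rise and 100° twist per residue
with a 2.3 Å Cα radius, axis along z. These are the textbook values for an
ideal α-helix; the source protocol specifies only "a helix", so the
canonical parameters were fixed here as a design choice.

Missing linker residues between the cysteine and the first resolved core
residue are modelled as disordered, with the cysteine placed
`n × 3.5 Å` below the core start (3.5 Å of unstructured chain per residue;
with zero missing residues a single 3.5 Å peptide-unit spacing is used).
The intervening beads start on the straight path with seeded uniform
lateral jitter (±1.5 Å) and relax by an iterative push-apart scheme:
non-bonded backbone pairs are forced ≥ 3.0 Å apart, consecutive residues
are pulled back under a 4.2 Å reach with a 0.6 damping factor to avoid
oscillation, and if a straight corridor is blocked by the core the
placement restarts with a laterally bowed initial path (amplitude growing
by 0.9 Å per attempt, direction rotating by 45°, up to 25 attempts). The
construction is deterministic given the seed. Any clash-free conformer
satisfying the endpoint rule is accepted: the linkers are disordered in
solution, so no single conformation is privileged, and the subsequent
simulation equilibrates them anyway. The span check errors when
`n × 3.5 Å` exceeds the reach of `n + 1` segments of 4.2 Å. Models whose
linker exceeds 35 residues are still built but carry a warning — beyond
that length a modelled tether dominates the structure and the result should
be treated as qualitative.

Tether residues are CG-ready: one backbone bead per residue plus side-chain
beads from a per-residue template count (0 for Gly/Ala up to 4 for Trp),
placed on short radial offsets. Atomistic tether detail is explicitly out
of scope. Chain breaks inside the core are tolerated; the tether attaches
to the first resolved residue of the first chain only.

# Cysteine lipidation topologies

Diacylcysteine is produced by grafting the glycerol and both acyl tails of
a phospholipid template onto the cysteine side-chain bead — mirroring the
enzymatic transfer of the sn-1,2-diacylglyceryl group from
phosphatidylglycerol — and triacylcysteine by bonding a linear palmitoyl
fragment to the cysteine backbone bead (the N-acylation). The templates are
**data, not code**: annotated itp files (Martini 2.2 and Martini 3
dialects) ship in `inst/extdata/` with a `role=` tag per bead (backbone,
sidechain, headgroup, phosphate, glycerol, tail), and the graft keeps
glycerol + tail beads, discards headgroup + phosphate beads, and preserves
every bonded term among retained beads verbatim. Bonded parameters for the
two new cross-fragment bonds are not printed in the source text; they
default to the template's analogous bonds (phosphate–glycerol for the
side-chain graft, glycerol–tail for the backbone graft) and should be
compared against published supplementary parameter files when exactness
matters. Virtual-site variants of these parameters are out of scope.

Elastic networks restrain all backbone-bead pairs within 0.7 nm. The force
constant defaults to 500 kJ mol⁻¹ nm⁻², the conventional Martini
elastic-network value, and is user-configurable since the source protocol
cites its ENM reference without printing the constant. Tether residues are
excluded from the network so the modelled linker stays unstructured and
dynamic — the source asserts the disorder but does not state the exclusion
explicitly; it is recorded here as a design decision.

# System specification

Leaflet compositions are mole-fraction lists validated to sum to 1; integer
lipid counts use largest-remainder rounding, which conserves leaflet totals
exactly and is deterministic. Species with an area-per-lipid override (LPS
at 1.7 nm²) are counted as `floor(area / areaPerLipid)`. Run-parameter
defaults: 20 fs timestep, 323 K production temperature (310 K for umbrella
sampling), 1 bar, 1.0 / 12.0 ps coupling times, 1.1 nm nonbonded cutoffs,
neighbour updates every 20 steps, 0.15 M NaCl. The mdp writer emits
key = value lines; lipid coordinate packing belongs to external bilayer
builders.

Umbrella windows are planned on a 0.1 nm ladder along the pulled
z-separation: each target takes the trace frame nearest to it, ties going
to the earlier frame, and a target with no frame within half a spacing is a
hard error naming the gap. Window counts outside the conventional 50--80
band only warn — they are legitimate for short or long pulls. Restraint
triangles for carrier proteins pick the three lowest-RMSF backbone beads in
the base region (default: the 20% of beads with lowest z) whose triangle
area exceeds 1 Å²; "low mobility" is operationalised as positional RMSF
over a supplied equilibration trajectory, since the source names the
property but not the measure. Whether membrane-only umbrella systems used
any protein restraint is not stated; none is applied by default.

# Contact analysis

A contact is counted per frame between a residue and a lipid bead class
(GL0, NH3, PO4, GL1:2, Tail) for every bead of that class within 6 Å of
any particle of the residue, under minimum-image distances in the
orthorhombic box; counts accumulate over frames. Replicate reproducibility
is the Pearson correlation of per-residue total-contact vectors (the
footprint a binding mode leaves), with a class-resolved option;
zero-variance profiles yield missing values, never zero. Binding modes are
single-linkage groups of replicates with pairwise r ≥ 0.5, labelled by
descending population with ties broken by lowest replicate index — the
source separates primary and secondary orientations qualitatively without
stating its procedure, so this rule is a declared substitute, configurable
via the threshold.

Membrane deformation maps bin phosphates on a 2 Å xy grid and accumulate
per-leaflet mean |z| relative to the instantaneous membrane center. The
center is the **median** phosphate z of the frame: a mean is dragged
toward a strongly deformed leaflet, biasing the very extremum being
measured. Leaflets split by the sign of z about the center; never-visited
bins are NA (not zero), and bins where phosphates persistently sit within
2 Å of the center are flagged as ambiguous. The summary reports the
maximum center-to-phosphate distance and a bulk thickness (sum of the two
leaflet medians over bins beyond a stated radius from the protein).

# WHAM

The estimator solves the standard self-consistency equations on shared
histograms (default: one bin per 0.02 nm over the sampled range), entirely
in log space, anchoring the first window's offset as the gauge. Iteration
stops when the offsets move by less than 1e-6 kJ/mol (conventional WHAM
practice; the tolerance is not stated in the source) and errors out at 1e5
iterations with the last residual. Adjacent-window histogram overlap below
1e-6 aborts the estimate before iteration: disconnected support cannot be
stitched. The profile is anchored at zero at its minimum, and the free
energy is formed from the unnormalised log-probabilities so that a single
unbiased window reproduces direct Boltzmann inversion of its histogram
bit-for-bit. kT uses the window temperature with the Boltzmann constant in
kJ mol⁻¹ K⁻¹ (0.0083144621).

Errors are Bayesian bootstrap over whole windows: each replicate reweights
windows by unit-mean Dirichlet(1, ..., 1) weights, re-solves WHAM, and the
per-bin standard deviation across replicates is the error. 200 replicates
by default (the source does not state its count); replicates where the
estimator fails are dropped and the failure rate reported. No
autocorrelation correction is applied to the raw sample counts — the
source does not mention one — with the whole-window bootstrap absorbing
trajectory-level correlation.

Convergence is assessed by re-estimating the profile on consecutive time
fractions of every window and reporting the maximum pairwise per-bin
deviation after re-anchoring, restricted to bins within the planned window
range (tail bins beyond the outermost centers hold a handful of transient
samples and carry no signal). Extraction free energies are the mean profile
value over a stated plateau region; a plateau spread above 5 kJ/mol
attaches a warning, and profiles are used as computed — no symmetrisation
or truncation.

# Transfer thermodynamics

With extraction free energies ΔG(IM), ΔG(LolA), ΔG(LolB), ΔG(OM) — each
the cost of moving the cysteine-lipid moiety from that environment into
water — the steps are pairwise differences (donor minus acceptor), positive
steps costing the cell energy, and the net cost equals
ΔG(IM) − ΔG(OM) as an exact identity. Per-step errors combine per-profile
bootstrap errors in quadrature. The ATP feasibility check compares the
uphill first step against n × |ΔG(ATP)| over the physiological per-ATP
range 31.55--46.5 kJ/mol (two ATP by default, the stoichiometry of the
IM ABC transporter), flagging values feasible only at part of the range as
marginal.

# Synthetic generators: what they do and do not show

The fixtures encode exactly the statistical or geometric structure each
analysis assumes, with a known ground truth and full determinism under a
seed:

* `makeToyStructure` — a compact three-helix bundle with a planted lipobox
  and a configurable number of unresolved linker residues. The remaining
  letters are drawn from an alphabet that cannot form a lipobox, so the
  planted site is provably the only match.
* `makeMembraneTrajectory` — dedicated contact beads at 5 Å from their
  residue with every other bead beyond 14 Å, so the ±0.3 Å frame jitter can
  never flip a count and the requested per-frame contact table is exact.
* `makeUmbrellaSamples` — exact independent draws from each window's biased
  Boltzmann density by rejection against a mode-matched Gaussian envelope
  (support truncated at ±6 bias standard deviations, where the density is
  negligible; an acceptance rate below the floor errors with advice to
  tighten the envelope). Exact sampling was chosen over Markov-chain
  sampling so estimator tests are free of autocorrelation confounds.
  Potentials: harmonic, quartic double well, and a bounded extraction well
  `D (1 − exp(−αξ))²` whose plateau models the water phase.
* `makeDeformedMembrane` — phosphate sheets on prescribed height fields
  plus Gaussian noise.

Passing tests on these fixtures demonstrate that the estimators recover
what they are defined to recover; they do **not** show that Martini
energetics, lipid diffusion or sampling convergence of real trajectories
are adequate. Absolute extraction free energies of real systems
(~115/50/62/112 kJ/mol for the triacyl moiety and 101/53/55/95 kJ/mol for
the diacyl, and deformation extrema of ~42 Å against a 22 Å bulk) require
microsecond-scale CG simulations on a cluster; the package reproduces such
values only when given trajectories or window samples carrying them, and
the acceptance script demonstrates exactly that by encoding the well depths
as generator ground truth and re-estimating them through the full WHAM
pipeline.

# Problem sizes

The test suite runs WHAM references at 1e5 samples per window (31 harmonic
and 17 double-well windows) where the <1 kJ/mol recovery claim is asserted,
and smaller sizes (2e3--4e4) for property checks; the acceptance script
uses 1e5 samples per window for the analytic references and 2e4 per window
for the eight extraction wells, 33 windows each. These sizes were chosen so
statistical noise sits an order of magnitude below every asserted
tolerance.

# Known limitations

* The linker construction is geometric; it optimises no physical energy
  beyond clash avoidance and makes no claim about conformer populations.
* Template topologies are representative Martini-style parameter sets for
  the grafting machinery; for production simulations the bonded terms of
  the two graft bonds should be checked against published parameter files.
* Binding-mode classification depends on the declared r ≥ 0.5 single-linkage
  rule; other clusterings of the same correlation matrices are defensible.
* The contact definition counts lipid beads within the cutoff once per
  residue per frame; residence times and kinetics are out of scope.
* WHAM assumes equal temperatures across windows and harmonic biases;
  MBAR-style estimators and umbrella integration are deliberately not
  provided.
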