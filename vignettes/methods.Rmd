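---
title: "Kinetic and flux-regression modeling of beta-cell insulin secretion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic and flux-regression modeling of beta-cell insulin secretion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betaGSIS)
```

# The model

betaGSIS implements a compartmental kinetic model of central carbon
metabolism in the insulin-secreting pancreatic beta cell (the INS1 832/13
cell line is the reference system), together with the statistical machinery
that turns it into a calibrated, interrogable pipeline. The network couples
glycolysis, the pentose phosphate pathway (PPP), the TCA cycle with
glutaminolysis and the malate–aspartate/citrate shuttles, the polyol
pathway, and a lumped electron transport chain (ETC) across a cytosolic and
a mitochondrial compartment (relative volumes 3:1, a configuration key) plus
an extracellular medium. The state vector has 56 compartment-qualified
dynamic species; 65 enzyme-catalyzed reactions connect them. Five boundary
species (extracellular glucose, glutamine, lactate and fructose, and
inorganic phosphate) are clamped by the stimulation protocol.

Each metabolite obeys one ODE,

$$\frac{dC_i}{dt} \;=\; \frac{V_\mathrm{ref}}{V_{c(i)}}\sum_j S_{ij}\, v_j(C,\theta),$$

with $S$ the integer stoichiometric matrix, $v_j$ the reaction rates
(mM/min, referenced to the cytosolic volume $V_\mathrm{ref}$) and
$V_{c(i)}$ the relative volume of species $i$'s compartment; the volume
scaling is what makes *amounts* balance when material crosses the 3:1
compartment boundary. Rate laws come from a small template family
(irreversible Michaelis–Menten with one or two substrates, reversible
uni–uni and generalized bi–bi forms with a saturating
convenience-kinetics denominator, symmetric facilitated transport, mass
action, and ETC complexes as saturable irreversible steps driven by a
modifier). Optional terms — product inhibition constants, dead-end-complex
constants ($K_{ia}, K_{ib}, K_{iq}$), a Hill exponent on glucokinase, and
saturating activator / non-competitive inhibitor modifiers (AMP and citrate
on PFK1, FBP on pyruvate kinase, acetyl-CoA on pyruvate carboxylase,
respiratory control of the ETC) — bring the inventory to 385 kinetic
parameters, of which 96 are maximal velocities (65 forward, 31 reverse; the
six facilitated transporters are symmetric carriers with a single velocity).

The exact per-reaction equations live in the model-definition document
(`betacell_definition()`), a JSON file with sections `compartments`,
`species`, `reactions` and `parameters` that round-trips through
`read_model_definition()`/`write_model_definition()`. The code supplies the
templates; the document is the single source of structural truth and can be
swapped wholesale.

```{r}
model <- betacell_model()
model
validate_mass_balance(model)
```

## Conserved moieties

Conservation analysis computes an integer-normalized basis of the left null
space of $S$ by exact fraction-free rational elimination, so the relations
hold to machine identity along trajectories (an SVD-based oracle is used
only in tests). The basis contains seven pools: the four cofactor pairs
NADP–NADPH, GSH–GSSG (weighted 1:2), extracellular–intracellular oxygen
and mitochondrial GDP–GTP, plus the adenine pool (ATP+ADP+AMP), the NAD(H)
pool and the cytochrome pool. The last three are forced by stoichiometry:
any species-balanced network with this reaction inventory conserves them,
so we report them rather than hide them. Closure of the oxygen pool
requires that cytochrome oxidase senses intracellular oxygen as a modifier
without consuming it stoichiometrically — a deliberate bookkeeping choice
implied by the closed o2 pair.

```{r}
sapply(conserved_moieties(model), function(r) paste(r$members, collapse = " + "))
```

## Bookkeeping choices worth knowing about

* **56 vs 58 species.** The model uses a single lumped NAD/NADH pair shared
  by both compartments, standing in for instantaneous hydrogen shuttling
  (the `dhases` reaction is the lumped dehydrogenase turnover). Splitting
  the pair per compartment gives the 58-species variant noted in the
  definition document.
* **Structural zero fluxes.** With the stated reaction inventory, several
  net fluxes vanish at any steady state: the non-oxidative PPP branch
  (tk1/ta/tk2 — there is no epimerase, so the branch is an equilibrium
  pool), oxygen transport (the pool is closed), alanine transamination and
  glutamate dehydrogenase (the mitochondrial aspartate node forces
  `got2 = aspglu`), and hence net glutamine uptake. These reactions act
  during transients — which is where the fold-change data live — but carry
  no steady flux. The PPP's oxidative outlet is PRPP synthesis followed by
  its consumption in lumped nucleotide synthesis (`prppat`).
* **Nominal parameterization.** Nominal concentrations were chosen at
  physiological scales; target fluxes were projected onto the null space of
  $S$ (so a consistent steady flux exists by construction) and each
  reaction's velocities were solved so that its rate at the nominal state
  equals its target flux, given Km values at the operating concentrations
  and a per-reaction equilibrium poise. Eleven reactions (hpi, tpi, pgam,
  eno, rpi, tk1, ta, tk2, acon, fum, sdh) are parameterized near
  equilibrium (poise 0.98, large balanced velocities): they are the
  designated structurally non-identifiable Vf/Vr pairs. Shipped initial
  conditions are the simulated basal (2.8 mM glucose) steady state.

# Simulation

The integrator is an adaptive Rosenbrock(2,3) method (the `ode15s`/`ode23s`
family of stiff solvers), implemented in C++ with a finite-difference
Jacobian refreshed every step. Defaults: relative tolerance `1e-8`,
absolute `1e-10`, output on a 1-minute grid; all are configuration keys.
Calibration loops run at `1e-5`/`1e-8` — the induced fold-change error is
below `5e-5` relative, orders of magnitude under the data noise — while
reporting runs and steady-state certificates keep the tight defaults.
Concentration excursions more negative than `-1e-9` mM force step
rejection; smaller ones are clamped to zero and counted (Michaelis–Menten
forms are undefined for negative state).

`steady_state()` certifies settling: over the final 60 minutes of the
horizon (72 h by default) the largest relative rate
$|dC_i/dt|/\max(C_i, 10^{-9})$ must stay below $10^{-6}$ per minute; the
certificate also reports $\lVert S v\rVert_\infty$ at the final state. The
criterion is ours — the source analyses state no quantitative test.

```{r, eval = FALSE}
ss <- steady_state(model, glucose = 16.7, horizon = 4320)
round(normalize_fluxes_to_glut(ss$fluxes), 1)  # glucose transport = 100
```

# Calibration

**Observables.** The emulated designs are: two hours of 2.8 mM glucose
followed by high glucose with sampling at 3/6/10/15 min (fold-changes of
the stimulated versus the basal trajectory at matched times), a 60-minute
constant-glucose comparison, and stimulations referenced to the 0-minute
state. Measured metabolites are compartment-pooled with 3:1 amount
weighting before comparison. The assembled table has 70 training
observations (high-vs-low at 3 and 10 min, the 60-min panel, vs-t0 at 6 and
15 min) and 28 validation observations (high-vs-low at 6 and 15 min);
`load_dataset()` enforces that split.

**Identifiability screen.** For each reversible reaction,
`detect_correlated_velocity_pairs()` compares the sensitivity vectors of
all training observables to Vf and to Vr (symmetric multiplicative
finite-difference probe, x1.5 up / /1.5 down). If outputs depend on the two
velocities only through their ratio the vectors are exactly anti-parallel;
pairs with $|\cos| > 0.99$ are declared correlated and re-expressed through
the equilibrium constant, $V_r = V_f/K$, which removes 11 reverse
velocities and leaves 85 free Vmax parameters. The multiplicative probe is
deliberate: an additive $\pm 50\%$ probe makes the two secants sample the
nonlinearity asymmetrically and scatters the cosine of genuinely ratio-only
reactions far below 1.

**Parameter selection.** `efast_sensitivity()` implements the extended
Fourier Amplitude Sensitivity Test with interference factor M = 4,
log-uniform ranges two decades above and below baseline, and total-order
indices; a parameter is influential when its maximal index across outputs
exceeds 0.85. Both the aggregation rule (max over outputs) and the index
type (total-order) are our choices; the selection count is data dependent.

**Objective and optimizer.** The weighted sum of squared residuals is

$$\mathrm{WSSR} = \sum_i \left(\frac{\hat y_i - y_i}{s_i\, y_i}\right)^2,$$

one concrete reading of weighting "by standard deviation and magnitude";
observations with $s_i = 0$ use the dataset's median relative sd.
`fit_pso()` minimizes it with a global-best particle swarm (time-varying
inertia 0.9 to 0.4, acceleration 1.49/1.49, swarm 50, one particle seeded at
the nominal start — none stated by the source, all configuration keys) in
log space within multiplicative bounds (default 100x above/below the start).
The decreasing inertia matters: with a constant weight the swarm converges
prematurely in the curved valleys that Vmax compensation produces, stalling
short of the optimum at fixed iteration budgets. The full protocol is 2000 iterations x 100 runs
with the best 8 parameter sets kept; desk-scale work reduces `runs` and
`iterations`. `evaluate_predictions()` scores an ensemble per observation
with a Welch two-sample t-test (model side n = ensemble size; experimental
replicate count defaults to 3, unstated in the sources) and a
sign-agreement flag relative to fold-change 1.

# Flux-to-insulin regression

`simpls_fit()` implements SIMPLS for a single response: X autoscaled, y
centered, components extracted with orthogonal scores by deflating the
cross-product vector. The flux table has one row per stimulation duration
(3/6/10/15/60 min; trapezoidal time-averaged fluxes from the glucose switch
to that time) and one column per reaction; the response is the insulin
secretion fold-change. Rows 3/15/60 train and 6/10 validate by default — a
documented discrepancy in the sources (methods text versus figure caption)
resolved in favor of the methods text, switchable via `train_times`.
Reported "weights" are standardized regression coefficients; raw SIMPLS
weight vectors are also exposed. Fit quality is R^2 on the training rows
and leave-one-out Q^2Y (`q2y_loo()`, scaling re-estimated per fold).
Variable importance in projection is

$$\mathrm{VIP}_j = \sqrt{p \, \frac{\sum_a q_a^2 (w_{ja}/\lVert w_a \rVert)^2}{\sum_a q_a^2}},$$

whose squares average to 1; VIP > 1 marks influential fluxes. Ensembles
(one PLSR per fitted parameter set) predict by arithmetic averaging. The
time-resolved variant (`timecourse_plsr()`) regresses per-minute fluxes on
insulin accrued linearly within a course,
$y_m = 1 + (\mathrm{FC}-1)\,m/T$.

Because no insulin fold-change values are printed in the sources, insulin
responses are consumed from a small user-editable table; the synthetic-data
module supplies a stand-in with known structure.

# Perturbations

`scan_vmax()` multiplies each reaction's forward and reverse velocities
together by 2 and by 1/2 (capacity changes that leave the equilibrium
position alone) and compares the stimulated steady state against the
unperturbed baseline: metabolite fold-changes (per species and pooled),
flux fold-changes, flux-direction reversals, and — given a PLSR ensemble —
the predicted insulin effect from window-averaged fluxes (60-minute window,
matching the regression's training rows). Species with |log2 FC| < 0.05
are flagged "no change" (the display cutoff is ours). A matched-timepoint
transient comparison can be built from `simulate()` output directly; the
steady-vs-steady contrast is the default because the reported perturbation
analyses describe post-stimulation behavior. Registered scenarios:
metformin = `glut` x 0.2, agrimony = `g6pd` x 5, adenylate-kinase
knockdown = `ak` x 0.2.

With the shipped nominal parameterization, metformin lowers intracellular
glucose while downstream glycolytic intermediates (1,3-BPG, 3PG, 2PG, PEP)
accumulate, and agrimony raises NADPH (and, through glutathione reductase,
GSH) while leaving glycolysis and the TCA cycle essentially unchanged —
the directional behaviors the study design probes.

# Synthetic data: what it emulates, and what a green test establishes

`simulate_study()` generates the training/validation table by simulating
the three designs under a known ground-truth parameter set and overlaying
multiplicative log-normal noise: each observation is the mean of
`replicates` (default 3, typical of metabolomics practice) draws
`noiseless * exp(eps)`, `eps ~ N(0, log(1+cv))` with `cv = 0.15` by
default, with the replicate sample sd in the `sd` column. Fold-changes are
ratio-scaled and positive, hence the multiplicative error model (the
sources state none). The insulin response is affine in three designated
reaction fluxes with recorded coefficients — the pipeline under test never
sees them.

Two recovery experiments give the pipeline a known answer:

* **Parameter recovery.** With noiseless data and the ground truth differing
  from the start only in the free Vmax parameters, one PSO run (swarm 30,
  300 iterations) recovers all five free velocities of the reduced fixture
  to well under 20% relative error. The truth must lie inside the fitted
  model class for this to be meaningful — resampling all velocities while
  fitting five tests robustness, not recovery.
* **Driver recovery.** `vip_recovery()` checks that the three designated
  insulin drivers take the top three VIP ranks. Its flux table is drawn
  with *independent* per-column log-normal variation around the model's
  predicted flux magnitudes. This is deliberate: fluxes simulated from the
  kinetic model cannot serve here, because steady-state fluxes along an
  unbranched chain are exactly proportional and window-averaged transient
  fluxes remain >0.97 correlated — attributing importance to one member of
  a chain is structurally ill-posed, and no VIP computation can resolve it.
  A green driver-recovery test therefore establishes that the SIMPLS/VIP
  machinery ranks genuine drivers correctly when the design allows it; it
  does not establish that reaction-level attribution is identifiable from a
  single stimulation time course (it is not).

The generator does not emulate mass-spectrometry peak-level artifacts
(drift, batch effects, missingness), islet multicellularity, or fatty-acid
pathways.

# Numerical choices and degenerate inputs

* Exact rational arithmetic for conservation; integer stoichiometries are
  validated at build time, unresolved references fail with the offending id.
* Fold-changes with reference below `1e-9` mM are flagged undefined, never
  thrown.
* Zero-variance flux columns (structurally zero fluxes produce them) are
  dropped from PLSR with a warning and carry zero coefficients and NA VIP.
* PSO penalizes failed objective evaluations with a large finite value;
  per-scenario failures in perturbation scans are recorded and skipped.
* Every stochastic step (LHS, PSO, noise, eFAST phases) is a pure function
  of an integer seed; the pipeline derives per-stage streams from one
  global seed.

# Known limitations

Single-cell, two-compartment, deterministic; insulin enters only through
the regression layer (no channel electrophysiology); glutaminolysis is
transient-only under the stated reaction inventory; the published fitted
parameter values and digitized datasets are not shipped, so quantities that
depend on them (e.g. the published R^2/Q^2Y of the insulin regression, or
the published eFAST selection count) are replaced by the property-based
checks above and recomputable only given those inputs.
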