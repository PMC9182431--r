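---
title: "Coarse-grained SOP mechanics of AAA+ unfoldase action"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained SOP mechanics of AAA+ unfoldase action}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sopmech)
```

## The model

`sopmech` implements the self-organized polymer (SOP) model: one bead per
residue at the C-alpha position, with a total potential

$$V_T = V_\mathrm{FENE} + V_\mathrm{NB}^\mathrm{ATT} + V_\mathrm{NB}^\mathrm{REP}.$$

The backbone is a chain of finite-extensible nonlinear elastic bonds,

$$V_\mathrm{FENE}(r) = -\tfrac{k}{2} R_0^2
  \ln\!\left[1 - \frac{(r - r_0)^2}{R_0^2}\right],$$

with $k = 20$ kcal/(mol Å$^2$) and $R_0 = 2$ Å: the bond energy is zero at
the native length $r_0$ and diverges as $|r - r_0| \to R_0$, so bonds never
break. Native contacts — residue pairs within the cutoff (13 Å for lattice
systems) in the native structure, with intra-chain sequence separation
$|i - j| \ge 3$ and no separation rule between chains — attract through a
full Lennard-Jones term with minimum $-\varepsilon_h$ at the native pair
distance. All other pairs repel via
$\varepsilon_l (\sigma / r)^6$, including the $i,i+2$ term with a single
constant $\sigma$. Because the contact list is fixed at construction, a
pair is either native or repulsive, never both.

The per-interface contact strengths default to the GDP microtubule lattice
values: intra-dimer 1.9, longitudinal 1.0, lateral and seam 0.9 kcal/mol,
with ring-machine values 1.3 (intra-/inter-protomer), machine–lattice 1.0
and pore-loop/handle 1.0. The MIT-domain/lattice strength is the sweep
variable of the severing experiments (1.0–4.0 kcal/mol;
`set_mit_interaction()`). The repulsive amplitude and range are not fixed
by the interface table's provenance, so we adopt the standard SOP
convention $\varepsilon_l = 1$ kcal/mol, $\sigma = 3.8$ Å, both exposed in
`interaction_table()`.

## Dynamics and numerics

Dynamics are overdamped Brownian (Ermak–McCammon): each bead moves by
$\Delta \mathbf r = \mathbf F \, h / \zeta_\mathrm{eff} + \boldsymbol\xi$
with $\langle \xi_\alpha^2 \rangle = 2 k_B T h / \zeta_\mathrm{eff}$. The
friction constant is quoted in the field as the dimensionless
$\zeta = 50$; we close the units as
$\zeta_\mathrm{eff} = \zeta \times 1\,$kcal mol$^{-1}$ ps Å$^{-2}$
(configurable via `zeta_unit`). Under this closure the traditional nominal
step of 40 ps is far too large for the stiff FENE term
($k\,\Delta t/\zeta_\mathrm{eff} = 16$), so the integrator subdivides each
nominal step into `n_sub` Euler–Maruyama substeps (default 40, i.e. a 1 ps
substep, $k h/\zeta_\mathrm{eff} = 0.4$). The nominal 40 ps step remains
the bookkeeping unit: the time axis, and the cantilever speed
$v_f = \Delta x / (n_\mathrm{av}\,\Delta t)$, which with the default
$\Delta x = 8\times10^{-4}$ Å per 1000 steps gives 2 μm/s. Absolute time
scales in this class of models are nominal; only relative rates matter.
Two further numerical guards: the deterministic drift of a substep is
capped at `max_disp` (0.5 Å) so a large transient force cannot push a bond
through the FENE singularity in one step (thermal noise is never capped —
capping it would violate fluctuation–dissipation, which we verify by the
equipartition test `var = k_BT/k_\mathrm{trap}`), and repulsive pairs
beyond $3\sigma$ are skipped (error $<10^{-3}$ kcal/mol per pair).
`kBT` defaults to 0.6 kcal/mol (~300 K); the temperature of the
coarse-grained system is not otherwise specified.

The cantilever is an isotropic 3-D spring ($k_\mathrm{trans} = 0.025$
kcal/(mol Å$^2$)) between the pulled bead and an anchor that advances by
$\Delta x$ along the pulling direction every $n_\mathrm{av}$ steps; the
recorded trace force is the component along the pulling direction, which
makes the fixed-bead loading ramp exactly
$k_\mathrm{trans} N \Delta x$ after $N$ updates.

## The pore-cycle protocol

The repetitive-force translocation protocol retains the allosteric cycle's
*logic* at C-alpha resolution while the ring itself is static: comparisons
of allosteric and non-allosteric pore models in this family show the
salient unfolding and translocation features survive that simplification,
and the cycle timing is what the protocol needs. Each cycle of
$\tau = 120$ ps comprises two hemicycles of six sequential protomer
transitions (the first protomer uniformly random, then clockwise ring
order), which with the 10 Å loop excursion gives the effective loop speed
$10/(120/12) = 1$ Å/ps. Whether $\tau$ spans one hemicycle or the full
cycle is ambiguous in the source description; the 12-transition reading
reproduces the stated 1 Å/ps and is adopted (both $\tau$ and the
transition count are protocol fields). During the open→close hemicycle a
total force drawn from $\mathcal N(\bar F, \sigma_F)$ (truncated at zero;
the truncated mass is negligible at the stated parameters) is shared
equally by the substrate beads inside the pore window
$|z - \langle z_\mathrm{loop}\rangle| < 5$ Å, selected at cycle start.
"Backbone heavy atoms" maps to C-alpha beads at this resolution; with ~20
beads in the window the per-bead force is $\bar F/20$, i.e. 35, 20, 20 and
30 pN for the four standard presets (700/50, 400/20, 400/20, 600/20 pN).
Since 120 ps is not an integer multiple of the 40 ps nominal step, the
translocation runner derives its substep as
$(\tau/2) / \lceil \tau/(2\,\Delta t)\rceil$ so hemicycles tile exactly.
The machine–substrate interaction is purely repulsive by default;
pore-loop grip contacts (class `protomer_e15`) can be enabled in the
configuration.

## Synthetic systems: what they emulate and what they do not

Real inputs are C-alpha PDB structures (`read_calpha_pdb()`, with a TSV
sidecar carrying subunit/domain annotations that standard PDB columns
cannot hold). The generators produce desk-scale stand-ins that reproduce
*interface connectivity*, not real geometry:

* `make_toy_lattice()` — protofilament rows of alpha/beta dimers, each
  monomer a compact zig-zag cluster and its own chain, beta monomers with
  a tail bead (the pulled handle). Longitudinal and lateral spacings are
  comparable (4.2 Å gaps along a protofilament, 8 Å between rows) so that
  the interaction table, not geometry, sets interface strength; rows wrap
  onto a cylinder from five protofilaments up, where the wrap interface
  can be declared the seam. Tubulin's internal monomer geometry is not
  reproducible from published coarse-grained descriptions and is not
  attempted.
* `make_toy_hexamer()` — six protomers around an exactly six-fold
  symmetric pore (one `pore_loop` bead each at the pore radius), with
  optional linker + three-bead MIT arms; only the arms receive the seeded
  jitter so pore symmetry is exact.
* `make_toy_globule()` — a planar beta-sheet analogue (strands 4.8 Å
  apart, beads 3.8 Å apart) with a pulling tail. A single serpentine
  bonded path connects the strands; truly parallel strand connectivity
  would need extra turn beads, so the `sheet_parallel` option instead
  staggers alternate strands by half a bead spacing (a registry change
  only). The tail-carrying terminal strand is selectable: strand 1 gives
  an edge terminal (native contacts with one neighbouring strand), an
  interior index a core terminal (two neighbours), the minimal analogue of
  wild-type versus circular-permutant terminals. The core-terminal variant
  has one long serpentine connection; its FENE bond is centred at the
  native length, which the bond table supports.

Every generator is deterministic given its seed (a small uniform jitter
breaks exact degeneracies). Passing tests on these systems demonstrates
the machinery — topology construction, energetics, protocols,
observables — not agreement with tubulin or DHFR structure.

## Observables

`fraction_native_contacts()` implements
$Q_N = N_C^{-1} \sum \theta(\eta - |r_{ij} - r_{ij}^0|)$ with $\eta = 2$ Å
(the Heaviside convention counts $|r - r^0| \le \eta$ as formed), with
class and subunit filters for the longitudinal/lateral severing split.
`fraction_nonnative()` counts currently formed non-native pairs within
6 Å against $N_C$. Rupture detection smooths the force trace by a moving
average (default 50 frames) and takes local maxima followed by a drop of
at least `min_drop` (default 50 pN); FBF is the first event, CBF the
smoothed global maximum; these two defaults are not fixed by the protocol
definitions and are config-exposed. The fragment census builds a graph
over subunits (edge = at least one inter-subunit contact within the same
2 Å tolerance as $Q_N$, one consistent "formed" criterion package-wide)
and igraph components give the fragment table, the dimers-lost pathway
label and the ring-oligomer decomposition. Orientation angles use the
gyration-tensor principal axis with deterministic sign and axis semantics
(folded to [0°, 90°]; `fold = FALSE` keeps [0°, 180°] for regimes where
orientations beyond 90° are meaningful). Near-degenerate inertia
eigenvalues make the principal axis ill-conditioned — the exactly
symmetric toy hexamer is the worst case — so orientation analyses should
use asymmetric selections; ties break by largest eigenvalue with a fixed
ordering. Translocation metrics follow the cis = $z<0$ convention with
$z_\mathrm{trans} = 12$ Å and $z_\mathrm{lumen} = -8$ Å: $x(t)$ the
translocated fraction, $I(t)$ the translocation line (non-decreasing
ratchet convention by default; transient back-crossings otherwise make
the line non-monotone), $w(I)$ the per-residue residence time at
$z \ge z_\mathrm{lumen}$ before translocation. Free-energy landscapes are
$-k_BT \ln P$ on a 2-D histogram with empty bins reported as `NA` (never
an infinite sentinel that could contaminate minima) and the global minimum
shifted to zero.

## Experiment presets and problem sizes

`toy_severing_config()` reproduces the severing setup shape at desk scale:
a 3×3-dimer lattice, lumen-side beads of both end dimers fixed, a
cantilever pull perpendicular to the sheet on a central beta-monomer tail.
The anchor step is scaled up (default 1000× the 2 μm/s reference) so that
rupture completes within a few thousand nominal steps; with three beads
per monomer a trajectory takes a few seconds. At these conditions the
pulled subunit's lateral interfaces (0.9 kcal/mol) fail before its
intra-dimer interface (1.9 kcal/mol) — the weaker-interface-first ordering
that drives protofilament severing — and the census labels the lost
fragments.

`toy_translocation_config()` probes terminal anisotropy: the toy globule
threaded through the hexamer pore. Three choices matter and were made
once, on mechanistic grounds. First, the pore radius is 4.5 Å: a wide pore
admits the *folded* sheet and the terminal's contact burden never becomes
rate-limiting. Second, the tail is threaded to $z = +6$ so several beads
sit in the force window each cycle; with a barely-inserted tail a single
backslide empties the window permanently (the machine has no grip by
default, so an empty window is absorbing). Third, the sheet strength is
1.5 kcal/mol and the mean force 90 pN: chain tension then lies between the
one-rung (~60 pN) and two-rung (~120 pN) rupture scales, the window in
which an edge terminal (one contact ladder) extracts measurably faster
than a core terminal (two ladders). The discriminating observable is the
extraction time of the terminal strand (`detachment_time()`); the
time-averaged translocated fraction orders the same way but with much
larger trajectory-to-trajectory spread. Far above the two-rung scale both
variants strip the terminal strand within a few cycles and translocation
becomes threading-limited, erasing the contrast — the anisotropy is a
property of the *unfolding* step, not of transport.

Default trajectory counts are three per setup (overridable), and
aggregates always carry counts alongside percentages because n is tiny.
Test and acceptance runs use 2–8 seeds per property, lattices of 63–81
beads, 150–200 pore cycles and $10^3$–$10^4$ nominal pulling steps —
sizes chosen so a full check of every property completes in minutes on
one core while each individual property remains comfortably resolved.

## Paper-scale use

The same machinery runs on real C-alpha structures: read the assembly
with `read_calpha_pdb()` (chain map and sidecar supply subunit/domain
annotations, e.g. pore-loop residues named in a configuration rather than
hard-coded, since residue numbering varies across PDB dialects), build
the topology at the 13 Å cutoff, and use the cantilever protocol at
2 μm/s. Full-scale breaking-force reproduction requires the homology-built
machine and multi-million-step runs and is deliberately outside the test
suite; the package documents it as optional validation.

## Known limitations

* Absolute time scales are nominal (friction units are a convention).
* The static ring omits allosteric grip; translocation is force-driven.
* Toy geometry reproduces interface connectivity only; numbers measured
  on toy systems are not predictions for tubulin or DHFR.
* The heavy-atom 6 Å contact rule for globular substrates is replaced by
  a C-alpha surrogate cutoff (6 Å), a free parameter of globule analyses.
* Hydrodynamic interactions, electrostatics and solvent models are out of
  scope, as is any atomistic energetics.

## A worked desk-scale example

```{r, eval = FALSE}
lat <- make_toy_lattice(n_pf = 3, n_dimers = 3, beads_per_monomer = 3)
topo <- build_native_contacts(lat, interaction_table())
cfg <- toy_severing_config(beads_per_monomer = 3, n_trajectories = 3,
                           seed = 1)
sev <- run_experiment(cfg)
sev$aggregate
pathway_census(sev)
autoplot(sev$runs[[1]])
```
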