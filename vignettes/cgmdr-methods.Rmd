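---
title: "Residue-level coarse-grained models in cgmdr: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-level coarse-grained models in cgmdr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmdr)
```

# The models

`cgmdr` implements residue-level coarse-grained (CG) representations of
biomolecules: one bead per amino acid centred on the C-alpha atom, and three
beads per nucleotide (phosphate P, sugar S, base B), each bead standing for
roughly ten heavy atoms.  The energy functions are assembled from a small
set of basic terms:

* **Bonds** — harmonic $k(b-b_0)^2$ or quadratic-plus-quartic
  $k_2(b-b_0)^2 + k_3(b-b_0)^4$ (the DNA backbone form).
* **Angles** — harmonic $k_a(\theta-\theta_0)^2$ or tabulated
  statistics-derived terms $-k_BT\,\ln P_a(\theta)/\sin\theta$, evaluated
  through C$^1$ cubic splines.
* **Dihedrals** — periodic $\sum_n k_n[1+\cos n(\phi-\phi_0)]$, Gaussian
  $-\epsilon_\phi\exp(-\Delta\phi^2/2\sigma_\phi^2)$, or tabulated
  Boltzmann-inversion terms $-k_BT\,\ln P_d(\phi)$.
* **Pairs** — Go-type 12–10 native contacts
  $\epsilon[5(\sigma/r)^{12}-6(\sigma/r)^{10}]$, plain 12-6 LJ, excluded
  volume as either the LJ form truncated at its minimum or the single
  12th-power repulsion $\epsilon(\sigma/r)^{12} - 2^{-12}\epsilon$ cut at
  $2\sigma$, Gaussian wells, and the repulsive/attractive split of the
  Morse potential about its minimum.
* **Screened electrostatics** — Debye–Hückel
  $K_C q_1 q_2 e^{-r/\lambda_D}/(\epsilon_r r)$ with
  $\epsilon_r = e(T)\,a(C)$ from empirical temperature and salt
  polynomials and $\lambda_D = \sqrt{k_BT\epsilon_0\epsilon_r /
  (2N_A e_c^2 I)}$.
* **Orientation gates** — the modulating function $f(\Delta\theta)$, equal
  to 1 inside $|\Delta\theta|<\gamma$, decaying as
  $1-\cos^2(\pi\Delta\theta/2\gamma)$ up to $2\gamma$, zero beyond; C$^1$ at
  both joins.

Five model families combine these terms:

* **Structure-based protein model** (`aicg2+` in
  `generate_model_topology()`): harmonic bonds, tabulated angles, 1–3
  Gaussian distance terms, Gaussian plus tabulated dihedrals, Go contacts
  between residues whose heavy atoms approach within a cutoff in the native
  structure, and 12th-power excluded volume between non-native pairs with
  the radius combination rule $\sigma = (\varsigma_1+\varsigma_2)/2$.
  Designated flexible tails receive only the local statistical terms and
  take part in no contacts.
* **Hydropathy-scale models** (`hps`, `kh`): harmonic bonds along the
  chain; all nonbonded interactions through the Ashbaugh–Hatch form, which
  keeps the full repulsive LJ core and scales the attractive branch by a
  per-residue hydropathy $\lambda$, plus screened electrostatics on charged
  residues.  A one-bead-per-nucleotide RNA variant uses the same
  functional form with larger beads.
* **Three-site DNA** (`3spn2c`): quartic bonds, harmonic angles, Gaussian
  plus periodic backbone dihedrals, and three multi-body base terms —
  stacking $E_{rep} + f(\Delta\theta_{BS})E_{attr}$ over intra-strand
  steps, Watson–Crick pairing $E_{rep} + \tfrac12(1+\cos\Delta\phi)
  f(\Delta\theta_1)f(\Delta\theta_2)E_{attr}$, and cross stacking
  $f(\Delta\theta_3)f(\Delta\theta_{CS})E_{attr}$ — with phosphate charges
  for the electrostics.
* **Structure-based RNA** (`rna_struct`): harmonic bonds/angles, periodic
  dihedrals, Go contacts, excluded volume and optional phosphate
  electrostatics.
* **Protein–DNA recognition**: PWM-weighted Gaussian wells
  $E_G(r)\,f(\Delta\theta_1)f(\Delta\theta_2)f(\Delta\theta_3)$ between
  DNA-binding C-alphas and candidate bases, with the well depth
  $\epsilon = \gamma(e_{PWM,m}(b)/N_m + \epsilon')$, and a
  sequence-nonspecific backbone hydrogen-bond variant anchored on
  phosphates with two gates.

# Geometry conventions for the multi-body terms

The literature defines the gating angles of the DNA and protein–DNA terms
through specific site constellations; implementations differ in detail.
`cgmdr` encodes one documented geometry map directly in the site records,
so it is data, not code:

* stacking angle: sugar–base–base (S$_i$–B$_i$–B$_{i+1}$);
* pairing: $\theta_1$ = S$_i$–B$_i$–B$_j$, $\theta_2$ = B$_i$–B$_j$–S$_j$,
  $\phi$ = S$_i$–B$_i$–B$_j$–S$_j$;
* cross stacking: the analogous angles with the partner's strand
  neighbours as anchors;
* PWM recognition: $\theta_1$ = S$_i$–B$_i$–C$\alpha_j$, $\theta_2$ =
  B$_i$–C$\alpha_j$–C$\alpha_{j-1}$, $\theta_3$ = B$_{i-1}$–B$_i$–C$\alpha_j$
  (so strand-terminal bases without a 5$'$ neighbour are not candidates);
* backbone hydrogen bonds: $\theta_1$ = S$_i$–P$_i$–C$\alpha_j$,
  $\theta_2$ = P$_i$–C$\alpha_j$–C$\alpha_{j'}$.

Because every reference value is measured from the same native structure by
the same conventions, the native frame is an exact minimum of each gated
term regardless of the convention chosen; users can substitute different
anchor particles record by record.

For each candidate (base, site) pair the PWM term sums the contribution of
the base read on its own strand and on the complementary strand.  Since
the well depth is linear in the PWM score, this is folded into one
effective per-base depth per record.

# Parameters, defaults and units

The unit system is Angstrom, femtosecond, amu and kcal/mol;
$k_B = 1.987204\times10^{-3}$ kcal/mol/K, the Coulomb constant
332.0637 kcal Å/(mol e$^2$), and the acceleration conversion
$4.184\times10^{-4}$ (Å/fs$^2$ per kcal/mol/Å/amu), centralised in
`cg_constants()`.

Default nonbonded cutoffs (Å), with pair-list distances 5 Å larger:
electrostatics 52/57 (the screened interaction of unit charges falls below
$10^{-4}$ kcal/mol there at 300 K and 150 mM — verified by
`debye_huckel()`), hydropathy pairs 39/44 (from the $|E| = 10^{-4}\epsilon$
criterion, $r_C \simeq 5.848\,\sigma$ by `lj_cutoff_ratio()`, applied to
the largest residue diameter), base pairing 18/23, recognition and
hydrogen-bond sites $r_0+5$ with a 23 Å list, excluded volume cutoff
built into the form ($2\sigma$) with a 15 Å list.  Ionic strength defaults
to the salt molarity (1:1 salt).

Parameter data ship as plain-text files under `inst/extdata/` with
documented schemas so that users can substitute their own calibrations:

* `hps_params.tsv` — per-residue mass, charge, diameter, hydropathy and
  well depth (published hydropathy-scale values for amino acids;
  representative values for the one-bead RNA rows).  The pairwise KH
  energy matrix is external calibration data; with the packaged tables the
  `kh` model evaluates the same per-residue form as `hps`.
* `aicg2p_params.tsv` — uniform fallback constants for the structure-based
  protein model (bond constant, 1–3 Gaussian depth/width, dihedral depth,
  contact energy, contact cutoff 6.5 Å — the conventional Go-model
  choice).  The published residue-specific contact calibration can be
  injected per record.
* `spn2c_params.tsv` — DNA constants (quartic bond, angle and dihedral
  constants, Morse depths/widths for stack/pair/cross-stack, gate widths,
  site radii and masses).  Representative values in the published model's
  ranges.
* `base_step.tsv` — dinucleotide twist/roll/tilt/shift/slide/rise used by
  the sequence-to-structure builder.
* `flex_*_synthetic.tsv` — *synthetic* statistics-derived angle/dihedral
  tables with a generic bimodal shape; the published residue-pair-specific
  tables are supplementary data of their original papers and can be
  dropped in with the same two-column schema.

Bead masses are the summed heavy-atom masses of the mapped group, and
nucleic beads sit at their group's centre of mass; the 5$'$-terminal
nucleotide carries no phosphate, so an $n$-nucleotide strand maps to
$3n-1$ beads.

# The sequence-to-structure DNA builder

`build_dsdna_from_sequence()` composes base-pair frames step by step:
frame $i+1$ is frame $i$ rotated by
$R_z(\text{twist})R_y(\text{roll})R_x(\text{tilt})$ and displaced by
(shift, slide, rise) in the local frame, with the six parameters looked up
per dinucleotide.  Within each frame one pseudo-atom per CG site is placed
from a fixed template with B-DNA-like radii (P at 8.9 Å, S at 6.9 Å, B at
3.2 Å from the axis), and the second strand is generated by the dyad
symmetry $(x, y, z) \to (x, -y, -z)$ with the complementary base.  The
pseudo-atoms carry full-group masses, so the subsequent CG mapping gets
correct bead masses; this synthetic atomistic model is intended for CG
work, not as an all-atom reconstruction.  With a homogeneous table (pure
twist and rise) the composition is an exact circular helix, which the test
suite checks against the closed form.

# Neighbor lists

Every nonbonded term keeps its own neighbor list built by a cell-linked
list: particles belonging to a term (for example, only charged particles
for electrostatics — in a three-site DNA system only the phosphates, about
a third of the beads) are binned into cells, and each term scans only the
neighboring cells whose *minimum inter-cell distance* is below its
pair-list distance.  Short-range terms therefore touch far fewer cells
than the electrostatic term.  Lists are rebuilt every 20 steps; energies
are independent of the rebuild cadence as long as no particle moves
further than half the pair-list margin between rebuilds.  Periodic boxes
must be at least three times the largest active pair-list distance along
every axis — enforced at configuration and at run time — because the
minimum-image convention with cached lists is only safe in that regime.
Non-periodic systems grid their instantaneous bounding box with a margin
cell and use no images.

The R-level `build_grid()`/`build_pairs()` expose the grid for inspection
and testing; the compiled engine runs the same algorithm internally, and
both are checked against an all-pairs $O(N^2)$ oracle in the test suite.

# Dynamics

Langevin dynamics are integrated with velocity Verlet in
half-kick/drift/half-kick form, algebraically equivalent to the two-line
update $v(t) = v(t-\Delta t) + \Delta t\,[F(t)+F(t-\Delta t)]/2m$,
$r(t+\Delta t) = r(t) + \Delta t\,v(t) + \Delta t^2 F(t)/2m$.  The total
force adds $-m\gamma v$ friction (evaluated with the velocity available at
each kick, a semi-implicit choice that reduces exactly to symplectic,
time-reversible Verlet at $\gamma = 0$) and Gaussian noise with variance
$2\gamma k_B T/(m\,\Delta t)$ per component.

The noise is *counter-based*: the draw for (seed, step, particle slot) is a
pure function of its key, so trajectories are bit-identical regardless of
evaluation order, chunking or worker count, and a chunked continuation run
reproduces a single run exactly (the acceleration is recomputed from the
full-step velocity at each step start for this reason).  The default time
step is 10 fs.  The friction default, 0.001 fs$^{-1}$ (1 ps$^{-1}$), is a
*free parameter of the thermostat*, not a property of the models: it sets
how strongly the heat bath couples, and published CG studies use anything
from 0.1 to 10 ps$^{-1}$.  Initial velocities are Maxwell–Boltzmann draws
at the run temperature unless supplied.  The first step's "previous force"
is the freshly evaluated initial force, i.e. the integrator starts from a
consistent state rather than a zero-filled history.

CG dynamics with implicit solvent have no literal time-scale mapping: the
10 fs step counts integration steps, while the effective physical time per
step is system-dependent and must be calibrated against experiment.

# What the synthetic generators emulate — and what they do not

`make_fixture()` builds every test system in code:

* `helix_ca` — an ideal C-alpha helix (2.3 Å radius, 100° twist, rise
  chosen so consecutive beads are exactly 3.8 Å apart) with one outward
  pseudo side-chain atom per residue, giving contact detection a non-trivial
  heavy-atom structure.
* `idp_chain` — disordered chains with a glycine/serine/glutamine/tyrosine
  rich low-complexity composition emulating the prion-like domains studied
  in phase-separation work, as self-avoiding random walks with 3.8 Å
  bonds.  This is a *synthetic* sequence: the specific natural sequences
  used in published condensation studies are supplementary data of those
  papers.
* `toy_dsdna` — sequence-built duplexes (poly-CG by default).
* `multi_chain_slab` — replicates a chain into an elongated periodic box
  at random positions/orientations without inter-chain contacts below a
  tolerance, the standard starting state of the slab coexistence method.

Passing tests on these fixtures show that the machinery — mapping, term
assembly, neighbor lists, integration, observables — is correct.  They do
not show that the packaged parameter values reproduce experimental phase
diagrams or binding specificity for natural sequences; that requires the
published calibrations and validation against experiment.

# Numerical choices

* Tabulated terms use natural cubic splines (periodic closure for
  dihedrals); the engine stores a densely resampled value/derivative table
  and interpolates each segment with the cubic Hermite polynomial, which
  is C$^1$, exact at the nodes, and makes energy and force come from the
  same polynomial so finite-difference consistency is machine-precision.
  Out-of-domain angle queries clamp to the boundary value with zero force
  and are counted, never fatal mid-run.
* Dihedral forces switch to a safe fallback (finite forces, term energy
  kept) when the sine squared of either bending angle drops below
  $10^{-6}$; angle-gradient factors of the multi-body terms do the same,
  keeping the energy and dropping only the undefined gradient component.
* The angle-difference wrap maps $\Delta\phi$ into $(-\pi, \pi]$ before
  any periodic or Gaussian dihedral evaluation.
* Excluded-volume and pair kernels are evaluated in $r^2$ form without
  square roots; the shift $-2^{-12}\epsilon$ makes the 12th-power form
  continuous (zero) at its $2\sigma$ cutoff.
* Ties in the DNA-binding-position observable break to the lower base-pair
  index; cluster analysis uses single-linkage over chains with an 8 Å
  linking distance.
* Contact detection runs through the same cell-list core as the neighbor
  lists and is deterministic and order-independent; the intra-chain
  exclusion window is $|i-j| \ge 4$ in residue numbering, the standard
  Go-model convention.

# Problem sizes used by the tests

The test suite sizes its simulations so the whole battery stays
desk-scale: force/energy consistency on 15–60-particle fixtures;
neighbor-list oracles on 150–180 particles; an NVE conservation run of
$10^4$ steps (drift measured as the secular linear trend of the conserved
energy — the instantaneous fluctuation amplitude depends on the random
initial mode energies); a $10^5$-step equipartition run of 50 free
particles; and a condensation check of 20 chains of 163 residues
(3260 beads) in a 180 × 180 × 333 Å slab.  That box keeps the particle
density of the full-size 120-chain setup (one sixth the chains in one
sixth the volume) while respecting the three-pair-list-distances box rule,
which an isotropic shrink would violate.  The condensation run uses a
20 Å hydropathy cutoff (pair list 23 Å) — the truncated tail is below
$10^{-3}$ kcal/mol per pair — and stops early once the largest
single-linkage cluster holds more than 80% of the chains; three seeds are
required to pass.

# Known limitations

* The KH variant currently evaluates the per-residue hydropathy form; the
  pairwise contact-energy matrix it was calibrated with is external data
  (supply it by extending the parameter schema).
* The packaged flexible-term tables and several DNA constants are
  synthetic/representative placeholders, clearly labelled; quantitative
  work on natural systems should substitute the published calibrations.
* Only orthorhombic periodic boxes and minimum-image electrostatics are
  supported; no Ewald/PME, no pressure coupling, no enhanced sampling.
* Base pairing is evaluated over the built (native) pairing records, so
  strand melting and re-hybridisation with non-native partners are outside
  the current scope.
* The generic nonbonded terms treat all particles as one population per
  term; per-molecule term masking beyond the model tags is not yet
  exposed.
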