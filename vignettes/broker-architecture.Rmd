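---
title: "Brokering fold-tree kinematics: model, design choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brokering fold-tree kinematics: model, design choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`foldbroker` treats a polypeptide as a set of internal coordinates — per
residue the backbone torsions phi, psi, omega (degrees), bond lengths
(Å) and planar angles (degrees) over the four backbone atoms N, CA, C,
O — plus a set of *jumps*, rigid transforms (rotation + translation)
between the local frames of two residues. Cartesian coordinates are not
state; they are derived by traversing the *fold tree*, a directed, rooted,
acyclic graph whose edges are either peptide stretches (folded N→C or
C→N) or numbered jumps. The tree exists to make coordinate propagation
unambiguous: perturbing a torsion moves exactly the atoms downstream of
its pivot, and the absence of cycles guarantees a single propagation path
to every atom. Because a jump sets the relative geometry of its two
residues directly, that geometry is invariant under any torsion change
elsewhere — this "pinning" is what lets a β-strand pairing or a docking
partner's pose survive aggressive backbone sampling. Every jump through a
bonded region obliges one *cut*, a deliberately broken peptide adjacency,
which must be repaired (here by cyclic coordinate descent) before a model
is physically meaningful.

The broker sits between sampling modules and these resources. Clients
assert *claims*; the broker expands them to atomic *elements* in three
ordered phases — sequence changes (virtual residues), fold-tree topology
(jumps and cuts), then DoF accessibility — because later phases reference
entities created by earlier ones (a jump cannot be expressed before both
its anchor residues exist). Access is resolved per scalar DoF by the
four-level control-strength matrix; a jump contributes six independent
scalars (rb1–rb3 translation in Å, rb4–rb6 rotation-vector components in
radians). After broking, the conformation is wrapped so that modification
requires the granting passport on top of an unlock stack; only the top is
consulted, one lookup per modification, and reads pass through freely. A
DoF granted to no client is frozen for the whole trajectory — this is what
turns a rigid chunk's "set and forget" into a guarantee rather than a
convention.

## Geometry and numerical choices

* Ideal backbone constants: N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å,
  C=O 1.231 Å; angles N–CA–C 111.2°, CA–C–N 116.2°, C–N–CA 121.7°,
  CA–C–O 121.0°; omega defaults to 180°. Any self-consistent set would do
  — all tests are internal — these are standard idealized values.
  Measured (non-ideal) geometry is carried per residue, so a structure
  loaded from PDB refolds to its input coordinates at file precision.
* Stub frame: origin at CA, x toward C, y in the N–CA–C plane on the N
  side. Jumps compose as `stub(downstream) = stub(upstream) ∘ T`. The
  frame convention is arbitrary but must be fixed; this one is the
  simplest orthonormalization of the three stub atoms.
* The carbonyl O is placed at dihedral `psi + 180° + o_offset`, where
  `o_offset` (default 0) is measured when importing coordinates. Without
  the offset term, PDB round-trips would lose the O atoms' sub-millidegree
  deviations from planarity and fail the 10⁻³ Å round-trip bound.
* Torsions are degrees at every API boundary; radians exist only inside
  trigonometric kernels. Rotation vectors (rb4–rb6) are radians, matching
  the axis-angle convention of the rotation library functions.
* Degenerate inputs fail loudly: collinear atom triples in dihedral or
  placement computations, zero-length axes, non-orthonormal rotations, and
  chainbreak queries at positions that are not cuts are all errors, not
  silent fallbacks.
* `set_dof` refreshes the whole Cartesian cache by re-traversal. Upstream
  atoms are recomputed from unchanged inputs and are therefore
  bit-identical, which is what the locality and atomicity tests assert.
  Batch writes (`set_dofs`, `protected_set_dofs`) assign all values first
  and traverse once; this is the fast path for fragment insertion.

## Broker design decisions

* **Cut accounting.** Chain boundaries and deliberate cuts are recorded
  uniformly: a cut at *i* means the i→i+1 adjacency carries no peptide
  edge. A valid tree then satisfies the exact graph identity
  `#cuts == #jumps` (connected + acyclic on n vertices). On a single
  chain this coincides with "cuts = jumps"; when claimed jumps leave
  segments disconnected the broker adds connecting jumps itself, one per
  leftover segment, which also restores the familiar
  "cuts = claimed jumps + segments − 1" count.
* **Order independence.** Broking output must not depend on the order in
  which clients were registered. Two mechanisms provide this: jumps are
  numbered canonically (sorted by anchor pair, claimed before
  auto-connecting), and every client draws its claim-time randomness (e.g.
  strand-pair anchor choice) from a stream seeded by the broking seed and
  the *client's name*, not its registration position. Cut draws happen in
  canonical jump order from a separate stream. Virtual residues are the
  documented exception: they are appended in claim order, so order
  independence is stated (and tested) for protocols without
  virtual-residue claims.
* **Merged jumps.** Jump claims resolving to the same anchor pair merge
  into one jump element; both claims' DoF elements attach to the shared
  jump number. This is how a docking client and the CoM star client
  address the same root→CoM jump without knowing about each other.
* **>2 claimants** resolve pairwise: any EXCLUSIVE beside another
  EXCLUSIVE or a MUST fails; one EXCLUSIVE demotes all CAN claimants;
  within one client, multiple claims on a DoF collapse to the strongest.
  The six rb components of one jump may be granted to different clients;
  nothing in the enforcement layer requires them to travel together
  (setting a whole transform requires all six).
* **Cut preferences.** A jump claim may prefer a cut interval (used by the
  loop-closure client to keep the cut inside its loop); the preference is
  honored when it intersects the legal positions and silently ignored
  otherwise, whereas *forbidden* intervals are hard and exhaust into a
  named error listing the cycle interval and the forbidding claims.

## Clients

* **Rigid chunk:** EXCLUSIVE torsion claims over its region, cut-forbid
  claims inside each contiguous segment, and — for discontinuous regions —
  an EXCLUSIVE fixed-geometry jump between segment midpoints whose
  transform is measured from the template at initialization. Template
  values are written once inside the client's own unlock during a
  post-broking initialize pass; exclusivity then makes re-sampling
  impossible rather than merely absent.
* **Fragment insertion:** CAN_CONTROL over the union of its windows
  (3–9 residues); each apply picks a fragment uniformly and writes its
  whole window in one batch, or rejects *before any write* when the window
  overlaps an ungranted DoF. Atomicity is therefore structural, not
  rollback-based (though every apply also carries a snapshot guard).
* **Strand pairing jumps:** only two residues can be pinned per strand
  pair, so each pairing lists candidate anchor pairs and one is drawn per
  trajectory; across many trajectories the ensemble covers the candidate
  space (tested at 4σ over 600 trajectories). Applies draw a stub-to-stub
  transform uniformly from a library. The shipped library is a small
  synthetic set of idealized antiparallel/parallel pair geometries
  (4.8–5.2 Å spacing, half-turn flips); it stands in for transforms
  harvested from crystal structures and is labelled synthetic throughout.
  The pinned frames are the N–CA–C stubs of the paired residues.
* **CoM star / docking:** one root virtual residue (the tree root) plus a
  CoM virtual per chain, jumps root→CoM and CoM→chain-midpoint. The
  tracking update moves the CoM virtual to the chain's unweighted backbone
  mean and recomputes *both* incident jumps so the composed transform to
  the chain anchor is unchanged — real atoms move by strictly less than
  1e-9 Å (measured ~1e-13, pure floating-point noise), and the update is
  idempotent. Masses are not used; the invariant being demonstrated does
  not depend on weighting.
* **CCD loop closure:** pivots are the granted phi/psi torsions in the
  loop that rigidly move exactly one side of the break (the fold tree
  itself excludes the three torsions parameterizing the broken bond:
  their downstream sets are empty at the cut). Each pivot gets the
  closed-form optimal rotation superposing the ideal continuation triplet
  onto the actual downstream N/CA/C; the update is applied as ±θ*,
  keeping whichever lowers the squared gap, which makes the step immune to
  dihedral sign-convention mistakes across forward/backward folding at the
  cost of two extra refreshes per pivot. Convergence is declared at a
  chainbreak distance gap below `tol` (default 0.05 Å, a loose
  "repairable" threshold, not a chemical claim); `max_iter` defaults to
  100 sweeps.

## The Monte Carlo driver and toy score

The protocol, not the broker, decides when and how often clients move:
per cycle one client is drawn by weight, its apply is scored, and the
move is accepted by the Metropolis criterion at temperature kT (score
units; default 1.0, optional multiplicative annealing). Rejected moves
restore the conformation bit-exactly by snapshot. Each output model
re-brokers from scratch, so cut placement and strand-anchor choices are
re-randomized per model while the tree stays frozen within a model. The
score is deliberately a toy: a soft CA–CA clash term Σ(4−d)² below 4 Å
(excluding sequence neighbours), a chainbreak term summing squared
distance and angle gaps over cuts, and an optional harmonic CA-pair
term. It exists to drive acceptance decisions in demonstrations, carries
arbitrary units, and makes no physical claim.

## What the fixtures emulate — and what they do not

The three generated fixtures reproduce the *constraint topology* of three
protocol archetypes: (1) single-chain folding with a rigid 17–40 template
chunk, self-harvested 3–9-mer fragments and two candidate strand pairings;
(2) domain insertion, with a discontinuous host (1–20, 51–70) pinned by a
fixed jump and cuts confined to the insert (21–50); (3) three-chain
docking (chains H, L, C) through a CoM star with two CCD-closed loops in
chain H. They are ideal-geometry toys: torsion presets instead of real
secondary structure, no side chains, no physical energies, synthetic
strand-pair transforms. Passing tests therefore demonstrate the
architectural guarantees — consensus-tree validity, access enforcement,
pin invariance, per-model randomization, order independence — on
realistic *topologies*, and say nothing about predictive accuracy on real
proteins.

## Problem sizes and statistical tests

The suite validates 1,000 randomized resolvable claim sets on chains of
20–100 residues; jump-pin drift over 100 random 30-mers × 100 torsion
moves (bound 1e-9, observed ~1e-13); a 500-cycle trajectory for the
chunk guarantee (bound 1e-12, observed 0); 1,000 fuzzed unauthorized
modifications; and cut-placement uniformity over 1,000 brokered models.
Because strand anchors are redrawn per trajectory, the marginal cut
distribution is a mixture of uniforms over anchor-dependent intervals;
the uniformity test is therefore stratified by (jump, chosen anchor) —
chi-square statistics and degrees of freedom summed across strata — which
tests exactly the "uniform over the legal positions of this cycle"
hypothesis. The acceptance script scales two of these down (500 fuzz sets,
600 uniformity seeds, 30 pin conformations × 50 moves) to keep a single
run inside a few minutes; the testthat suite runs the full sizes.

## Known limitations

Pure R at toy scale: a coordinate refresh re-traverses the whole tree
(no incremental update), fine for ≤100 residues and thousands of cycles,
not for Rosetta-scale systems. Residue-level fold trees only (no
atom-level trees), backbone atoms only, no side-chain kinematics or
minimization, no re-broking mid-trajectory, no nested brokers, and
unlocks are not thread-safe. The rotation-vector jump parameterization is
singular near 180° rotations; the decomposition handles the near-π case
explicitly but sampling that neighbourhood with per-component rb moves is
not recommended — docking clients compose full transforms instead.
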