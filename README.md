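# foldbroker

Combining several sources of prior knowledge in one conformational-sampling
protocol — fragment torsions here, a rigid template region there, a couple
of β-strand pairings, rigid-body docking between chains — is easy to state
and hard to wire up. In internal-coordinate modeling, every constraint has
opinions about the *fold tree*: the directed, rooted, acyclic graph over
residues that decides how a torsion change propagates into Cartesian space,
where *jumps* (direct rigid-body edges between distant residues) go, and
where the compensating *cuts* in the peptide chain fall. One hard-coded tree
cannot serve every combination, and letting each sampling module keep its
own tree means no module's constraints are enforced while another is
moving.

`foldbroker` implements a claim-based broker over fold-tree kinematics for
people prototyping such combined protocols at desk scale. Each sampling
module ("client mover") states its requirements as formalized **claims** —
torsion access, a jump between two anchors, forbidden cut regions, virtual
residues — each carrying a **control strength** (`DOES_NOT_CONTROL` <
`CAN_CONTROL` < `MUST_CONTROL` < `EXCLUSIVE`). The broker expands claims to
per-DoF elements in ordered phases (sequence changes, fold-tree topology,
DoF accessibility), builds a single **consensus fold tree** satisfying all
of them — or fails before sampling starts, naming the two movers and the
DoF that conflict — and issues each client a **passport**. Sampling then
runs against a **protected conformation**: a DoF modification succeeds only
if the passport on top of the active unlock stack grants that DoF, so an
exclusive region is not merely agreed to be fixed, it is impossible to
move.

Access resolution for two claimants of one DoF follows a fixed matrix:
`EXCLUSIVE` × (`EXCLUSIVE` | `MUST_CONTROL`) fails broking; `EXCLUSIVE` ×
`CAN_CONTROL` grants only the exclusive claimant; `DOES_NOT_CONTROL` is
never granted; every other pair grants both. More claimants resolve
pairwise, and the six rigid-body components of a jump are brokered as six
independent scalars.

The package provides, all in pure R:

- **kinematics** — internal-coordinate polypeptides (phi/psi/omega in
  degrees, ideal or measured bond geometry; backbone atoms N, CA, C, O),
  fold-tree-directed conversion to Cartesian coordinates in either folding
  direction, jumps as rigid transforms between N–CA–C stub frames,
  chainbreak measurement, Kabsch superposition;
- **foldtree** — validation, downstream-set queries, seeded random cut
  placement, text serialization;
- **broker / enforcement** — claims, elements, the control-strength matrix,
  consensus-tree construction, passports, stack-scoped unlocks;
- **clients** — fragment insertion, rigid template chunks (contiguous or
  pinned by fixed jumps), β-strand pairing jumps sampled from a transform
  library, rigid-body docking through a center-of-mass virtual-residue
  star, CCD loop closure;
- **sampling_driver** — a Metropolis Monte Carlo driver with a toy score
  (CA clash + chainbreak + pair constraints) that re-brokers per model so
  cut placement is re-randomized per model;
- **fixtures** — three generated toy protocols exercising the above; no
  external data is ever downloaded.

## Worked example

Three clients on a 76-residue toy: a rigid chunk fixing residues 17–40 to a
template, fragment insertion elsewhere, and two β-strand pairing jumps.

```r
library(foldbroker)

fx <- make_vignette1_fixture(seed = 1)
b <- broker_new()
for (cl in fx$clients) register_client(b, cl)
res <- broke(b, fx$conf, seed = 42)
cat(serialize_fold_tree(res$tree))
#> FOLD_TREE 76
#> ROOT 1
#> EDGE 1 7 -1
#> EDGE 13 8 -1
#> EDGE 13 55 -1
#> EDGE 70 56 -1
#> EDGE 70 76 -1
#> EDGE 5 13 1
#> EDGE 44 70 2
#> CUTS 7 55
```

The broker placed the two claimed strand-pair jumps (5↔13 and 44↔70 this
trajectory — the anchor pair is redrawn per trajectory), broke each cycle
with one cut drawn uniformly from the legal positions (7 and 55; never
inside the chunk, whose claim forbids cuts in 17–39), and oriented the
edges from the root. Residues 8–13 fold *backwards* from the jump landing
toward the cut. Passports reflect the matrix: the chunk client holds its
72 torsions exclusively, so the fragment client's `CAN_CONTROL` claim over
the same region was demoted:

```r
res$passports$chunk
#> <passport> chunk - 72 DoF(s) granted
res$passports$fragments
#> <passport> fragments - 132 DoF(s) granted
```

A full Monte Carlo run (two models, 500 cycles each, re-brokered per
model):

```r
proto <- protocol(fx$clients, cycles = 500, temperature = 1.0, anneal = 0.995,
                  weights = c(fragments = 3, strand_jumps = 1), n_struct = 2)
out <- run_protocol(proto, fx$conf, seed = 7)
out$scores
#>   model score_initial  score_final accepted cycles
#> 1     1  5.178488e-25 5.178488e-25      232    500
#> 2     2  5.368510e-25 5.368510e-25      219    500
identical(out$models[[1]]$phi[17:40], fx$template$phi[17:40])
#> [1] TRUE
```

The scores stay at numerical zero because this fixture's fragments are
harvested from its own native torsions — the run demonstrates the
architecture (232 of 500 trial moves accepted, chunk torsions bit-identical
to the template afterwards), not structure prediction.

## Command line

A thin CLI wraps the same functions:

```sh
inst/exec/foldbroker fixtures vignette1 --seed 1 --out demo/
inst/exec/foldbroker run demo/config.yaml --seed 1 --out demo/out --dump-foldtree
```

`fixtures` writes a start/template PDB, a fragment file (lines
`position length phi psi omega [phi psi omega ...]`), a strand-pairing
topology file (lines `PAIRING id res_i res_j A|P register`; lines sharing
an id are candidate anchor pairs, one drawn per trajectory), and a YAML
protocol config. `run` brokers and samples, writing PDB models and a
tab-separated score table.

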