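# Programmatic toy fixtures emulating the three protocol archetypes:
# (1) ab initio folding with multiscale constraints (fragments + a rigid
# template chunk + beta-strand pairing jumps on a 76-mer), (2) domain
# insertion (a discontinuous fixed host + a flexible insert), (3) multibody
# docking through a centre-of-mass star with loop closure. The fixtures
# emulate each protocol's constraint topology, not any real protein's
# structure; all inputs are generated, nothing is downloaded.

#' Idealized strand-pair transform library
#'
#' A small curated set of stub-to-stub rigid transforms representing paired
#' beta-strand geometries (antiparallel and parallel), expressed in the
#' upstream residue's stub frame. Synthetic stand-ins for transforms
#' harvested from crystal structures: adjacent-strand spacing near 4.8-5.2
#' \enc{Å}{Angstrom}, antiparallel pairs flipped by a half-turn.
#'
#' @return List of `rigid_transform`s.
#' @export
strand_pair_transforms <- function() {
  out <- list()
  flip <- rotation_about_axis(c(1, 0, 0), pi)
  for (dy in c(4.8, 5.0, 5.2)) {
    out[[length(out) + 1]] <- rigid_transform(flip, c(0.5, dy, 0))       # A
    out[[length(out) + 1]] <- rigid_transform(
      rotation_about_axis(c(0, 0, 1), deg2rad(10)) %*% flip, c(-0.5, dy, 0.3))
  }
  out[[length(out) + 1]] <- rigid_transform(diag(3), c(0.8, 4.9, 0.2))   # P
  out[[length(out) + 1]] <- rigid_transform(
    rotation_about_axis(c(0, 0, 1), deg2rad(-12)), c(0, 5.1, -0.2))
  out
}

# harvest a fragment library from a conformation's own torsions
harvest_fragments <- function(conf, positions, lengths) {
  entries <- list()
  for (k in seq_along(positions)) {
    pos <- positions[k]
    len <- lengths[k]
    rs <- seq(pos, pos + len - 1L)
    entries[[k]] <- list(position = pos, length = len,
                         torsions = cbind(conf$phi[rs], conf$psi[rs],
                                          conf$omega[rs]))
  }
  fragment_library(entries)
}

#' Ab initio fixture: fragments + rigid chunk + strand pairings
#'
#' A 76-residue single chain (helix torsions at residues 23-34, strand
#' torsions elsewhere), a rigid-chunk template for residues 17-40, a
#' fragment library of 3-9 residue windows harvested from the fixture
#' itself, and two candidate strand pairings (residues 3-15 and 44-70
#' regions) with an idealized transform library. Deterministic per seed.
#'
#' @param seed integer seed.
#' @param dir optional directory: also write PDB / fragment / topology
#'   files.
#' @return List: `conf`, `template`, `fragments`, `pairings`, `clients`,
#'   `chunk_region`, and `files` (when `dir` is given).
#' @export
make_vignette1_fixture <- function(seed = 1L, dir = NULL) {
  set.seed(derive_seed(seed, "vignette1"))
  n <- 76L
  phi <- rep(-120, n); psi <- rep(120, n)
  helix <- 23:34
  phi[helix] <- -57; psi[helix] <- -47
  conf <- build_ideal_polypeptide(n, torsion_preset = list(
    phi = phi, psi = psi, omega = rep(180, n)))
  template <- conf
  chunk_region <- 17:40
  positions <- seq(1L, 68L, by = 4L)
  lengths <- 3L + (seq_along(positions) - 1L) %% 7L
  lengths <- pmin(lengths, n - positions + 1L)
  keep <- lengths >= 3L
  fragments <- harvest_fragments(conf, positions[keep], lengths[keep])
  pairings <- strand_pairing_set(
    pairings = list(
      list(anchors = rbind(c(3L, 15L), c(4L, 14L), c(5L, 13L)),
           orientation = "A", register = 0L),
      list(anchors = rbind(c(44L, 70L), c(45L, 69L)),
           orientation = "A", register = 0L)),
    transforms = strand_pair_transforms())
  clients <- list(
    rigid_chunk_client("chunk", template, chunk_region),
    fragment_client("fragments", fragments),
    strand_jump_client("strand_jumps", pairings))
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(pdb = file.path(dir, "start.pdb"),
                  template = file.path(dir, "template.pdb"),
                  fragments = file.path(dir, "fragments.txt"),
                  topology = file.path(dir, "pairings.top"),
                  config = file.path(dir, "config.yaml"))
    write_pdb_backbone(conf, files$pdb)
    write_pdb_backbone(template, files$template)
    write_fragment_file(fragments, files$fragments)
    write_pairing_file(pairings, files$topology)
    cfg <- list(
      inputs = list(pdb = "start.pdb", template_pdb = "template.pdb",
                    fragments = "fragments.txt", topology = "pairings.top"),
      clients = list(
        list(type = "rigid_chunk", name = "chunk", region = "range(17,40)"),
        list(type = "fragment", name = "fragments"),
        list(type = "strand_jump", name = "strand_jumps")),
      schedule = list(cycles = 500L, temperature = 1.0, anneal = 0.995,
                      weights = list(fragments = 3, strand_jumps = 1)),
      score = list(clash = 1.0, chainbreak = 1.0, pair = 0.0),
      n_struct = 1L, seed = as.integer(seed))
    yaml::write_yaml(cfg, files$config)
  }
  list(conf = conf, template = template, fragments = fragments,
       pairings = pairings, clients = clients, chunk_region = chunk_region,
       files = files)
}

#' Domain-insertion fixture: discontinuous fixed host + flexible insert
#'
#' A 70-residue chain whose host domain consists of two discontinuous
#' segments (residues 1-20 and 51-70) held mutually rigid by a fixed jump
#' measured from the template, with a flexible insert (21-50) folded in
#' situ by fragment insertion and one strand-pairing jump. Cuts can only
#' fall in the insert, because the rigid chunk forbids them inside its
#' segments.
#'
#' @inheritParams make_vignette1_fixture
#' @return List: `conf`, `template`, `fragments`, `pairings`, `clients`,
#'   `host_segments`, `insert`, and `files` (when `dir` is given).
#' @export
make_vignette2_fixture <- function(seed = 1L, dir = NULL) {
  set.seed(derive_seed(seed, "vignette2"))
  n <- 70L
  phi <- rep(-120, n); psi <- rep(120, n)
  phi[5:16] <- -57; psi[5:16] <- -47     # a helix inside the host N-segment
  phi[55:66] <- -57; psi[55:66] <- -47   # and one in the C-segment
  conf <- build_ideal_polypeptide(n, torsion_preset = list(
    phi = phi, psi = psi, omega = rep(180, n)))
  template <- conf
  host <- c(1:20, 51:70)
  insert <- 21:50
  positions <- seq(21L, 46L, by = 3L)
  lengths <- pmin(3L + (seq_along(positions) - 1L) %% 5L,
                  50L - positions + 1L)
  fragments <- harvest_fragments(conf, positions, lengths)
  pairings <- strand_pairing_set(
    pairings = list(list(anchors = rbind(c(25L, 45L), c(26L, 44L)),
                         orientation = "A", register = 0L)),
    transforms = strand_pair_transforms())
  clients <- list(
    rigid_chunk_client("host_chunk", template, host),
    fragment_client("fragments", fragments),
    strand_jump_client("strand_jumps", pairings))
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(pdb = file.path(dir, "start.pdb"),
                  template = file.path(dir, "template.pdb"),
                  fragments = file.path(dir, "fragments.txt"),
                  topology = file.path(dir, "pairings.top"),
                  config = file.path(dir, "config.yaml"))
    write_pdb_backbone(conf, files$pdb)
    write_pdb_backbone(template, files$template)
    write_fragment_file(fragments, files$fragments)
    write_pairing_file(pairings, files$topology)
    cfg <- list(
      inputs = list(pdb = "start.pdb", template_pdb = "template.pdb",
                    fragments = "fragments.txt", topology = "pairings.top"),
      clients = list(
        list(type = "rigid_chunk", name = "host_chunk",
             region = "or(range(1,20),range(51,70))"),
        list(type = "fragment", name = "fragments"),
        list(type = "strand_jump", name = "strand_jumps")),
      schedule = list(cycles = 300L, temperature = 1.0, anneal = 0.995,
                      weights = list(fragments = 3, strand_jumps = 1)),
      score = list(clash = 1.0, chainbreak = 1.0, pair = 0.0),
      n_struct = 1L, seed = as.integer(seed))
    yaml::write_yaml(cfg, files$config)
  }
  list(conf = conf, template = template, fragments = fragments,
       pairings = pairings, clients = clients,
       host_segments = list(1:20, 51:70), insert = insert, files = files)
}

#' Multibody docking fixture: CoM star + docking + loop closure
#'
#' A three-chain toy complex (chains H, L, C), docked through a star of
#' centre-of-mass virtual residues: one root virtual plus one CoM virtual
#' per chain, each chain carrying a docking client on its root -> CoM jump.
#' Two loops in chain H are flexibly modeled with CCD loop closure; each
#' loop's bypass jump puts exactly one cut inside the loop.
#'
#' @inheritParams make_vignette1_fixture
#' @return List: `conf`, `clients`, `loops`, and `files` (when `dir` is
#'   given).
#' @export
make_vignette3_fixture <- function(seed = 1L, dir = NULL) {
  set.seed(derive_seed(seed, "vignette3"))
  conf <- build_ideal_polypeptide(72L, chain_spec = c(24L, 22L, 26L),
                                  torsion_preset = "helix",
                                  chain_ids = c("H", "L", "C"))
  loops <- list(c(5L, 10L), c(15L, 20L))
  clients <- c(
    list(com_star_client("com_star")),
    lapply(c("H", "L", "C"), function(ch)
      docking_client(paste0("dock_", ch), ch, rot_mag = 3, trans_mag = 0.5)),
    lapply(seq_along(loops), function(k)
      loop_close_client(paste0("loop_H", k), loops[[k]])))
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(pdb = file.path(dir, "start.pdb"),
                  config = file.path(dir, "config.yaml"))
    write_pdb_backbone(conf, files$pdb)
    cfg <- list(
      inputs = list(pdb = "start.pdb"),
      clients = c(
        list(list(type = "com_star", name = "com_star")),
        lapply(c("H", "L", "C"), function(ch)
          list(type = "docking", name = paste0("dock_", ch), chain = ch,
               rot_mag = 3, trans_mag = 0.5)),
        lapply(seq_along(loops), function(k)
          list(type = "loop_close", name = paste0("loop_H", k),
               loop = as.integer(loops[[k]])))),
      schedule = list(cycles = 200L, temperature = 1.0, anneal = 0.995,
                      weights = list(dock_H = 1, dock_L = 1, dock_C = 1,
                                     com_star = 1, loop_H1 = 1, loop_H2 = 1)),
      score = list(clash = 1.0, chainbreak = 1.0, pair = 0.0),
      n_struct = 1L, seed = as.integer(seed))
    yaml::write_yaml(cfg, files$config)
  }
  list(conf = conf, clients = clients, loops = loops, files = files)
}
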