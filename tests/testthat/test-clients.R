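test_that("rigid chunk claims: contiguous vs discontinuous regions", {
  fx <- make_vignette1_fixture(1)
  cont <- rigid_chunk_client("cont", fx$template, 17:40)
  claims <- yield_claims(cont, fx$conf)
  types <- vapply(claims, function(c) c$type, "")
  expect_equal(sum(types == "torsion"), 1)
  expect_equal(sum(types == "cut"), 1)
  expect_equal(sum(types == "jump"), 0)
  expect_equal(claims[[which(types == "torsion")]]$strength, "EXCLUSIVE")
  expect_equal(claims[[which(types == "cut")]]$forbidden, list(c(17L, 39L)))
  # two segments add exactly one fixed-geometry jump between them
  fx2 <- make_vignette2_fixture(1)
  disc <- rigid_chunk_client("disc", fx2$template, c(1:20, 51:70))
  claims2 <- yield_claims(disc, fx2$conf)
  types2 <- vapply(claims2, function(c) c$type, "")
  expect_equal(sum(types2 == "jump"), 1)
  jc <- claims2[[which(types2 == "jump")]]
  expect_true(jc$fixed_geometry)
  expect_equal(jc$strength, "EXCLUSIVE")
  # template must cover the region
  small <- build_ideal_polypeptide(10, torsion_preset = "helix")
  bad <- rigid_chunk_client("bad", small, 5:15)
  expect_error(yield_claims(bad, fx$conf), "missing residues")
})

test_that("chunk torsions survive a full MC trajectory exactly", {
  fx <- make_vignette1_fixture(1)
  proto <- protocol(fx$clients, cycles = 150, temperature = 1.0,
                    weights = c(fragments = 3, strand_jumps = 1), n_struct = 1)
  out <- run_protocol(proto, fx$conf, seed = 8)
  m <- out$models[[1]]
  for (kind in c("phi", "psi", "omega")) {
    expect_identical(m[[kind]][17:40], fx$template[[kind]][17:40])
  }
  expect_false(any(out$results[[1]]$tree$cuts %in% 17:39))
})

test_that("fragment insertion writes whole windows or nothing", {
  fx <- make_vignette1_fixture(1)
  # single 3-mer: after apply the window torsions equal the fragment
  frag <- fragment_library(list(list(
    position = 50L, length = 3L,
    torsions = matrix(c(-60, -45, 180, -65, -40, 179, -58, -47, 181),
                      nrow = 3, byrow = TRUE))))
  fc <- fragment_client("frags", frag)
  res <- broke_clients(list(fc), fx$conf, seed = 1)
  set.seed(1)
  out <- client_apply(fc, res$pconf)
  expect_true(out$moved)
  conf <- pconf_conformation(res$pconf)
  expect_equal(conf$phi[50:52], c(-60, -65, -58))
  expect_equal(conf$psi[50:52], c(-45, -40, -47))
  # a fragment overlapping an exclusive chunk is rejected with no change
  frag2 <- fragment_library(list(list(
    position = 18L, length = 4L, torsions = matrix(0, 4, 3))))
  fc2 <- fragment_client("frags", frag2)
  chunk <- rigid_chunk_client("chunk", fx$template, 17:40)
  res2 <- broke_clients(list(fc2, chunk), fx$conf, seed = 1)
  x0 <- conf_xyz(pconf_conformation(res2$pconf))
  out2 <- client_apply(fc2, res2$pconf)
  expect_false(out2$moved)
  expect_true(out2$rejected)
  expect_identical(conf_xyz(pconf_conformation(res2$pconf)), x0)
})

test_that("fragment selection is uniform over the library", {
  fx <- make_vignette1_fixture(1)
  frag <- fragment_library(list(
    list(position = 50L, length = 3L, torsions = matrix(-60, 3, 3)),
    list(position = 60L, length = 3L, torsions = matrix(120, 3, 3))))
  fc <- fragment_client("frags", frag)
  res <- broke_clients(list(fc), fx$conf, seed = 1)
  set.seed(51)
  picks <- replicate(4000, client_apply(fc, res$pconf)$position)
  n1 <- sum(picks == 50)
  sigma <- sqrt(4000 * 0.25)
  expect_lt(abs(n1 - 2000), 4 * sigma)
})

test_that("strand jumps pin pair geometry against torsion moves", {
  fx <- make_vignette1_fixture(1)
  single <- strand_pairing_set(
    pairings = list(list(anchors = rbind(c(10L, 60L)), orientation = "A",
                         register = 0L)),
    transforms = list(rigid_transform(
      foldbroker:::rotation_about_axis(c(1, 0, 0), pi), c(0.5, 4.8, 0))))
  sj <- strand_jump_client("strands", single)
  frag_all <- fragment_client("frags", fx$fragments)
  res <- broke_clients(list(sj, frag_all), fx$conf, seed = 2)
  set.seed(1)
  client_apply(sj, res$pconf)
  jno <- sj$jump_numbers[["pair_1"]]
  got <- jump_transform(pconf_conformation(res$pconf), jno)
  expect_equal(got$t, c(0.5, 4.8, 0), tolerance = 1e-9)
  # pinned geometry is untouched by torsion sampling elsewhere
  for (k in 1:10) client_apply(frag_all, res$pconf)
  got2 <- jump_transform(pconf_conformation(res$pconf), jno)
  expect_equal(got2$t, got$t, tolerance = 1e-9)
  expect_equal(got2$R, got$R, tolerance = 1e-9)
})

test_that("anchor pairs are re-drawn uniformly across trajectories", {
  fx <- make_vignette1_fixture(1)
  anchors <- rbind(c(3L, 15L), c(4L, 14L), c(5L, 13L), c(6L, 12L), c(7L, 11L))
  ps <- strand_pairing_set(
    pairings = list(list(anchors = anchors, orientation = "A", register = 0L)),
    transforms = strand_pair_transforms())
  counts <- integer(5)
  for (seed in 1:600) {
    sj <- strand_jump_client("strands", ps)
    res <- broke_clients(list(sj), fx$conf, seed = seed)
    row <- which(anchors[, 1] == sj$chosen_anchors[[1]][1])
    counts[row] <- counts[row] + 1L
  }
  sigma <- sqrt(600 * 0.2 * 0.8)
  expect_true(all(abs(counts - 120) < 4 * sigma))
})

test_that("CoM tracking re-centres virtuals without moving real atoms", {
  fx <- make_vignette3_fixture(1)
  res <- broke_clients(fx$clients[1:4], fx$conf, seed = 3)
  pconf <- res$pconf
  star <- fx$clients[[1]]
  dockers <- fx$clients[2:4]
  set.seed(61)
  worst <- 0
  for (k in 1:20) {
    client_apply(dockers[[sample.int(3, 1)]], pconf)
    before <- conf_xyz(pconf_conformation(pconf), real_only = TRUE)
    client_apply(star, pconf)
    after <- conf_xyz(pconf_conformation(pconf), real_only = TRUE)
    worst <- max(worst, max(abs(after - before)))
  }
  expect_lt(worst, 1e-9)
  # the virtual sits at the unweighted backbone mean, and updating twice
  # changes nothing
  conf <- pconf_conformation(pconf)
  vH <- virtual_residue_index(conf, "com_H")
  expect_equal(unname(conf_xyz(conf)[vH, 2, ]), chain_com(conf, "H"),
               tolerance = 1e-9)
  x1 <- conf_xyz(conf)
  client_apply(star, pconf)
  expect_lt(max(abs(conf_xyz(pconf_conformation(pconf)) - x1)), 1e-12)
})

test_that("docking moves are local to the docked partner's subtree", {
  fx <- make_vignette3_fixture(1)
  res <- broke_clients(fx$clients[1:4], fx$conf, seed = 4)
  pconf <- res$pconf
  x0 <- conf_xyz(pconf_conformation(pconf))
  # zero-magnitude perturbation: nothing moves
  zero <- docking_client("dock_C", "C", rot_mag = 0, trans_mag = 0)
  zero$passport <- res$passports$dock_C
  zero$jump_numbers <- fx$clients[[4]]$jump_numbers
  set.seed(62)
  client_apply(zero, pconf)
  expect_lt(max(abs(conf_xyz(pconf_conformation(pconf)) - x0)), 1e-10)
  # a real chain-C move leaves chains H and L bit-identical
  client_apply(fx$clients[[4]], pconf)
  x1 <- conf_xyz(pconf_conformation(pconf))
  expect_identical(x1[1:46, , ], x0[1:46, , ])
  expect_gt(max(abs(x1[47:72, , ] - x0[47:72, , ])), 1e-6)
})

test_that("dock perturbation magnitudes match their stated spreads", {
  set.seed(63)
  fx <- make_vignette3_fixture(1)
  res <- broke_clients(fx$clients[1:4], fx$conf, seed = 5)
  dock <- fx$clients[[2]]  # chain H, rot_mag 3 deg, trans_mag 0.5 A
  angles <- numeric(400)
  shifts <- matrix(0, 400, 3)
  for (k in 1:400) {
    out <- client_apply(dock, res$pconf)
    angles[k] <- out$angle
    shifts[k, ] <- out$shift
  }
  # sd of a Gaussian sample: within 4 sigma of its sampling spread
  expect_lt(abs(sd(angles) - 3), 4 * 3 / sqrt(2 * 400))
  expect_lt(abs(sd(as.vector(shifts)) - 0.5), 4 * 0.5 / sqrt(2 * 1200))
  expect_lt(abs(mean(angles)), 4 * 3 / sqrt(400))
})

test_that("CCD closes an opened loop and is a no-op when already closed", {
  fx <- make_vignette3_fixture(1)
  res <- broke_clients(fx$clients, fx$conf, seed = 6)
  pconf <- res$pconf
  lp <- fx$clients[[5]]
  cut <- res$tree$cuts[res$tree$cuts >= 5 & res$tree$cuts < 10]
  expect_length(cut, 1)
  # already closed: zero iterations, deviation untouched
  out0 <- client_apply(lp, pconf)
  expect_true(out0$converged)
  expect_equal(out0$iterations, 0L)
  # open the break with a single torsion change, then close
  with_unlock(pconf, lp$passport, function()
    protected_set_dof(pconf, dof_phi(7),
                      get_dof(pconf$conf, dof_phi(7)) + 35))
  expect_gt(chainbreak_deviation(pconf$conf, cut)$dist, 0.1)
  out <- client_apply(lp, pconf)
  expect_true(out$converged)
  expect_lte(out$iterations, 100)
  expect_lt(out$deviation$dist, 0.05)
  # CCD only ever touches granted loop torsions: outside the loop the
  # torsions still equal their start values
  conf <- pconf_conformation(pconf)
  outside <- setdiff(1:24, 5:10)
  expect_identical(conf$psi[outside], fx$conf$psi[outside])
})

test_that("a loop with no granted torsions fails at configure time", {
  fx <- make_vignette3_fixture(1)
  freezer <- scripted_client("freezer", list(torsion_claim(5:10, "EXCLUSIVE")))
  lp <- loop_close_client("loop", c(5L, 10L))
  expect_error(
    broke_clients(c(fx$clients[1:4], list(freezer, lp)), fx$conf, seed = 1),
    class = "foldbroker_config_error")
})

test_that("removing a client only stops the behaviours it owned", {
  # fragments mildly perturbed from the starting torsions: accepted often,
  # and visibly different from the start values in the final model
  helix_frags <- fragment_library(lapply(c(3L, 45L, 60L), function(p)
    list(position = p, length = 5L,
         torsions = matrix(rep(c(-123, 117, 180), each = 5), ncol = 3))))
  run_once <- function(with_fragments) {
    fx <- make_vignette1_fixture(1)
    clients <- list(fx$clients[[1]], fx$clients[[3]])
    w <- c(strand_jumps = 1)
    if (with_fragments) {
      clients[[3]] <- fragment_client("fragments", helix_frags)
      w <- c(fragments = 3, strand_jumps = 1)
    }
    proto <- protocol(clients, cycles = 80, temperature = 1.0,
                      weights = w, n_struct = 1)
    run_protocol(proto, fx$conf, seed = 12)$models[[1]]
  }
  fx <- make_vignette1_fixture(1)
  without <- run_once(FALSE)
  with_ <- run_once(TRUE)
  # without the fragment client, every torsion outside the chunk stays at
  # its starting value; with it, some move
  outside <- setdiff(1:76, 17:40)
  expect_identical(without$phi[outside], fx$conf$phi[outside])
  expect_identical(without$psi[outside], fx$conf$psi[outside])
  expect_gt(sum(abs(with_$phi[outside] - fx$conf$phi[outside]) > 1e-9), 0)
  # the chunk is at template values in both runs
  expect_identical(without$phi[17:40], fx$template$phi[17:40])
  expect_identical(with_$phi[17:40], fx$template$phi[17:40])
})
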