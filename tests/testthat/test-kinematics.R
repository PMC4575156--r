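# Independent 2D oracle for the trans backbone: with all torsions at 180 the
# chain is planar, so consecutive-CA distance follows from walking the three
# bonds in the plane with alternating turn signs at each bond angle.
planar_ca_ca_distance <- function() {
  steps <- list(c(IDEAL_CONST("ca_c"), IDEAL_CONST("ca_c_n")),
                c(IDEAL_CONST("c_n"), IDEAL_CONST("c_n_ca")),
                c(IDEAL_CONST("n_ca"), NA))
  pos <- 0 + 0i
  dir <- 1 + 0i
  sgn <- 1
  for (s in steps) {
    pos <- pos + dir * s[1]
    if (!is.na(s[2])) {
      dir <- dir * exp(1i * sgn * (pi - s[2] * pi / 180))
      sgn <- -sgn
    }
  }
  Mod(pos)
}

IDEAL_CONST <- function(nm) foldbroker:::IDEAL[[nm]]

test_that("ideal polypeptide presets and atom counts", {
  h5 <- build_ideal_polypeptide(5, torsion_preset = "helix")
  expect_equal(h5$phi, rep(-57, 5))
  expect_equal(h5$psi, rep(-47, 5))
  e3 <- build_ideal_polypeptide(3, torsion_preset = "extended")
  xyz <- conf_xyz(e3)
  expect_equal(dim(xyz), c(3, 4, 3))
  expect_true(all(is.finite(xyz)))
  expect_error(build_ideal_polypeptide(5, chain_spec = c(5, 0)),
               "non-positive")
  expect_error(build_ideal_polypeptide(5, chain_spec = c(2, 2)), "sum")
})

test_that("helix is compact relative to the extended chain", {
  h <- conf_xyz(build_ideal_polypeptide(10, torsion_preset = "helix"))
  e <- conf_xyz(build_ideal_polypeptide(10, torsion_preset = "extended"))
  d_h <- foldbroker:::vnorm(h[10, 2, ] - h[1, 2, ])
  d_e <- foldbroker:::vnorm(e[10, 2, ] - e[1, 2, ])
  expect_lt(d_h, 16)
  expect_lt(d_h, d_e)
})

test_that("peptide bond and CA-CA spacing follow the ideal constants", {
  conf <- build_ideal_polypeptide(6, torsion_preset = "extended")
  xyz <- conf_xyz(conf)
  expect_equal(foldbroker:::vnorm(xyz[2, 1, ] - xyz[1, 3, ]),
               IDEAL_CONST("c_n"), tolerance = 1e-9)
  d <- sapply(1:5, function(i) foldbroker:::vnorm(xyz[i + 1, 2, ] - xyz[i, 2, ]))
  expect_lt(diff(range(d)), 1e-9)
  expect_equal(d[1], planar_ca_ca_distance(), tolerance = 1e-9)
})

test_that("internal -> Cartesian -> internal round-trips torsions", {
  set.seed(21)
  for (k in 1:20) {
    n <- sample(8:25, 1)
    conf <- build_ideal_polypeptide(n, torsion_preset = list(
      phi = runif(n, -180, 180), psi = runif(n, -180, 180),
      omega = runif(n, 160, 200)))
    ic <- cartesian_to_internal(conf_xyz(conf), conf$chains)
    expect_lt(max(abs(foldbroker:::wrap180(ic$phi[-1] - conf$phi[-1]))), 1e-6)
    expect_lt(max(abs(foldbroker:::wrap180(ic$psi - conf$psi))), 1e-6)
    expect_lt(max(abs(foldbroker:::wrap180(ic$omega[-n] - conf$omega[-n]))), 1e-6)
    expect_lt(max(abs(ic$lengths$n_ca - conf$lengths$n_ca)), 1e-9)
    expect_lt(max(abs(ic$angles$n_ca_c - conf$angles$n_ca_c)), 1e-6)
  }
})

test_that("cartesian_to_internal: missing atoms and localized perturbation", {
  conf <- build_ideal_polypeptide(8, torsion_preset = "helix")
  xyz <- conf_xyz(conf)
  bad <- xyz
  bad[4, 2, ] <- NA
  expect_error(cartesian_to_internal(bad, conf$chains), "missing")
  # perturbing one CA changes only the internal coordinates touching it
  pert <- xyz
  pert[5, 2, ] <- pert[5, 2, ] + c(0.1, 0, 0)
  a <- cartesian_to_internal(xyz, conf$chains)
  b <- cartesian_to_internal(pert, conf$chains)
  # CA(5) appears in phi(5), psi(5) and in omega(4) and omega(5); no other
  # torsion involves it
  touched_phi <- abs(foldbroker:::wrap180(a$phi - b$phi)) > 1e-9
  touched_psi <- abs(foldbroker:::wrap180(a$psi - b$psi)) > 1e-9
  touched_omega <- abs(foldbroker:::wrap180(a$omega - b$omega)) > 1e-9
  expect_equal(which(touched_phi), 5L)
  expect_equal(which(touched_psi), 5L)
  expect_equal(which(touched_omega), c(4L, 5L))
})

test_that("set_dof is exact at identity and local in the fold tree", {
  conf <- build_ideal_polypeptide(9, torsion_preset = "helix")
  same <- set_dof(conf, dof_psi(4), conf$psi[4])
  expect_identical(conf_xyz(same), conf_xyz(conf))
  # linear tree rooted at 1: psi(2) moves residues 3..N only (their N/CA/C);
  # O(2) co-rotates with psi but N/CA of 1..2 are fixed
  moved <- set_dof(conf, dof_psi(2), conf$psi[2] + 25)
  x0 <- conf_xyz(conf); x1 <- conf_xyz(moved)
  expect_identical(x1[1:2, 1:2, ], x0[1:2, 1:2, ])
  expect_identical(x1[1:2, 3, ], x0[1:2, 3, ])
  for (r in 3:9) expect_gt(max(abs(x1[r, , ] - x0[r, , ])), 1e-9)
  expect_equal(downstream_set(conf$fold_tree, dof_psi(2)), 3:9)
  expect_error(set_dof(conf, dof_phi(40), 10), "unknown DoF")
})

test_that("set_dof respects jump/cut propagation boundaries", {
  conf <- build_ideal_polypeptide(25, torsion_preset = "helix")
  tree <- fold_tree(data.frame(start = c(1, 20, 20, 5),
                               stop = c(10, 11, 25, 20),
                               label = c(-1, -1, -1, 1)),
                    root = 1, cuts = 10, n_residues = 25)
  expect_length(validate_fold_tree(tree), 0)
  conf <- foldbroker:::set_fold_tree(conf, tree, keep_coords = TRUE)
  x0 <- conf_xyz(conf)
  moved <- set_dof(conf, dof_phi(7), conf$phi[7] - 70)
  x1 <- conf_xyz(moved)
  # residues beyond the pivot up to the cut move; the jump side refolds
  # identically
  per_res <- sapply(1:25, function(r) max(abs(x1[r, , ] - x0[r, , ])))
  expect_setequal(which(per_res > 1e-9), 7:10)
  expect_identical(x1[11:25, , ], x0[11:25, , ])
  expect_setequal(downstream_set(tree, dof_phi(7)), 7:10)
})

test_that("jump transforms: set/read inverse pair and torsion-pin invariance", {
  conf <- build_ideal_polypeptide(25, torsion_preset = "helix")
  tree <- fold_tree(data.frame(start = c(1, 20, 20, 5),
                               stop = c(10, 11, 25, 20),
                               label = c(-1, -1, -1, 1)),
                    root = 1, cuts = 10, n_residues = 25)
  conf <- foldbroker:::set_fold_tree(conf, tree, keep_coords = TRUE)
  Tj <- rigid_transform(foldbroker:::rotation_about_axis(c(0, 1, 1), 0.7),
                        c(3, -4, 8))
  conf <- set_jump(conf, 1, Tj)
  got <- jump_transform(conf, 1)
  expect_equal(got$R, Tj$R, tolerance = 1e-9)
  expect_equal(got$t, Tj$t, tolerance = 1e-9)
  # torsion changes away from the stub residues leave the transform fixed
  set.seed(22)
  for (r in c(2, 3, 8, 13, 17, 23)) {
    conf <- set_dof(conf, dof_phi(r), runif(1, -180, 180))
    conf <- set_dof(conf, dof_psi(r), runif(1, -180, 180))
  }
  got2 <- jump_transform(conf, 1)
  expect_lt(max(abs(got2$R - Tj$R)), 1e-9)
  expect_lt(max(abs(got2$t - Tj$t)), 1e-9)
  # identity transform makes the stub frames coincide
  conf <- set_jump(conf, 1, rt_identity())
  s5 <- foldbroker:::residue_stub(conf, 5)
  s20 <- foldbroker:::residue_stub(conf, 20)
  expect_equal(s5$R, s20$R, tolerance = 1e-9)
  expect_equal(s5$t, s20$t, tolerance = 1e-9)
  expect_error(jump_transform(conf, 9), "unknown jump")
})

test_that("chainbreak deviation tracks geometric continuity across a cut", {
  conf <- build_ideal_polypeptide(25, torsion_preset = "helix")
  x_uncut <- conf_xyz(conf)
  tree <- fold_tree(data.frame(start = c(1, 20, 20, 5),
                               stop = c(10, 11, 25, 20),
                               label = c(-1, -1, -1, 1)),
                    root = 1, cuts = 10, n_residues = 25)
  conf <- foldbroker:::set_fold_tree(conf, tree, keep_coords = TRUE)
  dv <- chainbreak_deviation(conf, 10)
  expect_lt(dv$dist, 1e-6)
  expect_lt(max(dv$angles), 1e-6)
  opened <- set_dof(conf, dof_phi(9), conf$phi[9] + 60)
  dv2 <- chainbreak_deviation(opened, 10)
  expect_gt(dv2$dist, 0.01)
  expect_error(chainbreak_deviation(conf, 15), "not a cut")
})

test_that("cache always matches a from-scratch recomputation", {
  set.seed(23)
  conf <- build_ideal_polypeptide(15, torsion_preset = "strand")
  for (k in 1:10) {
    conf <- set_dof(conf, dof_phi(sample(2:15, 1)), runif(1, -180, 180))
    expect_lt(max(abs(conf$xyz - internal_to_cartesian(conf))), 1e-9)
  }
})
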