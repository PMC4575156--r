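test_that("a jump claim expands to six DoF elements, one jump and one cut", {
  conf <- build_ideal_polypeptide(40, torsion_preset = "extended")
  els <- expand_jump_claim(jump_claim(5, 20, "CAN_CONTROL"), conf, "A")
  types <- vapply(els, function(e) e$etype, "")
  expect_equal(sum(types == "dof_jump"), 6)
  expect_equal(sum(types == "jump"), 1)
  expect_equal(sum(types == "cut"), 1)
  rb <- sort(vapply(els[types == "dof_jump"], function(e) e$rb, 1L))
  expect_equal(rb, 1:6)
  expect_true(all(vapply(els[types == "dof_jump"],
                         function(e) e$strength, "") == "CAN_CONTROL"))
  # additivity over independent claims
  els2 <- c(els, expand_jump_claim(jump_claim(25, 35, "MUST_CONTROL"),
                                   conf, "B"))
  types2 <- vapply(els2, function(e) e$etype, "")
  expect_equal(as.integer(table(types2)[c("dof_jump", "jump", "cut")]),
               c(12L, 2L, 2L))
  # a fixed-geometry pin carries EXCLUSIVE on all six components
  els3 <- expand_jump_claim(jump_claim(5, 20, "EXCLUSIVE",
                                       fixed_geometry = TRUE), conf, "C")
  t3 <- vapply(els3, function(e) e$etype, "")
  expect_true(all(vapply(els3[t3 == "dof_jump"],
                         function(e) e$strength, "") == "EXCLUSIVE"))
  expect_error(expand_jump_claim(jump_claim(7, 7, "CAN_CONTROL"), conf, "D"),
               "identical")
})

test_that("the control-strength matrix resolves every pair as specified", {
  mk <- function(sa, sb) {
    list(foldbroker:::element_dof("A", dof_psi(12), sa),
         foldbroker:::element_dof("B", dof_psi(12), sb))
  }
  outcome <- function(sa, sb) {
    tryCatch({
      g <- resolve_access(mk(sa, sb))
      paste(sort(g$owner), collapse = "+")
    }, foldbroker_conflict_error = function(e) "CONFLICT")
  }
  cs <- CONTROL_STRENGTHS
  expected <- function(sa, sb) {
    if (sa == "EXCLUSIVE" && sb %in% c("EXCLUSIVE", "MUST_CONTROL")) return("CONFLICT")
    if (sb == "EXCLUSIVE" && sa %in% c("EXCLUSIVE", "MUST_CONTROL")) return("CONFLICT")
    granted <- c("A", "B")
    if (sa == "EXCLUSIVE") granted <- "A"
    if (sb == "EXCLUSIVE") granted <- "B"
    if (sa == "DOES_NOT_CONTROL") granted <- setdiff(granted, "A")
    if (sb == "DOES_NOT_CONTROL") granted <- setdiff(granted, "B")
    paste(sort(granted), collapse = "+")
  }
  for (sa in cs) for (sb in cs) {
    expect_identical(outcome(sa, sb), expected(sa, sb),
                     label = paste(sa, "x", sb))
  }
  # conflict errors name both movers and the DoF
  err <- tryCatch(resolve_access(mk("EXCLUSIVE", "MUST_CONTROL")),
                  error = identity)
  expect_match(conditionMessage(err), "A")
  expect_match(conditionMessage(err), "B")
  expect_match(conditionMessage(err), "psi:12", fixed = TRUE)
})

test_that("more than two claimants resolve pairwise", {
  el <- function(o, s) foldbroker:::element_dof(o, dof_phi(3), s)
  # one EXCLUSIVE demotes every CAN claimant
  g <- resolve_access(list(el("A", "EXCLUSIVE"), el("B", "CAN_CONTROL"),
                           el("C", "CAN_CONTROL")))
  expect_equal(g$owner, "A")
  # EXCLUSIVE against any MUST fails, whatever else is present
  expect_error(resolve_access(list(el("A", "EXCLUSIVE"), el("B", "CAN_CONTROL"),
                                   el("C", "MUST_CONTROL"))),
               class = "foldbroker_conflict_error")
  # without an EXCLUSIVE, everyone but DOES_NOT gets access
  g2 <- resolve_access(list(el("A", "MUST_CONTROL"), el("B", "CAN_CONTROL"),
                            el("C", "DOES_NOT_CONTROL")))
  expect_setequal(g2$owner, c("A", "B"))
})

test_that("registration is open until broking, once per client", {
  conf <- build_ideal_polypeptide(20, torsion_preset = "extended")
  b <- broker_new()
  register_client(b, scripted_client("x", list(torsion_claim(1:5, "CAN_CONTROL"))))
  expect_error(register_client(b, scripted_client("x", list())),
               class = "foldbroker_registration_error")
  register_client(b, scripted_client("y", list()))
  broke(b, conf, seed = 1)
  expect_error(register_client(b, scripted_client("z", list())),
               class = "foldbroker_registration_error")
  # zero clients: a valid linear tree, empty passports
  res0 <- broke_clients(list(), conf, seed = 1)
  expect_length(validate_fold_tree(res0$tree), 0)
  expect_equal(n_jumps(res0$tree), 0)
  expect_length(res0$passports, 0)
})

test_that("consensus trees place one random legal cut per jump cycle", {
  conf <- build_ideal_polypeptide(40, torsion_preset = "extended")
  cuts_seen <- integer(0)
  for (seed in 1:100) {
    res <- broke_clients(list(scripted_client(
      "j", list(jump_claim(5, 20, "MUST_CONTROL")))), conf, seed = seed)
    expect_length(validate_fold_tree(res$tree), 0)
    expect_equal(n_jumps(res$tree), 1)
    expect_length(res$tree$cuts, 1)
    expect_true(res$tree$cuts >= 5 && res$tree$cuts <= 19)
    cuts_seen <- c(cuts_seen, res$tree$cuts)
  }
  expect_gt(length(unique(cuts_seen)), 5)  # actually randomized
  # no jumps, one chain: linear tree, no cuts
  res <- broke_clients(list(), conf, seed = 3)
  expect_equal(nrow(res$tree$edges), 1)
  expect_length(res$tree$cuts, 0)
})

test_that("forbidden intervals steer cuts and exhaust into a clear error", {
  conf <- build_ideal_polypeptide(40, torsion_preset = "extended")
  for (seed in 1:300) {
    res <- broke_clients(list(
      scripted_client("j", list(jump_claim(5, 30, "MUST_CONTROL"))),
      scripted_client("guard", list(cut_claim(forbidden = list(c(17, 40)))))),
      conf, seed = seed)
    expect_true(res$tree$cuts >= 5 && res$tree$cuts <= 16)
  }
  err <- tryCatch(broke_clients(list(
    scripted_client("j", list(jump_claim(17, 30, "MUST_CONTROL"))),
    scripted_client("guard", list(cut_claim(forbidden = list(c(17, 40)))))),
    conf, seed = 1), error = identity)
  expect_s3_class(err, "foldbroker_no_cut_error")
  expect_match(conditionMessage(err), "guard")
  expect_match(conditionMessage(err), "\\[17,29\\]")
})

test_that("vignette-1-shaped broking: chunk uncut, exclusively granted", {
  fx <- make_vignette1_fixture(1)
  res <- broke_clients(fx$clients, fx$conf, seed = 5)
  expect_length(validate_fold_tree(res$tree), 0)
  expect_false(any(res$tree$cuts %in% 17:39))
  chunk_dofs <- dof_torsions(17:40)
  g <- res$grants
  expect_true(all(chunk_dofs %in% g$dof[g$owner == "chunk"]))
  expect_false(any(chunk_dofs %in% g$dof[g$owner != "chunk"]))
})

test_that("overlapping exclusive chunks fail naming both clients", {
  fx <- make_vignette1_fixture(1)
  c1 <- rigid_chunk_client("chunk_one", fx$template, 17:40)
  c2 <- rigid_chunk_client("chunk_two", fx$template, 20:25)
  err <- tryCatch(broke_clients(list(c1, c2), fx$conf, seed = 1),
                  error = identity)
  expect_s3_class(err, "foldbroker_conflict_error")
  expect_match(conditionMessage(err), "chunk_one")
  expect_match(conditionMessage(err), "chunk_two")
})

test_that("CoM star broking grows the pose and roots it at the virtual", {
  fx <- make_vignette3_fixture(1)
  star_only <- fx$clients[1:4]  # star + three docking clients
  res <- broke_clients(star_only, fx$conf, seed = 2)
  conf <- pconf_conformation(res$pconf)
  expect_equal(conf$n_residues, 72 + 4)
  expect_equal(sum(conf$virtual), 4)
  expect_equal(res$tree$root, virtual_residue_index(conf, "star_root"))
  expect_equal(n_jumps(res$tree), 6)
  expect_length(validate_fold_tree(res$tree), 0)
})

test_that("broking output is invariant to registration order", {
  fx <- make_vignette1_fixture(1)
  perms <- list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1))
  outs <- lapply(perms, function(p) {
    fresh <- make_vignette1_fixture(1)  # clients carry per-broke state
    broke_clients(fresh$clients[p], fresh$conf, seed = 9)
  })
  base <- outs[[1]]
  for (o in outs[-1]) {
    expect_identical(serialize_fold_tree(o$tree),
                     serialize_fold_tree(base$tree))
    expect_identical(o$grants, base$grants)
  }
})

test_that("on conflict no passports are issued and the input is untouched", {
  fx <- make_vignette1_fixture(1)
  conf <- fx$conf
  x0 <- conf_xyz(conf)
  c1 <- rigid_chunk_client("one", fx$template, 17:40)
  c2 <- rigid_chunk_client("two", fx$template, 30:45)
  b <- broker_new()
  register_client(b, c1)
  register_client(b, c2)
  expect_error(broke(b, conf, seed = 1), class = "foldbroker_conflict_error")
  expect_identical(conf_xyz(conf), x0)
  expect_null(c1$passport)
  expect_null(c2$passport)
})

test_that("brokered trees from random resolvable claim sets validate", {
  set.seed(34)
  n_ok <- 0
  for (k in 1:60) {
    n <- sample(20:60, 1)
    conf <- build_ideal_polypeptide(n, torsion_preset = "extended")
    clients <- random_claim_clients(n)
    res <- tryCatch(broke_clients(clients, conf, seed = k),
                    foldbroker_no_cut_error = function(e) NULL)
    if (is.null(res)) next
    n_ok <- n_ok + 1
    expect_length(validate_fold_tree(res$tree), 0)
    expect_equal(length(res$tree$cuts), n_jumps(res$tree))
  }
  expect_gt(n_ok, 40)
})
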