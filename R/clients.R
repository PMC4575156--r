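# Client movers: each couples a broking layer (yield_claims / configure /
# initialize hooks) to an effector layer (the sampling move in apply). All
# modification goes through with_unlock + protected_set_dof, so a client can
# only ever move DoFs its passport grants.

#' Client mover framework
#'
#' Clients are environments dispatched through four S3 generics:
#' `yield_claims(client, conf)` (pure: returns a list of claims),
#' `client_configure(client, result)` (interpret the broking result, e.g.
#' learn which jump number is its own), `client_initialize(client, pconf)`
#' (optional one-off setup inside the client's own unlock, e.g. a rigid
#' chunk writing its template torsions), and `client_apply(client, pconf)`
#' (one sampling move; atomic: on rejection or error the conformation is
#' restored bit-exactly).
#'
#' @param client a client mover object.
#' @param conf a `conformation`.
#' @param result a `broker_result`.
#' @param pconf a protected conformation.
#' @name client_mover
NULL

#' @rdname client_mover
#' @export
yield_claims <- function(client, conf) UseMethod("yield_claims")

#' @rdname client_mover
#' @export
client_configure <- function(client, result) UseMethod("client_configure")

#' @rdname client_mover
#' @export
client_initialize <- function(client, pconf) UseMethod("client_initialize")

#' @rdname client_mover
#' @export
client_apply <- function(client, pconf) UseMethod("client_apply")

#' @export
client_configure.default <- function(client, result) {
  client$passport <- result$passports[[client$name]]
  client$jump_numbers <- jump_numbers_for(client, result)
  invisible(client)
}

#' @export
client_initialize.default <- function(client, pconf) invisible(client)

#' @export
print.client_mover <- function(x, ...) {
  cat("<client_mover:", class(x)[1], ">", x$name, "\n")
  invisible(x)
}

new_client <- function(name, class1) {
  cl <- new.env(parent = emptyenv())
  cl$name <- name
  cl$claims_issued <- list()
  class(cl) <- c(class1, "client_mover")
  cl
}

# map this client's tagged jump claims to brokered jump numbers
jump_numbers_for <- function(client, result) {
  out <- integer(0)
  for (c1 in client$claims_issued) {
    if (!identical(c1$type, "jump") || is.null(c1$tag)) next
    a <- resolve_anchor(c1$anchor1, result$pconf$conf)
    b <- resolve_anchor(c1$anchor2, result$pconf$conf)
    jt <- result$jump_numbers
    row <- which(jt$a == min(a, b) & jt$b == max(a, b))
    if (length(row)) out[c1$tag] <- jt$number[row[1]]
  }
  out
}

# run an action with snapshot/rollback so failed moves leave no trace
atomic_apply <- function(pconf, action) {
  snap <- pconf$conf
  tryCatch(action(), error = function(e) {
    pconf$conf <- snap
    stop(e)
  })
}

# ---- rigid chunk ------------------------------------------------------------

#' Rigid chunk client
#'
#' Claims exclusive access to all torsions of a region, forbids cuts inside
#' each contiguous segment of the region, and — for discontinuous regions —
#' pins consecutive segments together with fixed-geometry jumps whose
#' transforms are measured from the template. At initialization it sets all
#' claimed DoFs to the template values once; exclusivity guarantees they
#' are never re-sampled ("set and forget").
#'
#' @param name client id.
#' @param template a `conformation` sharing the pose numbering, providing
#'   coordinates/torsions for the region.
#' @param region residue indices, selector, or selector string.
#' @return A client mover.
#' @export
rigid_chunk_client <- function(name, template, region) {
  cl <- new_client(name, "rigid_chunk_client")
  cl$template <- template
  cl$region <- region
  cl
}

#' @export
yield_claims.rigid_chunk_client <- function(client, conf) {
  rs <- resolve_selector(client$region, conf)
  if (!all(rs <= client$template$n_residues)) {
    stop("template is missing residues: ",
         paste(rs[rs > client$template$n_residues], collapse = ","))
  }
  client$residues <- rs
  segs <- split(rs, cumsum(c(1, diff(rs) != 1)))
  claims <- list(torsion_claim(rs, "EXCLUSIVE"))
  forbidden <- unname(lapply(Filter(function(s) length(s) > 1, segs),
                             function(s) c(min(s), max(s) - 1L)))
  if (length(forbidden)) {
    claims[[length(claims) + 1]] <- cut_claim(forbidden = forbidden)
  }
  if (length(segs) > 1) {
    mids <- vapply(segs, function(s) s[ceiling(length(s) / 2)], 1L)
    for (k in seq_len(length(segs) - 1)) {
      claims[[length(claims) + 1]] <- jump_claim(
        mids[k], mids[k + 1], "EXCLUSIVE", fixed_geometry = TRUE,
        tag = paste0("pin_", k))
    }
  }
  client$claims_issued <- claims
  claims
}

#' @export
client_initialize.rigid_chunk_client <- function(client, pconf) {
  tmpl <- client$template
  rs <- client$residues
  with_unlock(pconf, client$passport, function() {
    protected_set_dofs(pconf,
                       c(dof_phi(rs), dof_psi(rs), dof_omega(rs)),
                       c(tmpl$phi[rs], tmpl$psi[rs], tmpl$omega[rs]))
    # fixed inter-segment jumps: transform measured from the template
    txyz <- conf_xyz(tmpl)
    for (tag in names(client$jump_numbers)) {
      jno <- client$jump_numbers[[tag]]
      je <- jump_edge(pconf$tree, jno)
      Tj <- rt_compose(rt_inverse(stub_from_xyz(txyz, je$start)),
                       stub_from_xyz(txyz, je$stop))
      protected_set_jump(pconf, jno, Tj)
    }
  })
  invisible(client)
}

#' @export
client_apply.rigid_chunk_client <- function(client, pconf) {
  list(moved = FALSE)  # set-and-forget: nothing to sample
}

# ---- fragment insertion -----------------------------------------------------

#' Fragment library
#'
#' @param entries list of entries, each `list(position, length, torsions)`
#'   with `torsions` a `length x 3` matrix of (phi, psi, omega) in degrees;
#'   window lengths must be 3-9 residues.
#' @return A `fragment_library`.
#' @export
fragment_library <- function(entries) {
  for (e in entries) {
    stopifnot(e$length >= 3, e$length <= 9,
              nrow(e$torsions) == e$length, ncol(e$torsions) == 3,
              all(is.finite(e$torsions)))
  }
  structure(list(entries = entries), class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat("<fragment_library>", length(x$entries), "fragment(s)\n")
  invisible(x)
}

#' Fragment insertion client
#'
#' Claims CAN_CONTROL over the torsions its fragments cover; each apply
#' writes one uniformly chosen fragment's torsion window. Insertions whose
#' window overlaps any DoF the client was not granted (e.g. demoted by a
#' rigid chunk's exclusive claim) are rejected before any modification.
#'
#' @param name client id.
#' @param library a `fragment_library`.
#' @return A client mover.
#' @export
fragment_client <- function(name, library) {
  stopifnot(inherits(library, "fragment_library"))
  cl <- new_client(name, "fragment_client")
  cl$library <- library
  cl
}

#' @export
yield_claims.fragment_client <- function(client, conf) {
  covered <- sort(unique(unlist(lapply(client$library$entries, function(e)
    seq(e$position, e$position + e$length - 1L)))))
  claims <- list(torsion_claim(covered, "CAN_CONTROL"))
  client$claims_issued <- claims
  claims
}

#' @export
client_apply.fragment_client <- function(client, pconf) {
  entries <- client$library$entries
  if (!length(entries)) stop("empty fragment library")
  e <- entries[[sample.int(length(entries), 1)]]
  rs <- seq(e$position, e$position + e$length - 1L)
  dofs <- c(dof_phi(rs), dof_psi(rs), dof_omega(rs))
  if (!all(dofs %in% client$passport$granted)) {
    return(list(moved = FALSE, rejected = TRUE,
                reason = "fragment window overlaps ungranted DoFs"))
  }
  atomic_apply(pconf, function() {
    with_unlock(pconf, client$passport, function() {
      protected_set_dofs(pconf,
                         c(dof_phi(rs), dof_psi(rs), dof_omega(rs)),
                         c(e$torsions[, 1], e$torsions[, 2], e$torsions[, 3]))
    })
  })
  list(moved = TRUE, position = e$position, length = e$length)
}

# ---- beta-strand pairing jumps ----------------------------------------------

#' Strand pairing set
#'
#' Candidate beta-strand pairings. Only two residues can be pinned per
#' strand pair, so each pairing lists the candidate anchor residue pairs;
#' one pair is drawn per trajectory at claim time.
#'
#' @param pairings list of pairings, each `list(anchors, orientation,
#'   register)` with `anchors` an `m x 2` matrix of candidate residue
#'   pairs, `orientation` `"A"` (antiparallel) or `"P"` (parallel).
#' @param transforms list of `rigid_transform`s: observed strand-pair
#'   stub-to-stub geometries sampled at apply time.
#' @return A `strand_pairing_set`.
#' @export
strand_pairing_set <- function(pairings, transforms) {
  for (p in pairings) {
    stopifnot(is.matrix(p$anchors), ncol(p$anchors) == 2,
              nrow(p$anchors) >= 1, p$orientation %in% c("A", "P"))
  }
  stopifnot(length(transforms) >= 0,
            all(vapply(transforms, inherits, TRUE, "rigid_transform")))
  structure(list(pairings = pairings, transforms = transforms),
            class = "strand_pairing_set")
}

#' Strand-pairing jump client
#'
#' Pins the stub frames of one residue pair per strand pairing with a jump
#' (MUST_CONTROL on its six rigid-body DoFs); the anchor pair is drawn
#' uniformly from the candidates once per trajectory, so the ensemble
#' samples the whole space of pairs. Each apply sets one of its jumps to a
#' transform drawn uniformly from the pairing-geometry library.
#'
#' @param name client id.
#' @param pairing_set a `strand_pairing_set`.
#' @return A client mover.
#' @export
strand_jump_client <- function(name, pairing_set) {
  stopifnot(inherits(pairing_set, "strand_pairing_set"))
  cl <- new_client(name, "strand_jump_client")
  cl$pairing_set <- pairing_set
  cl
}

#' @export
yield_claims.strand_jump_client <- function(client, conf) {
  claims <- list()
  chosen <- list()
  for (k in seq_along(client$pairing_set$pairings)) {
    p <- client$pairing_set$pairings[[k]]
    row <- if (nrow(p$anchors) == 1) 1L else sample.int(nrow(p$anchors), 1)
    ab <- p$anchors[row, ]
    chosen[[k]] <- ab
    claims[[length(claims) + 1]] <- jump_claim(
      ab[1], ab[2], "MUST_CONTROL", tag = paste0("pair_", k))
  }
  client$chosen_anchors <- chosen
  client$claims_issued <- claims
  claims
}

#' @export
client_apply.strand_jump_client <- function(client, pconf) {
  tl <- client$pairing_set$transforms
  if (!length(tl)) stop("empty strand-pair transform library")
  jno <- client$jump_numbers[[sample.int(length(client$jump_numbers), 1)]]
  Tj <- tl[[sample.int(length(tl), 1)]]
  atomic_apply(pconf, function() {
    with_unlock(pconf, client$passport, function() {
      protected_set_jump(pconf, jno, Tj)
    })
  })
  list(moved = TRUE, jump = jno)
}

# ---- centre-of-mass star ----------------------------------------------------

#' Centre-of-mass star client
#'
#' Claims one root virtual residue plus, per chain, a CoM virtual residue
#' with two jumps: root -> CoM (the docking jump) and CoM -> chain (anchored
#' at the chain's middle residue). After any move that displaces a chain,
#' [com_tracking_update()] re-centres the CoM virtual on the chain without
#' moving any real atom, by updating both jumps.
#'
#' @param name client id.
#' @param chains chain ids to track (default: all chains of the pose).
#' @return A client mover.
#' @export
com_star_client <- function(name, chains = NULL) {
  cl <- new_client(name, "com_star_client")
  cl$chains <- chains
  cl
}

#' @export
yield_claims.com_star_client <- function(client, conf) {
  chains <- client$chains
  if (is.null(chains)) chains <- conf$chains$chain_id
  client$chains <- chains
  claims <- list(virtual_residue_claim("star_root", attach = "root"))
  for (ch in chains) {
    lab <- paste0("com_", ch)
    mid <- chain_residues(conf, ch)
    mid <- mid[ceiling(length(mid) / 2)]
    claims[[length(claims) + 1]] <- virtual_residue_claim(lab, attach = "com",
                                                          chain = ch)
    claims[[length(claims) + 1]] <- jump_claim(
      virtual_anchor("star_root"), virtual_anchor(lab), "MUST_CONTROL",
      tag = paste0("dock_", ch))
    claims[[length(claims) + 1]] <- jump_claim(
      virtual_anchor(lab), mid, "MUST_CONTROL", tag = paste0("track_", ch))
  }
  client$claims_issued <- claims
  claims
}

#' @export
client_apply.com_star_client <- function(client, pconf) {
  for (ch in client$chains) {
    com_tracking_update(pconf, client$passport, ch,
                        client$jump_numbers[[paste0("dock_", ch)]],
                        client$jump_numbers[[paste0("track_", ch)]])
  }
  list(moved = TRUE)
}

#' Re-centre a CoM virtual residue on its chain
#'
#' Moves the virtual residue to the chain's current backbone centre of mass
#' without altering the location of any real atom, by changing both the
#' incoming (root -> CoM) and outgoing (CoM -> chain) jump transforms.
#' Idempotent.
#'
#' @param pconf a protected conformation.
#' @param passport a passport granting both jumps' rigid-body DoFs.
#' @param chain chain id.
#' @param jump_in jump number of the incoming (root -> CoM) jump.
#' @param jump_out jump number of the outgoing (CoM -> chain) jump.
#' @return The new CoM position, invisibly.
#' @export
com_tracking_update <- function(pconf, passport, chain, jump_in, jump_out) {
  conf <- pconf$conf
  p <- chain_com(conf, chain)
  xyz <- conf_xyz(conf)
  ein <- jump_edge(conf$fold_tree, jump_in)
  eout <- jump_edge(conf$fold_tree, jump_out)
  stopifnot(ein$stop == eout$start)  # the CoM virtual residue
  s_up <- stub_from_xyz(xyz, ein$start)
  s_com <- stub_from_xyz(xyz, ein$stop)
  s_anchor <- stub_from_xyz(xyz, eout$stop)
  s_com_new <- rigid_transform(s_com$R, p)
  t_in <- rt_compose(rt_inverse(s_up), s_com_new)
  t_out <- rt_compose(rt_inverse(s_com_new), s_anchor)
  atomic_apply(pconf, function() {
    with_unlock(pconf, passport, function() {
      protected_set_jump(pconf, jump_in, t_in)
      protected_set_jump(pconf, jump_out, t_out)
    })
  })
  invisible(p)
}

# ---- rigid-body docking -----------------------------------------------------

#' Rigid-body docking client
#'
#' Perturbs the root -> CoM jump of one chain: a rotation of Gaussian
#' magnitude about a uniformly random axis composed with a Gaussian
#' translation. Only the docked partner's subtree moves.
#'
#' @param name client id.
#' @param chain the docked chain id.
#' @param rot_mag rotation magnitude (sd, degrees).
#' @param trans_mag translation magnitude (sd per component,
#'   \enc{Å}{Angstrom}).
#' @return A client mover.
#' @export
docking_client <- function(name, chain, rot_mag = 3, trans_mag = 0.5) {
  cl <- new_client(name, "docking_client")
  cl$chain <- chain
  cl$rot_mag <- rot_mag
  cl$trans_mag <- trans_mag
  cl
}

#' @export
yield_claims.docking_client <- function(client, conf) {
  claims <- list(jump_claim(virtual_anchor("star_root"),
                            virtual_anchor(paste0("com_", client$chain)),
                            "MUST_CONTROL", tag = "dock"))
  client$claims_issued <- claims
  claims
}

#' @export
client_apply.docking_client <- function(client, pconf) {
  rigid_body_dock_apply(pconf, client$passport,
                        client$jump_numbers[["dock"]],
                        client$rot_mag, client$trans_mag)
}

#' Perturb a jump's rigid-body DoFs
#'
#' Composes a random perturbation onto the jump: rotation angle drawn from
#' N(0, rot_mag) degrees about a uniformly random axis, translation drawn
#' from N(0, trans_mag) per component.
#'
#' @param pconf a protected conformation.
#' @param passport a passport granting the jump's six rigid-body DoFs.
#' @param jump_number the jump to perturb.
#' @param rot_mag rotation sd, degrees.
#' @param trans_mag translation sd per component, \enc{Å}{Angstrom}.
#' @return Move outcome list.
#' @export
rigid_body_dock_apply <- function(pconf, passport, jump_number,
                                  rot_mag, trans_mag) {
  axis <- stats::rnorm(3)
  while (vnorm(axis) < 1e-8) axis <- stats::rnorm(3)
  ang <- deg2rad(stats::rnorm(1, 0, rot_mag))
  shift <- stats::rnorm(3, 0, trans_mag)
  delta <- rigid_transform(rotation_about_axis(axis, ang), shift)
  t_old <- pconf$conf$jumps[[as.character(jump_number)]]
  if (is.null(t_old)) stop("unknown jump: ", jump_number)
  atomic_apply(pconf, function() {
    with_unlock(pconf, passport, function() {
      protected_set_jump(pconf, jump_number, rt_compose(t_old, delta))
    })
  })
  list(moved = TRUE, jump = jump_number, angle = rad2deg(ang), shift = shift)
}

# ---- CCD loop closure -------------------------------------------------------

#' Loop closure client
#'
#' Claims CAN_CONTROL torsions over a loop, plus a jump bypassing the loop
#' with a cut preferred inside it. Its apply runs cyclic coordinate descent
#' on the granted loop torsions to repair the chainbreak at the cut. If no
#' loop torsion was granted, configuration fails fast (before any sampling).
#'
#' @param name client id.
#' @param loop `c(start, end)` loop residue range.
#' @param max_iter maximum CCD sweeps per apply.
#' @param tol convergence tolerance on the chainbreak distance gap
#'   (\enc{Å}{Angstrom}).
#' @return A client mover.
#' @export
loop_close_client <- function(name, loop, max_iter = 100, tol = 0.05) {
  cl <- new_client(name, "loop_close_client")
  cl$loop <- c(as.integer(loop[1]), as.integer(loop[2]))
  cl$max_iter <- max_iter
  cl$tol <- tol
  cl
}

#' @export
yield_claims.loop_close_client <- function(client, conf) {
  lo <- client$loop[1]; hi <- client$loop[2]
  claims <- list(
    torsion_claim(seq(lo, hi), "CAN_CONTROL"),
    jump_claim(lo - 1L, hi + 1L, "CAN_CONTROL",
               cut_preference = c(lo, hi - 1L),
               tag = "bypass")
  )
  client$claims_issued <- claims
  claims
}

#' @export
client_configure.loop_close_client <- function(client, result) {
  NextMethod()
  granted_torsions <- intersect(
    dof_torsions(seq(client$loop[1], client$loop[2])),
    client$passport$granted)
  if (!length(granted_torsions)) {
    stop(fb_condition("foldbroker_config_error", sprintf(
      "loop closure client '%s': no torsion in loop [%d,%d] was granted",
      client$name, client$loop[1], client$loop[2])))
  }
  invisible(client)
}

#' @export
client_apply.loop_close_client <- function(client, pconf) {
  ccd_loop_close_apply(pconf, client$passport, client$loop,
                       max_iter = client$max_iter, tol = client$tol)
}

#' Cyclic coordinate descent loop closure
#'
#' Iteratively adjusts the granted phi/psi torsions inside the loop to
#' minimise the chainbreak at the loop's cut: for each pivot torsion the
#' closed-form optimal rotation is computed (superposing the broken bond's
#' ideal continuation onto the actual downstream atoms) and applied if it
#' reduces the squared triplet gap. Never touches ungranted DoFs.
#'
#' @param pconf a protected conformation.
#' @param passport passport granting the loop torsions used.
#' @param loop `c(start, end)` residue range containing exactly one cut.
#' @param max_iter maximum sweeps.
#' @param tol stop once the chainbreak distance gap falls below this
#'   (\enc{Å}{Angstrom}).
#' @return List: `converged`, `iterations`, `deviation` (the final
#'   chainbreak deviation).
#' @export
ccd_loop_close_apply <- function(pconf, passport, loop, max_iter = 100,
                                 tol = 0.05) {
  conf <- pconf$conf
  tree <- conf$fold_tree
  cuts_in <- tree$cuts[tree$cuts >= loop[1] & tree$cuts < loop[2]]
  if (length(cuts_in) != 1) {
    stop("loop [", loop[1], ",", loop[2], "] must contain exactly one cut (found ",
         length(cuts_in), ")")
  }
  cut <- cuts_in
  # candidate pivots: granted phi/psi in the loop that rigidly move exactly
  # one side of the break
  pivots <- list()
  for (r in seq(loop[1], loop[2])) {
    for (kind in c("phi", "psi")) {
      dof <- if (kind == "phi") dof_phi(r) else dof_psi(r)
      if (!(dof %in% passport$granted)) next
      ds <- downstream_set(tree, dof)
      m_up <- cut %in% ds        # moves the upstream side's continuation
      m_dn <- (cut + 1L) %in% ds # moves the actual downstream triplet
      if (m_up == m_dn) next
      pivots[[length(pivots) + 1]] <- list(dof = dof, residue = r,
                                           kind = kind, side_up = m_up)
    }
  }
  triplet_gap <- function(conf) {
    xyz <- conf_xyz(conf)
    i <- cut
    Nh <- place_atom(xyz[i, 1, ], xyz[i, 2, ], xyz[i, 3, ],
                     conf$lengths$c_n[i], conf$angles$ca_c_n[i], conf$psi[i])
    CAh <- place_atom(xyz[i, 2, ], xyz[i, 3, ], Nh,
                      conf$lengths$n_ca[i + 1], conf$angles$c_n_ca[i],
                      conf$omega[i])
    Ch <- place_atom(xyz[i, 3, ], Nh, CAh,
                     conf$lengths$ca_c[i + 1], conf$angles$n_ca_c[i + 1],
                     conf$phi[i + 1])
    M <- rbind(Nh, CAh, Ch)                       # ideal continuation
    F_ <- xyz[i + 1, 1:3, ]                       # actual N, CA, C
    list(M = M, F = F_, sq = sum((M - F_)^2), xyz = xyz)
  }
  dev0 <- chainbreak_deviation(conf, cut)
  if (dev0$dist < tol) {
    return(list(converged = TRUE, iterations = 0L, deviation = dev0))
  }
  result <- atomic_apply(pconf, function() {
    with_unlock(pconf, passport, function() {
      iter <- 0L
      repeat {
        iter <- iter + 1L
        for (pv in pivots) {
          st <- triplet_gap(pconf$conf)
          xyz <- st$xyz
          r <- pv$residue
          axis_pts <- if (pv$kind == "phi") xyz[r, 1:2, ] else xyz[r, 2:3, ]
          k <- unit(axis_pts[2, ] - axis_pts[1, ])
          o <- axis_pts[1, ]
          moving <- if (pv$side_up) st$M else st$F
          fixed <- if (pv$side_up) st$F else st$M
          num <- 0; den <- 0
          for (j in 1:3) {
            oj <- o + sum((moving[j, ] - o) * k) * k
            rj <- moving[j, ] - oj
            Rj <- vnorm(rj)
            if (Rj < 1e-9) next
            rhat <- rj / Rj
            shat <- pracma_cross(k, rhat)
            fj <- fixed[j, ] - oj
            den <- den + Rj * sum(fj * rhat)
            num <- num + Rj * sum(fj * shat)
          }
          theta <- rad2deg(atan2(num, den))
          if (abs(theta) < 1e-10) next
          cur <- get_dof(pconf$conf, pv$dof)
          best_val <- cur; best_sq <- st$sq
          for (cand in c(cur + theta, cur - theta)) {
            protected_set_dof(pconf, pv$dof, cand)
            sq <- triplet_gap(pconf$conf)$sq
            if (sq < best_sq) { best_sq <- sq; best_val <- cand }
          }
          protected_set_dof(pconf, pv$dof, best_val)
        }
        dev <- chainbreak_deviation(pconf$conf, cut)
        if (dev$dist < tol || iter >= max_iter) {
          return(list(converged = dev$dist < tol, iterations = iter,
                      deviation = dev))
        }
      }
    })
  })
  result
}
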