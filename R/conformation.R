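# Internal-coordinate polypeptide representation. A conformation stores
# backbone torsions (phi/psi/omega, degrees), per-residue bond lengths and
# angles, jump rigid transforms, chain layout, virtual-residue flags, and a
# fold tree; Cartesian coordinates (backbone N, CA, C, O) are a cache derived
# from the internal coordinates by fold-tree traversal.

# Idealised backbone geometry (Angstrom / degrees). Any self-consistent set
# works; these are standard idealised values.
IDEAL <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  n_ca_c = 111.2, ca_c_n = 116.2, c_n_ca = 121.7, ca_c_o = 121.0,
  omega = 180
)

TORSION_PRESETS <- list(
  helix = c(phi = -57, psi = -47),
  strand = c(phi = -120, psi = 120),
  extended = c(phi = 180, psi = 180)
)

ATOMS <- c("N", "CA", "C", "O")

new_conformation <- function(n, chains, phi, psi, omega, virtual = rep(FALSE, n)) {
  structure(list(
    n_residues = as.integer(n),
    chains = chains,                      # data.frame(chain_id, start, end)
    phi = phi, psi = psi, omega = omega,  # degrees
    lengths = list(n_ca = rep(IDEAL$n_ca, n), ca_c = rep(IDEAL$ca_c, n),
                   c_n = rep(IDEAL$c_n, n), c_o = rep(IDEAL$c_o, n)),
    angles = list(n_ca_c = rep(IDEAL$n_ca_c, n), ca_c_n = rep(IDEAL$ca_c_n, n),
                  c_n_ca = rep(IDEAL$c_n_ca, n), ca_c_o = rep(IDEAL$ca_c_o, n)),
    o_offset = rep(0, n),                 # O dihedral minus (psi + 180), deg
    jumps = list(),                       # rigid_transform by jump number
    virtual = virtual,
    virtual_labels = character(0),        # label -> residue index (names)
    vr_com_chain = list(),                # label -> tracked chain id
    fold_tree = NULL,
    par = NULL,                           # cached ft_parents(fold_tree)
    xyz = NULL,
    xyz_valid = FALSE
  ), class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat("<conformation>", x$n_residues, "residues (",
      sum(x$virtual), "virtual ),", nrow(x$chains), "chain(s),",
      n_jumps(x$fold_tree), "jump(s)\n")
  invisible(x)
}

#' Build an ideal polypeptide
#'
#' Constructs a conformation with ideal bond lengths and angles, omega =
#' 180 degrees and torsions from a preset (`helix`: phi -57 / psi -47;
#' `strand`: -120 / 120; `extended`: 180 / 180) or an explicit list. Chains
#' get linear fold trees; multi-chain poses are connected by jumps from
#' residue 1 to the first residue of each later chain, with the chains laid
#' out 30 \enc{Å}{Angstrom} apart.
#'
#' @param n total residue count (>= 2).
#' @param chain_spec integer vector of chain lengths summing to `n`.
#' @param torsion_preset `"helix"`, `"strand"`, `"extended"`, or a list with
#'   numeric vectors `phi`, `psi` (and optionally `omega`) of length `n`.
#' @param chain_ids chain identifiers (single characters).
#' @return A `conformation` with a valid Cartesian cache.
#' @export
build_ideal_polypeptide <- function(n, chain_spec = n,
                                    torsion_preset = "extended",
                                    chain_ids = LETTERS[seq_along(chain_spec)]) {
  n <- as.integer(n)
  if (n < 2) stop("need at least 2 residues")
  chain_spec <- as.integer(chain_spec)
  if (any(chain_spec <= 0)) stop("non-positive chain length")
  if (sum(chain_spec) != n) stop("chain lengths must sum to n")
  ends <- cumsum(chain_spec)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  chains <- data.frame(chain_id = chain_ids[seq_along(chain_spec)],
                       start = starts, end = ends,
                       stringsAsFactors = FALSE)
  if (is.character(torsion_preset)) {
    ps <- TORSION_PRESETS[[match.arg(torsion_preset, names(TORSION_PRESETS))]]
    phi <- rep(ps["phi"], n); psi <- rep(ps["psi"], n)
    omega <- rep(IDEAL$omega, n)
  } else {
    phi <- as.numeric(torsion_preset$phi)
    psi <- as.numeric(torsion_preset$psi)
    omega <- if (!is.null(torsion_preset$omega))
      as.numeric(torsion_preset$omega) else rep(IDEAL$omega, n)
    stopifnot(length(phi) == n, length(psi) == n, length(omega) == n)
  }
  conf <- new_conformation(n, chains, unname(phi), unname(psi), unname(omega))
  # linear tree per chain, chains hung off residue 1 by jumps
  edges <- list()
  cuts <- integer(0)
  jumps <- list()
  jn <- 0L
  for (k in seq_len(nrow(chains))) {
    s <- starts[k]; e <- ends[k]
    if (k > 1) {
      jn <- jn + 1L
      edges[[length(edges) + 1]] <- data.frame(start = 1L, stop = s, label = jn)
      cuts <- c(cuts, s - 1L)
      jumps[[as.character(jn)]] <-
        rigid_transform(diag(3), c(30 * (k - 1), 0, 0))
    }
    if (e > s) edges[[length(edges) + 1]] <-
        data.frame(start = s, stop = e, label = -1L)
  }
  tree <- fold_tree(do.call(rbind, edges), root = 1L, cuts = cuts,
                    n_residues = n)
  conf$jumps <- jumps
  set_fold_tree(conf, tree)
}

# replace the fold tree (pre-broking plumbing; after broking the protected
# conformation refuses this). With keep_coords, jump transforms are measured
# from reference coordinates (default: the current cache) so every placed
# atom keeps its position; otherwise missing jumps default to identity.
set_fold_tree <- function(conf, tree, keep_coords = FALSE, ref_xyz = NULL) {
  viol <- validate_fold_tree(tree, conf$n_residues)
  if (length(viol)) {
    stop(fb_condition("foldbroker_tree_error",
                      paste("invalid fold tree:", paste(viol, collapse = "; "))))
  }
  old_xyz <- ref_xyz
  if (is.null(old_xyz) && keep_coords && isTRUE(conf$xyz_valid)) {
    old_xyz <- conf$xyz
  }
  if (!keep_coords) old_xyz <- NULL
  conf$fold_tree <- tree
  conf$par <- ft_parents(tree)
  jn <- tree$edges$label[tree$edges$label > 0]
  for (j in jn) {
    key <- as.character(j)
    if (!is.null(old_xyz)) {
      je <- jump_edge(tree, j)
      su <- stub_from_xyz(old_xyz, je$start)
      sd <- stub_from_xyz(old_xyz, je$stop)
      conf$jumps[[key]] <- rt_compose(rt_inverse(su), sd)
    } else if (is.null(conf$jumps[[key]])) {
      conf$jumps[[key]] <- rt_identity()
    }
  }
  conf$jumps <- conf$jumps[as.character(sort(jn))]
  refresh_cache(conf)
}

refresh_cache <- function(conf) {
  conf$xyz <- internal_to_cartesian(conf)
  conf$xyz_valid <- TRUE
  conf
}

#' Cartesian coordinates of a conformation
#'
#' @param conf a `conformation`.
#' @param real_only drop virtual residues from the result.
#' @return Numeric array `n x 4 x 3` (atoms N, CA, C, O).
#' @export
conf_xyz <- function(conf, real_only = FALSE) {
  x <- if (isTRUE(conf$xyz_valid)) conf$xyz else internal_to_cartesian(conf)
  if (real_only) x[!conf$virtual, , , drop = FALSE] else x
}

# flattened m x 3 matrix of real-atom coordinates
conf_real_atoms <- function(conf) {
  x <- conf_xyz(conf)[!conf$virtual, , , drop = FALSE]
  matrix(aperm(x, c(2, 1, 3)), ncol = 3)
}

chain_residues <- function(conf, chain_id) {
  row <- conf$chains[conf$chains$chain_id == chain_id, ]
  if (!nrow(row)) stop("unknown chain: ", chain_id)
  seq(row$start[1], row$end[1])
}

# local orthonormal stub frame of a residue: origin at CA, x towards C,
# y in the N-CA-C plane on the N side
stub_from_xyz <- function(xyz, i) {
  N <- xyz[i, 1, ]; CA <- xyz[i, 2, ]; C <- xyz[i, 3, ]
  x <- unit(C - CA)
  yraw <- (N - CA) - sum((N - CA) * x) * x
  y <- unit(yraw)
  z <- pracma_cross(x, y)
  rigid_transform(unname(cbind(x, y, z)), unname(CA))
}

residue_stub <- function(conf, i) stub_from_xyz(conf_xyz(conf), i)

# ---- internal -> Cartesian --------------------------------------------------

#' Convert internal coordinates to Cartesian coordinates
#'
#' Traverses the fold tree from its root. Within a peptide edge each atom is
#' placed from the three preceding atoms by bond length / planar angle /
#' torsion (natural chain extension, in the folding direction); across a
#' jump edge the downstream residue's stub frame equals the upstream stub
#' composed with the jump's rigid transform. Deterministic.
#'
#' @param conf a `conformation` with a valid fold tree.
#' @return Numeric array `n x 4 x 3` (atoms N, CA, C, O, \enc{Å}{Angstrom}).
#' @export
internal_to_cartesian <- function(conf) {
  n <- conf$n_residues
  par <- conf$par
  if (is.null(par)) par <- ft_parents(conf$fold_tree)
  xyz <- array(NA_real_, dim = c(n, 4, 3),
               dimnames = list(NULL, ATOMS, c("x", "y", "z")))
  L <- conf$lengths; A <- conf$angles
  phi <- conf$phi; psi <- conf$psi; omega <- conf$omega
  place_O <- function(r) {
    place_atom(xyz[r, 1, ], xyz[r, 2, ], xyz[r, 3, ],
               L$c_o[r], A$ca_c_o[r], psi[r] + 180 + conf$o_offset[r])
  }
  for (r in par$order) {
    switch(par$ptype[r],
      root = {
        th <- deg2rad(A$n_ca_c[r])
        xyz[r, 2, ] <- c(0, 0, 0)
        xyz[r, 3, ] <- c(L$ca_c[r], 0, 0)
        xyz[r, 1, ] <- L$n_ca[r] * c(cos(th), sin(th), 0)
      },
      pep_fwd = {
        p <- r - 1L
        xyz[r, 1, ] <- place_atom(xyz[p, 1, ], xyz[p, 2, ], xyz[p, 3, ],
                                  L$c_n[p], A$ca_c_n[p], psi[p])
        xyz[r, 2, ] <- place_atom(xyz[p, 2, ], xyz[p, 3, ], xyz[r, 1, ],
                                  L$n_ca[r], A$c_n_ca[p], omega[p])
        xyz[r, 3, ] <- place_atom(xyz[p, 3, ], xyz[r, 1, ], xyz[r, 2, ],
                                  L$ca_c[r], A$n_ca_c[r], phi[r])
      },
      pep_bwd = {
        p <- r + 1L
        xyz[r, 3, ] <- place_atom(xyz[p, 3, ], xyz[p, 2, ], xyz[p, 1, ],
                                  L$c_n[r], A$c_n_ca[r], phi[p])
        xyz[r, 2, ] <- place_atom(xyz[p, 2, ], xyz[p, 1, ], xyz[r, 3, ],
                                  L$ca_c[r], A$ca_c_n[r], omega[r])
        xyz[r, 1, ] <- place_atom(xyz[p, 1, ], xyz[r, 3, ], xyz[r, 2, ],
                                  L$n_ca[r], A$n_ca_c[r], psi[r])
      },
      jump = {
        up <- stub_from_xyz(xyz, par$parent[r])
        Tj <- conf$jumps[[as.character(par$pjump[r])]]
        if (is.null(Tj)) stop("missing transform for jump ", par$pjump[r])
        fr <- rt_compose(up, Tj)
        th <- deg2rad(A$n_ca_c[r])
        xyz[r, 2, ] <- fr$t
        xyz[r, 3, ] <- fr$t + fr$R %*% c(L$ca_c[r], 0, 0)
        xyz[r, 1, ] <- fr$t + fr$R %*% (L$n_ca[r] * c(cos(th), sin(th), 0))
      },
      stop("unplaced residue ", r)
    )
    xyz[r, 4, ] <- place_O(r)
  }
  xyz
}

# ---- Cartesian -> internal --------------------------------------------------

#' Measure internal coordinates from Cartesian coordinates
#'
#' Dihedrals, planar angles and bond lengths are measured from backbone
#' coordinates. Adjacency is honoured only within a chain; torsions that
#' span no physical bond (phi at a chain start; psi/omega at a chain end)
#' fall back to the O-derived psi where possible, otherwise to 180 degrees.
#' Round-trips with [internal_to_cartesian()].
#'
#' @param xyz numeric `n x 4 x 3` array (atoms N, CA, C, O).
#' @param chains data.frame with columns `chain_id`, `start`, `end`.
#' @return List with `phi`, `psi`, `omega` (degrees) and `lengths`,
#'   `angles` lists.
#' @export
cartesian_to_internal <- function(xyz, chains = NULL) {
  n <- dim(xyz)[1]
  if (any(!is.finite(xyz))) stop("missing atoms in coordinate array")
  if (is.null(chains)) chains <- data.frame(chain_id = "A", start = 1L, end = n)
  seg <- integer(n)
  for (k in seq_len(nrow(chains))) seg[chains$start[k]:chains$end[k]] <- k
  bonded <- function(i, j) i >= 1 && j <= n && seg[i] == seg[j] && seg[i] != 0
  phi <- rep(180, n); psi <- rep(180, n); omega <- rep(180, n)
  o_offset <- rep(0, n)
  L <- list(n_ca = numeric(n), ca_c = numeric(n), c_n = rep(IDEAL$c_n, n),
            c_o = numeric(n))
  A <- list(n_ca_c = numeric(n), ca_c_n = rep(IDEAL$ca_c_n, n),
            c_n_ca = rep(IDEAL$c_n_ca, n), ca_c_o = numeric(n))
  for (i in seq_len(n)) {
    N <- xyz[i, 1, ]; CA <- xyz[i, 2, ]; C <- xyz[i, 3, ]; O <- xyz[i, 4, ]
    L$n_ca[i] <- vnorm(CA - N)
    L$ca_c[i] <- vnorm(C - CA)
    L$c_o[i] <- vnorm(O - C)
    A$n_ca_c[i] <- angle3(N, CA, C)
    A$ca_c_o[i] <- angle3(CA, C, O)
    o_dih <- dihedral4(N, CA, C, O)
    psi[i] <- wrap180(o_dih - 180)  # O-derived fallback at chain ends
    if (bonded(i, i + 1)) {
      N2 <- xyz[i + 1, 1, ]; CA2 <- xyz[i + 1, 2, ]
      L$c_n[i] <- vnorm(N2 - C)
      A$ca_c_n[i] <- angle3(CA, C, N2)
      A$c_n_ca[i] <- angle3(C, N2, CA2)
      psi[i] <- dihedral4(N, CA, C, N2)
      omega[i] <- dihedral4(CA, C, N2, CA2)
    }
    o_offset[i] <- wrap180(o_dih - psi[i] - 180)
    if (bonded(i - 1, i)) {
      phi[i] <- dihedral4(xyz[i - 1, 3, ], N, CA, C)
    }
  }
  list(phi = phi, psi = psi, omega = omega, o_offset = o_offset,
       lengths = L, angles = A)
}

wrap180 <- function(x) ((x + 180) %% 360) - 180

#' Rebuild a conformation from Cartesian coordinates
#'
#' Convenience wrapper around [cartesian_to_internal()] producing a full
#' `conformation` with linear per-chain fold trees.
#'
#' @param xyz numeric `n x 4 x 3` array.
#' @param chains data.frame with `chain_id`, `start`, `end` (default: one
#'   chain).
#' @return A `conformation`.
#' @export
conformation_from_xyz <- function(xyz, chains = NULL) {
  n <- dim(xyz)[1]
  if (is.null(chains)) chains <- data.frame(chain_id = "A", start = 1L, end = n,
                                            stringsAsFactors = FALSE)
  ic <- cartesian_to_internal(xyz, chains)
  conf <- new_conformation(n, chains, ic$phi, ic$psi, ic$omega)
  conf$lengths <- ic$lengths
  conf$angles <- ic$angles
  conf$o_offset <- ic$o_offset
  # linear tree per chain with connecting jumps, as in build_ideal_polypeptide
  edges <- list(); cuts <- integer(0); jn <- 0L
  for (k in seq_len(nrow(chains))) {
    s <- chains$start[k]; e <- chains$end[k]
    if (k > 1) {
      jn <- jn + 1L
      edges[[length(edges) + 1]] <- data.frame(start = 1L, stop = s, label = jn)
      cuts <- c(cuts, s - 1L)
    }
    if (e > s) edges[[length(edges) + 1]] <-
        data.frame(start = s, stop = e, label = -1L)
  }
  tree <- fold_tree(do.call(rbind, edges), root = 1L, cuts = cuts,
                    n_residues = n)
  conf$fold_tree <- tree
  conf$par <- ft_parents(tree)
  # measure jump transforms from the input coordinates so they are preserved
  for (j in seq_len(jn)) {
    je <- jump_edge(tree, j)
    conf$jumps[[as.character(j)]] <-
      rt_compose(rt_inverse(stub_from_xyz(xyz, je$start)),
                 stub_from_xyz(xyz, je$stop))
  }
  refresh_cache(conf)
}

# ---- DoF access -------------------------------------------------------------

#' Read a degree of freedom
#' @param conf a `conformation`.
#' @param dof DoF id string.
#' @return Torsion in degrees, or one rigid-body component.
#' @export
get_dof <- function(conf, dof) {
  d <- dof_parse(dof)
  if (d$kind == "jump") {
    Tj <- conf$jumps[[as.character(d$jump)]]
    if (is.null(Tj)) stop("unknown jump: ", d$jump)
    return(rt_to_rb(Tj)[d$rb])
  }
  if (d$residue < 1 || d$residue > conf$n_residues) stop("unknown DoF: ", dof)
  conf[[d$kind]][d$residue]
}

#' Set a degree of freedom
#'
#' Changes one scalar DoF and refreshes the Cartesian cache. Only atoms
#' downstream of the DoF in the fold tree move; upstream atoms are
#' bit-identical (the traversal recomputes them from unchanged inputs).
#'
#' @param conf a `conformation`.
#' @param dof DoF id string.
#' @param value new torsion (degrees) or rigid-body component.
#' @return The updated `conformation`.
#' @export
set_dof <- function(conf, dof, value) {
  d <- dof_parse(dof)
  if (d$kind == "jump") {
    key <- as.character(d$jump)
    Tj <- conf$jumps[[key]]
    if (is.null(Tj)) stop("unknown jump: ", d$jump)
    rb <- rt_to_rb(Tj)
    rb[d$rb] <- value
    conf$jumps[[key]] <- rb_to_rt(rb)
  } else {
    if (d$residue < 1 || d$residue > conf$n_residues) stop("unknown DoF: ", dof)
    conf[[d$kind]][d$residue] <- value
  }
  refresh_cache(conf)
}

#' Set several degrees of freedom at once
#'
#' Batch form of [set_dof()]: assigns all values, then refreshes the
#' Cartesian cache once.
#'
#' @param conf a `conformation`.
#' @param dofs character vector of DoF ids.
#' @param values numeric vector of the same length.
#' @return The updated `conformation`.
#' @export
set_dofs <- function(conf, dofs, values) {
  stopifnot(length(dofs) == length(values))
  for (k in seq_along(dofs)) {
    d <- dof_parse(dofs[k])
    if (d$kind == "jump") {
      key <- as.character(d$jump)
      Tj <- conf$jumps[[key]]
      if (is.null(Tj)) stop("unknown jump: ", d$jump)
      rb <- rt_to_rb(Tj)
      rb[d$rb] <- values[k]
      conf$jumps[[key]] <- rb_to_rt(rb)
    } else {
      if (d$residue < 1 || d$residue > conf$n_residues) {
        stop("unknown DoF: ", dofs[k])
      }
      conf[[d$kind]][d$residue] <- values[k]
    }
  }
  refresh_cache(conf)
}

#' Set a jump's full rigid transform
#' @param conf a `conformation`.
#' @param jump_number jump number on the fold tree.
#' @param transform a `rigid_transform`.
#' @return The updated `conformation`.
#' @export
set_jump <- function(conf, jump_number, transform) {
  key <- as.character(jump_number)
  if (is.null(conf$jumps[[key]])) stop("unknown jump: ", jump_number)
  stopifnot(inherits(transform, "rigid_transform"))
  conf$jumps[[key]] <- transform
  refresh_cache(conf)
}

#' Stub-to-stub transform of a jump
#'
#' Measured from the current Cartesian coordinates; immediately after
#' [set_jump()] this returns the stored transform, and it is invariant under
#' torsion changes at residues other than the two stub residues.
#'
#' @param conf a `conformation`.
#' @param jump_number jump number.
#' @return A `rigid_transform`.
#' @export
jump_transform <- function(conf, jump_number) {
  je <- jump_edge(conf$fold_tree, jump_number)
  xyz <- conf_xyz(conf)
  rt_compose(rt_inverse(stub_from_xyz(xyz, je$start)),
             stub_from_xyz(xyz, je$stop))
}

# ---- chainbreak -------------------------------------------------------------

#' Deviation of the virtual peptide bond across a cut
#'
#' Cuts must be repaired for a model to be physically meaningful. Returns
#' the absolute deviation of the C(i)-N(i+1) pseudo-bond from the ideal
#' peptide geometry: bond length, and the two flanking planar angles.
#'
#' @param conf a `conformation`.
#' @param cut_position a cut recorded on the fold tree.
#' @return List with `dist` (\enc{Å}{Angstrom}) and `angles` (two absolute
#'   angle deviations, degrees).
#' @export
chainbreak_deviation <- function(conf, cut_position) {
  i <- as.integer(cut_position)
  if (!(i %in% conf$fold_tree$cuts)) {
    stop("position ", i, " is not a cut on the fold tree")
  }
  xyz <- conf_xyz(conf)
  C <- xyz[i, 3, ]; CA <- xyz[i, 2, ]
  N2 <- xyz[i + 1, 1, ]; CA2 <- xyz[i + 1, 2, ]
  list(
    dist = abs(vnorm(N2 - C) - conf$lengths$c_n[i]),
    angles = c(abs(angle3(CA, C, N2) - conf$angles$ca_c_n[i]),
               abs(angle3(C, N2, CA2) - conf$angles$c_n_ca[i]))
  )
}

# ---- virtual residues -------------------------------------------------------

# Append a coordinate-frame-only residue. It carries pseudo backbone atoms
# for its stub but is excluded from real-atom queries.
append_virtual_residue <- function(conf, label) {
  n <- conf$n_residues + 1L
  conf$n_residues <- n
  for (f in c("phi", "psi", "omega")) conf[[f]] <- c(conf[[f]], 180)
  conf$o_offset <- c(conf$o_offset, 0)
  conf$lengths <- lapply(stats::setNames(names(conf$lengths), names(conf$lengths)),
                         function(nm) c(conf$lengths[[nm]], IDEAL[[nm]]))
  conf$angles <- lapply(stats::setNames(names(conf$angles), names(conf$angles)),
                        function(nm) c(conf$angles[[nm]], IDEAL[[nm]]))
  conf$virtual <- c(conf$virtual, TRUE)
  vl <- conf$virtual_labels
  vl[label] <- n
  conf$virtual_labels <- vl
  conf$xyz_valid <- FALSE
  conf
}

#' Residue index of a labelled virtual residue
#' @param conf a `conformation`.
#' @param label virtual-residue label assigned at claim time.
#' @return Integer residue index.
#' @export
virtual_residue_index <- function(conf, label) {
  i <- conf$virtual_labels[label]
  if (is.na(i)) stop("unknown virtual residue label: ", label)
  as.integer(i)
}

#' Backbone centre of mass of a chain
#'
#' Unweighted mean of the chain's backbone atom coordinates.
#'
#' @param conf a `conformation`.
#' @param chain_id chain identifier.
#' @return Length-3 numeric vector.
#' @export
chain_com <- function(conf, chain_id) {
  rs <- chain_residues(conf, chain_id)
  if (!length(rs)) stop("chain empty: ", chain_id)
  x <- conf_xyz(conf)[rs, , , drop = FALSE]
  colMeans(matrix(aperm(x, c(2, 1, 3)), ncol = 3))
}
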