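# The broker. Collects claims from registered client movers, expands them to
# elements in phases (sequence changes, then fold-tree topology, then DoF
# accessibility), builds the single consensus fold tree satisfying all
# claims — or fails with a named conflict before any sampling begins — and
# issues per-client passports over a protected conformation.

#' Create a broker
#'
#' @return A broker object (mutable). Register clients with
#'   [register_client()] and execute broking with [broke()].
#' @export
broker_new <- function() {
  b <- new.env(parent = emptyenv())
  b$clients <- list()
  b$broked <- FALSE
  class(b) <- "broker"
  b
}

#' @export
print.broker <- function(x, ...) {
  cat("<broker>", length(x$clients), "client(s),",
      if (x$broked) "broked" else "not yet broked", "\n")
  invisible(x)
}

#' Register a client mover
#'
#' Clients can be registered in any number and any order, but only until
#' broking is executed.
#'
#' @param broker a broker from [broker_new()].
#' @param client a client mover (see [client_mover()]).
#' @return The broker, invisibly.
#' @export
register_client <- function(broker, client) {
  if (broker$broked) {
    stop(fb_condition("foldbroker_registration_error",
                      "cannot register clients after broking"))
  }
  nm <- client$name
  if (is.null(nm) || !nzchar(nm)) stop("client must have a name")
  if (nm %in% vapply(broker$clients, function(c) c$name, "")) {
    stop(fb_condition("foldbroker_registration_error",
                      paste0("duplicate client: ", nm)))
  }
  broker$clients[[length(broker$clients) + 1]] <- client
  invisible(broker)
}

# order-independent, seed-stable 31-bit stream seed from a string
derive_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

#' Resolve DoF access from competing claims
#'
#' Applies the control-strength matrix pairwise over all claimants of each
#' DoF: two EXCLUSIVE claims, or EXCLUSIVE against MUST_CONTROL, are an
#' unsatisfiable conflict (broking fails, naming both movers and the DoF);
#' EXCLUSIVE against CAN_CONTROL demotes the CAN claimant; DOES_NOT_CONTROL
#' is never granted; in all other cases both claimants receive access.
#'
#' @param dof_elements list of DoF elements (owner, dof id, strength).
#' @return data.frame with columns `owner`, `dof`: the granted pairs.
#' @export
resolve_access <- function(dof_elements) {
  if (!length(dof_elements)) {
    return(data.frame(owner = character(0), dof = character(0),
                      stringsAsFactors = FALSE))
  }
  owner <- vapply(dof_elements, function(e) e$owner, "")
  dof <- vapply(dof_elements, function(e) e$dof, "")
  strength <- vapply(dof_elements, function(e) e$strength, "")
  # one effective strength per (owner, dof): the strongest
  rank <- control_rank(strength)
  ord <- order(dof, owner, -rank)
  owner <- owner[ord]; dof <- dof[ord]; strength <- strength[ord]
  keep <- !duplicated(paste0(owner, "\r", dof))
  owner <- owner[keep]; dof <- dof[keep]; strength <- strength[keep]
  # pairwise conflicts, applied per DoF across all claimants
  is_excl <- strength == "EXCLUSIVE"
  excl_dofs <- dof[is_excl]
  dup <- excl_dofs[duplicated(excl_dofs)]
  if (length(dup)) {
    d <- dup[1]
    both <- owner[is_excl & dof == d]
    stop(fb_condition("foldbroker_conflict_error", sprintf(
      "broking failed: movers '%s' and '%s' both claim EXCLUSIVE control of DoF %s",
      both[1], both[2], d)))
  }
  is_must <- strength == "MUST_CONTROL"
  clash <- intersect(excl_dofs, dof[is_must])
  if (length(clash)) {
    d <- clash[1]
    stop(fb_condition("foldbroker_conflict_error", sprintf(
      "broking failed: mover '%s' claims EXCLUSIVE and mover '%s' claims MUST_CONTROL of DoF %s",
      owner[is_excl & dof == d][1], owner[is_must & dof == d][1], d)))
  }
  # a single EXCLUSIVE claimant demotes every CAN claimant of the same DoF;
  # DOES_NOT_CONTROL is never granted
  has_excl <- dof %in% excl_dofs
  granted <- strength != "DOES_NOT_CONTROL" & (!has_excl | is_excl)
  out <- data.frame(owner = owner[granted], dof = dof[granted],
                    stringsAsFactors = FALSE)
  out <- out[order(out$dof, out$owner), ]
  rownames(out) <- NULL
  out
}

#' Build the consensus fold tree
#'
#' Places all claimed jumps, breaks each cycle a jump creates with one cut
#' drawn uniformly from the legal positions on the cycle (honouring
#' forbidden intervals and fixed cut positions from cut elements, and a
#' jump's preferred cut region when it is satisfiable), connects any
#' remaining disconnected segment to the root by an additional jump, and
#' orients the result from the root. Cut draws use R's global RNG in
#' canonical jump order, so the tree is reproducible per seed and
#' independent of claim arrival order.
#'
#' @param jump_elements list of jump elements (canonicalised anchors).
#' @param cut_elements list of cut elements.
#' @param n_residues total residue count (including virtual residues).
#' @param segments list of `c(start, end)` contiguous peptide segments;
#'   residues outside any segment (virtual residues) are isolated vertices.
#' @param root root residue.
#' @return A list: `tree` (the `fold_tree`) and `jump_numbers` (data.frame
#'   mapping anchor pairs to jump numbers).
#' @export
build_consensus_tree <- function(jump_elements, cut_elements, n_residues,
                                 segments, root = 1L) {
  n <- as.integer(n_residues)
  bond <- rep(FALSE, max(n - 1, 0))
  for (s in segments) {
    if (s[2] > s[1]) bond[seq(s[1], s[2] - 1)] <- TRUE
  }
  forbidden <- integer(0)
  forbid_owner <- character(0)
  cuts <- which(!bond)  # segment boundaries count as cuts
  for (ce in cut_elements) {
    for (iv in ce$forbidden) {
      pos <- seq(iv[1], iv[2])
      forbidden <- c(forbidden, pos)
      forbid_owner <- c(forbid_owner, rep(ce$owner, length(pos)))
    }
    if (!is.null(ce$fixed)) {
      p <- as.integer(ce$fixed)
      if (p >= 1 && p < n && bond[p]) {
        bond[p] <- FALSE
        cuts <- c(cuts, p)
      }
    }
  }
  # canonical jump order: by (a, b); merge duplicates (same anchor pair)
  if (length(jump_elements)) {
    key <- vapply(jump_elements, function(e) sprintf("%09d:%09d", e$a, e$b), "")
    ord <- order(key)
    jump_elements <- jump_elements[ord]
    key <- key[ord]
    keep <- !duplicated(key)
    merged <- jump_elements[keep]
    # merged element keeps any fixed_geometry flag / cut preference present
    for (i in which(!keep)) {
      j <- match(key[i], key[keep])
      if (isTRUE(jump_elements[[i]]$fixed_geometry)) merged[[j]]$fixed_geometry <- TRUE
      if (is.null(merged[[j]]$cut_preference)) {
        merged[[j]]$cut_preference <- jump_elements[[i]]$cut_preference
      }
    }
    jump_elements <- merged
  }
  # adjacency for path finding: peptide bonds + accepted jump edges
  adj <- vector("list", n)
  add_edge <- function(u, v) {
    adj[[u]] <<- c(adj[[u]], v)
    adj[[v]] <<- c(adj[[v]], u)
  }
  for (i in which(bond)) add_edge(i, i + 1L)
  find_path <- function(a, b) {
    # BFS; returns vertex path a..b or NULL
    prev <- rep(NA_integer_, n)
    prev[a] <- a
    q <- a
    while (length(q)) {
      u <- q[[1]]; q <- q[-1]
      if (u == b) break
      for (v in adj[[u]]) if (is.na(prev[v])) { prev[v] <- u; q <- c(q, v) }
    }
    if (is.na(prev[b])) return(NULL)
    path <- b
    while (path[1] != a) path <- c(prev[path[1]], path)
    path
  }
  jump_tab <- data.frame(number = integer(0), a = integer(0), b = integer(0),
                         fixed_geometry = logical(0))
  jn <- 0L
  for (je in jump_elements) {
    a <- je$a; b <- je$b
    if (a == b) stop("jump anchors are identical: residue ", a)
    jn <- jn + 1L
    path <- find_path(a, b)
    if (!is.null(path)) {
      # jump closes a cycle: break one peptide bond on the path
      bonds_on_path <- integer(0)
      for (k in seq_len(length(path) - 1)) {
        u <- path[k]; v <- path[k + 1]
        if (abs(u - v) == 1) {
          p <- min(u, v)
          if (bond[p]) bonds_on_path <- c(bonds_on_path, p)
        }
      }
      allowed <- setdiff(bonds_on_path, forbidden)
      if (!length(allowed)) {
        owners <- unique(forbid_owner[forbid_owner != "" &
                                        forbidden %in% bonds_on_path])
        stop(fb_condition("foldbroker_no_cut_error", sprintf(
          "no legal cutpoint for jump %d<->%d: cycle interval [%d,%d] fully forbidden%s",
          a, b, min(bonds_on_path), max(bonds_on_path),
          if (length(owners)) paste0(" (forbidding claims from: ",
                                     paste(owners, collapse = ", "), ")")
          else "")))
      }
      pref <- je$cut_preference
      if (!is.null(pref)) {
        pin <- allowed[allowed >= pref[1] & allowed <= pref[2]]
        if (length(pin)) allowed <- pin
      }
      cutpos <- if (length(allowed) == 1) allowed else
        allowed[sample.int(length(allowed), 1)]
      bond[cutpos] <- FALSE
      cuts <- c(cuts, cutpos)
      # remove bond from adjacency
      adj[[cutpos]] <- setdiff(adj[[cutpos]], cutpos + 1L)
      adj[[cutpos + 1L]] <- setdiff(adj[[cutpos + 1L]], cutpos)
    }
    add_edge(a, b)
    jump_tab <- rbind(jump_tab, data.frame(
      number = jn, a = a, b = b,
      fixed_geometry = isTRUE(je$fixed_geometry)))
  }
  # connect any components not reachable from the root with extra jumps
  repeat {
    reach <- rep(FALSE, n)
    q <- root
    reach[root] <- TRUE
    while (length(q)) {
      u <- q[[1]]; q <- q[-1]
      for (v in adj[[u]]) if (!reach[v]) { reach[v] <- TRUE; q <- c(q, v) }
    }
    if (all(reach)) break
    tgt <- which(!reach)[1]
    jn <- jn + 1L
    add_edge(root, tgt)
    jump_tab <- rbind(jump_tab, data.frame(
      number = jn, a = min(root, tgt), b = max(root, tgt),
      fixed_geometry = FALSE))
  }
  # orient from the root: BFS assigning parents, then compress runs
  prev <- rep(NA_integer_, n)
  via_jump <- rep(NA_integer_, n)
  prev[root] <- 0L
  q <- root
  while (length(q)) {
    u <- q[[1]]; q <- q[-1]
    for (v in adj[[u]]) {
      if (!is.na(prev[v])) next
      prev[v] <- u
      if (abs(u - v) != 1 || !bond[min(u, v)]) {
        jrow <- which((jump_tab$a == min(u, v)) & (jump_tab$b == max(u, v)))
        via_jump[v] <- jump_tab$number[jrow[1]]
      }
      q <- c(q, v)
    }
  }
  edges <- list()
  # jump edges oriented by BFS
  for (v in which(!is.na(via_jump))) {
    edges[[length(edges) + 1]] <- data.frame(start = prev[v], stop = v,
                                             label = via_jump[v])
  }
  # peptide runs: group consecutive bonds with the same orientation
  if (n > 1) {
    orient <- rep(NA_integer_, n - 1)  # +1 fwd, -1 bwd at bond i (i,i+1)
    for (i in seq_len(n - 1)) {
      if (!bond[i]) next
      orient[i] <- if (!is.na(prev[i + 1]) && prev[i + 1] == i) 1L else -1L
    }
    i <- 1L
    while (i <= n - 1) {
      if (is.na(orient[i])) { i <- i + 1L; next }
      j <- i
      while (j < n - 1 && !is.na(orient[j + 1]) && orient[j + 1] == orient[i]) {
        j <- j + 1L
      }
      if (orient[i] > 0) {
        edges[[length(edges) + 1]] <- data.frame(start = i, stop = j + 1L,
                                                 label = -1L)
      } else {
        edges[[length(edges) + 1]] <- data.frame(start = j + 1L, stop = i,
                                                 label = -1L)
      }
      i <- j + 1L
    }
  }
  tree <- fold_tree(do.call(rbind, edges), root = root,
                    cuts = sort(unique(cuts)), n_residues = n)
  list(tree = tree, jump_numbers = jump_tab)
}

#' Execute broking
#'
#' Runs the brokered phases in order: sequence changes (virtual residues are
#' appended to the conformation, in claim order), fold-tree topology (jumps
#' and cuts, via [build_consensus_tree()]), then DoF accessibility
#' ([resolve_access()]). After each phase the clients' claims are informed
#' of resolved indices (virtual-residue positions, then jump numbers)
#' through each client's configure hook. On success the conformation is
#' wrapped in a protected conformation and per-client passports are issued;
#' on any conflict broking fails before any sampling begins, no passports
#' are issued, and the input conformation is unmodified.
#'
#' @param broker a broker with registered clients.
#' @param conformation the starting `conformation`.
#' @param seed integer seed controlling randomized cut placement and each
#'   client's claim-time draws (each client gets an independent stream
#'   derived from its name, so broking is registration-order independent).
#' @return A `broker_result`: list with `pconf` (protected conformation),
#'   `tree`, `passports` (by client name), `virtuals` (label -> residue),
#'   `jump_numbers`, `grants`.
#' @export
broke <- function(broker, conformation, seed = 0L) {
  if (broker$broked) stop("broker has already run")
  conf <- conformation
  clients <- broker$clients
  names(clients) <- vapply(clients, function(c) c$name, "")
  # claim collection: per-client RNG stream keyed by name, not by position
  claims <- list()
  for (cl in clients) {
    set.seed(derive_seed(seed, paste0("claims:", cl$name)))
    cc <- yield_claims(cl, conf)
    for (c1 in cc) {
      c1$owner <- cl$name
      claims[[length(claims) + 1]] <- c1
    }
  }
  # phase 1: sequence changes
  vr_claims <- Filter(function(c) c$type == "virtual_residue", claims)
  root <- 1L
  for (vc in vr_claims) {
    conf <- append_virtual_residue(conf, vc$label)
    if (identical(vc$attach, "com")) {
      if (is.null(vc$chain)) stop("com virtual residue needs a chain")
      conf$vr_com_chain[[vc$label]] <- vc$chain
    }
    if (identical(vc$attach, "root")) {
      root <- virtual_residue_index(conf, vc$label)
    }
  }
  # phase 2 + 3: expand remaining claims against the extended conformation
  elements <- list()
  for (c1 in Filter(function(c) c$type != "virtual_residue", claims)) {
    els <- expand_claim(c1, conf, owner = c1$owner)
    elements <- c(elements, els)
  }
  etypes <- vapply(elements, function(e) e$etype, "")
  segments <- lapply(seq_len(nrow(conf$chains)), function(k)
    c(conf$chains$start[k], conf$chains$end[k]))
  set.seed(derive_seed(seed, "cuts"))
  built <- build_consensus_tree(elements[etypes == "jump"],
                                elements[etypes == "cut"],
                                conf$n_residues, segments, root = root)
  tree <- built$tree
  jtab <- built$jump_numbers
  # phase 3: assign jump numbers to jump DoF elements, then resolve access
  dof_elements <- elements[etypes == "dof"]
  for (e in elements[etypes == "dof_jump"]) {
    jrow <- which(jtab$a == e$a & jtab$b == e$b)
    stopifnot(length(jrow) == 1)
    dof_elements[[length(dof_elements) + 1]] <-
      element_dof(e$owner, dof_jump_rb(jtab$number[jrow], e$rb), e$strength)
  }
  grants <- resolve_access(dof_elements)
  round_id <- paste0("broking-", seed, "-",
                     paste(sample.int(1e6, 2), collapse = "."))
  passports <- lapply(clients, function(cl) {
    new_passport(cl$name, grants$dof[grants$owner == cl$name], round_id)
  })
  # initialise virtual residue frames, then adopt the consensus tree while
  # preserving every real atom's position
  ref_xyz <- virtual_reference_xyz(conf)
  conf <- set_fold_tree(conf, tree, keep_coords = TRUE, ref_xyz = ref_xyz)
  pconf <- new_protected_conformation(conf, tree, round_id, grants)
  result <- structure(list(
    pconf = pconf, tree = tree, passports = passports,
    virtuals = conf$virtual_labels, jump_numbers = jtab,
    grants = grants, seed = seed
  ), class = "broker_result")
  broker$broked <- TRUE
  # communicate brokered results back to the clients
  for (cl in clients) client_configure(cl, result)
  # post-broking initialize pass (rigid chunks set template DoFs here)
  for (cl in clients) client_initialize(cl, pconf)
  result
}

# reference coordinates for re-treeing: real residues keep their current
# positions; virtual residues get identity-orientation frames at the origin
# (root) or at the tracked chain's centre of mass (com)
virtual_reference_xyz <- function(conf) {
  n <- conf$n_residues
  xyz <- array(NA_real_, dim = c(n, 4, 3))
  nreal <- sum(!conf$virtual)
  old <- conf_xyz_partial(conf)
  xyz[!conf$virtual, , ] <- old
  if (any(conf$virtual)) {
    for (lb in names(conf$virtual_labels)) {
      r <- virtual_residue_index(conf, lb)
      origin <- c(0, 0, 0)
      com_chain <- conf$vr_com_chain[[lb]]
      if (!is.null(com_chain)) origin <- chain_com_xyz(old, com_chain, conf)
      xyz[r, , ] <- frame_pseudo_atoms(origin, diag(3), conf, r)
    }
  }
  xyz
}

# helpers for virtual_reference_xyz ------------------------------------------

# coordinates of the real residues under the *current* (pre-consensus) tree,
# which spans only the real residues
conf_xyz_partial <- function(conf) {
  sub <- conf
  keep <- !conf$virtual
  sub$n_residues <- sum(keep)
  for (f in c("phi", "psi", "omega", "o_offset", "virtual")) {
    sub[[f]] <- conf[[f]][keep]
  }
  sub$lengths <- lapply(conf$lengths, `[`, keep)
  sub$angles <- lapply(conf$angles, `[`, keep)
  sub$par <- ft_parents(conf$fold_tree)
  internal_to_cartesian(sub)
}

chain_com_xyz <- function(xyz, chain_id, conf) {
  row <- conf$chains[conf$chains$chain_id == chain_id, ]
  if (!nrow(row)) stop("unknown chain for CoM attachment: ", chain_id)
  rs <- seq(row$start[1], row$end[1])
  colMeans(matrix(aperm(xyz[rs, , , drop = FALSE], c(2, 1, 3)), ncol = 3))
}

# pseudo backbone atoms realising a stub frame (origin at CA)
frame_pseudo_atoms <- function(origin, R, conf, r) {
  th <- deg2rad(conf$angles$n_ca_c[r])
  CA <- origin
  C <- origin + R %*% c(conf$lengths$ca_c[r], 0, 0)
  N <- origin + R %*% (conf$lengths$n_ca[r] * c(cos(th), sin(th), 0))
  O <- place_atom(as.numeric(N), as.numeric(CA), as.numeric(C),
                  conf$lengths$c_o[r], conf$angles$ca_c_o[r],
                  conf$psi[r] + 180)
  rbind(as.numeric(N), as.numeric(CA), as.numeric(C), as.numeric(O))
}
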