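# The fold tree: a directed, rooted, acyclic graph over residues that fixes
# the direction in which internal-coordinate changes propagate into Cartesian
# space. Peptide edges follow the chain (in either direction); jump edges set
# the rigid-body relationship between two residues directly; every cycle a
# jump would create is broken by a cut.

#' Construct a fold tree
#'
#' @param edges data.frame with columns `start`, `stop`, `label`; `label` is
#'   `-1` for a peptide edge (covering residues `start..stop` folded from
#'   `start` towards `stop`) or a positive jump number.
#' @param root residue index at which coordinate propagation starts.
#' @param cuts integer vector: a cut at `i` means the i -> i+1 peptide
#'   adjacency is broken (chain boundaries are recorded here too).
#' @param n_residues total number of residues the tree spans.
#' @return An object of class `fold_tree`.
#' @export
fold_tree <- function(edges, root = 1L, cuts = integer(0), n_residues) {
  edges <- as.data.frame(edges)
  stopifnot(all(c("start", "stop", "label") %in% names(edges)))
  edges$start <- as.integer(edges$start)
  edges$stop <- as.integer(edges$stop)
  edges$label <- as.integer(edges$label)
  edges <- ft_sort_edges(edges)
  structure(list(edges = edges, root = as.integer(root),
                 cuts = sort(unique(as.integer(cuts))),
                 n_residues = as.integer(n_residues)),
            class = "fold_tree")
}

# deterministic edge ordering: peptide edges by start, then jumps by number
ft_sort_edges <- function(edges) {
  pep <- edges[edges$label < 0, , drop = FALSE]
  jmp <- edges[edges$label > 0, , drop = FALSE]
  pep <- pep[order(pep$start, pep$stop), , drop = FALSE]
  jmp <- jmp[order(jmp$label), , drop = FALSE]
  out <- rbind(pep, jmp)
  rownames(out) <- NULL
  out
}

#' Linear fold tree over one chain
#'
#' @param n number of residues.
#' @param root root residue (default 1).
#' @return A `fold_tree` with a single peptide edge (or two, if the root is
#'   internal).
#' @export
linear_fold_tree <- function(n, root = 1L) {
  root <- as.integer(root)
  ed <- list()
  if (root > 1) ed[[length(ed) + 1]] <- data.frame(start = root, stop = 1L, label = -1L)
  if (root < n) ed[[length(ed) + 1]] <- data.frame(start = root, stop = n, label = -1L)
  if (n == 1) ed[[1]] <- data.frame(start = 1L, stop = 1L, label = -1L)[0, ]
  edges <- if (length(ed)) do.call(rbind, ed) else
    data.frame(start = integer(0), stop = integer(0), label = integer(0))
  fold_tree(edges, root = root, cuts = integer(0), n_residues = n)
}

#' @export
print.fold_tree <- function(x, ...) {
  cat("<fold_tree>", x$n_residues, "residues, root", x$root, "\n")
  cat(serialize_fold_tree(x))
  invisible(x)
}

#' Number of jump edges on a fold tree
#' @param tree a `fold_tree`.
#' @return Integer count of jump edges.
#' @export
n_jumps <- function(tree) sum(tree$edges$label > 0)

jump_edge <- function(tree, jump_number) {
  i <- which(tree$edges$label == jump_number)
  if (length(i) != 1) stop("unknown jump number: ", jump_number)
  tree$edges[i, ]
}

#' Validate a fold tree
#'
#' Checks the structural invariants: full residue coverage, connectivity,
#' acyclicity (exactly one propagation path reaches each residue), a single
#' root, consecutive jump numbering from 1, and consistency of the recorded
#' cuts with the peptide edges (every broken adjacency is balanced by a jump:
#' `length(cuts) == n_jumps`). Violations are returned, never raised.
#'
#' @param tree a `fold_tree`.
#' @param n_residues expected residue count.
#' @return Character vector of violation messages; `character(0)` if valid.
#' @export
validate_fold_tree <- function(tree, n_residues = tree$n_residues) {
  v <- character(0)
  ed <- tree$edges
  if (tree$n_residues != n_residues) {
    v <- c(v, sprintf("tree spans %d residues, expected %d",
                      tree$n_residues, n_residues))
  }
  if (tree$root < 1 || tree$root > n_residues) {
    v <- c(v, "root outside residue range")
  }
  jn <- sort(ed$label[ed$label > 0])
  if (length(jn) && !identical(jn, seq_along(jn))) {
    v <- c(v, "jump numbers not consecutive from 1")
  }
  if (anyDuplicated(ed$label[ed$label > 0])) {
    v <- c(v, "duplicate jump numbers")
  }
  # expand to unit steps and count incoming paths per residue
  parent <- rep(NA_integer_, n_residues)
  seen <- rep(FALSE, n_residues)
  seen[tree$root] <- TRUE
  multi <- FALSE
  oob <- FALSE
  step <- function(from, to) {
    if (to < 1 || to > n_residues || from < 1 || from > n_residues) {
      oob <<- TRUE
      return()
    }
    if (seen[to]) multi <<- TRUE
    seen[to] <<- TRUE
    parent[to] <<- from
  }
  for (k in seq_len(nrow(ed))) {
    s <- ed$start[k]; e <- ed$stop[k]
    if (ed$label[k] < 0) {
      if (s == e) next
      dir <- sign(e - s)
      for (r in seq(s, e - dir, by = dir)) step(r, r + dir)
    } else {
      step(s, e)
    }
  }
  if (oob) v <- c(v, "edge references residue outside range")
  if (multi) {
    v <- c(v, "cycle: multiple propagation paths reach a residue")
  }
  if (!all(seen)) {
    v <- c(v, sprintf("residues not covered: %s",
                      paste(utils::head(which(!seen), 5), collapse = ",")))
  }
  # edge starts must themselves be reachable (single rooted component)
  starts <- unique(ed$start)
  if (!oob && length(starts) && !all(seen[starts])) {
    v <- c(v, "multiple roots: edge starts from an unreached residue")
  }
  # cuts consistent: adjacency i,i+1 must be covered by a peptide edge
  # exactly when i is not a cut
  if (!oob && n_residues > 1) {
    covered <- rep(FALSE, n_residues - 1)
    for (k in seq_len(nrow(ed))) {
      if (ed$label[k] < 0 && ed$start[k] != ed$stop[k]) {
        rng <- seq(min(ed$start[k], ed$stop[k]),
                   max(ed$start[k], ed$stop[k]) - 1)
        covered[rng] <- TRUE
      }
    }
    declared <- rep(FALSE, n_residues - 1)
    declared[tree$cuts[tree$cuts >= 1 & tree$cuts < n_residues]] <- TRUE
    if (!identical(covered, !declared)) {
      v <- c(v, "cut list inconsistent with peptide edges")
    }
    if (sum(declared) != length(jn)) {
      v <- c(v, sprintf("broken adjacencies (%d) != jumps (%d)",
                        sum(declared), length(jn)))
    }
  }
  v
}

# ---- propagation structure --------------------------------------------------

# Per-residue parent table derived from a (valid) fold tree:
#   parent  : residue the step came from (NA at root)
#   ptype   : "root", "pep_fwd" (parent is r-1), "pep_bwd" (parent is r+1),
#             or "jump"
#   pjump   : jump number for ptype == "jump"
# Also an ordered placement list used by the kinematics traversal.
ft_parents <- function(tree) {
  n <- tree$n_residues
  parent <- rep(NA_integer_, n)
  ptype <- rep(NA_character_, n)
  pjump <- rep(NA_integer_, n)
  ptype[tree$root] <- "root"
  order_out <- integer(0)
  ed <- tree$edges
  # BFS over edges starting from the root so that placement order respects
  # dependencies (an edge is expanded only once its start residue is placed)
  placed <- rep(FALSE, n)
  placed[tree$root] <- TRUE
  order_out <- tree$root
  pending <- ed
  repeat {
    if (!nrow(pending)) break
    ready <- placed[pending$start]
    if (!any(ready)) stop("fold tree is not connected from its root")
    batch <- pending[ready, , drop = FALSE]
    pending <- pending[!ready, , drop = FALSE]
    for (k in seq_len(nrow(batch))) {
      s <- batch$start[k]; e <- batch$stop[k]; lab <- batch$label[k]
      if (lab > 0) {
        parent[e] <- s
        ptype[e] <- "jump"
        pjump[e] <- lab
        placed[e] <- TRUE
        order_out <- c(order_out, e)
      } else if (s != e) {
        dir <- sign(e - s)
        for (r in seq(s + dir, e, by = dir)) {
          parent[r] <- r - dir
          ptype[r] <- if (dir > 0) "pep_fwd" else "pep_bwd"
          placed[r] <- TRUE
          order_out <- c(order_out, r)
        }
      }
    }
  }
  list(parent = parent, ptype = ptype, pjump = pjump, order = order_out)
}

# children of each residue, from the parent table
ft_children <- function(par) {
  n <- length(par$parent)
  ch <- vector("list", n)
  for (r in seq_len(n)) {
    p <- par$parent[r]
    if (!is.na(p)) ch[[p]] <- c(ch[[p]], r)
  }
  ch
}

# all residues in the subtree rooted at r (inclusive)
ft_subtree <- function(par, r) {
  ch <- ft_children(par)
  out <- integer(0)
  stack <- r
  while (length(stack)) {
    x <- stack[[1]]
    stack <- stack[-1]
    out <- c(out, x)
    stack <- c(stack, ch[[x]])
  }
  sort(out)
}

#' Residues that move when a degree of freedom changes
#'
#' The fold tree resolves the ambiguity of internal-coordinate propagation:
#' for each DoF it defines exactly which residues lie downstream. Backbone
#' torsions move the subtree beyond their pivot in the folding direction
#' through that residue; a jump DoF moves the subtree hanging from the
#' jump's downstream residue. The pivot residue itself is included exactly
#' when one of its own N/CA/C atoms moves (phi at a forward-folded residue
#' moves its C; psi/omega at a backward-folded residue move its N/CA).
#'
#' @param tree a valid `fold_tree`.
#' @param dof a DoF identifier string (see [dof_phi()]).
#' @return Sorted integer vector of residue indices.
#' @export
downstream_set <- function(tree, dof) {
  par <- ft_parents(tree)
  d <- dof_parse(dof)
  n <- tree$n_residues
  if (d$kind == "jump") {
    je <- jump_edge(tree, d$jump)
    return(ft_subtree(par, je$stop))
  }
  i <- d$residue
  if (i < 1 || i > n) stop("DoF residue outside tree: ", dof)
  ch <- ft_children(par)
  fwd_child <- intersect(ch[[i]], if (i < n) i + 1L else integer(0))
  fwd_child <- fwd_child[!is.na(par$ptype[fwd_child]) &
                           par$ptype[fwd_child] == "pep_fwd"]
  bwd_child <- intersect(ch[[i]], if (i > 1) i - 1L else integer(0))
  bwd_child <- bwd_child[!is.na(par$ptype[bwd_child]) &
                           par$ptype[bwd_child] == "pep_bwd"]
  jump_children <- ch[[i]][!is.na(par$ptype[ch[[i]]]) &
                             par$ptype[ch[[i]]] == "jump"]
  backward <- !is.na(par$ptype[i]) && par$ptype[i] == "pep_bwd"
  forward <- !is.na(par$ptype[i]) && par$ptype[i] == "pep_fwd"
  sub <- function(rs) if (length(rs)) unlist(lapply(rs, ft_subtree, par = par)) else integer(0)
  moved <- switch(d$kind,
    phi = {
      if (forward) {
        # phi places C(i) itself: residue i counts as moving, as do the
        # forward continuation and any jump anchored at i (stub contains C)
        c(i, sub(fwd_child), sub(jump_children))
      } else {
        # root / jump-landing / backward: phi only places C(i-1)
        sub(bwd_child)
      }
    },
    psi = {
      if (backward) {
        # psi places N(i) itself: residue i partially moves, as do the
        # backward continuation and jumps anchored at i
        c(i, sub(bwd_child), sub(jump_children))
      } else {
        sub(fwd_child)
      }
    },
    omega = {
      if (backward) {
        c(i, sub(bwd_child), sub(jump_children))
      } else {
        sub(fwd_child)
      }
    },
    stop("unknown DoF kind")
  )
  sort(unique(as.integer(moved)))
}

#' Randomized cut placement
#'
#' Draws one cut position uniformly from the allowed positions of a set of
#' peptide intervals, excluding forbidden positions. Uses R's global RNG, so
#' results are reproducible under [set.seed()].
#'
#' @param segments list of `c(start, stop)` pairs; a cut at position `i`
#'   (with `start <= i <= stop`) breaks the i -> i+1 adjacency.
#' @param forbidden integer vector of forbidden cut positions.
#' @return A single cut position.
#' @export
random_cut_placement <- function(segments, forbidden = integer(0)) {
  pos <- unique(unlist(lapply(segments, function(s) seq(s[1], s[2]))))
  allowed <- setdiff(pos, forbidden)
  if (!length(allowed)) {
    stop(fb_condition("foldbroker_no_cut_error", sprintf(
      "no legal cutpoint: all of {%s} forbidden (forbidden set: %s)",
      paste(range(pos), collapse = ".."),
      paste(sort(forbidden), collapse = ","))))
  }
  if (length(allowed) == 1) return(allowed)
  allowed[sample.int(length(allowed), 1)]
}

# ---- serialization ----------------------------------------------------------

#' Serialize a fold tree to text
#'
#' One edge per line, `EDGE start stop label`, followed by `ROOT` and `CUTS`
#' lines. Round-trips bit-exactly through [parse_fold_tree()].
#'
#' @param tree a `fold_tree`.
#' @return A single character string.
#' @export
serialize_fold_tree <- function(tree) {
  ed <- tree$edges
  lines <- c(
    sprintf("FOLD_TREE %d", tree$n_residues),
    sprintf("ROOT %d", tree$root),
    vapply(seq_len(nrow(ed)), function(k)
      sprintf("EDGE %d %d %d", ed$start[k], ed$stop[k], ed$label[k]), ""),
    sprintf("CUTS %s", paste(tree$cuts, collapse = " "))
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse a serialized fold tree
#' @param text output of [serialize_fold_tree()].
#' @return A `fold_tree`.
#' @export
parse_fold_tree <- function(text) {
  lines <- strsplit(trimws(text), "\n")[[1]]
  toks <- strsplit(trimws(lines), "\\s+")
  n <- NULL; root <- NULL; cuts <- integer(0)
  ed <- list()
  for (tk in toks) {
    key <- tk[[1]]
    if (key == "FOLD_TREE") n <- as.integer(tk[2])
    else if (key == "ROOT") root <- as.integer(tk[2])
    else if (key == "EDGE") ed[[length(ed) + 1]] <-
        data.frame(start = as.integer(tk[2]), stop = as.integer(tk[3]),
                   label = as.integer(tk[4]))
    else if (key == "CUTS") cuts <- as.integer(tk[-1])
    else stop("unrecognised fold tree line: ", paste(tk, collapse = " "))
  }
  if (is.null(n) || is.null(root)) stop("missing FOLD_TREE/ROOT header")
  edges <- if (length(ed)) do.call(rbind, ed) else
    data.frame(start = integer(0), stop = integer(0), label = integer(0))
  fold_tree(edges, root = root, cuts = cuts, n_residues = n)
}

# package condition helper: classed errors carrying a message
fb_condition <- function(class, message) {
  structure(class = c(class, "foldbroker_error", "error", "condition"),
            list(message = message, call = sys.call(-1)))
}
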