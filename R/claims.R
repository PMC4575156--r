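# Claims and elements. A claim is a client mover's human-level statement of
# its fold-tree and DoF requirements; at broking time each claim is expanded
# into machine-level elements (virtual-residue additions, jumps, cuts, and
# single-DoF access requests carrying a control strength).

#' Control strengths
#'
#' The four-valued priority attached to a DoF access request, totally
#' ordered: does-not-control < can-control < must-control < exclusive.
#' Pairwise resolution follows a fixed matrix (see [resolve_access()]).
#'
#' @format Character vector of the four levels in increasing order.
#' @export
CONTROL_STRENGTHS <- c("DOES_NOT_CONTROL", "CAN_CONTROL", "MUST_CONTROL",
                       "EXCLUSIVE")

control_rank <- function(s) {
  r <- match(s, CONTROL_STRENGTHS)
  if (anyNA(r)) stop("invalid control strength: ",
                     paste(s[is.na(r)], collapse = ", "))
  r
}

#' Claim constructors
#'
#' Claims are issued by client movers from their `yield_claims` hook.
#'
#' `torsion_claim`: access to the phi/psi/omega torsions of a residue set.
#' `jump_claim`: a jump between two anchors; expands to six rigid-body DoF
#' elements, one jump element and one cut element. `cut_claim`: constrain
#' cut placement (forbid intervals, or fix a position). `virtual_residue_claim`:
#' append a coordinate-frame-only residue (optionally the tree root, or a
#' chain centre-of-mass tracker).
#'
#' @param residues integer vector, or a `residue_selector` / selector string.
#' @param strength one of [CONTROL_STRENGTHS].
#' @param anchor1,anchor2 residue index, selector (resolved to a single
#'   residue), or `virtual(label)` reference created with [virtual_anchor()].
#' @param fixed_geometry logical: the jump transform is set once (by its
#'   owner) and never sampled.
#' @param cut_preference optional `c(lo, hi)` interval: place this jump's
#'   cut inside it when possible.
#' @param tag owner-local identifier used to look up the brokered jump
#'   number after broking.
#' @param forbidden list of `c(lo, hi)` intervals whose cut positions are
#'   forbidden.
#' @param fixed optional fixed cut position.
#' @param label virtual-residue label (pose-wide, used by jump anchors).
#' @param attach `"free"`, `"root"` (becomes the fold-tree root) or `"com"`.
#' @param chain chain id for `attach = "com"`.
#' @return A claim object.
#' @name claims
NULL

#' @rdname claims
#' @export
torsion_claim <- function(residues, strength) {
  control_rank(strength)
  structure(list(type = "torsion", residues = residues, strength = strength),
            class = c("torsion_claim", "claim"))
}

#' @rdname claims
#' @export
jump_claim <- function(anchor1, anchor2, strength,
                       fixed_geometry = FALSE, cut_preference = NULL,
                       tag = NULL) {
  control_rank(strength)
  structure(list(type = "jump", anchor1 = anchor1, anchor2 = anchor2,
                 strength = strength, fixed_geometry = fixed_geometry,
                 cut_preference = cut_preference, tag = tag),
            class = c("jump_claim", "claim"))
}

#' @rdname claims
#' @export
cut_claim <- function(forbidden = list(), fixed = NULL) {
  structure(list(type = "cut", forbidden = forbidden, fixed = fixed),
            class = c("cut_claim", "claim"))
}

#' @rdname claims
#' @export
virtual_residue_claim <- function(label, attach = "free", chain = NULL) {
  attach <- match.arg(attach, c("free", "root", "com"))
  structure(list(type = "virtual_residue", label = label, attach = attach,
                 chain = chain),
            class = c("virtual_residue_claim", "claim"))
}

#' Reference a virtual residue as a jump anchor
#' @param label the virtual residue's label.
#' @return An anchor reference resolved at broking time.
#' @export
virtual_anchor <- function(label) {
  structure(list(label = label), class = "virtual_anchor")
}

# resolve an anchor to a single residue index
resolve_anchor <- function(anchor, conf) {
  if (inherits(anchor, "virtual_anchor")) {
    return(virtual_residue_index(conf, anchor$label))
  }
  r <- resolve_selector(anchor, conf)
  if (length(r) != 1) {
    stop("jump anchor must resolve to exactly one residue (got ",
         length(r), ")")
  }
  r
}

#' Expand a jump claim into elements
#'
#' A jump claim expands to exactly six DoF elements (one per rigid-body
#' component, each carrying the claim's control strength), one jump element
#' and one cut element.
#'
#' @param claim a `jump_claim`.
#' @param conf the conformation against which anchors are resolved.
#' @param owner owning client id.
#' @return List of element objects.
#' @export
expand_jump_claim <- function(claim, conf, owner = "<anon>") {
  a <- resolve_anchor(claim$anchor1, conf)
  b <- resolve_anchor(claim$anchor2, conf)
  if (a == b) stop("jump anchors are identical: residue ", a)
  els <- list(element_jump(owner, a, b, claim$fixed_geometry,
                           claim$cut_preference, claim$tag))
  for (rb in 1:6) {
    els[[length(els) + 1]] <- element_dof_jump(owner, a, b, rb, claim$strength)
  }
  els[[length(els) + 1]] <- element_cut(owner, forbidden = list(), fixed = NULL,
                                        for_jump = c(a, b))
  els
}

# ---- elements (internal) ----------------------------------------------------

element_jump <- function(owner, a, b, fixed_geometry, cut_preference, tag) {
  structure(list(etype = "jump", owner = owner,
                 a = min(a, b), b = max(a, b),
                 fixed_geometry = fixed_geometry,
                 cut_preference = cut_preference, tag = tag),
            class = "broker_element")
}

element_cut <- function(owner, forbidden = list(), fixed = NULL,
                        for_jump = NULL) {
  structure(list(etype = "cut", owner = owner, forbidden = forbidden,
                 fixed = fixed, for_jump = for_jump),
            class = "broker_element")
}

element_residue <- function(owner, label, attach, chain) {
  structure(list(etype = "residue", owner = owner, label = label,
                 attach = attach, chain = chain),
            class = "broker_element")
}

# torsion DoF element: concrete id. jump DoF element: anchors + rb, id
# assigned once jump numbers exist (topology phase precedes DoF phase)
element_dof <- function(owner, dof, strength) {
  structure(list(etype = "dof", owner = owner, dof = dof,
                 strength = strength),
            class = "broker_element")
}

element_dof_jump <- function(owner, a, b, rb, strength) {
  structure(list(etype = "dof_jump", owner = owner,
                 a = min(a, b), b = max(a, b), rb = rb,
                 strength = strength),
            class = "broker_element")
}

# expand any claim to its elements (jump claims via expand_jump_claim)
expand_claim <- function(claim, conf, owner) {
  switch(claim$type,
    torsion = {
      rs <- resolve_selector(claim$residues, conf)
      lapply(dof_torsions(rs), element_dof, owner = owner,
             strength = claim$strength)
    },
    jump = expand_jump_claim(claim, conf, owner),
    cut = list(element_cut(owner, forbidden = claim$forbidden,
                           fixed = claim$fixed)),
    virtual_residue = list(element_residue(owner, claim$label, claim$attach,
                                           claim$chain)),
    stop("unknown claim type: ", claim$type)
  )
}
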