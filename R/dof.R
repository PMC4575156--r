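# Degree-of-freedom identifiers. Every sampled scalar has a unique id:
# backbone torsions "phi:12" / "psi:12" / "omega:12", and jump rigid-body
# components "jump:2:rb4" (rb1..rb3 translation, rb4..rb6 rotation vector).
# Plain strings sort deterministically and make good error messages.

#' DoF identifiers
#'
#' Construct canonical identifiers for single scalar degrees of freedom:
#' backbone torsions or one of a jump's six rigid-body components.
#'
#' @param i residue index.
#' @param jump jump number.
#' @param rb rigid-body component index in 1..6 (1-3 translation x/y/z in
#'   \enc{Å}{Angstrom}, 4-6 rotation-vector components in radians).
#' @return Character scalar (or vector for the vectorised torsion forms).
#' @export
dof_phi <- function(i) paste0("phi:", as.integer(i))

#' @rdname dof_phi
#' @export
dof_psi <- function(i) paste0("psi:", as.integer(i))

#' @rdname dof_phi
#' @export
dof_omega <- function(i) paste0("omega:", as.integer(i))

#' @rdname dof_phi
#' @export
dof_jump_rb <- function(jump, rb) {
  stopifnot(all(rb %in% 1:6))
  paste0("jump:", as.integer(jump), ":rb", as.integer(rb))
}

#' All torsion DoF ids for a residue range
#' @param residues integer vector of residue indices.
#' @return Character vector of phi/psi/omega ids.
#' @export
dof_torsions <- function(residues) {
  c(dof_phi(residues), dof_psi(residues), dof_omega(residues))
}

# parse an id back into its parts
dof_parse <- function(dof) {
  stopifnot(is.character(dof), length(dof) == 1)
  parts <- strsplit(dof, ":", fixed = TRUE)[[1]]
  kind <- parts[1]
  if (kind %in% c("phi", "psi", "omega")) {
    return(list(kind = kind, residue = as.integer(parts[2])))
  }
  if (kind == "jump") {
    rb <- as.integer(sub("rb", "", parts[3]))
    if (is.na(rb) || !(rb %in% 1:6)) stop("bad jump DoF id: ", dof)
    return(list(kind = "jump", jump = as.integer(parts[2]), rb = rb))
  }
  stop("unrecognised DoF id: ", dof)
}
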