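# Toy score function for driving Metropolis Monte Carlo at desk scale:
# a soft CA-CA clash repulsion, a chainbreak penalty over the fold tree's
# cuts, and an optional harmonic pair constraint on declared strand pairs.
# Arbitrary units; every term is nonnegative.

#' Toy score function
#'
#' @param weights named numeric: `clash`, `chainbreak`, `pair`.
#' @param pairs optional `m x 2` matrix of residue pairs for the harmonic
#'   pair-constraint term.
#' @param pair_d0 target CA-CA distance for constrained pairs
#'   (\enc{Å}{Angstrom}).
#' @return A `toy_score` function object.
#' @export
toy_score <- function(weights = c(clash = 1, chainbreak = 1, pair = 0),
                      pairs = NULL, pair_d0 = 5.0) {
  w <- c(clash = 0, chainbreak = 0, pair = 0)
  w[names(weights)] <- weights
  if (any(w < 0)) stop("score weights must be nonnegative")
  structure(list(weights = w, pairs = pairs, pair_d0 = pair_d0),
            class = "toy_score")
}

#' Evaluate the toy score
#'
#' @param score a `toy_score`.
#' @param conf a `conformation`.
#' @param terms return the per-term breakdown as an attribute.
#' @return Total score (numeric scalar); with `terms = TRUE`, attribute
#'   `terms` carries the unweighted term values.
#' @export
score_conformation <- function(score, conf, terms = FALSE) {
  w <- score$weights
  xyz <- conf_xyz(conf)
  real <- which(!conf$virtual)
  ca <- xyz[real, 2, , drop = FALSE]
  dim(ca) <- c(length(real), 3)
  # clash: sum over CA pairs of (4 - d)^2 for d < 4 A, skipping i, i+-1
  clash <- 0
  if (length(real) > 2) {
    dm <- as.matrix(stats::dist(ca))
    sep <- abs(outer(real, real, "-"))
    mask <- upper.tri(dm) & sep > 1 & dm < 4
    if (any(mask)) clash <- sum((4 - dm[mask])^2)
  }
  # chainbreak: distance + angle gaps over cuts between same-chain residues
  cb <- 0
  for (cut in conf$fold_tree$cuts) {
    seg_i <- pose_segment(conf, cut)
    seg_j <- pose_segment(conf, cut + 1L)
    if (is.na(seg_i) || !identical(seg_i, seg_j)) next  # chain boundary
    dv <- chainbreak_deviation(conf, cut)
    cb <- cb + dv$dist^2 + sum(deg2rad(dv$angles)^2)
  }
  pairterm <- 0
  if (!is.null(score$pairs) && nrow(score$pairs)) {
    for (k in seq_len(nrow(score$pairs))) {
      d <- vnorm(xyz[score$pairs[k, 1], 2, ] - xyz[score$pairs[k, 2], 2, ])
      pairterm <- pairterm + (d - score$pair_d0)^2
    }
  }
  tv <- c(clash = clash, chainbreak = cb, pair = pairterm)
  total <- sum(w * tv)
  if (terms) attr(total, "terms") <- tv
  total
}

# chain id a residue belongs to (NA for virtual residues)
pose_segment <- function(conf, r) {
  k <- which(conf$chains$start <= r & conf$chains$end >= r)
  if (!length(k)) NA_character_ else conf$chains$chain_id[k[1]]
}
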