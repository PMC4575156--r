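# Residue selectors: small declarative expressions resolved against the
# conformation at broking time, so protocols can name regions the way a
# designer would ("chain H", "residues 17-40") instead of hard-coding pose
# indices. Supported: chain(X), range(i,j), and Boolean and/or/not.

#' Residue selectors
#'
#' Build selector expressions resolved to residue indices at broking time.
#'
#' @param chain_id chain identifier.
#' @param from,to residue range bounds (pose numbering).
#' @param a,b selectors to combine.
#' @return A `residue_selector` object.
#' @export
selector_chain <- function(chain_id) {
  structure(list(op = "chain", chain = chain_id), class = "residue_selector")
}

#' @rdname selector_chain
#' @export
selector_range <- function(from, to) {
  structure(list(op = "range", from = as.integer(from), to = as.integer(to)),
            class = "residue_selector")
}

#' @rdname selector_chain
#' @export
selector_and <- function(a, b) {
  structure(list(op = "and", a = a, b = b), class = "residue_selector")
}

#' @rdname selector_chain
#' @export
selector_or <- function(a, b) {
  structure(list(op = "or", a = a, b = b), class = "residue_selector")
}

#' @rdname selector_chain
#' @export
selector_not <- function(a) {
  structure(list(op = "not", a = a), class = "residue_selector")
}

#' Resolve a selector to residue indices
#'
#' @param sel a `residue_selector`, an integer vector (passed through), or a
#'   selector expression string (parsed first).
#' @param conf the `conformation` to resolve against.
#' @return Sorted integer vector of residue indices (real residues only for
#'   `chain` / `not`).
#' @export
resolve_selector <- function(sel, conf) {
  if (is.numeric(sel)) return(sort(unique(as.integer(sel))))
  if (is.character(sel)) sel <- parse_selector(sel)
  stopifnot(inherits(sel, "residue_selector"))
  all_real <- which(!conf$virtual)
  out <- switch(sel$op,
    chain = chain_residues(conf, sel$chain),
    range = seq(sel$from, sel$to),
    and = intersect(resolve_selector(sel$a, conf), resolve_selector(sel$b, conf)),
    or = union(resolve_selector(sel$a, conf), resolve_selector(sel$b, conf)),
    not = setdiff(all_real, resolve_selector(sel$a, conf)),
    stop("unknown selector op: ", sel$op)
  )
  sort(unique(as.integer(out)))
}

#' Parse a selector expression string
#'
#' Grammar: `chain(X)`, `range(i,j)`, `and(e1,e2)`, `or(e1,e2)`, `not(e)`.
#'
#' @param text selector expression.
#' @return A `residue_selector`.
#' @export
parse_selector <- function(text) {
  text <- gsub("\\s+", "", text)
  m <- regmatches(text, regexec("^([a-z]+)\\((.*)\\)$", text))[[1]]
  if (length(m) != 3) stop("cannot parse selector: ", text)
  op <- m[2]; body <- m[3]
  split_top <- function(s) {
    depth <- 0L; cutpos <- NA_integer_
    chars <- strsplit(s, "")[[1]]
    for (i in seq_along(chars)) {
      if (chars[i] == "(") depth <- depth + 1L
      if (chars[i] == ")") depth <- depth - 1L
      if (chars[i] == "," && depth == 0L) { cutpos <- i; break }
    }
    if (is.na(cutpos)) stop("expected two arguments in: ", s)
    c(substr(s, 1, cutpos - 1), substr(s, cutpos + 1, nchar(s)))
  }
  switch(op,
    chain = selector_chain(body),
    range = { ab <- split_top(body); selector_range(as.integer(ab[1]), as.integer(ab[2])) },
    and = { ab <- split_top(body); selector_and(parse_selector(ab[1]), parse_selector(ab[2])) },
    or = { ab <- split_top(body); selector_or(parse_selector(ab[1]), parse_selector(ab[2])) },
    not = selector_not(parse_selector(body)),
    stop("unknown selector op: ", op)
  )
}
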