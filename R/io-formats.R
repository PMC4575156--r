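# Plain-text dialects for sampling inputs.
#
# Fragment file: one fragment per line,
#   position length phi psi omega [phi psi omega ...]
# with `length` torsion triples following.
#
# Strand-pairing topology file: candidate anchor pairs grouped by pairing id
# (one anchor pair is selected per pairing per trajectory),
#   PAIRING id res_i res_j orientation(A|P) register

#' Read / write fragment files
#'
#' @param path file path.
#' @param library a `fragment_library`.
#' @return `read_fragment_file` returns a `fragment_library`;
#'   `write_fragment_file` returns `path` invisibly.
#' @export
read_fragment_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  entries <- lapply(lines, function(ln) {
    x <- as.numeric(strsplit(ln, "\\s+")[[1]])
    pos <- as.integer(x[1]); len <- as.integer(x[2])
    tors <- x[-(1:2)]
    if (length(tors) != 3 * len) {
      stop("fragment line has ", length(tors), " torsions, expected ", 3 * len)
    }
    list(position = pos, length = len,
         torsions = matrix(tors, nrow = len, ncol = 3, byrow = TRUE))
  })
  fragment_library(entries)
}

#' @rdname read_fragment_file
#' @export
write_fragment_file <- function(library, path) {
  lines <- vapply(library$entries, function(e) {
    paste(c(e$position, e$length,
            sprintf("%.4f", as.vector(t(e$torsions)))), collapse = " ")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write strand-pairing topology files
#'
#' @param path file path.
#' @param pairing_set a `strand_pairing_set` (its transforms are not
#'   serialized; supply them when reading).
#' @param transforms transform library to attach to the read pairing set.
#' @return `read_pairing_file` returns a `strand_pairing_set`;
#'   `write_pairing_file` returns `path` invisibly.
#' @export
read_pairing_file <- function(path, transforms = list()) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  recs <- lapply(lines, function(ln) {
    tk <- strsplit(ln, "\\s+")[[1]]
    if (tk[1] != "PAIRING" || length(tk) != 6) {
      stop("bad pairing line: ", ln)
    }
    list(id = tk[2], i = as.integer(tk[3]), j = as.integer(tk[4]),
         orientation = tk[5], register = as.integer(tk[6]))
  })
  ids <- unique(vapply(recs, `[[`, "", "id"))
  pairings <- lapply(ids, function(id) {
    rr <- Filter(function(r) r$id == id, recs)
    list(anchors = do.call(rbind, lapply(rr, function(r) c(r$i, r$j))),
         orientation = rr[[1]]$orientation,
         register = rr[[1]]$register)
  })
  strand_pairing_set(pairings, transforms)
}

#' @rdname read_pairing_file
#' @export
write_pairing_file <- function(pairing_set, path) {
  lines <- character(0)
  for (k in seq_along(pairing_set$pairings)) {
    p <- pairing_set$pairings[[k]]
    for (r in seq_len(nrow(p$anchors))) {
      lines <- c(lines, sprintf("PAIRING %d %d %d %s %d", k,
                                p$anchors[r, 1], p$anchors[r, 2],
                                p$orientation, p$register))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
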