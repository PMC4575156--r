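# Minimal PDB reader/writer: ATOM records only (PDB v3.3 columns), backbone
# atoms N/CA/C/O, chain IDs honoured. HETATM, alternate locations and
# insertion codes are rejected outright; the writer emits TER between chains.

#' Write backbone coordinates as PDB
#'
#' @param conf a `conformation`; virtual residues are skipped.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_backbone <- function(conf, path) {
  xyz <- conf_xyz(conf)
  lines <- character(0)
  serial <- 0L
  for (k in seq_len(nrow(conf$chains))) {
    ch <- conf$chains$chain_id[k]
    rs <- seq(conf$chains$start[k], conf$chains$end[k])
    resseq <- 0L
    for (r in rs) {
      if (conf$virtual[r]) next
      resseq <- resseq + 1L
      for (a in seq_along(ATOMS)) {
        serial <- serial + 1L
        nm <- sprintf("%-3s", ATOMS[a])  # left-justified from column 14
        lines <- c(lines, sprintf(
          "ATOM  %5d  %-3s ALA %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, ch, resseq,
          xyz[r, a, 1], xyz[r, a, 2], xyz[r, a, 3], 1, 0,
          substr(ATOMS[a], 1, 1)))
      }
    }
    serial <- serial + 1L
    lines <- c(lines, sprintf("TER   %5d      ALA %1s%4d", serial, ch, resseq))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read backbone coordinates from PDB
#'
#' Strict minimal reader: accepts ATOM records for backbone atoms N, CA, C,
#' O; any HETATM record, alternate-location indicator or insertion code is
#' an error. Residues are renumbered sequentially pose-wide in file order;
#' chain IDs define the chain table.
#'
#' @param path PDB file path.
#' @return A `conformation` (linear per-chain fold trees).
#' @export
read_pdb_backbone <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  if (any(trimws(rec) == "HETATM")) {
    stop("HETATM records are not supported: ", path)
  }
  atom <- lines[trimws(rec) == "ATOM"]
  if (!length(atom)) stop("no ATOM records in ", path)
  name <- trimws(substr(atom, 13, 16))
  altloc <- substr(atom, 17, 17)
  chain <- substr(atom, 22, 22)
  resseq <- as.integer(substr(atom, 23, 26))
  icode <- substr(atom, 27, 27)
  if (any(altloc != " ")) stop("alternate locations are not supported")
  if (any(icode != " ")) stop("insertion codes are not supported")
  keep <- name %in% ATOMS
  atom <- atom[keep]; name <- name[keep]
  chain <- chain[keep]; resseq <- resseq[keep]
  x <- as.numeric(substr(atom, 31, 38))
  y <- as.numeric(substr(atom, 39, 46))
  z <- as.numeric(substr(atom, 47, 54))
  key <- paste(chain, resseq)
  ukey <- unique(key)
  n <- length(ukey)
  xyz <- array(NA_real_, dim = c(n, 4, 3),
               dimnames = list(NULL, ATOMS, c("x", "y", "z")))
  idx <- match(key, ukey)
  aidx <- match(name, ATOMS)
  for (i in seq_along(atom)) xyz[idx[i], aidx[i], ] <- c(x[i], y[i], z[i])
  if (any(!is.finite(xyz))) {
    bad <- which(apply(xyz, 1, function(m) any(!is.finite(m))))[1]
    stop("missing backbone atoms at residue ", ukey[bad])
  }
  uchain <- unname(vapply(strsplit(ukey, " "), `[[`, "", 1))
  rle_ch <- rle(uchain)
  if (anyDuplicated(rle_ch$values)) stop("chain appears twice (non-contiguous)")
  ends <- cumsum(rle_ch$lengths)
  chains <- data.frame(chain_id = rle_ch$values,
                       start = c(1L, utils::head(ends, -1) + 1L),
                       end = ends, stringsAsFactors = FALSE)
  conformation_from_xyz(xyz, chains)
}
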