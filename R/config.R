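# Declarative protocol configuration (YAML): inputs (PDB / fragment /
# topology paths), an ordered client list, the MC schedule, and score
# weights. This is the whole protocol definition — assembling a new
# combination of constraints is an edit to this document, not new code.

#' Read a protocol configuration
#'
#' Loads a YAML protocol document and assembles the starting conformation
#' and a [protocol()] from it. Client blocks (`type`, `name`, plus
#' type-specific fields) are instantiated in order; paths are resolved
#' relative to the config file.
#'
#' Supported client types: `rigid_chunk` (field `region`, selector string;
#' template from `inputs$template_pdb`, falling back to the start PDB),
#' `fragment` (`inputs$fragments`), `strand_jump` (`inputs$topology`),
#' `com_star` (optional `chains`), `docking` (`chain`, `rot_mag`,
#' `trans_mag`), `loop_close` (`loop: [start, end]`).
#'
#' @param path YAML config path.
#' @return List: `start` (a `conformation`), `proto` (a `protocol`), `seed`.
#' @export
read_protocol_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p)) NULL else file.path(base, p)
  start <- read_pdb_backbone(rel(cfg$inputs$pdb))
  template <- if (!is.null(cfg$inputs$template_pdb)) {
    read_pdb_backbone(rel(cfg$inputs$template_pdb))
  } else start
  fragments <- if (!is.null(cfg$inputs$fragments)) {
    read_fragment_file(rel(cfg$inputs$fragments))
  }
  pairings <- if (!is.null(cfg$inputs$topology)) {
    read_pairing_file(rel(cfg$inputs$topology),
                      transforms = strand_pair_transforms())
  }
  clients <- lapply(cfg$clients, function(cc) {
    switch(cc$type,
      rigid_chunk = rigid_chunk_client(cc$name, template, cc$region),
      fragment = {
        if (is.null(fragments)) stop("client '", cc$name,
                                     "' needs inputs$fragments")
        fragment_client(cc$name, fragments)
      },
      strand_jump = {
        if (is.null(pairings)) stop("client '", cc$name,
                                    "' needs inputs$topology")
        strand_jump_client(cc$name, pairings)
      },
      com_star = com_star_client(cc$name, chains = cc$chains),
      docking = docking_client(cc$name, cc$chain,
                               rot_mag = cc$rot_mag %||% 3,
                               trans_mag = cc$trans_mag %||% 0.5),
      loop_close = loop_close_client(cc$name, unlist(cc$loop)),
      stop("unknown client type: ", cc$type)
    )
  })
  sched <- cfg$schedule %||% list()
  sc <- cfg$score %||% list()
  proto <- protocol(
    clients,
    cycles = sched$cycles %||% 1000L,
    temperature = sched$temperature %||% 1.0,
    anneal = sched$anneal %||% 1.0,
    weights = if (!is.null(sched$weights)) unlist(sched$weights),
    score = toy_score(c(clash = sc$clash %||% 1,
                        chainbreak = sc$chainbreak %||% 1,
                        pair = sc$pair %||% 0)),
    n_struct = cfg$n_struct %||% 1L)
  list(start = start, proto = proto, seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
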