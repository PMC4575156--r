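# Metropolis Monte Carlo protocol driver. The protocol owns the schedule:
# the broker decides what may move, never when or how often. Each output
# model re-brokers from scratch, so cut placement is re-randomized on a
# per-model basis; within a model the consensus tree is frozen.

#' Metropolis acceptance test
#'
#' @param delta_score score change of the trial move.
#' @param temperature Monte Carlo temperature (kT, score units; > 0).
#' @return `TRUE` to accept: always when `delta_score <= 0`, else with
#'   probability `exp(-delta_score / temperature)` (one uniform draw from
#'   R's global RNG).
#' @export
metropolis_accept <- function(delta_score, temperature) {
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be positive")
  }
  if (delta_score <= 0) return(TRUE)
  if (!is.finite(delta_score)) return(FALSE)
  stats::runif(1) < exp(-delta_score / temperature)
}

#' Protocol configuration
#'
#' @param clients ordered list of client movers.
#' @param cycles Monte Carlo cycles per model (>= 0).
#' @param temperature starting temperature (kT, score units).
#' @param anneal multiplicative temperature decay per cycle (1 = constant).
#' @param weights named nonnegative per-client selection weights (at least
#'   one positive); default: uniform.
#' @param score a `toy_score`.
#' @param n_struct number of models to generate.
#' @return A `protocol` object.
#' @export
protocol <- function(clients, cycles = 1000, temperature = 1.0, anneal = 1.0,
                     weights = NULL, score = toy_score(), n_struct = 1) {
  nms <- vapply(clients, function(c) c$name, "")
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(clients)), nms)
  w <- stats::setNames(rep(0, length(clients)), nms)
  w[names(weights)] <- weights
  if (any(w < 0) || (length(w) && !any(w > 0))) {
    stop("weights must be nonnegative with at least one positive")
  }
  stopifnot(cycles >= 0, n_struct >= 1)
  structure(list(clients = clients, cycles = as.integer(cycles),
                 temperature = temperature, anneal = anneal, weights = w,
                 score = score, n_struct = as.integer(n_struct)),
            class = "protocol")
}

#' Run a brokered Monte Carlo protocol
#'
#' Per model: registers fresh clones of the protocol's clients with a new
#' broker (re-randomizing cut placement per model), initializes them, then
#' runs the Monte Carlo schedule, choosing a client per cycle by weight and
#' accepting moves by the Metropolis criterion on the toy score. Rejected
#' moves restore the conformation bit-exactly. Fully reproducible per seed.
#'
#' @param proto a [protocol()].
#' @param start a `conformation`.
#' @param seed integer master seed; model m uses `seed + m`.
#' @param out_dir optional directory: write each model as PDB plus a
#'   tab-separated score table.
#' @return List with `models` (list of final `conformation`s), `scores`
#'   (data.frame: model, initial, final, accepted moves), `results`
#'   (per-model `broker_result`s).
#' @export
run_protocol <- function(proto, start, seed = 1L, out_dir = NULL) {
  stopifnot(inherits(proto, "protocol"), inherits(start, "conformation"))
  models <- list()
  results <- list()
  tab <- data.frame(model = integer(0), score_initial = numeric(0),
                    score_final = numeric(0), accepted = integer(0),
                    cycles = integer(0))
  for (m in seq_len(proto$n_struct)) {
    model_seed <- (seed + m) %% 2147483647L
    clients <- lapply(proto$clients, clone_client)
    b <- broker_new()
    for (cl in clients) register_client(b, cl)
    res <- broke(b, start, seed = model_seed)
    pconf <- res$pconf
    sc <- proto$score
    set.seed(derive_seed(model_seed, "mc"))
    s_cur <- score_conformation(sc, pconf$conf)
    s_init <- s_cur
    temp <- proto$temperature
    accepted <- 0L
    w <- proto$weights
    pick <- which(w > 0)
    for (cyc in seq_len(proto$cycles)) {
      ci <- if (length(pick) == 1) pick else
        sample(pick, 1, prob = w[pick])
      snap <- pconf$conf
      out <- tryCatch(client_apply(clients[[ci]], pconf),
                      error = function(e) {
                        pconf$conf <- snap
                        stop(e)
                      })
      if (isTRUE(out$moved)) {
        s_new <- score_conformation(sc, pconf$conf)
        if (metropolis_accept(s_new - s_cur, temp)) {
          s_cur <- s_new
          accepted <- accepted + 1L
        } else {
          pconf$conf <- snap
        }
      }
      temp <- temp * proto$anneal
    }
    models[[m]] <- pconf$conf
    results[[m]] <- res
    tab <- rbind(tab, data.frame(model = m, score_initial = s_init,
                                 score_final = s_cur, accepted = accepted,
                                 cycles = proto$cycles))
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_pdb_backbone(pconf$conf,
                         file.path(out_dir, sprintf("model_%04d.pdb", m)))
    }
  }
  if (!is.null(out_dir)) {
    utils::write.table(tab, file.path(out_dir, "scores.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  list(models = models, scores = tab, results = results)
}

# fresh copy of a client environment (clients hold per-trajectory state:
# chosen anchors, passports, jump numbers)
clone_client <- function(client) {
  cl <- new.env(parent = emptyenv())
  for (nm in ls(client, all.names = TRUE)) assign(nm, get(nm, client), cl)
  cl$passport <- NULL
  cl$jump_numbers <- NULL
  class(cl) <- class(client)
  cl
}
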