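# Test helpers: a scripted client that yields a fixed claim list, and a
# generator of random-but-resolvable claim sets for fuzzing the broker.

scripted_client <- function(name, claims) {
  cl <- foldbroker:::new_client(name, "scripted_client")
  cl$script <- claims
  cl
}

yield_claims.scripted_client <- function(client, conf) {
  client$claims_issued <- client$script
  client$script
}

client_apply.scripted_client <- function(client, pconf) list(moved = FALSE)

# register an S3 method from the helper environment
registerS3method("yield_claims", "scripted_client", yield_claims.scripted_client,
                 envir = asNamespace("foldbroker"))
registerS3method("client_apply", "scripted_client", client_apply.scripted_client,
                 envir = asNamespace("foldbroker"))

# broker a list of clients against a conformation in one call
broke_clients <- function(clients, conf, seed = 1L) {
  b <- broker_new()
  for (cl in clients) register_client(b, cl)
  broke(b, conf, seed = seed)
}

# a random claim set guaranteed to be resolvable: CAN/MUST torsion claims
# may overlap freely; at most one EXCLUSIVE torsion region, disjoint from a
# small forbidden-cut interval so every jump cycle keeps a legal cut
random_claim_clients <- function(n) {
  n_jumps <- sample(0:3, 1)
  claims_a <- list()
  claims_b <- list()
  used_pairs <- list()
  for (j in seq_len(n_jumps)) {
    a <- sample(seq(2, n - 1), 1)
    b <- sample(setdiff(seq(2, n - 1), a), 1)
    claims_a[[length(claims_a) + 1]] <-
      jump_claim(min(a, b), max(a, b), "MUST_CONTROL", tag = paste0("j", j))
  }
  r1 <- sort(sample(n, 2))
  claims_a[[length(claims_a) + 1]] <-
    torsion_claim(seq(r1[1], r1[2]), "CAN_CONTROL")
  r2 <- sort(sample(n, 2))
  claims_b[[length(claims_b) + 1]] <-
    torsion_claim(seq(r2[1], r2[2]), sample(c("CAN_CONTROL", "MUST_CONTROL"), 1))
  if (stats::runif(1) < 0.5) {
    s <- sample(seq(1, n - 4), 1)
    claims_b[[length(claims_b) + 1]] <-
      cut_claim(forbidden = list(c(s, min(s + 3, n - 1))))
  }
  list(scripted_client("fuzz_a", claims_a),
       scripted_client("fuzz_b", claims_b))
}
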