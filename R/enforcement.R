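# Enforcement of the broking contract. After broking, the conformation is
# replaced by a protected conformation that demands a valid passport —
# presented through a stack-scoped unlock — before any DoF modification.
# Reads always pass through; the fold tree can never be replaced.

new_passport <- function(owner, granted, round_id) {
  structure(list(owner = owner, granted = sort(unique(granted)),
                 round_id = round_id),
            class = "passport")
}

#' @export
print.passport <- function(x, ...) {
  cat("<passport>", x$owner, "-", length(x$granted), "DoF(s) granted\n")
  invisible(x)
}

new_protected_conformation <- function(conf, tree, round_id, grants) {
  p <- new.env(parent = emptyenv())
  p$conf <- conf
  p$tree <- tree
  p$round_id <- round_id
  p$stack <- list()
  p$lookup_count <- 0L
  p$grants <- grants       # data.frame(owner, dof): for error messages
  p$violation_log <- list()
  class(p) <- "protected_conformation"
  p
}

#' @export
print.protected_conformation <- function(x, ...) {
  cat("<protected_conformation> stack depth", length(x$stack), "\n")
  print(x$conf)
  invisible(x)
}

#' Run an action under an unlock
#'
#' Pushes the passport onto the protected conformation's stack, runs the
#' action, and pops the passport again — also on error paths. Only the top
#' of the stack authorises modifications, so a nested unlock fully shadows
#' the outer one.
#'
#' @param pconf a protected conformation (from [broke()]).
#' @param passport the client's passport from the same broking round.
#' @param action a function of no arguments.
#' @return The action's return value, unchanged.
#' @export
with_unlock <- function(pconf, passport, action) {
  stopifnot(inherits(pconf, "protected_conformation"),
            inherits(passport, "passport"))
  if (!identical(passport$round_id, pconf$round_id)) {
    stop(fb_condition("foldbroker_auth_error", sprintf(
      "passport of mover '%s' was not issued by this broking round",
      passport$owner)))
  }
  pconf$stack[[length(pconf$stack) + 1]] <- passport
  on.exit(pconf$stack[[length(pconf$stack)]] <- NULL)
  action()
}

# single authorization check: consults exactly one passport (the stack top)
check_access <- function(pconf, dofs) {
  depth <- length(pconf$stack)
  if (!depth) {
    err <- fb_condition("foldbroker_auth_error", sprintf(
      "no unlock active: modification of %s refused",
      paste(dofs, collapse = ", ")))
    pconf$violation_log[[length(pconf$violation_log) + 1]] <-
      list(owner = NA_character_, dofs = dofs)
    stop(err)
  }
  top <- pconf$stack[[depth]]
  pconf$lookup_count <- pconf$lookup_count + 1L
  missing <- setdiff(dofs, top$granted)
  if (length(missing)) {
    holders <- unique(pconf$grants$owner[pconf$grants$dof %in% missing])
    pconf$violation_log[[length(pconf$violation_log) + 1]] <-
      list(owner = top$owner, dofs = missing)
    stop(fb_condition("foldbroker_auth_error", sprintf(
      "mover '%s' is not granted DoF %s%s",
      top$owner, paste(missing, collapse = ", "),
      if (length(holders)) paste0(" (granted to: ",
                                  paste(holders, collapse = ", "), ")")
      else " (granted to no mover: frozen for this trajectory)")))
  }
  invisible(top)
}

#' Modify a DoF through the protected conformation
#'
#' Delegates to [set_dof()] if — and only if — the passport on top of the
#' unlock stack grants the DoF; otherwise raises an authorization error
#' naming the acting client, the DoF, and the clients that do hold the
#' grant (fail-fast). A DoF granted to no client is immutable for the whole
#' trajectory.
#'
#' @param pconf a protected conformation.
#' @param dof DoF id string.
#' @param value new value (degrees, or rigid-body component).
#' @return The protected conformation, invisibly.
#' @export
protected_set_dof <- function(pconf, dof, value) {
  check_access(pconf, dof)
  pconf$conf <- set_dof(pconf$conf, dof, value)
  invisible(pconf)
}

#' Modify several DoFs through the protected conformation
#'
#' Batch form of [protected_set_dof()]: one authorization check over the
#' whole set (all-or-nothing), then one cache refresh.
#'
#' @param pconf a protected conformation.
#' @param dofs character vector of DoF ids.
#' @param values numeric vector of the same length.
#' @return The protected conformation, invisibly.
#' @export
protected_set_dofs <- function(pconf, dofs, values) {
  check_access(pconf, dofs)
  pconf$conf <- set_dofs(pconf$conf, dofs, values)
  invisible(pconf)
}

#' Set a jump's full transform through the protected conformation
#'
#' Requires all six of the jump's rigid-body DoFs to be granted to the
#' active passport.
#'
#' @param pconf a protected conformation.
#' @param jump_number jump number on the consensus tree.
#' @param transform a `rigid_transform`.
#' @return The protected conformation, invisibly.
#' @export
protected_set_jump <- function(pconf, jump_number, transform) {
  check_access(pconf, dof_jump_rb(jump_number, 1:6))
  pconf$conf <- set_jump(pconf$conf, jump_number, transform)
  invisible(pconf)
}

#' Attempt to replace the fold tree of a protected conformation
#'
#' Always refused: the consensus fold tree is part of the broking contract.
#' Change the claims and re-broker instead.
#'
#' @param pconf a protected conformation.
#' @param tree ignored.
#' @return Never returns; raises a contract error.
#' @export
attempt_set_foldtree <- function(pconf, tree) {
  stop(fb_condition("foldbroker_contract_error", paste(
    "the consensus fold tree cannot be replaced after broking;",
    "register different claims and re-broker")))
}

#' Read access to the wrapped conformation
#'
#' Reads pass through the protection layer unchanged.
#'
#' @param pconf a protected conformation.
#' @return The wrapped `conformation`.
#' @export
pconf_conformation <- function(pconf) pconf$conf
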