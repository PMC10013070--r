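#' @title State serialization
#' @description Full-state dumps of a community (consumer traits in sparse
#'   form plus lineage metadata and parameters) as JSON, for restart and
#'   post-hoc analysis, and CSV export of run tables.
#' @name cfn-io
NULL

#' Dump a community (or the final state of a run) as JSON
#'
#' @param x A \code{cfn_community} or \code{cfn_sim}.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
save_cfn_state <- function(x, file) {
  community <- if (inherits(x, "cfn_sim")) x$final$community else x
  if (!inherits(community, "cfn_community"))
    stop("'x' must be a cfn_community or cfn_sim")
  p <- community$params
  consumers <- lapply(seq_along(community$ids), function(i) {
    ui <- which(community$U[, i] > 0)
    ri <- which(community$Rho[, i] > 0)
    list(id = community$ids[i],
         ancestor = community$ancestor[i],
         birth_step = community$birth_step[i],
         u_index = ui, u_value = community$U[ui, i],
         rho_index = ri, rho_value = community$Rho[ri, i])
  })
  state <- list(
    format = "cfn_state",
    version = 1L,
    step = community$step,
    params = p[setdiff(names(p), c("beta_u", "beta_rho"))],
    consumers = consumers
  )
  jsonlite::write_json(state, file, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(file)
}

#' Restore a community from a JSON state dump
#'
#' @param file Path written by \code{\link{save_cfn_state}}.
#' @return A \code{cfn_community}.
#' @export
load_cfn_state <- function(file) {
  state <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!identical(state$format, "cfn_state"))
    stop("not a cfn_state file")
  pl <- state$params
  pl$supply <- as.numeric(pl$supply)
  params <- do.call(cfn_params, pl)
  G <- params$pool_size
  cons <- state$consumers
  n <- if (is.data.frame(cons)) nrow(cons) else length(cons)
  U <- matrix(0, G, n)
  Rho <- matrix(0, G, n)
  get <- function(i, nm) {
    if (is.data.frame(cons)) cons[[nm]][[i]] else cons[[i]][[nm]]
  }
  for (i in seq_len(n)) {
    U[unlist(get(i, "u_index")), i] <- unlist(get(i, "u_value"))
    Rho[unlist(get(i, "rho_index")), i] <- unlist(get(i, "rho_value"))
  }
  ids <- vapply(seq_len(n), get, numeric(1), nm = "id")
  anc <- vapply(seq_len(n), function(i) {
    a <- get(i, "ancestor")
    if (is.null(a) || length(a) == 0L || is.na(a)) NA_integer_ else as.integer(a)
  }, integer(1))
  births <- vapply(seq_len(n), get, numeric(1), nm = "birth_step")
  new_community(U, Rho, ids = ids, ancestor = anc, birth_step = births,
                params = params, step = state$step)
}
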