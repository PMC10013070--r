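#' @title Community containers and bookkeeping
#' @description Internal representation: a community stores the affinity and
#'   release vectors of all resident consumers column-wise in two
#'   \code{pool_size x N} matrices, together with lineage metadata. Resources
#'   are indexed 1..G over the global pool; supplied resources occupy the
#'   lowest indices.
#' @name cfn_community
NULL

new_community <- function(U, Rho, ids, ancestor, birth_step, params, step = 0L) {
  structure(
    list(U = U, Rho = Rho,
         ids = as.integer(ids),
         ancestor = as.integer(ancestor),
         birth_step = as.integer(birth_step),
         params = params,
         step = as.integer(step),
         # per-resource producer count, maintained incrementally so that the
         # present-resource set is O(G) to obtain inside the hot loop
         prod_count = as.integer(rowSums(Rho > 0))),
    class = "cfn_community"
  )
}

#' Build a community from explicit consumer trait vectors
#'
#' Mainly used to construct small hand-built networks with known flows for
#' testing and illustration. Vectors shorter than the pool are zero-padded.
#'
#' @param consumers A list of consumers, each a list with numeric vectors
#'   \code{u} (non-negative affinities, any positive total) and \code{rho}
#'   (non-negative release proportions summing to 1).
#' @param params A \code{\link{cfn_params}} object; its \code{pool_size} and
#'   \code{supply} define the resource index space.
#' @return A \code{cfn_community}.
#' @examples
#' p <- cfn_params(pool_size = 4)
#' comm <- cfn_community(list(list(u = c(1, 0, 0, 0), rho = c(1, 0, 0, 0))), p)
#' community_richness(comm)
#' @export
cfn_community <- function(consumers, params) {
  G <- params$pool_size
  n <- length(consumers)
  U <- matrix(0, G, n)
  Rho <- matrix(0, G, n)
  for (i in seq_len(n)) {
    u <- consumers[[i]]$u
    r <- consumers[[i]]$rho
    if (length(u) > G || length(r) > G)
      stop("consumer trait vector longer than the resource pool")
    if (any(u < 0) || any(r < 0))
      stop("negative trait entries are not allowed")
    U[seq_along(u), i] <- u
    Rho[seq_along(r), i] <- r
    if (sum(r) > 0 && abs(sum(r) - 1) > 1e-8)
      stop("release proportions of each consumer must sum to 1")
  }
  new_community(U, Rho, ids = seq_len(n), ancestor = rep(NA_integer_, n),
                birth_step = rep(0L, n), params = params)
}

#' Create a random founding consumer
#'
#' The founder has positive affinity for every externally supplied resource;
#' its remaining uptake slots are drawn uniformly without replacement from the
#' rest of the global pool. Affinity magnitudes and release proportions are
#' drawn i.i.d. uniform on (0, 1) and normalized (affinities to
#' \code{u_bar}, release proportions to 1). Release targets are drawn
#' uniformly from the whole pool, so the founder typically introduces
#' resources that are not supplied.
#'
#' Draw order (affinity support, affinity magnitudes, release support,
#' release magnitudes) is fixed, so a given RNG state always yields the same
#' founder.
#'
#' @param params A \code{\link{cfn_params}} object.
#' @return A list with fields \code{u}, \code{rho} (length-\code{pool_size}
#'   vectors), \code{id}, \code{ancestor} (\code{NA}), \code{birth_step}.
#' @examples
#' p <- cfn_params()
#' set.seed(1)
#' f <- cfn_founder(p)
#' sum(f$u > 0)  # n_u
#' @export
cfn_founder <- function(params) {
  G <- params$pool_size
  supplied <- which(params$supply > 0)
  if (params$n_u < length(supplied))
    stop("'n_u' is smaller than the number of supplied resources; ",
         "the founder cannot cover all supply points")
  extra <- params$n_u - length(supplied)
  idx <- supplied
  if (extra > 0) {
    free <- setdiff(seq_len(G), supplied)
    idx <- c(supplied, free[sample.int(length(free), extra)])
  }
  u <- numeric(G)
  w <- stats::runif(params$n_u)
  u[idx] <- params$u_bar * w / sum(w)
  ridx <- sample.int(G, params$n_rho)
  rho <- numeric(G)
  rw <- stats::runif(params$n_rho)
  rho[ridx] <- rw / sum(rw)
  list(u = u, rho = rho, id = 1L, ancestor = NA_integer_, birth_step = 0L)
}

founder_community <- function(params) {
  f <- cfn_founder(params)
  new_community(matrix(f$u, ncol = 1), matrix(f$rho, ncol = 1),
                ids = f$id, ancestor = f$ancestor, birth_step = f$birth_step,
                params = params)
}

#' Resources currently present in the system
#'
#' A resource is present when it is externally supplied or released by at
#' least one resident consumer. A resource that is merely consumable (some
#' resident has affinity for it) but neither supplied nor produced carries no
#' flow and is not counted.
#'
#' @param community A \code{cfn_community}.
#' @return Integer vector of present resource indices.
#' @export
present_resources <- function(community) {
  which(community$params$supply > 0 | community$prod_count > 0L)
}

#' Consumer and resource richness
#'
#' @param community A \code{cfn_community}.
#' @return Named integer vector \code{c(N = ..., M = ...)}: the number of
#'   resident consumers and of present resources.
#' @examples
#' p <- cfn_params(pool_size = 5)
#' community_richness(cfn_community(list(), p))  # N = 0, M = 1 (supply only)
#' @export
community_richness <- function(community) {
  c(N = ncol(community$U), M = length(present_resources(community)))
}

#' @export
print.cfn_community <- function(x, ...) {
  r <- community_richness(x)
  cat(sprintf("Cross-feeding community at step %d: %d consumers, %d present resources\n",
              x$step, r[["N"]], r[["M"]]))
  invisible(x)
}

# drop consumers by column index (keeps matrices in id order)
remove_consumers <- function(community, cols) {
  lost <- rowSums(community$Rho[, cols, drop = FALSE] > 0)
  community$prod_count <- community$prod_count - as.integer(lost)
  community$U <- community$U[, -cols, drop = FALSE]
  community$Rho <- community$Rho[, -cols, drop = FALSE]
  community$ids <- community$ids[-cols]
  community$ancestor <- community$ancestor[-cols]
  community$birth_step <- community$birth_step[-cols]
  community
}

add_consumer <- function(community, consumer) {
  community$U <- cbind(community$U, consumer$u, deparse.level = 0)
  community$Rho <- cbind(community$Rho, consumer$rho, deparse.level = 0)
  community$ids <- c(community$ids, consumer$id)
  community$ancestor <- c(community$ancestor, consumer$ancestor)
  community$birth_step <- c(community$birth_step, consumer$birth_step)
  community$prod_count <- community$prod_count + as.integer(consumer$rho > 0)
  community
}
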