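#' Model parameters for a cross-feeding network simulation
#'
#' Bundles every constant of the evolutionary cross-feeding-network (CFN)
#' model into one validated, immutable record. Defaults reproduce the
#' reference configuration used throughout the package: a single externally
#' supplied resource entering a pool of 250 possible compounds, recycling
#' fraction 0.7, extinction threshold 0.01, and uptake/release diversities of
#' three resources per consumer.
#'
#' @param eta Recycling fraction \eqn{\eta \in (0,1)}: the share of consumed
#'   flow that is retained in organic form and re-released by a consumer;
#'   \eqn{1-\eta} is respired and leaves the system.
#' @param mu Extinction threshold \eqn{\mu > 0}: the minimum stationary uptake
#'   flow a consumer needs to persist (flow units).
#' @param alpha Mutation amplitude \eqn{\alpha \ge 0} of the per-entry
#'   symmetric multiplicative noise applied at speciation.
#' @param p_u,p_rho Probabilities in \eqn{[0,1]} that a speciation event also
#'   substitutes one utilized resource (respectively one released product) for
#'   a new one.
#' @param n_u,n_rho Uptake and release diversity: the fixed number of
#'   resources a consumer consumes / produces; constant along a lineage.
#' @param pool_size Size \eqn{G} of the global pool of possible compounds from
#'   which substitution mutations draw.
#' @param supply Either a full length-\code{pool_size} vector of non-negative
#'   external supply rates, or a short numeric vector placed on the lowest
#'   resource indices (default: a single supply of rate 1.0 at resource 1).
#' @param u_bar Total affinity budget \eqn{\bar u > 0} per consumer. Uptake
#'   shares are invariant under a common rescaling of all affinities, so this
#'   choice is observationally neutral; it is exposed for completeness.
#' @param theta Cluster diameter threshold \eqn{\vartheta \in (0,1]} used by
#'   the dynamic similarity clustering.
#' @param w_u,w_rho Non-negative weights of the affinity and release parts of
#'   the genotypic dissimilarity (at least one must be positive).
#' @param n_steps Number of evolutionary steps to simulate.
#' @param seed Integer seed for the single run-level random generator.
#' @param record_every Interval (steps) at which the more expensive
#'   observables (diversity, evolutionary potential, effective richness,
#'   evenness) are evaluated along a run.
#' @param snapshot_every Interval (steps) at which full community snapshots
#'   are stored; \code{Inf} disables intermediate snapshots (the final state
#'   is always kept).
#' @param uptake_substitution_pool Where the uptake substitution draws the new
#'   resource from: \code{"present"} (resources currently in the system;
#'   default) or \code{"global"} (the whole pool).
#'
#' @return An object of class \code{cfn_params}: a named list with the fields
#'   above plus the derived drift bounds \code{beta_u = alpha/n_u} and
#'   \code{beta_rho = alpha/n_rho}.
#'
#' @examples
#' p <- cfn_params(n_steps = 100)
#' p$beta_u  # alpha / n_u
#' @export
cfn_params <- function(eta = 0.7,
                       mu = 0.01,
                       alpha = 0.2,
                       p_u = 0.2,
                       p_rho = 0.2,
                       n_u = 3L,
                       n_rho = 3L,
                       pool_size = 250L,
                       supply = 1.0,
                       u_bar = 1.0,
                       theta = 0.4,
                       w_u = 1.0,
                       w_rho = 0.2,
                       n_steps = 1000L,
                       seed = 1L,
                       record_every = 250L,
                       snapshot_every = Inf,
                       uptake_substitution_pool = c("present", "global")) {
  uptake_substitution_pool <- match.arg(uptake_substitution_pool)
  pool_size <- as.integer(pool_size)
  n_u <- as.integer(n_u)
  n_rho <- as.integer(n_rho)
  stopifnot(
    is.numeric(eta), length(eta) == 1L, eta > 0, eta < 1,
    is.numeric(mu), length(mu) == 1L, mu > 0,
    is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
    p_u >= 0, p_u <= 1, p_rho >= 0, p_rho <= 1,
    n_u >= 1L, n_rho >= 1L, pool_size >= 1L,
    n_u <= pool_size, n_rho <= pool_size,
    u_bar > 0,
    theta > 0, theta <= 1,
    w_u >= 0, w_rho >= 0,
    n_steps >= 0, record_every >= 1, snapshot_every >= 1
  )
  if (w_u == 0 && w_rho == 0)
    stop("at least one of 'w_u', 'w_rho' must be positive")
  if (length(supply) < pool_size) {
    s <- numeric(pool_size)
    s[seq_along(supply)] <- supply
    supply <- s
  }
  if (length(supply) != pool_size || any(supply < 0))
    stop("'supply' must be non-negative and at most 'pool_size' long")
  if (sum(supply) <= 0)
    stop("total supply must be positive")
  structure(
    list(
      eta = eta, mu = mu, alpha = alpha,
      p_u = p_u, p_rho = p_rho,
      n_u = n_u, n_rho = n_rho,
      pool_size = pool_size, supply = supply,
      u_bar = u_bar,
      theta = theta, w_u = w_u, w_rho = w_rho,
      n_steps = as.integer(n_steps), seed = as.integer(seed),
      record_every = as.integer(record_every),
      snapshot_every = snapshot_every,
      uptake_substitution_pool = uptake_substitution_pool,
      beta_u = alpha / n_u,
      beta_rho = alpha / n_rho
    ),
    class = "cfn_params"
  )
}

#' @export
print.cfn_params <- function(x, ...) {
  cat("Cross-feeding network parameters\n")
  cat(sprintf("  eta = %g, mu = %g, alpha = %g (beta_u = %.4g, beta_rho = %.4g)\n",
              x$eta, x$mu, x$alpha, x$beta_u, x$beta_rho))
  cat(sprintf("  n_u = %d, n_rho = %d, p_u = %g, p_rho = %g\n",
              x$n_u, x$n_rho, x$p_u, x$p_rho))
  cat(sprintf("  pool size G = %d, total supply = %g (%d supplied resource%s)\n",
              x$pool_size, sum(x$supply), sum(x$supply > 0),
              if (sum(x$supply > 0) == 1L) "" else "s"))
  cat(sprintf("  clustering: theta = %g, w_u = %g, w_rho = %g\n",
              x$theta, x$w_u, x$w_rho))
  cat(sprintf("  n_steps = %d, seed = %d\n", x$n_steps, x$seed))
  invisible(x)
}
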