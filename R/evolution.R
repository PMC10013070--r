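#' @title Evolutionary protocol
#' @description One evolutionary step has two stages: (1) a new consumer is
#'   generated as a mutated descendant of a flow-weighted random ancestor and
#'   inserted; (2) stationary flows are recomputed and consumers whose uptake
#'   falls below the extinction threshold \eqn{\mu} are removed one at a time
#'   (lowest first, flows updated after every removal) until the community is
#'   stable. All randomness is consumed from R's global generator in a fixed
#'   draw order (ancestor choice; affinity noise and drift; release noise and
#'   drift; uptake substitution coin, index, target; release substitution
#'   coin, index, target), so runs are reproducible for a given seed.
#' @name evolution
NULL

# lean flow evaluation used inside the simulation loop; mirrors cfn_flow()
# without naming/link assembly. Returns flows on the present subspace.
.flow_fast <- function(community, params) {
  U <- community$U
  Rho <- community$Rho
  supply <- params$supply
  eta <- params$eta
  Mt <- which(supply > 0 | community$prod_count > 0L)
  s <- supply[Mt]
  if (ncol(U) == 0L)
    return(list(F = s, J = numeric(0), Mt = Mt, A = sum(s),
                Sh = matrix(0, length(Mt), 0L), Utot = numeric(length(Mt))))
  Usub <- U[Mt, , drop = FALSE]
  Utot <- rowSums(Usub)
  Sh <- Usub / Utot                    # rows: resources, cols: consumers
  Sh[Utot == 0, ] <- 0
  M <- length(Mt)
  Tm <- Rho[Mt, , drop = FALSE] %*% t(Sh)
  F <- solve(diag(M) - eta * Tm, s)
  F[abs(F) < .flow_clamp] <- 0
  J <- eta * as.vector(crossprod(Sh, F))
  list(F = F, J = J, Mt = Mt, A = sum(F[Utot == 0]), Sh = Sh, Utot = Utot)
}

#' Choose the ancestor of the next consumer
#'
#' A resident is selected at random with probability proportional to its
#' stationary uptake flow \eqn{J_a}; residents with zero uptake are never
#' chosen.
#'
#' @param community A \code{cfn_community}.
#' @param J Stationary uptake flows of the residents, in community order.
#' @return The selected column index (position in the community).
#' @export
choose_ancestor <- function(community, J) {
  if (length(J) == 0L || sum(J) <= 0)
    stop("no resident with positive uptake flow; the community is nonviable")
  sample.int(length(J), 1L, prob = J)
}

#' Generate a mutated offspring of an ancestor
#'
#' Every positive trait entry x is replaced by
#' \eqn{\max(0, x (1 + \epsilon_1 + \epsilon_2))}, where \eqn{\epsilon_1} is
#' symmetric uniform noise on \eqn{[-\alpha, \alpha]} and \eqn{\epsilon_2} is
#' an equalizing drift drawn per entry from \eqn{U(0, \alpha/n_u)} (affinity)
#' or \eqn{U(0, \alpha/n_\varrho)} (release). Totals are then renormalized
#' (affinities to \eqn{\bar u}, release proportions to 1), so the trait
#' support is inherited unchanged.
#'
#' @param u,rho Trait vectors of the ancestor over the global pool.
#' @param params A \code{\link{cfn_params}} object.
#' @return List with mutated \code{u} and \code{rho}.
#' @export
mutate_offspring <- function(u, rho, params) {
  pu <- which(u > 0)
  pr <- which(rho > 0)
  e1 <- stats::runif(length(pu), -params$alpha, params$alpha)
  e2 <- stats::runif(length(pu), 0, params$beta_u)
  u[pu] <- pmax(0, u[pu] * (1 + e1 + e2))
  d1 <- stats::runif(length(pr), -params$alpha, params$alpha)
  d2 <- stats::runif(length(pr), 0, params$beta_rho)
  rho[pr] <- pmax(0, rho[pr] * (1 + d1 + d2))
  su <- sum(u)
  sr <- sum(rho)
  if (su <= 0 || sr <= 0)
    stop("mutation annihilated a trait vector; 'alpha' is too large")
  list(u = params$u_bar * u / su, rho = rho / sr)
}

#' Substitute one utilized resource for a new one
#'
#' With probability \code{p_u} one positive affinity entry (chosen uniformly)
#' is moved in full to a resource the consumer does not yet utilize. The
#' target is drawn uniformly from the configured source pool: the resources
#' currently present in the system (default) or the whole global pool.
#' Support size is invariant under any outcome.
#'
#' @param u Affinity vector of the candidate.
#' @param present Integer indices of currently present resources.
#' @param params A \code{\link{cfn_params}} object.
#' @return The (possibly) modified affinity vector.
#' @export
substitute_uptake <- function(u, present, params) {
  if (stats::runif(1L) >= params$p_u) return(u)
  pos <- which(u > 0)
  j <- pos[sample.int(length(pos), 1L)]
  cand <- if (params$uptake_substitution_pool == "present")
    setdiff(present, pos)
  else
    setdiff(seq_len(params$pool_size), pos)
  if (length(cand) == 0L)
    cand <- setdiff(seq_len(params$pool_size), pos)
  if (length(cand) == 0L) return(u)   # degenerate pool: nothing to swap in
  jp <- cand[sample.int(length(cand), 1L)]
  u[jp] <- u[j]
  u[j] <- 0
  u
}

#' Substitute one released product for a new one
#'
#' With probability \code{p_rho} one positive release entry (chosen
#' uniformly) is moved in full to a product drawn uniformly from the global
#' pool among resources the consumer does not currently release. This may
#' introduce a resource that was absent from the system, creating a potential
#' niche.
#'
#' @param rho Release vector of the candidate.
#' @param params A \code{\link{cfn_params}} object.
#' @return The (possibly) modified release vector.
#' @export
substitute_release <- function(rho, params) {
  if (stats::runif(1L) >= params$p_rho) return(rho)
  pos <- which(rho > 0)
  j <- pos[sample.int(length(pos), 1L)]
  cand <- which(rho == 0)
  if (length(cand) == 0L) return(rho)
  jp <- cand[sample.int(length(cand), 1L)]
  rho[jp] <- rho[j]
  rho[j] <- 0
  rho
}

#' Iterate threshold extinctions until the community is stable
#'
#' While any uptake flow lies below \eqn{\mu}, the consumer with the lowest
#' flow is removed (ties broken towards the youngest, i.e. largest id) and
#' the stationary flow recomputed. The candidate of the current step takes
#' part like any resident.
#'
#' @param community A \code{cfn_community} (typically with the freshly
#'   inserted candidate).
#' @param params A \code{\link{cfn_params}} object.
#' @return List with the stable \code{community}, the ids of removed
#'   consumers in removal order (\code{extinct}), and the final internal flow
#'   evaluation (\code{flow}).
#' @export
extinction_loop <- function(community, params) {
  extinct <- integer(0)
  repeat {
    fl <- .flow_fast(community, params)
    if (length(fl$J) == 0L || min(fl$J) >= params$mu) break
    worst <- which(fl$J == min(fl$J))
    worst <- worst[length(worst)]      # ids are in column order: youngest last
    extinct <- c(extinct, community$ids[worst])
    community <- remove_consumers(community, worst)
  }
  list(community = community, extinct = extinct, flow = fl)
}

#' Perform one evolutionary step
#'
#' @param community A stable \code{cfn_community}.
#' @param params A \code{\link{cfn_params}} object.
#' @param flow Optional internal flow evaluation of \code{community} (reused
#'   when the caller already has it).
#' @param new_id Id to assign to the candidate consumer.
#' @return List with the next stable \code{community}, its internal
#'   \code{flow}, and a \code{record} (class \code{cfn_step_record}) holding
#'   step, candidate and ancestor ids, establishment flag, resident
#'   extinctions with their competitive/cascade classification, resource
#'   gains and losses, and summary scalars.
#' @export
evolution_step <- function(community, params, flow = NULL,
                           new_id = max(community$ids) + 1L) {
  if (is.null(flow))
    flow <- .flow_fast(community, params)
  pre_res <- flow$Mt
  a <- choose_ancestor(community, flow$J)
  mut <- mutate_offspring(community$U[, a], community$Rho[, a], params)
  u <- substitute_uptake(mut$u, pre_res, params)
  rho <- substitute_release(mut$rho, params)
  cand <- list(u = u, rho = rho, id = new_id,
               ancestor = community$ids[a],
               birth_step = community$step + 1L)
  ext <- extinction_loop(add_consumer(community, cand), params)
  out <- ext$community
  out$step <- community$step + 1L
  established <- new_id %in% out$ids
  resident_ext <- setdiff(ext$extinct, new_id)
  classification <- classify_extinctions(
    community$U[, match(resident_ext, community$ids), drop = FALSE], u)
  post_res <- ext$flow$Mt
  record <- structure(list(
    step = out$step,
    new_consumer_id = new_id,
    ancestor_id = community$ids[a],
    established = established,
    extinct_ids = resident_ext,
    extinct_class = classification,
    resources_gained = setdiff(post_res, pre_res),
    resources_lost = setdiff(pre_res, post_res),
    N = ncol(out$U),
    M = length(post_res),
    A = ext$flow$A,
    surplus = sum(ext$flow$J - params$mu)
  ), class = "cfn_step_record")
  list(community = out, flow = ext$flow, record = record)
}

#' Simulate the evolutionary assembly of a cross-feeding network
#'
#' Runs the full protocol from a single random founding consumer for
#' \code{n_steps} steps. Per-step scalars are always recorded; the more
#' expensive community observables are evaluated every \code{record_every}
#' steps, and per-resource network statistics are stored as snapshots every
#' \code{snapshot_every} steps (the final state is always kept). Optionally
#' maintains the dynamic similarity clustering from a given step onwards.
#'
#' @param params A \code{\link{cfn_params}} object.
#' @param cluster_from Step at which to initialize dynamic cluster tracking
#'   (\code{NULL} disables it).
#' @param keep_events Keep the per-step extinction id lists (needed only for
#'   post-hoc event analyses; off by default to save memory).
#' @param progress Print a throttled progress line.
#' @return An object of class \code{cfn_sim}; see Details.
#' @details The returned object contains \describe{
#'   \item{steps}{data frame with one row per step: \code{step}, \code{N},
#'     \code{M}, \code{A}, \code{surplus}, \code{established},
#'     \code{n_extinct}, \code{n_cascade}, \code{n_gained}, \code{n_lost},
#'     \code{new_id}, \code{ancestor_id}.}
#'   \item{records}{data frame of windowed observables at
#'     \code{record_every} intervals: mean evolutionary potential, genotypic
#'     and functional diversity, mean effective richness (affinity and
#'     inflow), uptake evenness, Pielou evenness of consumer and resource
#'     flows.}
#'   \item{snapshots}{list of per-resource statistic tables (see
#'     \code{\link{network_statistics}}) at \code{snapshot_every} intervals.}
#'   \item{final}{the final stable community and its full
#'     \code{\link{cfn_flow}}.}
#'   \item{clusters}{the cluster tracker state and history, when enabled.}
#' }
#' @examples
#' sim <- cfn_simulate(cfn_params(n_steps = 50, seed = 42))
#' summary(sim)
#' @export
cfn_simulate <- function(params, cluster_from = NULL, keep_events = FALSE,
                         progress = FALSE) {
  set.seed(params$seed)
  community <- founder_community(params)
  n <- params$n_steps

  # per-step scalars collected in plain vectors (cheap to write in the loop)
  sv <- list(N = integer(n), M = integer(n), A = numeric(n),
             surplus = numeric(n), established = logical(n),
             n_extinct = integer(n), n_cascade = integer(n),
             n_gained = integer(n), n_lost = integer(n),
             new_id = integer(n), ancestor_id = integer(n))
  rec_steps <- seq_len(n)[seq_len(n) %% params$record_every == 0L]
  nr <- length(rec_steps)
  records <- data.frame(
    step = rec_steps, mean_potential = rep(NA_real_, nr),
    D_genotypic = rep(NA_real_, nr), D_functional = rep(NA_real_, nr),
    reff_affinity = rep(NA_real_, nr), reff_inflow = rep(NA_real_, nr),
    uptake_evenness = rep(NA_real_, nr),
    consumer_evenness = rep(NA_real_, nr), resource_evenness = rep(NA_real_, nr)
  )
  snapshots <- list()
  snapshot_steps <- integer(0)
  events <- if (keep_events) vector("list", n)
  clusters <- NULL

  flow <- .flow_fast(community, params)
  next_id <- 2L
  ri <- 1L
  terminated <- NA_integer_

  for (t in seq_len(n)) {
    stepres <- evolution_step(community, params, flow, new_id = next_id)
    community <- stepres$community
    flow <- stepres$flow
    rec <- stepres$record
    next_id <- next_id + 1L
    sv$N[t] <- rec$N; sv$M[t] <- rec$M
    sv$A[t] <- rec$A; sv$surplus[t] <- rec$surplus
    sv$established[t] <- rec$established
    sv$n_extinct[t] <- length(rec$extinct_ids)
    sv$n_cascade[t] <- sum(rec$extinct_class == "cascade")
    sv$n_gained[t] <- length(rec$resources_gained)
    sv$n_lost[t] <- length(rec$resources_lost)
    sv$new_id[t] <- rec$new_consumer_id
    sv$ancestor_id[t] <- rec$ancestor_id
    if (keep_events) events[[t]] <- rec

    if (!is.null(cluster_from) && t >= cluster_from) {
      if (t == cluster_from || is.null(clusters)) {
        clusters <- initial_clustering(community, params)
      } else {
        clusters <- update_clusters(clusters, rec, community, params)
      }
    }

    if (ri <= length(rec_steps) && t == rec_steps[ri]) {
      obs <- .record_observables(community, flow, params)
      records[ri, -1L] <- obs
      ri <- ri + 1L
    }
    if (is.finite(params$snapshot_every) &&
        t %% params$snapshot_every == 0L) {
      snapshots[[length(snapshots) + 1L]] <-
        .snapshot_statistics(community, flow)
      snapshot_steps <- c(snapshot_steps, t)
    }
    if (progress && t %% 5000L == 0L)
      message(sprintf("step %d / %d: N = %d, M = %d", t, n, rec$N, rec$M))
    if (rec$N == 0L) {
      terminated <- t
      sv <- lapply(sv, `[`, seq_len(t))
      break
    }
  }

  steps <- data.frame(step = seq_along(sv$N), sv)
  full_flow <- cfn_flow(community)
  structure(list(
    params = params,
    steps = steps,
    records = records[!is.na(records$D_genotypic), , drop = FALSE],
    snapshots = snapshots,
    snapshot_steps = snapshot_steps,
    final = list(community = community, flow = full_flow),
    events = events,
    clusters = clusters,
    terminated_at = terminated
  ), class = "cfn_sim")
}

# observables logged along a run (community-level scalars)
.record_observables <- function(community, flow, params) {
  fullflow <- .as_cfn_flow(flow, community)
  pot <- evolutionary_potential(community, fullflow)
  dg <- similarity_diversity(community, fullflow, mode = "genotypic")
  df <- similarity_diversity(community, fullflow, mode = "functional")
  ra <- mean(apply(community$U, 2L, effective_richness))
  link <- t(flow$Sh) * rep(flow$F, each = ncol(community$U))
  rf <- mean(apply(link, 1L, effective_richness))
  ue <- mean(apply(community$U, 2L, evenness, mode = "uptake",
                   n_u = params$n_u))
  c(mean_potential = mean(pot$delta_J),
    D_genotypic = dg$D, D_functional = df$D,
    reff_affinity = ra, reff_inflow = rf,
    uptake_evenness = ue,
    consumer_evenness = evenness(flow$J),
    resource_evenness = evenness(flow$F))
}

# promote a lean loop flow to the subset of cfn_flow fields observables use
.as_cfn_flow <- function(flow, community) {
  sigma <- t(flow$Sh)
  dimnames(sigma) <- list(community$ids, flow$Mt)
  F <- flow$F
  names(F) <- flow$Mt
  J <- flow$J
  names(J) <- community$ids
  structure(list(resources = flow$Mt, F = F, J = J, sigma = sigma,
                 A = flow$A, Utot = flow$Utot,
                 consumed = flow$Mt[flow$Utot > 0]),
            class = "cfn_flow")
}

.snapshot_statistics <- function(community, flow) {
  network_statistics(community, .as_cfn_flow(flow, community))$resources
}

#' @export
print.cfn_step_record <- function(x, ...) {
  cat(sprintf("Step %d: candidate %d (ancestor %d) %s; %d extinction%s\n",
              x$step, x$new_consumer_id, x$ancestor_id,
              if (x$established) "established" else "failed",
              length(x$extinct_ids),
              if (length(x$extinct_ids) == 1L) "" else "s"))
  invisible(x)
}
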