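#' @title Stationary network flow
#' @description The stationary resource flow of a fixed community solves the
#'   linear balance \eqn{F = s + \eta T F} on the present-resource subspace,
#'   where \eqn{T = R S} is the resource transformation matrix composed of
#'   release partitioning \eqn{R} and uptake shares \eqn{S}. Because
#'   \eqn{0 < \eta < 1} and \eqn{T} is a flow redistribution (column sums at
#'   most one), \eqn{\mathrm{Id} - \eta T} is invertible and the solution
#'   equals the geometric (Neumann) series \eqn{\sum_n \eta^n T^n s}.
#' @name stationary-flow
NULL

# numerical guards
.flow_residual_tol <- 1e-10
.flow_clamp <- 1e-14

#' Uptake share matrix
#'
#' Share \eqn{\sigma_{i,j} = u_{i,j} / \sum_k u_{k,j}} of resource j acquired
#' by consumer i. Columns over consumed resources sum to one; a resource with
#' no positive-affinity resident gets an all-zero column.
#'
#' @param community A \code{cfn_community}.
#' @param resources Integer vector of resource indices to use (defaults to
#'   the present resources).
#' @return An \code{N x M} matrix; rows named by consumer id, columns by
#'   resource index.
#' @examples
#' p <- cfn_params(pool_size = 2)
#' comm <- cfn_community(list(
#'   list(u = c(2, 0), rho = c(1, 0)),
#'   list(u = c(1, 0), rho = c(1, 0))), p)
#' uptake_shares(comm)  # 2/3 and 1/3 on resource 1
#' @export
uptake_shares <- function(community, resources = present_resources(community)) {
  if (any(community$U < 0)) stop("negative affinities are invalid")
  Usub <- community$U[resources, , drop = FALSE]
  tot <- rowSums(Usub)
  Sh <- Usub / tot
  Sh[tot == 0, ] <- 0
  sigma <- t(Sh)
  dimnames(sigma) <- list(community$ids, resources)
  sigma
}

#' Resource transformation matrix
#'
#' Concatenation \eqn{T = R S} of uptake partitioning and release
#' partitioning: the projection of one pass through the bipartite network
#' onto the unipartite resource space. \eqn{T} never increases the total
#' flow, \eqn{\|Tv\|_1 \le \|v\|_1} for \eqn{v \ge 0}.
#'
#' @param sigma \code{N x M} uptake-share matrix (from
#'   \code{\link{uptake_shares}}).
#' @param releases \code{M x N} release matrix with columns summing to at
#'   most one (a consumer may release to resources outside the selected set).
#' @return The \code{M x M} transformation matrix.
#' @export
transformation_matrix <- function(sigma, releases) {
  if (ncol(releases) != nrow(sigma) || nrow(releases) != ncol(sigma))
    stop("dimension mismatch between 'sigma' and 'releases'")
  releases %*% sigma
}

#' Solve the stationary flow balance
#'
#' Direct dense solve of \eqn{(\mathrm{Id} - \eta T) F = s}. The residual is
#' checked against an absolute tolerance of 1e-10 and tiny flows (< 1e-14)
#' are clamped to zero so that accumulation sums are free of sign noise.
#'
#' @param Tm Transformation matrix (\code{M x M}).
#' @param supply Supply vector of length \code{M}.
#' @param eta Recycling fraction in (0, 1).
#' @return Stationary flow vector \code{F >= 0}.
#' @examples
#' solve_flow(matrix(1), 1, 0.7)  # 1 / (1 - 0.7)
#' @export
solve_flow <- function(Tm, supply, eta) {
  if (eta <= 0 || eta >= 1) stop("'eta' must lie in (0, 1)")
  M <- length(supply)
  if (M == 0L) return(numeric(0))
  A <- diag(M) - eta * Tm
  F <- solve(A, supply)
  if (max(abs(A %*% F - supply)) > .flow_residual_tol)
    stop("stationary flow solve exceeded residual tolerance")
  F[abs(F) < .flow_clamp] <- 0
  F
}

#' Consumer uptake flows and per-link flows
#'
#' Stationary uptake of consumer i is \eqn{J_i = \eta \sum_j \sigma_{i,j}
#' F_j}; the per-link uptake is \eqn{J_{j \to i} = \eta \sigma_{i,j} F_j} and
#' (when \code{releases} is supplied) the per-link release is
#' \eqn{F_{i \to j} = \varrho_{j,i} J_i}.
#'
#' @param sigma \code{N x M} uptake-share matrix.
#' @param F Stationary resource flow vector (length \code{M}).
#' @param eta Recycling fraction.
#' @param releases Optional \code{M x N} release matrix for link releases.
#' @return List with \code{J} (length \code{N}), \code{link_uptake}
#'   (\code{N x M}) and, if requested, \code{link_release} (\code{M x N}).
#' @export
consumer_uptakes <- function(sigma, F, eta, releases = NULL) {
  link_uptake <- eta * sweep(sigma, 2L, F, "*")
  J <- rowSums(link_uptake)
  out <- list(J = J, link_uptake = link_uptake)
  if (!is.null(releases))
    out$link_release <- sweep(releases, 2L, J, "*")
  out
}

#' Accumulation flow
#'
#' Total stationary flow into present resources that currently have no
#' consumer; such resources act as sinks.
#'
#' @param F Stationary flow vector.
#' @param consumed Logical vector marking resources with at least one
#'   positive-affinity resident.
#' @return The accumulation flow \code{A}.
#' @export
accumulation_flow <- function(F, consumed) {
  sum(F[!consumed])
}

#' Full stationary flow state of a community
#'
#' Convenience wrapper computing shares, transformation matrix, stationary
#' flows, per-consumer and per-link flows, accumulation and surplus flow in
#' one pass on the present-resource subspace.
#'
#' @param community A \code{cfn_community}.
#' @param detail If \code{FALSE}, skip the per-link matrices (cheaper).
#' @return An object of class \code{cfn_flow}: list with \code{resources}
#'   (present resource indices), \code{F} (flows, named by resource),
#'   \code{J} (uptake flows, named by consumer id), \code{sigma},
#'   \code{link_uptake}, \code{link_release}, \code{A} (accumulation flow),
#'   \code{surplus} (\eqn{\sum_i (J_i - \mu)}), \code{consumed} (indices of
#'   consumed resources).
#' @examples
#' p <- cfn_params(pool_size = 2, eta = 0.7)
#' comm <- cfn_community(list(list(u = c(1, 0), rho = c(1, 0))), p)
#' fl <- cfn_flow(comm)
#' fl$F  # 1 / 0.3 on the supplied resource
#' @export
cfn_flow <- function(community, detail = TRUE) {
  params <- community$params
  res <- present_resources(community)
  s <- params$supply[res]
  N <- ncol(community$U)
  if (N == 0L) {
    F <- s
    names(F) <- res
    return(structure(list(resources = res, F = F, J = numeric(0),
                          sigma = matrix(0, 0, length(res)),
                          link_uptake = NULL, link_release = NULL,
                          A = sum(s), surplus = 0,
                          consumed = integer(0)),
                     class = "cfn_flow"))
  }
  sigma <- uptake_shares(community, res)
  releases <- community$Rho[res, , drop = FALSE]
  Tm <- transformation_matrix(sigma, releases)
  F <- solve_flow(Tm, s, params$eta)
  names(F) <- res
  consumed_mask <- colSums(sigma) > 0
  up <- consumer_uptakes(sigma, F, params$eta,
                         releases = if (detail) releases)
  J <- up$J
  names(J) <- community$ids
  structure(list(resources = res, F = F, J = J, sigma = sigma,
                 link_uptake = if (detail) up$link_uptake,
                 link_release = if (detail) up$link_release,
                 A = accumulation_flow(F, consumed_mask),
                 surplus = sum(J - params$mu),
                 consumed = res[consumed_mask]),
            class = "cfn_flow")
}

#' @export
print.cfn_flow <- function(x, ...) {
  cat(sprintf("Stationary CFN flow: %d resources, %d consumers\n",
              length(x$F), length(x$J)))
  cat(sprintf("  total resource flow = %.6g, total uptake = %.6g\n",
              sum(x$F), sum(x$J)))
  cat(sprintf("  accumulation A = %.6g, surplus = %.6g\n", x$A, x$surplus))
  invisible(x)
}

#' Theoretical capacity bounds
#'
#' Given total supply \eqn{\bar s}, recycling fraction \eqn{\eta}, extinction
#' threshold \eqn{\mu} and accumulation flow \eqn{A}, the total resource flow
#' is \eqn{\bar F = (\bar s - \eta A)/(1-\eta) \le F_{max} = \bar s/(1-\eta)},
#' the total uptake flow is \eqn{\bar J = \eta(\bar F - A)} and the number of
#' persistent consumers is bounded by \eqn{N_{max} =
#' \lfloor \eta (\bar s - A) / (\mu (1-\eta)) \rfloor}.
#'
#' @param supply_total Total external supply rate \eqn{\bar s}.
#' @param eta Recycling fraction in (0, 1).
#' @param mu Extinction threshold.
#' @param A Accumulation flow (default 0 gives the network-structure-free
#'   bound).
#' @return Object of class \code{cfn_capacity}: list with \code{F_max},
#'   \code{F_bar}, \code{J_bar}, \code{A}, \code{N_max} and \code{N_max_A0}.
#' @examples
#' capacity(1.0, eta = 0.7, mu = 0.01)$N_max  # 233
#' @export
capacity <- function(supply_total, eta, mu, A = 0) {
  if (eta <= 0 || eta >= 1) stop("'eta' must lie in (0, 1)")
  if (supply_total < 0 || mu <= 0 || A < 0) stop("invalid capacity inputs")
  F_max <- supply_total / (1 - eta)
  if (A > F_max) stop("accumulation flow cannot exceed the maximal total flow")
  F_bar <- (supply_total - eta * A) / (1 - eta)
  J_bar <- eta * (F_bar - A)
  structure(list(
    F_max = F_max, F_bar = F_bar, J_bar = J_bar, A = A,
    N_max = floor(eta / (mu * (1 - eta)) * (supply_total - A)),
    N_max_A0 = floor(eta / (mu * (1 - eta)) * supply_total)
  ), class = "cfn_capacity")
}

#' @export
print.cfn_capacity <- function(x, ...) {
  cat("CFN capacity bounds\n")
  cat(sprintf("  F_max = %.6g, F_bar = %.6g, J_bar = %.6g (A = %.6g)\n",
              x$F_max, x$F_bar, x$J_bar, x$A))
  cat(sprintf("  N_max = %d (with A = 0: %d)\n", x$N_max, x$N_max_A0))
  invisible(x)
}

#' Export a flow state as a weighted bipartite edge list
#'
#' One row per realized uptake link (resource to consumer) and release link
#' (consumer to resource). Consumers are labelled \code{c<id>}, resources
#' \code{r<index>}.
#'
#' @param flow A \code{cfn_flow} computed with \code{detail = TRUE}.
#' @param file Optional path; when given, the table is written as
#'   tab-separated text.
#' @return The edge-list \code{data.frame} (invisibly when written to file)
#'   with columns \code{source}, \code{target}, \code{type}, \code{flow}.
#' @export
flow_edges <- function(flow, file = NULL) {
  if (is.null(flow$link_uptake))
    stop("flow was computed without link detail")
  up <- which(flow$link_uptake > 0, arr.ind = TRUE)
  rel <- which(flow$link_release > 0, arr.ind = TRUE)
  ids <- rownames(flow$sigma)
  res <- flow$resources
  edges <- rbind(
    data.frame(source = paste0("r", res[up[, 2L]]),
               target = paste0("c", ids[up[, 1L]]),
               type = "uptake",
               flow = flow$link_uptake[up],
               stringsAsFactors = FALSE),
    data.frame(source = paste0("c", ids[rel[, 2L]]),
               target = paste0("r", res[rel[, 1L]]),
               type = "release",
               flow = flow$link_release[rel],
               stringsAsFactors = FALSE)
  )
  edges <- edges[order(edges$type, edges$source, edges$target), ]
  rownames(edges) <- NULL
  if (!is.null(file)) {
    utils::write.table(edges, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(edges))
  }
  edges
}

#' Export a flow state in GraphML format
#'
#' Writes the bipartite flow network to a standard graph-exchange file that
#' network tools (igraph, Gephi, Cytoscape) read directly.
#'
#' @param flow A \code{cfn_flow} computed with \code{detail = TRUE}.
#' @param file Output path (conventionally \code{.graphml}).
#' @return The path, invisibly.
#' @export
flow_graphml <- function(flow, file) {
  edges <- flow_edges(flow)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  igraph::V(g)$kind <- ifelse(substr(igraph::V(g)$name, 1L, 1L) == "r",
                              "resource", "consumer")
  igraph::E(g)$weight <- edges$flow
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}
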