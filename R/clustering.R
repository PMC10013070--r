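#' @title Dynamic similarity clustering
#' @description Consumers are grouped into taxon-like clusters by their
#'   genotypic dissimilarity. An initial complete-linkage clustering (cut at
#'   the diameter threshold \eqn{\vartheta}) seeds the partition; afterwards
#'   every established consumer joins its direct ancestor's cluster, and a
#'   cluster whose diameter is pushed beyond \eqn{\vartheta} by the addition
#'   is split by re-clustering its members, the part containing the newcomer
#'   receiving a fresh cluster id. Extinctions remove members; a cluster
#'   closes when its last member dies.
#' @name clustering
NULL

#' Genotypic dissimilarity between two consumers
#'
#' Weighted, normalized L1 distance of affinity and release vectors:
#' \deqn{d_{i,k} = (w_u \sum_j |u_{i,j} - u_{k,j}| +
#'   w_\varrho \sum_j |\varrho_{j,i} - \varrho_{j,k}|) /
#'   (2 w_u \bar u + 2 w_\varrho),}
#' which lies in [0, 1]: 0 for identical consumers, 1 when both supports are
#' disjoint.
#'
#' @param a,b Consumers: lists with vectors \code{u} and \code{rho} over the
#'   same resource index space.
#' @param params A \code{\link{cfn_params}} (supplies \code{w_u},
#'   \code{w_rho}, \code{u_bar}).
#' @return Dissimilarity in [0, 1].
#' @examples
#' p <- cfn_params(pool_size = 2)
#' x <- list(u = c(1, 0), rho = c(1, 0))
#' y <- list(u = c(0, 1), rho = c(0, 1))
#' dissimilarity(x, y, p)  # 1
#' @export
dissimilarity <- function(a, b, params) {
  denom <- 2 * params$w_u * params$u_bar + 2 * params$w_rho
  if (denom <= 0) stop("at least one of 'w_u', 'w_rho' must be positive")
  (params$w_u * sum(abs(a$u - b$u)) +
     params$w_rho * sum(abs(a$rho - b$rho))) / denom
}

#' Pairwise dissimilarity matrix of a community
#'
#' @param community A \code{cfn_community}.
#' @param params Parameters (defaults to the community's own).
#' @return A symmetric matrix with consumer ids as dimnames.
#' @export
dissimilarity_matrix <- function(community, params = community$params) {
  denom <- 2 * params$w_u * params$u_bar + 2 * params$w_rho
  if (denom <= 0) stop("at least one of 'w_u', 'w_rho' must be positive")
  du <- as.matrix(stats::dist(t(community$U), method = "manhattan"))
  dr <- as.matrix(stats::dist(t(community$Rho), method = "manhattan"))
  d <- (params$w_u * du + params$w_rho * dr) / denom
  dimnames(d) <- list(community$ids, community$ids)
  d
}

# registry row helper
.new_cluster_row <- function(id, step, parent = NA_integer_) {
  data.frame(cluster = id, birth_step = step, parent = parent,
             closed_step = NA_integer_)
}

#' Initial hierarchical clustering of a community
#'
#' Complete-linkage agglomerative clustering of the pairwise genotypic
#' dissimilarities, cut at height \eqn{\vartheta}; every resulting cluster
#' has diameter (maximal within-cluster dissimilarity) at most
#' \eqn{\vartheta}. Ancestry is deliberately ignored here; it only drives
#' the subsequent updates.
#'
#' @param community A \code{cfn_community}.
#' @param params Parameters (defaults to the community's own).
#' @return An object of class \code{cfn_clusters}: list with
#'   \code{assignment} (consumer id -> cluster id), \code{registry} (one row
#'   per cluster ever opened), \code{dmat} (pairwise dissimilarities of
#'   residents), \code{links} (cluster lineage edges), \code{history}
#'   (per-step active cluster/consumer sets), \code{dendrogram} (the initial
#'   \code{hclust} tree) and \code{next_cluster}.
#' @export
initial_clustering <- function(community, params = community$params) {
  d <- dissimilarity_matrix(community, params)
  n <- ncol(d)
  if (n == 0L) stop("cannot cluster an empty community")
  if (n == 1L) {
    assignment <- stats::setNames(1L, community$ids)
    hc <- NULL
  } else {
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    assignment <- stats::cutree(hc, h = params$theta)
    names(assignment) <- community$ids
  }
  ids <- sort(unique(assignment))
  registry <- do.call(rbind, lapply(ids, .new_cluster_row,
                                    step = community$step))
  structure(list(
    assignment = assignment,
    registry = registry,
    dmat = d,
    links = data.frame(step = integer(0), from = integer(0),
                       to = integer(0), weight = numeric(0)),
    history = list(list(step = community$step,
                        clusters = ids,
                        consumers = community$ids,
                        sizes = as.integer(table(assignment)))),
    dendrogram = hc,
    theta = params$theta,
    next_cluster = max(ids) + 1L
  ), class = "cfn_clusters")
}

#' Advance the cluster partition by one evolutionary step
#'
#' Removes extinct consumers (closing emptied clusters), adds an established
#' candidate to its ancestor's cluster and, if the extended cluster's
#' diameter exceeds \eqn{\vartheta}, splits it by complete-linkage
#' re-clustering of the extended membership cut at \eqn{\vartheta}; the part
#' containing the newcomer (and any further part, in the rare event the cut
#' yields more than two) receives a fresh cluster id while the largest
#' remaining part keeps the old id. Lineage links from the previous step's
#' clusters to the current ones are appended with weights proportional to
#' the receiving cluster's relative size.
#'
#' @param state A \code{cfn_clusters} state consistent with the community
#'   before the step.
#' @param record The \code{cfn_step_record} of the step.
#' @param community The community after the step.
#' @param params Parameters (defaults to the community's own).
#' @return The updated \code{cfn_clusters} state.
#' @export
update_clusters <- function(state, record, community,
                            params = community$params) {
  assignment <- state$assignment
  prev_clusters <- sort(unique(assignment))
  # carried-over membership: cluster id of each surviving consumer
  gone <- as.character(record$extinct_ids)
  if (!record$established)
    gone <- c(gone, as.character(record$new_consumer_id))
  gone <- intersect(gone, names(assignment))
  assignment <- assignment[setdiff(names(assignment), gone)]
  state$dmat <- state$dmat[!rownames(state$dmat) %in% gone,
                           !colnames(state$dmat) %in% gone, drop = FALSE]

  if (record$established) {
    anc <- as.character(record$ancestor_id)
    if (!anc %in% names(state$assignment))
      stop("ancestor is not tracked by the cluster state")
    target <- state$assignment[[anc]]
    # distances of the newcomer to all survivors
    i <- match(record$new_consumer_id, community$ids)
    newc <- list(u = community$U[, i], rho = community$Rho[, i])
    others <- match(as.integer(names(assignment)), community$ids)
    denom <- 2 * params$w_u * params$u_bar + 2 * params$w_rho
    dnew <- (params$w_u *
               colSums(abs(community$U[, others, drop = FALSE] - newc$u)) +
             params$w_rho *
               colSums(abs(community$Rho[, others, drop = FALSE] - newc$rho))) /
      denom
    key <- as.character(record$new_consumer_id)
    dm <- rbind(cbind(state$dmat, dnew), c(dnew, 0))
    rownames(dm)[nrow(dm)] <- key
    colnames(dm)[ncol(dm)] <- key
    state$dmat <- dm
    assignment[key] <- target

    members <- names(assignment)[assignment == target]
    diam <- if (length(members) > 1L)
      max(state$dmat[members, members]) else 0
    if (diam > params$theta) {
      sub <- state$dmat[members, members]
      hc <- stats::hclust(stats::as.dist(sub), method = "complete")
      parts <- stats::cutree(hc, h = params$theta)
      if (max(parts) < 2L) parts <- stats::cutree(hc, k = 2L)
      new_part <- parts[[key]]
      old_parts <- setdiff(unique(parts), new_part)
      # the largest part not containing the newcomer keeps the old id
      keep <- old_parts[which.max(tabulate(parts)[old_parts])]
      for (p in setdiff(unique(parts), keep)) {
        fresh <- state$next_cluster
        state$next_cluster <- state$next_cluster + 1L
        assignment[members[parts == p]] <- fresh
        state$registry <- rbind(state$registry,
                                .new_cluster_row(fresh, record$step,
                                                 parent = target))
      }
    }
  }

  # close clusters that lost their last member
  active <- unique(assignment)
  emptied <- setdiff(prev_clusters, active)
  if (length(emptied))
    state$registry$closed_step[state$registry$cluster %in% emptied &
                                 is.na(state$registry$closed_step)] <-
      record$step

  # lineage links: survivors map old cluster -> new cluster; weights are
  # proportional to the receiving cluster's relative size at the new step
  old_assign <- state$assignment
  common <- intersect(names(assignment), names(old_assign))
  if (length(common)) {
    pairs <- data.frame(from = old_assign[common], to = assignment[common])
    agg <- stats::aggregate(list(n = pairs$from),
                            by = list(from = pairs$from, to = pairs$to),
                            FUN = length)
    agg$weight <- agg$n / length(assignment)
    state$links <- rbind(state$links,
                         data.frame(step = record$step, from = agg$from,
                                    to = agg$to, weight = agg$weight))
  }

  state$assignment <- assignment
  state$history[[length(state$history) + 1L]] <-
    list(step = record$step,
         clusters = sort(active),
         consumers = as.integer(names(assignment)),
         sizes = as.integer(table(assignment)))
  state
}

#' Cluster-level statistics of a tracked run
#'
#' Turnover curves for consumers and clusters over a set of step intervals,
#' distributions of (log) cluster sizes and lifespans, and the alluvial link
#' table.
#'
#' @param state A \code{cfn_clusters} state after a tracked run.
#' @param intervals Step intervals for the turnover curves; intervals longer
#'   than the tracked window are dropped.
#' @return List with \code{turnover} (data frame: interval, mean and sd of
#'   consumer and cluster turnover), \code{sizes} (pooled cluster sizes),
#'   \code{lifespans} (per closed or still-open cluster), and \code{links}.
#' @export
cluster_statistics <- function(state,
                               intervals = c(1L, 10L, 100L, 1000L, 10000L)) {
  hist <- state$history
  steps <- vapply(hist, `[[`, integer(1), "step")
  last <- steps[length(steps)]
  turn <- do.call(rbind, lapply(intervals[intervals < length(steps)],
    function(I) {
      idx <- seq_len(length(steps) - I)
      ct <- vapply(idx, function(k)
        turnover(hist[[k]]$consumers, hist[[k + I]]$consumers), numeric(1))
      kt <- vapply(idx, function(k)
        turnover(hist[[k]]$clusters, hist[[k + I]]$clusters), numeric(1))
      data.frame(interval = I,
                 consumer_mean = mean(ct), consumer_sd = stats::sd(ct),
                 cluster_mean = mean(kt), cluster_sd = stats::sd(kt))
    }))
  reg <- state$registry
  lifespans <- data.frame(
    cluster = reg$cluster,
    birth_step = reg$birth_step,
    end_step = ifelse(is.na(reg$closed_step), last, reg$closed_step),
    closed = !is.na(reg$closed_step)
  )
  lifespans$lifespan <- lifespans$end_step - lifespans$birth_step
  list(turnover = turn,
       sizes = unlist(lapply(hist, `[[`, "sizes")),
       lifespans = lifespans,
       links = state$links)
}

#' @export
print.cfn_clusters <- function(x, ...) {
  cat(sprintf("Cluster state: %d consumers in %d clusters (theta = %g, %d ever opened)\n",
              length(x$assignment), length(unique(x$assignment)),
              x$theta, nrow(x$registry)))
  invisible(x)
}

#' Export the initial dendrogram as a Newick tree string
#'
#' Nested-parentheses representation with branch lengths derived from the
#' complete-linkage merge heights, readable by any phylogenetics tool.
#'
#' @param state A \code{cfn_clusters} state whose initial clustering had at
#'   least two members.
#' @param file Optional path to write the string to.
#' @return The Newick string, invisibly when written to file.
#' @export
cluster_dendrogram_newick <- function(state, file = NULL) {
  if (is.null(state$dendrogram))
    stop("no dendrogram available (initial community had a single member)")
  phy <- ape::as.phylo(state$dendrogram)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
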