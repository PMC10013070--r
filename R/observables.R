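#' @title Community observables
#' @description Scalar and distributional statistics of an evolved
#'   cross-feeding community: evolutionary potential, similarity-sensitive
#'   diversity, effective richness, evenness, displacement classification,
#'   turnover, network statistics and series smoothing.
#' @name observables
NULL

#' Evolutionary potential of the resident consumers
#'
#' The marginal uptake gain of consumer i from affinity on resource j is
#' \eqn{dJ_i/du_{i,j} = \eta (1 - \sigma_{i,j}) R_j} with
#' \eqn{R_j = F_j / \sum_n u_{n,j}}. The evolutionary potential
#' \eqn{\Delta J_i} is the spread between the largest and smallest marginal
#' gain over the consumer's utilized resources (only entries with
#' \eqn{u_{i,j} > 0} may vary under the fixed affinity budget). A utilized
#' resource that is absent from the system, or has no consumers, contributes
#' a marginal gain of zero.
#'
#' @param community A \code{cfn_community}.
#' @param flow The community's \code{\link{cfn_flow}}.
#' @return List with \code{delta_J} (per consumer, named by id),
#'   \code{gain} (the N x M marginal gain matrix over present resources) and
#'   \code{mean} (the community average).
#' @export
evolutionary_potential <- function(community, flow) {
  eta <- community$params$eta
  N <- ncol(community$U)
  res <- flow$resources
  Utot <- rowSums(community$U[res, , drop = FALSE])
  R <- ifelse(Utot > 0, flow$F / Utot, 0)
  gain <- eta * (1 - flow$sigma) * rep(R, each = N)
  delta <- numeric(N)
  for (i in seq_len(N)) {
    used <- which(community$U[, i] > 0)
    g <- gain[i, match(used, res)]
    g[is.na(g)] <- 0     # utilized but absent resources carry no flow
    delta[i] <- max(g) - min(g)
  }
  names(delta) <- community$ids
  list(delta_J = delta, gain = gain, mean = mean(delta))
}

#' Similarity-sensitive community diversity
#'
#' Pairwise consumer similarities are cosine similarities of either the
#' affinity vectors (genotypic mode) or the realized per-link uptake flows
#' (functional mode). The ordinarity of consumer i is its summed similarity
#' to all residents, \eqn{\bar z_i = \sum_k z_{i,k}}, and the community
#' diversity of order 2 is \eqn{D = N^2 / \sum_{i,k} z_{i,k}}, which ranges
#' from 1 (all consumers identical) to N (pairwise orthogonal). A literal
#' variant \eqn{D = N / \sum_i \bar z_i} is available for comparison; it is
#' bounded above by 1 and is not the default (see the package vignette).
#'
#' @param x A \code{cfn_community}, or a matrix whose columns are the
#'   consumer vectors to compare.
#' @param flow The community's \code{\link{cfn_flow}}; required for
#'   functional mode when \code{x} is a community.
#' @param mode \code{"genotypic"} (affinities) or \code{"functional"}
#'   (uptake-flow profiles).
#' @param literal Use the order-1 normalization \eqn{N / \sum_i \bar z_i}
#'   instead of the order-2 index.
#' @return List with the diversity \code{D}, the ordinarity vector
#'   \code{ordinarity}, the similarity matrix \code{z} and the \code{mode}.
#' @examples
#' m <- diag(3)  # three orthogonal specialists
#' similarity_diversity(m)$D  # 3
#' @export
similarity_diversity <- function(x, flow = NULL,
                                 mode = c("genotypic", "functional"),
                                 literal = FALSE) {
  mode <- match.arg(mode)
  V <- if (inherits(x, "cfn_community")) {
    if (mode == "genotypic") {
      x$U
    } else {
      if (is.null(flow)) stop("functional mode needs the community flow")
      # per-link uptake profiles J_{j->i} as columns (resources down the
      # rows, so F recycles correctly); cosine similarity is invariant to
      # the common eta factor
      t(flow$sigma) * as.numeric(flow$F)
    }
  } else {
    as.matrix(x)
  }
  N <- ncol(V)
  if (N == 0L) stop("at least one consumer is required")
  nrm <- sqrt(colSums(V^2))
  zero <- nrm == 0
  Vn <- V
  Vn[, !zero] <- V[, !zero, drop = FALSE] /
    rep(nrm[!zero], each = nrow(V))
  Vn[, zero] <- 0
  z <- crossprod(Vn)
  diag(z) <- 1                      # self-similarity, also for zero vectors
  z[z > 1] <- 1
  ord <- rowSums(z)
  D <- if (literal) N / sum(ord) else N^2 / sum(z)
  list(D = D, ordinarity = ord, z = z, mode = mode)
}

#' Effective richness of a weight vector
#'
#' The exponential of the Shannon entropy of the normalized weights: 1 for a
#' single-resource specialist, up to the number of positive entries for a
#' perfect generalist.
#'
#' @param weights Non-negative weights (affinities or inflows).
#' @return A scalar in [1, number of positive entries].
#' @examples
#' effective_richness(c(0.5, 0.5, 0))  # 2
#' @export
effective_richness <- function(weights) {
  if (any(weights < 0)) stop("weights must be non-negative")
  s <- sum(weights)
  if (s <= 0) stop("all-zero weights have no effective richness")
  p <- weights[weights > 0] / s
  exp(-sum(p * log(p)))
}

#' Evenness of a value distribution
#'
#' Shannon entropy of the normalized values divided by the log of the number
#' of elements (Pielou mode, the default) or by \eqn{\log n_u} (uptake mode,
#' for per-consumer affinity or inflow profiles with fixed uptake
#' diversity). A singleton is perfectly even by convention.
#'
#' @param values Non-negative values with positive sum. Zero entries
#'   contribute nothing to the entropy but do count towards the element
#'   number in Pielou mode.
#' @param mode \code{"pielou"} or \code{"uptake"}.
#' @param n_u Uptake diversity; required in uptake mode.
#' @return Evenness in [0, 1].
#' @examples
#' evenness(c(1, 1, 0))  # log(2)/log(3)
#' @export
evenness <- function(values, mode = c("pielou", "uptake"), n_u = NULL) {
  mode <- match.arg(mode)
  if (any(values < 0) || sum(values) <= 0)
    stop("values must be non-negative with positive sum")
  denom <- if (mode == "uptake") {
    if (is.null(n_u)) stop("uptake mode requires 'n_u'")
    log(n_u)
  } else {
    log(length(values))
  }
  if (denom <= 0) return(1)         # singleton: no inequality expressible
  p <- values[values > 0] / sum(values)
  -sum(p * log(p)) / denom
}

#' Classify extinctions as competitive or cascade
#'
#' An extinction in a step is competitive exclusion when the extinct
#' consumer shares at least one positive-affinity resource with the newly
#' introduced consumer, and a cascade effect (indirect displacement through
#' the altered flow pattern) otherwise.
#'
#' @param extinct_u Affinity vectors of the extinct consumers (a matrix with
#'   one column per consumer, or a single vector).
#' @param new_u Affinity vector of the new consumer.
#' @return Character vector of labels, \code{"competitive"} or
#'   \code{"cascade"}.
#' @export
classify_extinctions <- function(extinct_u, new_u) {
  if (is.null(extinct_u) || length(extinct_u) == 0L) return(character(0))
  U <- as.matrix(extinct_u)
  shared <- colSums(U > 0 & new_u > 0) > 0
  ifelse(shared, "competitive", "cascade")
}

#' Turnover between two sets
#'
#' The size of the symmetric difference divided by the summed sizes,
#' \eqn{|A \Delta B| / (|A| + |B|) \in [0, 1]}: 0 for identical sets, 1 for
#' disjoint nonempty sets.
#'
#' @param a,b Vectors interpreted as sets (of consumer ids, cluster ids,
#'   resource indices, ...).
#' @return The turnover value.
#' @examples
#' turnover(1:3, 2:4)  # 1/3
#' @export
turnover <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) + length(b) == 0L)
    stop("turnover of two empty sets is undefined")
  sym <- length(setdiff(a, b)) + length(setdiff(b, a))
  sym / (length(a) + length(b))
}

#' Per-resource and per-consumer network statistics
#'
#' For each present resource: the stationary flow \eqn{F_j}, the community
#' total affinity \eqn{U_j = \sum_i u_{i,j}}, the consumer count \eqn{C_j}
#' (number of residents with positive affinity), the producer count
#' \eqn{P_j} (number with positive release), and the mean affinity
#' \eqn{U_j / C_j}. For each consumer: the uptake flow and its rank. Degree
#' histograms count resources by their consumer (out-) and producer (in-)
#' degree.
#'
#' @param community A \code{cfn_community}.
#' @param flow The community's \code{\link{cfn_flow}}.
#' @return List of data frames \code{resources}, \code{consumers} and
#'   \code{degrees} (columns \code{degree}, \code{n_consumers_hist},
#'   \code{n_producers_hist}).
#' @export
network_statistics <- function(community, flow) {
  res <- flow$resources
  Usub <- community$U[res, , drop = FALSE]
  Rsub <- community$Rho[res, , drop = FALSE]
  C <- rowSums(Usub > 0)
  P <- rowSums(Rsub > 0)
  Uj <- rowSums(Usub)
  resources <- data.frame(
    resource = res, F = as.numeric(flow$F), U = Uj,
    n_consumers = C, n_producers = P,
    mean_affinity = ifelse(C > 0, Uj / C, 0)
  )
  J <- flow$J
  consumers <- data.frame(id = community$ids, J = as.numeric(J),
                          rank = rank(-J, ties.method = "first"))
  degmax <- max(C, P, 0L)
  degrees <- data.frame(
    degree = 0:degmax,
    n_consumers_hist = tabulate(C + 1L, degmax + 1L),
    n_producers_hist = tabulate(P + 1L, degmax + 1L)
  )
  list(resources = resources, consumers = consumers, degrees = degrees)
}

#' Log-log slope of total affinity against resource flow
#'
#' Ordinary least squares on base-10 logarithms of the pooled
#' \eqn{(F_j, U_j)} pairs, restricted to resources with flow above
#' \code{min_flow}. A slope near one indicates that the community's total
#' uptake effort on a resource is proportional to its availability.
#'
#' @param resource_tables A single per-resource table from
#'   \code{\link{network_statistics}} or a list of them (e.g. the snapshots
#'   of a run), pooled.
#' @param min_flow Lower flow cutoff (default 0.001).
#' @return List with \code{slope}, \code{intercept} and the number of pooled
#'   points \code{n}.
#' @export
affinity_flow_slope <- function(resource_tables, min_flow = 0.001) {
  if (is.data.frame(resource_tables)) resource_tables <- list(resource_tables)
  tab <- do.call(rbind, resource_tables)
  tab <- tab[tab$F > min_flow & tab$U > 0, ]
  if (nrow(tab) < 2L) stop("not enough points above the flow cutoff")
  fit <- stats::lm(log10(U) ~ log10(F), data = tab)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       n = nrow(tab))
}

#' Exponent of a log-linear fit to degree frequencies
#'
#' Least squares of log relative frequency against log degree, excluding
#' zero counts and degrees above \code{max_degree} (power-law exponent of a
#' degree distribution).
#'
#' @param degrees Integer vector of observed degrees (one entry per
#'   resource, possibly pooled over snapshots).
#' @param max_degree Largest degree included in the fit.
#' @return List with \code{exponent} and the number of fitted frequencies
#'   \code{n}.
#' @export
degree_distribution_exponent <- function(degrees, max_degree = 50) {
  degrees <- degrees[degrees >= 1 & degrees <= max_degree]
  tb <- table(degrees)
  k <- as.numeric(names(tb))
  f <- as.numeric(tb) / sum(tb)
  if (length(k) < 2L) stop("not enough distinct degrees to fit")
  fit <- stats::lm(log(f) ~ log(k))
  list(exponent = unname(stats::coef(fit)[2L]), n = length(k))
}

#' Exponential decay rate of extinction-cascade sizes
#'
#' Histogram of the number of extinctions per step (sizes >= 1), fitted by
#' least squares of log relative frequency against cascade size.
#'
#' @param sizes Integer vector of per-step extinction counts.
#' @return List with \code{exponent} (the fitted slope, negative for a
#'   decaying distribution), the size/frequency table \code{freq}, and the
#'   number of cascades \code{n}.
#' @export
cascade_size_fit <- function(sizes) {
  sizes <- sizes[sizes >= 1]
  if (length(sizes) == 0L) stop("no extinction cascades observed")
  tb <- table(sizes)
  k <- as.numeric(names(tb))
  f <- as.numeric(tb) / sum(tb)
  if (length(k) < 2L) stop("not enough distinct cascade sizes to fit")
  fit <- stats::lm(log(f) ~ k)
  list(exponent = unname(stats::coef(fit)[2L]),
       freq = data.frame(size = k, rel_freq = f),
       n = length(sizes))
}

#' Establishment success rate conditioned on community size
#'
#' Bins the steps of a run by the resident community size at the start of
#' the step and reports the fraction of steps whose candidate survived the
#' extinction loop.
#'
#' @param steps The per-step data frame of a \code{\link{cfn_simulate}} run.
#' @param from First step to include (e.g. the start of the stationary
#'   window).
#' @param min_count Bins with fewer observations are dropped (rates over a
#'   handful of trials carry no information).
#' @return Data frame with columns \code{N}, \code{trials},
#'   \code{successes}, \code{rate}.
#' @export
establishment_success <- function(steps, from = 1L, min_count = 10L) {
  s <- steps[steps$step >= from, ]
  # community size when the candidate arrived
  N_before <- s$N - s$established + s$n_extinct
  agg <- stats::aggregate(list(trials = N_before),
                          by = list(N = N_before), FUN = length)
  succ <- stats::aggregate(list(successes = s$established),
                           by = list(N = N_before), FUN = sum)
  out <- merge(agg, succ, by = "N")
  out$rate <- out$successes / out$trials
  out[out$trials >= min_count, ]
}

#' Fraction of extinctions attributed to cascade effects
#'
#' @param steps The per-step data frame of a run.
#' @param from First step to include.
#' @return Percentage of all resident extinctions in the window whose victim
#'   shared no uptake resource with the newly introduced consumer.
#' @export
cascade_fraction <- function(steps, from = 1L) {
  s <- steps[steps$step >= from, ]
  tot <- sum(s$n_extinct)
  if (tot == 0L) stop("no extinctions in the selected window")
  100 * sum(s$n_cascade) / tot
}

# standard three-term Blackman window, unit sum
.blackman <- function(K) {
  if (K == 1L) return(1)
  k <- seq_len(K) - 1L
  w <- 0.42 - 0.5 * cos(2 * pi * k / (K - 1)) + 0.08 * cos(4 * pi * k / (K - 1))
  w / sum(w)
}

#' Smooth a series with a Blackman window
#'
#' Convolution with a unit-sum Blackman kernel (coefficients 0.42, 0.5,
#' 0.08). The output has the same length as the input; near the edges the
#' kernel is truncated and renormalized.
#'
#' @param x Numeric series.
#' @param window_size Kernel length (1 returns the input unchanged).
#' @return The smoothed series.
#' @export
smooth_series <- function(x, window_size) {
  n <- length(x)
  if (n == 0L) stop("empty series")
  window_size <- as.integer(window_size)
  if (window_size < 1L || window_size > n)
    stop("'window_size' must lie in [1, length(x)]")
  if (window_size == 1L) return(x)
  w <- .blackman(window_size)
  num <- stats::convolve(x, rev(w), type = "open")
  den <- stats::convolve(rep(1, n), rev(w), type = "open")
  mid <- seq.int(floor((window_size + 1L) / 2L), length.out = n)
  num[mid] / den[mid]
}
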