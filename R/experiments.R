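#' @title Experiment runner
#' @description Seeded multi-run experiments: the reference simulation with
#'   its stationary-window summary, one-parameter sweeps, and the library of
#'   small hand-built networks with analytically known flows.
#' @name experiments
NULL

#' Summarize a run over a step window
#'
#' Means and standard deviations of the per-step quantities and of the
#' windowed observable records inside \code{[from, to]}, plus the
#' displacement rates (establishments, extinctions, cascade extinctions and
#' resource losses per step).
#'
#' @param sim A \code{cfn_sim}.
#' @param from,to Window bounds in steps (defaults: second half of the run).
#' @return A one-row data frame of \code{<name>_mean} / \code{<name>_sd}
#'   columns.
#' @export
window_summary <- function(sim, from = max(sim$steps$step) %/% 2 + 1L,
                           to = max(sim$steps$step)) {
  s <- sim$steps[sim$steps$step >= from & sim$steps$step <= to, ]
  r <- sim$records[sim$records$step >= from & sim$records$step <= to, ]
  if (nrow(s) == 0L) stop("empty summary window")
  cols <- c(N = "N", M = "M", A = "A", surplus = "surplus")
  out <- list()
  for (nm in names(cols)) {
    out[[paste0(nm, "_mean")]] <- mean(s[[cols[[nm]]]])
    out[[paste0(nm, "_sd")]] <- stats::sd(s[[cols[[nm]]]])
  }
  rates <- c(establishment = mean(s$established),
             extinction = mean(s$n_extinct),
             cascade_extinction = mean(s$n_cascade),
             resource_loss = mean(s$n_lost),
             resource_gain = mean(s$n_gained))
  for (nm in names(rates)) out[[paste0(nm, "_rate")]] <- rates[[nm]]
  if (nrow(r) > 0L) {
    for (nm in setdiff(names(r), "step")) {
      out[[paste0(nm, "_mean")]] <- mean(r[[nm]])
      out[[paste0(nm, "_sd")]] <- stats::sd(r[[nm]])
    }
  }
  as.data.frame(out)
}

#' Run the reference experiment
#'
#' Simulates the reference configuration (single supplied resource at unit
#' rate, \code{n_u = n_rho = 3}, \code{eta = 0.7}, \code{mu = 0.01},
#' \code{p_u = p_rho = 0.2}, \code{alpha = 0.2}, pool size 250) once per
#' seed and summarizes each run over the stationary window.
#'
#' @param n_steps Steps per run.
#' @param seeds Integer vector of seeds (one run each).
#' @param window Two-element step window for the summary (default: second
#'   half).
#' @param snapshot_every Snapshot interval passed to the runs.
#' @param params Base parameters; seed and step count are overridden per
#'   run.
#' @param out_dir Optional directory: per-step tables, summaries and final
#'   snapshot edge lists are written as text files.
#' @param progress Print progress lines.
#' @return List with \code{sims} (one \code{cfn_sim} per seed),
#'   \code{summary} (one row per seed) and \code{window}.
#' @export
run_reference_experiment <- function(n_steps = 1e5L, seeds = 1:3,
                                     window = c(n_steps %/% 2 + 1L, n_steps),
                                     snapshot_every = 250L,
                                     params = cfn_params(),
                                     out_dir = NULL, progress = FALSE) {
  sims <- lapply(seeds, function(sd) {
    p <- params
    p$n_steps <- as.integer(n_steps)
    p$seed <- as.integer(sd)
    p$snapshot_every <- snapshot_every
    cfn_simulate(p, progress = progress)
  })
  names(sims) <- paste0("seed", seeds)
  summary <- do.call(rbind, lapply(sims, window_summary,
                                   from = window[1L], to = window[2L]))
  summary <- cbind(data.frame(seed = seeds), summary)
  rownames(summary) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(sims)) {
      utils::write.csv(sims[[nm]]$steps,
                       file.path(out_dir, paste0("steps_", nm, ".csv")),
                       row.names = FALSE)
      utils::write.csv(sims[[nm]]$records,
                       file.path(out_dir, paste0("records_", nm, ".csv")),
                       row.names = FALSE)
      flow_edges(sims[[nm]]$final$flow,
                 file.path(out_dir, paste0("final_edges_", nm, ".tsv")))
    }
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  list(sims = sims, summary = summary, window = window)
}

#' Run a one-parameter sweep
#'
#' Repeats shortened simulations for each value of one parameter and
#' reports, per value, the stationary-window mean and a two-standard-
#' deviation band of the main observables (consumer and resource richness,
#' surplus and accumulation flow, both diversities, evennesses, displacement
#' rates).
#'
#' @param parameter Name of the swept \code{\link{cfn_params}} field
#'   (e.g. \code{"eta"}, \code{"n_rho"}, \code{"n_u"}, \code{"pool_size"}).
#' @param values Values to sweep over.
#' @param n_steps Steps per run.
#' @param seeds Seeds (each value is run once per seed).
#' @param window Summary window (default: second half).
#' @param params Base parameters.
#' @param progress Print progress lines.
#' @return Data frame: one row per (value, seed) in \code{$runs} and one
#'   aggregated row per value in \code{$summary} (columns \code{*_mean},
#'   \code{*_lo}, \code{*_hi} with the 2-sd band across steps and seeds).
#' @export
run_sweep <- function(parameter, values, n_steps = 2e4L, seeds = 1:2,
                      window = c(n_steps %/% 2 + 1L, n_steps),
                      params = cfn_params(), progress = FALSE) {
  stopifnot(parameter %in% names(params))
  runs <- list()
  for (v in values) {
    for (sd in seeds) {
      p <- params
      p[[parameter]] <- if (parameter %in%
                            c("n_u", "n_rho", "pool_size")) as.integer(v) else v
      # re-validate and refresh derived fields; keep supply in compact form
      # so that pool-size sweeps re-pad it to the new length
      p$supply <- p$supply[seq_len(max(which(p$supply > 0)))]
      p <- do.call(cfn_params, p[setdiff(names(p), c("beta_u", "beta_rho"))])
      p$n_steps <- as.integer(n_steps)
      p$seed <- as.integer(sd)
      sim <- cfn_simulate(p, progress = progress)
      ws <- window_summary(sim, window[1L], window[2L])
      runs[[length(runs) + 1L]] <-
        cbind(data.frame(value = v, seed = sd), ws)
    }
  }
  runs <- do.call(rbind, runs)
  meancols <- grep("_mean$|_rate$", names(runs), value = TRUE)
  summary <- do.call(rbind, lapply(split(runs, runs$value), function(g) {
    out <- data.frame(value = g$value[1L])
    for (cl in meancols) {
      m <- mean(g[[cl]])
      # spread: seed-to-seed variation of window means
      s <- if (nrow(g) > 1L) stats::sd(g[[cl]]) else 0
      out[[cl]] <- m
      out[[sub("(_mean|_rate)$", "_lo", cl)]] <- m - 2 * s
      out[[sub("(_mean|_rate)$", "_hi", cl)]] <- m + 2 * s
    }
    out
  }))
  rownames(summary) <- NULL
  list(parameter = parameter, runs = runs, summary = summary)
}

#' Hand-built fixture networks with known stationary flows
#'
#' Small deterministic communities used across the test suites and the
#' documentation: \describe{
#'   \item{self_loop}{one consumer eating the supplied resource and
#'     releasing everything back to it; F = s/(1-eta).}
#'   \item{sink_chain}{one consumer eating the supplied resource and
#'     releasing to an unconsumed product; F = (s, eta s), A = eta s.}
#'   \item{shared_pair}{two consumers sharing the supplied resource with
#'     affinities 2:1, both full self-release; J = eta s/(1-eta) * (2/3, 1/3).}
#'   \item{two_groups}{six consumers in two tight trait groups, for
#'     clustering tests.}
#'   \item{empty}{no consumers; all supply accumulates.}
#' }
#'
#' @param eta Recycling fraction used for the fixture parameters.
#' @return Named list of \code{cfn_community} objects.
#' @export
cfn_fixtures <- function(eta = 0.7) {
  p4 <- cfn_params(eta = eta, pool_size = 4L, n_u = 1L, n_rho = 1L)
  self_loop <- cfn_community(list(
    list(u = c(1, 0, 0, 0), rho = c(1, 0, 0, 0))), p4)
  sink_chain <- cfn_community(list(
    list(u = c(1, 0, 0, 0), rho = c(0, 1, 0, 0))), p4)
  shared_pair <- cfn_community(list(
    list(u = c(2, 0, 0, 0), rho = c(1, 0, 0, 0)),
    list(u = c(1, 0, 0, 0), rho = c(1, 0, 0, 0))), p4)
  p10 <- cfn_params(eta = eta, pool_size = 10L, n_u = 2L, n_rho = 2L)
  mk <- function(i1, i2, w) {
    u <- numeric(10); rho <- numeric(10)
    u[c(i1, i2)] <- c(w, 1 - w)
    rho[c(i1, i2)] <- c(1 - w, w)
    list(u = u, rho = rho)
  }
  two_groups <- cfn_community(c(
    lapply(c(0.50, 0.55, 0.60), function(w) mk(1L, 2L, w)),
    lapply(c(0.50, 0.55, 0.60), function(w) mk(5L, 6L, w))), p10)
  empty <- cfn_community(list(), p4)
  list(self_loop = self_loop, sink_chain = sink_chain,
       shared_pair = shared_pair, two_groups = two_groups, empty = empty)
}
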