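#' @export
print.cfn_sim <- function(x, ...) {
  n <- nrow(x$steps)
  last <- x$steps[n, ]
  cat(sprintf("Evolutionary CFN simulation: %d steps (seed %d)\n",
              n, x$params$seed))
  if (!is.na(x$terminated_at))
    cat(sprintf("  terminated early at step %d (community extinct)\n",
                x$terminated_at))
  cat(sprintf("  final state: N = %d consumers, M = %d resources, A = %.4g\n",
              last$N, last$M, last$A))
  cat(sprintf("  establishment rate %.2f, extinction rate %.2f per step\n",
              mean(x$steps$established), mean(x$steps$n_extinct)))
  invisible(x)
}

#' Stationary-window summary of a simulation
#'
#' @param object A \code{cfn_sim}.
#' @param from,to Step window (default: second half of the run).
#' @param ... Unused.
#' @return An object of class \code{summary.cfn_sim}.
#' @export
summary.cfn_sim <- function(object, from = max(object$steps$step) %/% 2 + 1L,
                            to = max(object$steps$step), ...) {
  ws <- window_summary(object, from, to)
  cap <- capacity(sum(object$params$supply), object$params$eta,
                  object$params$mu, A = ws$A_mean)
  structure(list(window = c(from, to), summary = ws, capacity = cap,
                 params = object$params),
            class = "summary.cfn_sim")
}

#' @export
print.summary.cfn_sim <- function(x, ...) {
  w <- x$window
  s <- x$summary
  cat(sprintf("Window [%d, %d] of the evolutionary CFN simulation\n",
              w[1L], w[2L]))
  cat(sprintf("  consumer richness N  = %.1f (sd %.1f), bound N_max = %d (A = 0: %d)\n",
              s$N_mean, s$N_sd, x$capacity$N_max, x$capacity$N_max_A0))
  cat(sprintf("  resource richness M  = %.1f (sd %.1f)\n", s$M_mean, s$M_sd))
  cat(sprintf("  accumulation flow A  = %.4g, surplus flow = %.4g\n",
              s$A_mean, s$surplus_mean))
  cat(sprintf("  establishment rate   = %.2f, extinction rate = %.2f (cascade %.2f)\n",
              s$establishment_rate, s$extinction_rate, s$cascade_extinction_rate))
  if (!is.null(s$D_genotypic_mean))
    cat(sprintf("  diversity D          = %.2f (genotypic), %.2f (functional)\n",
                s$D_genotypic_mean, s$D_functional_mean))
  if (!is.null(s$mean_potential_mean))
    cat(sprintf("  evolutionary potential = %.4g\n", s$mean_potential_mean))
  invisible(x)
}

#' Trajectory plot of a simulation
#'
#' Four panels: consumer/resource richness with the capacity bound,
#' accumulation and surplus flow, the windowed diversity records, and the
#' mean evolutionary potential.
#'
#' @param x A \code{cfn_sim}.
#' @param smooth Blackman window size applied to the flow panel series
#'   (1 disables smoothing).
#' @param ... Passed to \code{matplot}.
#' @export
plot.cfn_sim <- function(x, smooth = 1L, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  s <- x$steps
  nmax <- capacity(sum(x$params$supply), x$params$eta, x$params$mu)$N_max
  graphics::matplot(s$step, cbind(s$N, s$M), type = "l", lty = c(1, 4),
                    col = c("blue", "red"), xlab = "step", ylab = "richness",
                    main = "richness", ...)
  graphics::abline(h = nmax, lty = 2, col = "blue")
  graphics::legend("bottomright", c("N", "M", "N_max"), lty = c(1, 4, 2),
                   col = c("blue", "red", "blue"), bty = "n", cex = 0.8)
  graphics::matplot(s$step,
                    cbind(smooth_series(s$A, smooth),
                          smooth_series(s$surplus, smooth)),
                    type = "l", lty = 1, col = c("darkorange", "darkgreen"),
                    xlab = "step", ylab = "flow", main = "accumulation / surplus")
  graphics::legend("topright", c("A", "surplus"), lty = 1,
                   col = c("darkorange", "darkgreen"), bty = "n", cex = 0.8)
  r <- x$records
  if (nrow(r) > 0L) {
    graphics::matplot(r$step, cbind(r$D_genotypic, r$D_functional),
                      type = "l", lty = 1, col = c("purple", "gray40"),
                      xlab = "step", ylab = "D", main = "diversity (order 2)")
    graphics::legend("bottomright", c("genotypic", "functional"), lty = 1,
                     col = c("purple", "gray40"), bty = "n", cex = 0.8)
    graphics::plot(r$step, r$mean_potential, type = "l", col = "brown",
                   xlab = "step", ylab = expression(Delta * J),
                   main = "evolutionary potential")
  }
  invisible(x)
}
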