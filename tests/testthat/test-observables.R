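test_that("evolutionary potential matches hand-evaluated marginal gains", {
  # sole consumer of all its resources: sigma = 1 everywhere, potential 0
  p <- cfn_params(pool_size = 4L)
  solo <- cfn_community(list(
    list(u = c(0.5, 0.5, 0, 0), rho = c(1, 0, 0, 0))), p)
  pot <- evolutionary_potential(solo, cfn_flow(solo))
  expect_equal(unname(pot$delta_J), 0)

  # single-resource consumer: max = min, potential 0
  single <- cfn_fixtures()$self_loop
  expect_equal(unname(evolutionary_potential(
    single, cfn_flow(single))$delta_J), 0)

  # consumer 1 is sole consumer of resource 1 (gain 0) and shares resource 2
  # half-half with consumer 2: its potential is eta * (1 - 1/2) * F_2 / U_2
  p2 <- cfn_params(pool_size = 2L, eta = 0.7, n_u = 2L, n_rho = 1L)
  comm <- cfn_community(list(
    list(u = c(0.5, 0.5), rho = c(1, 0)),
    list(u = c(0, 0.5), rho = c(0, 1))), p2)
  fl <- cfn_flow(comm)
  pot2 <- evolutionary_potential(comm, fl)
  expect_equal(unname(pot2$delta_J[1]),
               0.7 * 0.5 * unname(fl$F[2]) / 1, tolerance = 1e-12)
})

test_that("closed-form potential agrees with a finite-difference oracle", {
  # shift a small amount of affinity from the min- to the max-gain resource,
  # recompute the uptake shares at the fixed stationary flow field (the
  # first-order estimate deliberately ignores network feedback) and verify
  # the realized uptake gain approaches the analytic spread
  set.seed(11)
  checked <- 0L
  for (rep in 1:8) {
    params <- cfn_params(pool_size = 12L, n_u = 3L, n_rho = 2L)
    comm <- random_community(6L, params)
    fl <- cfn_flow(comm)
    pot <- evolutionary_potential(comm, fl)
    i <- which.max(pot$delta_J)
    if (pot$delta_J[i] < 1e-8) next
    used <- which(comm$U[, i] > 0)
    g <- pot$gain[i, match(used, fl$resources)]
    g[is.na(g)] <- 0
    jmax <- used[which.max(g)]
    jmin <- used[which.min(g)]
    delta <- 1e-6
    shifted <- comm
    shifted$U[jmax, i] <- shifted$U[jmax, i] + delta
    shifted$U[jmin, i] <- shifted$U[jmin, i] - delta
    sigma2 <- uptake_shares(shifted, fl$resources)
    J2 <- params$eta * sum(sigma2[i, ] * fl$F)
    realized <- J2 - unname(fl$J[i])
    expect_equal(realized, pot$delta_J[[i]] * delta, tolerance = 1e-3)
    checked <- checked + 1L
  }
  expect_gte(checked, 3L)
})

test_that("similarity diversity spans [1, N] and respects invariances", {
  expect_equal(similarity_diversity(matrix(rep(c(1, 2, 0), 4), 3))$D, 1)
  expect_equal(similarity_diversity(diag(4))$D, 4)
  # relabeling and common rescaling leave D unchanged
  set.seed(8)
  V <- matrix(runif(30), 5)
  d0 <- similarity_diversity(V)$D
  expect_equal(similarity_diversity(V[, sample(6)])$D, d0)
  expect_equal(similarity_diversity(V * 3.7)$D, d0)
  # the literal order-1 normalization never exceeds one
  expect_lte(similarity_diversity(V, literal = TRUE)$D, 1)
  # zero vectors are maximally dissimilar to everything but themselves
  z <- similarity_diversity(cbind(c(1, 0), c(0, 0)))$z
  expect_equal(unname(z[1, 2]), 0)
  expect_equal(unname(diag(z)), c(1, 1))
})

test_that("functional and genotypic diversity modes work on communities", {
  fx <- cfn_fixtures()
  fl <- cfn_flow(fx$shared_pair)
  # both consumers eat only resource 1: functionally identical
  expect_equal(similarity_diversity(fx$shared_pair, fl,
                                    mode = "functional")$D, 1)
  # genotypically identical up to scale as well
  expect_equal(similarity_diversity(fx$shared_pair, fl,
                                    mode = "genotypic")$D, 1)
})

test_that("functional similarities equal cosines of hand-built uptake profiles", {
  p <- cfn_params(pool_size = 3L, n_u = 2L, n_rho = 1L)
  comm <- cfn_community(list(
    list(u = c(0.7, 0.3, 0), rho = c(0, 1, 0)),
    list(u = c(0.2, 0.8, 0), rho = c(0, 0, 1)),
    list(u = c(0, 0.5, 0.5), rho = c(1, 0, 0))), p)
  fl <- cfn_flow(comm)
  # profiles J_{j->i} built entry by entry from sigma and F
  V <- vapply(1:3, function(i) fl$sigma[i, ] * fl$F, numeric(3))
  zexp <- crossprod(V / rep(sqrt(colSums(V^2)), each = 3))
  got <- similarity_diversity(comm, fl, mode = "functional")
  expect_equal(unname(got$z), unname(zexp), tolerance = 1e-12)
  expect_equal(got$D, 9 / sum(zexp), tolerance = 1e-12)
})

test_that("effective richness is the exponential Shannon entropy", {
  expect_equal(effective_richness(c(1, 1, 1) / 3), 3)
  expect_equal(effective_richness(c(0, 5, 0)), 1)
  expect_equal(effective_richness(c(0.5, 0.5, 0)), 2)
  expect_error(effective_richness(c(0, 0)), "all-zero")
})

test_that("evenness handles Pielou and uptake normalizations", {
  expect_equal(evenness(rep(2, 6)), 1)
  expect_equal(evenness(c(1, rep(0, 9))), 0)
  expect_equal(evenness(c(1, 1, 0)), log(2) / log(3))
  expect_equal(evenness(5), 1)                      # singleton convention
  expect_equal(evenness(c(1, 1, 1), mode = "uptake", n_u = 3), 1)
  expect_error(evenness(c(1, 1), mode = "uptake"), "n_u")
})

test_that("extinctions are classified by shared uptake resources", {
  new_u <- c(1, 1, 0, 0)
  expect_equal(classify_extinctions(c(0, 2, 0, 0), new_u), "competitive")
  expect_equal(classify_extinctions(c(0, 0, 1, 1), new_u), "cascade")
  expect_equal(classify_extinctions(cbind(c(0, 2, 0, 0), c(0, 0, 1, 1)),
                                    new_u), c("competitive", "cascade"))
  expect_length(classify_extinctions(NULL, new_u), 0)
})

test_that("turnover is the normalized symmetric difference", {
  expect_equal(turnover(1:5, 1:5), 0)
  expect_equal(turnover(1:3, 4:6), 1)
  expect_equal(turnover(1:3, 2:4), 1 / 3)
  expect_equal(turnover(1:3, 2:4), turnover(2:4, 1:3))
  expect_error(turnover(integer(0), integer(0)), "empty")
  # bounded in [0, 1] on random sets
  set.seed(14)
  for (i in 1:20) {
    a <- sample(20, sample(0:10, 1))
    b <- sample(20, sample(1:10, 1))
    tv <- turnover(a, b)
    expect_gte(tv, 0)
    expect_lte(tv, 1)
  }
})

test_that("network statistics count consumers, producers and affinities", {
  fx <- cfn_fixtures()
  ns <- network_statistics(fx$self_loop, cfn_flow(fx$self_loop))
  r1 <- ns$resources[ns$resources$resource == 1, ]
  expect_equal(r1$U, 1)
  expect_equal(r1$n_consumers, 1L)
  expect_equal(r1$n_producers, 1L)
  ns2 <- network_statistics(fx$sink_chain, cfn_flow(fx$sink_chain))
  r2 <- ns2$resources[ns2$resources$resource == 2, ]
  expect_equal(r2$n_consumers, 0L)
  expect_equal(r2$n_producers, 1L)
  expect_equal(ns2$consumers$rank, 1L)
})

test_that("log-log fits recover known slopes and decay rates", {
  # exact power law U = 2 * F^1.3
  F <- 10^seq(-2, 1, length.out = 20)
  tab <- data.frame(resource = 1:20, F = F, U = 2 * F^1.3,
                    n_consumers = 1, n_producers = 1, mean_affinity = 1)
  fit <- affinity_flow_slope(tab, min_flow = 0.001)
  expect_equal(fit$slope, 1.3, tolerance = 1e-10)
  # the cutoff drops low-flow points
  expect_equal(affinity_flow_slope(tab, min_flow = 0.1)$n, sum(F > 0.1))
  # exact exponential cascade-size distribution
  sizes <- rep(1:6, times = round(1000 * exp(-0.4 * (1:6))))
  cf <- cascade_size_fit(sizes)
  expect_equal(cf$exponent, -0.4, tolerance = 0.01)
  # exact power-law degree frequencies
  degs <- rep(1:10, times = round(1e4 * (1:10)^-1.5))
  expect_equal(degree_distribution_exponent(degs)$exponent, -1.5,
               tolerance = 0.01)
})

test_that("establishment success is binned by pre-step community size", {
  steps <- data.frame(step = 1:6,
                      N = c(2, 3, 3, 4, 3, 4),
                      established = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
                      n_extinct = c(0, 0, 0, 0, 1, 0))
  out <- establishment_success(steps, min_count = 1L)
  # pre-step sizes: 1, 2, 3, 3, 4, 3
  expect_equal(out$N, c(1, 2, 3, 4))
  expect_equal(out$trials, c(1, 1, 3, 1))
  expect_equal(out$rate[out$N == 3], 2 / 3)
})

test_that("Blackman smoothing preserves constants and means", {
  x <- rep(3.5, 50)
  expect_equal(smooth_series(x, 15), x)
  y <- rnorm(200)
  expect_equal(smooth_series(y, 1), y)
  # unit-sum kernel: interior mean preserved for long series
  z <- 2 + sin(seq(0, 4 * pi, length.out = 500))
  sm <- smooth_series(z, 25)
  expect_equal(mean(sm[50:450]), mean(z[50:450]), tolerance = 1e-3)
  expect_error(smooth_series(numeric(0), 3), "empty")
  expect_error(smooth_series(1:5, 9), "window_size")
})
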