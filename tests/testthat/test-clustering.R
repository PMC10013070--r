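test_that("genotypic dissimilarity is a normalized weighted L1 distance", {
  p <- cfn_params(pool_size = 6L, w_u = 1, w_rho = 0.2, u_bar = 1)
  a <- list(u = c(0.5, 0.5, 0, 0, 0, 0), rho = c(1, 0, 0, 0, 0, 0))
  expect_equal(dissimilarity(a, a, p), 0)
  # fully disjoint supports saturate the bound
  b <- list(u = c(0, 0, 0.5, 0.5, 0, 0), rho = c(0, 0, 0, 0, 1, 0))
  expect_equal(dissimilarity(a, b, p), 1)
  # identical releases, affinity L1 distance 1: (1 * 1) / (2 * 1 + 2 * 0.2)
  cc <- list(u = c(1, 0, 0, 0, 0, 0), rho = c(1, 0, 0, 0, 0, 0))
  expect_equal(dissimilarity(a, cc, p), 1 / 2.4)
  expect_equal(dissimilarity(a, b, p), dissimilarity(b, a, p))
  p0 <- p
  p0$w_u <- 0
  p0$w_rho <- 0
  expect_error(dissimilarity(a, b, p0), "positive")
})

test_that("initial clustering cuts the complete-linkage tree at theta", {
  fx <- cfn_fixtures()
  tg <- fx$two_groups
  cs <- initial_clustering(tg)
  # two tight trait groups, far apart: exactly two clusters
  expect_equal(length(unique(cs$assignment)), 2L)
  expect_equal(unname(cs$assignment[1:3]), rep(cs$assignment[[1]], 3))
  # every cluster diameter is at most theta
  d <- dissimilarity_matrix(tg)
  for (cl in unique(cs$assignment)) {
    m <- names(cs$assignment)[cs$assignment == cl]
    expect_lte(max(d[m, m]), tg$params$theta)
  }
  # degenerate cases: all identical -> one cluster; all far -> singletons
  p <- cfn_params(pool_size = 4L)
  same <- cfn_community(rep(list(
    list(u = c(1, 0, 0, 0), rho = c(1, 0, 0, 0))), 4), p)
  expect_equal(length(unique(initial_clustering(same)$assignment)), 1L)
  spread <- cfn_community(list(
    list(u = c(1, 0, 0, 0), rho = c(1, 0, 0, 0)),
    list(u = c(0, 1, 0, 0), rho = c(0, 1, 0, 0)),
    list(u = c(0, 0, 1, 0), rho = c(0, 0, 1, 0))), p)
  expect_equal(length(unique(initial_clustering(spread)$assignment)), 3L)
  # the dendrogram exports as a parseable Newick tree
  nwk <- cluster_dendrogram_newick(cs)
  phy <- ape::read.tree(text = nwk)
  expect_equal(length(phy$tip.label), 6L)
})

test_that("complete-linkage split matches the brute-force 2-partition oracle", {
  # for small clusters the top cut must minimize (or tie) the maximal
  # within-part diameter over all 2-partitions
  brute_best <- function(d) {
    n <- nrow(d)
    best <- Inf
    for (code in 1:(2^(n - 1) - 1)) {
      part <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
      d1 <- d[part, part, drop = FALSE]
      d2 <- d[!part, !part, drop = FALSE]
      dm <- max(0, d1[upper.tri(d1)], d2[upper.tri(d2)])
      best <- min(best, dm)
    }
    best
  }
  # cases mirror the situation in which splits occur: a tight cluster grown
  # by mutation drift, extended by one consumer that drifted far away (for
  # arbitrary point sets the greedy complete-linkage cut need not be optimal)
  set.seed(21)
  p <- cfn_params(pool_size = 8L, n_u = 2L, n_rho = 2L)
  for (rep in 1:15) {
    G <- p$pool_size
    base_u <- numeric(G); base_u[sample(G, 2)] <- runif(2)
    base_u <- base_u / sum(base_u)
    base_r <- numeric(G); base_r[sample(G, 2)] <- runif(2)
    base_r <- base_r / sum(base_r)
    k <- sample(2:7, 1)
    cons <- lapply(seq_len(k), function(i) {
      u <- base_u * (1 + runif(G, -0.15, 0.15))
      r <- base_r * (1 + runif(G, -0.15, 0.15))
      list(u = u / sum(u), rho = r / sum(r))
    })
    nu <- numeric(G); nu[sample(G, 2)] <- runif(2)
    cons[[k + 1L]] <- list(u = nu / sum(nu), rho = base_r)
    comm <- cfn_community(cons, p)
    d <- dissimilarity_matrix(comm)
    hc <- hclust(as.dist(d), method = "complete")
    top <- cutree(hc, k = 2)
    dm <- max(vapply(1:2, function(k) {
      dd <- d[top == k, top == k, drop = FALSE]
      max(0, dd[upper.tri(dd)])
    }, numeric(1)))
    expect_equal(dm, brute_best(d), tolerance = 1e-12)
  }
})

test_that("cluster updates follow ancestry and split on diameter overflow", {
  p <- cfn_params(pool_size = 4L, theta = 0.3)
  base <- cfn_community(list(
    list(u = c(1, 0, 0, 0), rho = c(1, 0, 0, 0)),
    list(u = c(0.95, 0.05, 0, 0), rho = c(1, 0, 0, 0))), p)
  cs <- initial_clustering(base)
  expect_equal(length(unique(cs$assignment)), 1L)

  # a close descendant joins without splitting
  comm3 <- cfn_community(list(
    list(u = c(1, 0, 0, 0), rho = c(1, 0, 0, 0)),
    list(u = c(0.95, 0.05, 0, 0), rho = c(1, 0, 0, 0)),
    list(u = c(0.97, 0.03, 0, 0), rho = c(1, 0, 0, 0))), p)
  comm3$ancestor <- c(NA, 1L, 1L)
  rec <- structure(list(step = 1L, new_consumer_id = 3L, ancestor_id = 1L,
                        established = TRUE, extinct_ids = integer(0),
                        extinct_class = character(0)),
                   class = "cfn_step_record")
  cs2 <- update_clusters(cs, rec, comm3, p)
  expect_equal(length(unique(cs2$assignment)), 1L)
  expect_equal(unname(cs2$assignment[["3"]]), unname(cs2$assignment[["1"]]))

  # a distant descendant pushes the diameter beyond theta and splits off;
  # the union of the two parts is the old membership plus the newcomer
  comm4 <- cfn_community(list(
    list(u = c(1, 0, 0, 0), rho = c(1, 0, 0, 0)),
    list(u = c(0.95, 0.05, 0, 0), rho = c(1, 0, 0, 0)),
    list(u = c(0.97, 0.03, 0, 0), rho = c(1, 0, 0, 0)),
    list(u = c(0.2, 0.8, 0, 0), rho = c(0, 1, 0, 0))), p)
  comm4$ancestor <- c(NA, 1L, 1L, 1L)
  rec2 <- structure(list(step = 2L, new_consumer_id = 4L, ancestor_id = 1L,
                         established = TRUE, extinct_ids = integer(0),
                         extinct_class = character(0)),
                    class = "cfn_step_record")
  cs3 <- update_clusters(cs2, rec2, comm4, p)
  expect_equal(length(unique(cs3$assignment)), 2L)
  expect_setequal(names(cs3$assignment), c("1", "2", "3", "4"))
  # the newcomer's part has a fresh id, the rest keep the old one
  expect_false(cs3$assignment[["4"]] %in% cs2$assignment)
  expect_equal(unname(cs3$assignment[["1"]]), unname(cs2$assignment[["1"]]))
  # diameters below theta after the split
  d4 <- dissimilarity_matrix(comm4)
  for (cl in unique(cs3$assignment)) {
    m <- names(cs3$assignment)[cs3$assignment == cl]
    expect_lte(max(d4[m, m]), p$theta)
  }

  # the last member of a cluster going extinct closes it
  rec3 <- structure(list(step = 3L, new_consumer_id = 5L, ancestor_id = 1L,
                         established = FALSE, extinct_ids = 4L,
                         extinct_class = "cascade"),
                    class = "cfn_step_record")
  cs4 <- update_clusters(cs3, rec3, comm3, p)
  gonecl <- setdiff(unique(cs3$assignment), unique(cs4$assignment))
  expect_length(gonecl, 1L)
  expect_equal(cs4$registry$closed_step[cs4$registry$cluster == gonecl], 3L)
})

test_that("tracked runs keep cluster diameters within theta", {
  p <- cfn_params(n_steps = 150L, seed = 17L)
  sim <- cfn_simulate(p, cluster_from = 80L)
  cs <- sim$clusters
  d <- dissimilarity_matrix(sim$final$community)
  for (cl in unique(cs$assignment)) {
    m <- names(cs$assignment)[cs$assignment == cl]
    if (length(m) > 1L)
      expect_lte(max(d[m, m]), p$theta + 1e-12)
  }
  st <- cluster_statistics(cs, intervals = c(1L, 10L))
  expect_true(all(st$turnover$consumer_mean >= 0 &
                    st$turnover$consumer_mean <= 1))
  expect_true(all(st$turnover$cluster_mean >= 0 &
                    st$turnover$cluster_mean <= 1))
  expect_true(all(st$lifespans$lifespan >= 0))
  # static community over an interval: both turnovers zero
  h <- cs$history[[length(cs$history)]]
  expect_equal(turnover(h$consumers, h$consumers), 0)
  expect_equal(turnover(h$clusters, h$clusters), 0)
})
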