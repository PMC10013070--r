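test_that("uptake shares partition consumed resources and ignore the rest", {
  p <- cfn_params(pool_size = 3L)
  comm <- cfn_community(list(
    list(u = c(2, 0, 0), rho = c(0, 1, 0)),
    list(u = c(1, 0, 0), rho = c(0, 1, 0))), p)
  sigma <- uptake_shares(comm)
  expect_equal(unname(sigma[, "1"]), c(2 / 3, 1 / 3))
  expect_equal(unname(sigma[, "2"]), c(0, 0))   # produced but unconsumed
  expect_equal(colSums(sigma)[["1"]], 1)
})

test_that("transformation matrix reproduces hand-evaluated small networks", {
  fx <- cfn_fixtures()
  # self loop: eat resource 1, release to resource 1
  sl <- fx$self_loop
  Tm <- transformation_matrix(uptake_shares(sl),
                              sl$Rho[present_resources(sl), , drop = FALSE])
  expect_equal(Tm, matrix(1), ignore_attr = TRUE)
  # sink chain: T e1 = e2, T e2 = 0
  sc <- fx$sink_chain
  res <- present_resources(sc)
  Tm2 <- transformation_matrix(uptake_shares(sc),
                               sc$Rho[res, , drop = FALSE])
  expect_equal(Tm2 %*% c(1, 0), matrix(c(0, 1)), ignore_attr = TRUE)
  expect_equal(Tm2 %*% c(0, 1), matrix(c(0, 0)), ignore_attr = TRUE)
  # empty community: T = 0
  em <- fx$empty
  expect_equal(sum(abs(transformation_matrix(
    uptake_shares(em), em$Rho[present_resources(em), , drop = FALSE]))), 0)
})

test_that("closed-form fixture flows are reproduced exactly", {
  fx <- cfn_fixtures(eta = 0.7)
  expect_equal(unname(cfn_flow(fx$self_loop)$F), 1 / 0.3)
  expect_equal(unname(cfn_flow(fx$self_loop)$J), 0.7 / 0.3)
  sc <- cfn_flow(fx$sink_chain)
  expect_equal(unname(sc$F), c(1, 0.7))
  expect_equal(sc$A, 0.7)
  expect_equal(unname(cfn_flow(fx$shared_pair)$J), c(14 / 9, 7 / 9))
  expect_equal(cfn_flow(fx$empty)$A, 1)
})

test_that("solve_flow validates inputs and residuals", {
  expect_equal(solve_flow(matrix(1), 1, 0.7), 10 / 3)
  expect_equal(solve_flow(matrix(0, 1, 1), 0, 0.5), 0)
  expect_error(solve_flow(matrix(1), 1, 1.2), "eta")
})

test_that("capacity bounds match the closed forms", {
  cap <- capacity(1.0, eta = 0.7, mu = 0.01, A = 0)
  expect_identical(cap$N_max, 233)
  expect_equal(cap$F_max, 10 / 3)
  expect_identical(capacity(1.0, eta = 0.5, mu = 0.1)$N_max, 10)
  capA <- capacity(1.0, eta = 0.7, mu = 0.01, A = 1)
  expect_identical(capA$N_max, 0)
  expect_true(capA$N_max_A0 >= capA$N_max)
  expect_error(capacity(1, 0.7, 0.01, A = 10), "accumulation")
})

test_that("stationary flows obey the conservation identities on random communities", {
  set.seed(42)
  for (rep in 1:40) {
    params <- cfn_params(pool_size = sample(5:20, 1),
                         n_u = sample(1:3, 1), n_rho = sample(1:3, 1),
                         eta = runif(1, 0.2, 0.9))
    comm <- random_community(sample(0:15, 1), params)
    fl <- cfn_flow(comm)
    s_bar <- sum(params$supply)
    # total-flow identity and uptake identity
    expect_equal(sum(fl$F), (s_bar - params$eta * fl$A) / (1 - params$eta),
                 tolerance = 1e-9)
    expect_equal(sum(fl$J), params$eta * (sum(fl$F) - fl$A),
                 tolerance = 1e-9)
    # the capacity bound, tight exactly when nothing accumulates
    expect_lte(sum(fl$F), s_bar / (1 - params$eta) + 1e-9)
    if (fl$A == 0)
      expect_equal(sum(fl$F), s_bar / (1 - params$eta), tolerance = 1e-9)
    # agreement with the truncated geometric-series oracle
    expect_equal(unname(fl$F), neumann_flow(comm), tolerance = 1e-8)
  }
})

test_that("the transformation matrix is an L1 contraction on non-negative vectors", {
  set.seed(7)
  for (rep in 1:20) {
    comm <- random_community(sample(1:10, 1))
    res <- present_resources(comm)
    Tm <- transformation_matrix(uptake_shares(comm),
                                comm$Rho[res, , drop = FALSE])
    v <- runif(length(res))
    expect_lte(sum(abs(Tm %*% v)), sum(v) + 1e-12)
  }
})

test_that("flow edge lists are consistent and round-trip through TSV", {
  fx <- cfn_fixtures()
  fl <- cfn_flow(fx$shared_pair)
  edges <- flow_edges(fl)
  expect_setequal(unique(edges$type), c("uptake", "release"))
  # uptake edges sum to total uptake, release edges to total release
  expect_equal(sum(edges$flow[edges$type == "uptake"]), sum(fl$J))
  expect_equal(sum(edges$flow[edges$type == "release"]), sum(fl$J))
  file <- tempfile(fileext = ".tsv")
  flow_edges(fl, file)
  back <- utils::read.delim(file)
  expect_equal(back$flow, edges$flow)
  expect_equal(back$source, edges$source)
  # graph-exchange export parses as a directed bipartite graph
  gml <- tempfile(fileext = ".graphml")
  flow_graphml(fl, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), nrow(edges))
})
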