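# shared helpers: random valid communities and an independent flow oracle

# a random community with the structural invariants of the model:
# affinity support n_u summing to u_bar, release support n_rho summing to 1
random_community <- function(n_consumers, params = cfn_params(pool_size = 20L,
                                                              n_u = 3L,
                                                              n_rho = 3L)) {
  G <- params$pool_size
  consumers <- lapply(seq_len(max(n_consumers, 0L)), function(i) {
    u <- numeric(G)
    idx <- sample.int(G, params$n_u)
    w <- runif(params$n_u)
    u[idx] <- params$u_bar * w / sum(w)
    rho <- numeric(G)
    ridx <- sample.int(G, params$n_rho)
    rw <- runif(params$n_rho)
    rho[ridx] <- rw / sum(rw)
    list(u = u, rho = rho)
  })
  cfn_community(consumers, params)
}

# brute-force Neumann-series flow: F = sum_n eta^n T^n s truncated so that
# the neglected tail is below `tail_tol`
neumann_flow <- function(community, tail_tol = 1e-12) {
  params <- community$params
  res <- present_resources(community)
  s <- params$supply[res]
  if (ncol(community$U) == 0L) return(s)
  sigma <- uptake_shares(community, res)
  Tm <- transformation_matrix(sigma, community$Rho[res, , drop = FALSE])
  K <- ceiling(log(tail_tol) / log(params$eta))
  F <- s
  v <- s
  for (n in seq_len(K)) {
    v <- params$eta * (Tm %*% v)
    F <- F + v
  }
  as.vector(F)
}
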