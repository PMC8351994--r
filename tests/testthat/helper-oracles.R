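# Independent oracles and shared fixtures for the test suite.

# single-linkage clustering oracle via hclust (cut strictly below delta)
oracle_cluster_count <- function(points, delta) {
  n <- nrow(points)
  if (n == 0) return(0L)
  if (n == 1) return(1L)
  hc <- hclust(dist(points), method = "single")
  # components joined at height < delta (strict, matching the graph rule)
  length(unique(cutree(hc, h = delta * (1 - 1e-12))))
}

# brute-force invasion fitness straight from the formula, scalar code path
oracle_fitness <- function(Z, N, zm, params) {
  K <- function(z) {
    if (params$carrying == "quartic") exp(-sum(z^4) / 4)
    else exp(-(sum(z^2) / 2)^2 / 2)
  }
  alpha <- function(zi, zj) {
    asym <- 0
    for (k in 1:params$d) for (l in 1:params$d)
      asym <- asym + params$b[k, l] * (zi[k] - zj[k]) * zi[l]
    exp(asym - sum((zi - zj)^2) / (2 * params$sigma_alpha^2))
  }
  load <- 0
  for (j in seq_len(nrow(Z))) load <- load + alpha(Z[j, ], zm) * N[j]
  1 - load / K(zm)
}

# random feasible community used across property tests
random_community <- function(M, params, box = 1.5) {
  Z <- matrix(runif(M * params$d, -box, box), ncol = params$d)
  community(Z, params = params)
}

# the converged 16-species quartic ESC, computed once per test run
quartic_esc <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      mp <- model_params("quartic", sigma_alpha = 0.5)
      tr <- run_ad(mp, ad_config(n_attempts = 4000L, seed = 101L))
      cache <<- list(model = mp, trajectory = tr,
                     community = ecological_equilibrium(tr$final, mp))
    }
    cache
  }
})
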