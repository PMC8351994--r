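mp <- model_params("quartic", sigma_alpha = 0.5)

test_that("death rates match the closed forms", {
  cfg <- ibm_config(k_max = 100)
  # lone individual at the origin: only the self term, alpha = 1, K = 1
  p1 <- ibm_population(matrix(0, 1, 2))
  expect_equal(death_rate(p1, mp, cfg), 1 / 100, tolerance = 1e-12)
  # N identical individuals at the origin: N / k_max each
  pN <- ibm_population(matrix(0, 37, 2))
  expect_equal(death_rate(pN, mp, cfg), rep(37 / 100, 37), tolerance = 1e-12)
  # far outside viable space the rate explodes
  pfar <- ibm_population(matrix(c(3.5, 3.5), 1, 2))
  expect_gt(death_rate(pfar, mp, cfg)[1], 1e5)
  # self-term switch removes exactly one alpha = 1 contribution
  cfg0 <- ibm_config(k_max = 100, self_term = FALSE)
  expect_equal(death_rate(p1, mp, cfg0), 0, tolerance = 1e-12)
})

test_that("single events change the population by exactly one individual", {
  cfg <- ibm_config(k_max = 50, sigma_mut_ibm = 0.01, seed = 1)
  set.seed(5)
  pop <- ibm_population(matrix(rnorm(20, 0, 0.2), 10, 2))
  for (i in 1:50) {
    nxt <- step_ibm(pop, mp, cfg)
    expect_true(abs(nrow(nxt$phenotypes) - nrow(pop$phenotypes)) == 1L)
    expect_gt(nxt$time, pop$time)
    pop <- nxt
  }
})

test_that("offspring displacement is centred Gaussian with the mutation scale", {
  cfg <- ibm_config(k_max = 1e7, sigma_mut_ibm = 0.02, birth_rate = 1)
  # enormous k_max makes deaths vanishingly rare: almost every event a birth
  set.seed(8)
  parent <- c(0.25, -0.5)
  pop <- ibm_population(matrix(parent, 1, 2, byrow = TRUE))
  disp <- matrix(NA_real_, 0, 2)
  while (nrow(disp) < 1e4) {
    res <- nichepack:::cpp_run_ibm(pop$phenotypes, mp$sigma_alpha, mp$b,
                                   FALSE, 0L, cfg$k_max, 1,
                                   cfg$sigma_mut_ibm, 1, 2L, 0.1, TRUE,
                                   0L, FALSE)
    if (nrow(res$Z) == 2) disp <- rbind(disp, res$Z[2, ] - parent)
  }
  expect_lt(max(abs(apply(disp, 2, sd) - 0.02) / 0.02), 0.03)
  expect_lt(max(abs(colMeans(disp))), 3 * 0.02 / sqrt(1e4))
})

test_that("incremental competition cache equals full recomputation", {
  set.seed(3)
  Z0 <- matrix(rnorm(80, 0, 0.3), 40, 2)
  for (b in list(matrix(0, 2, 2), asymmetric_b())) {
    mpx <- model_params("quartic", 0.5, b = b)
    set.seed(3)
    out <- nichepack:::cpp_run_ibm(Z0, mpx$sigma_alpha, mpx$b, FALSE, 0L,
                                   60, 1, 0.02, 1e4, 1e5L, 0.1, TRUE, 0L,
                                   FALSE)
    S_inc <- drop(out$S_cache)
    A <- nichepack:::cpp_interaction_matrix(out$Z, mpx$sigma_alpha, mpx$b,
                                            FALSE)
    expect_lt(max(abs(S_inc - rowSums(A))), 1e-9)
  }
})

test_that("monomorphic stationary size sits at k_max * K(z)", {
  # vanishing mutation scale pins the population at a fixed phenotype
  for (z in list(c(0, 0), c(1.1, 0.4))) {
    K <- carrying_capacity(z, mp)
    target <- 150 * K
    cfg <- ibm_config(k_max = 150, sigma_mut_ibm = 1e-9, seed = 17,
                      max_events = 3e5, record_every = 200L)
    tr <- run_ibm(mp, cfg,
                  init = ibm_population(matrix(z, round(target), 2,
                                               byrow = TRUE)))
    sizes <- tr$records$size[tr$records$time > 100]
    # batch-means standard error of the time average
    nb <- 20
    batches <- split(sizes, cut(seq_along(sizes), nb))
    bm <- vapply(batches, mean, 0)
    se <- sd(bm) / sqrt(nb)
    expect_lt(abs(mean(sizes) - target), 3 * se + 1)
  }
})

test_that("the two schedulers both run and stay near the demographic balance", {
  cfg <- ibm_config(k_max = 80, sigma_mut_ibm = 1e-9, seed = 4,
                    max_events = 5e4, record_every = 500L,
                    scheduler = "sequential")
  tr <- run_ibm(mp, cfg, init = ibm_population(matrix(0, 80, 2)))
  sizes <- tr$records$size
  expect_gt(mean(sizes[-(1:10)]), 60)
  expect_lt(mean(sizes[-(1:10)]), 100)
})

test_that("run_ibm is reproducible given the seed", {
  cfg <- ibm_config(k_max = 40, sigma_mut_ibm = 0.01, seed = 12,
                    max_events = 2e4, record_every = 1000L)
  tr1 <- run_ibm(mp, cfg)
  tr2 <- run_ibm(mp, cfg)
  expect_identical(tr1$records, tr2$records)
  expect_identical(tr1$final, tr2$final)
})
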