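mp <- model_params("quartic", sigma_alpha = 0.5)

test_that("merge_close: identity, coincident pairs, transitive chains", {
  co <- community(rbind(c(0, 0), c(1, 0), c(0, 1)), c(1, 2, 3), 1:3)
  expect_identical(merge_close(co, 0.01), co)
  # coincident pair collapses with summed abundance
  co2 <- community(rbind(c(0.5, 0.5), c(0.5, 0.5) + 1e-9, c(-1, 0)),
                   c(1, 2, 4), 1:3)
  m2 <- merge_close(co2, 0.01)
  expect_equal(n_species(m2), 2L)
  expect_equal(sum(m2$abundances), sum(co2$abundances))
  expect_true(2L %in% m2$labels)  # label of the most abundant member kept
  # chain A-B-C with A-C beyond delta still merges transitively
  co3 <- community(rbind(c(0, 0), c(0.008, 0), c(0.016, 0)), c(1, 1, 1), 1:3)
  m3 <- merge_close(co3, 0.01)
  expect_equal(n_species(m3), 1L)
  # abundance-weighted mean phenotype
  co4 <- community(rbind(c(0, 0), c(0.01, 0)), c(1, 3), 1:2)
  m4 <- merge_close(co4, 0.02)
  expect_equal(m4$phenotypes[1, 1], 0.0075)
})

test_that("propose_mutant: fixed offset length, Gaussian scale, sole parent", {
  co <- community(rbind(c(0.3, -0.7)), 1, 5L)
  cf <- ad_config(eps_mut = 0.02)
  set.seed(1)
  for (i in 1:25) {
    pr <- propose_mutant(co, cf)
    expect_equal(pr$parent, 5L)
    expect_equal(sqrt(sum((pr$phenotype - c(0.3, -0.7))^2)), 0.02,
                 tolerance = 1e-12)
  }
  cfg <- ad_config(eps_mut = 0.02, sigma_mut = 0.05)
  set.seed(2)
  off <- t(replicate(1e4, propose_mutant(co, cfg)$phenotype - c(0.3, -0.7)))
  expect_lt(max(abs(apply(off, 2, sd) - 0.05) / 0.05), 0.03)
  expect_lt(max(abs(colMeans(off))), 3 * 0.05 / sqrt(1e4) * 3)
  expect_error(ad_config(sigma_mut = 0.01, eps_mut = 0.02), "sigma_mut")
})

test_that("attempt_branch: strict positivity gate and re-equilibration", {
  co <- ecological_equilibrium(community(rbind(c(0, 0)), params = mp), mp)
  # mutant identical to a resident has fitness exactly 0 -> rejected
  res <- attempt_branch(co, list(parent = 1L, phenotype = c(0, 0)), mp)
  expect_false(res$admitted)
  expect_equal(res$fitness, 0)
  # the origin is a fitness minimum: any small offset is admitted
  res2 <- attempt_branch(co, list(parent = 1L, phenotype = c(0.02, 0)), mp)
  expect_true(res2$admitted)
  expect_true(res2$mutual)
  expect_equal(n_species(res2$community), 2L)
  expect_lt(max(abs(invasion_fitness_community(
    res2$community, res2$community$phenotypes, mp))), 1e-8)
  # deep inside a saturated ESC's negative basin the mutant is rejected
  esc <- quartic_esc()$community
  mid <- (esc$phenotypes[1, ] + esc$phenotypes[2, ]) / 2
  f <- invasion_fitness_community(esc, mid, mp)
  if (f <= 0) {
    res3 <- attempt_branch(esc, list(parent = 1L, phenotype = mid), mp)
    expect_false(res3$admitted)
  }
})

test_that("canonical_step: fixed at an ESS, descends toward the origin otherwise", {
  esc <- quartic_esc()$community
  stepd <- canonical_step(esc, 5, mp)
  expect_lt(max(abs(stepd$phenotypes - esc$phenotypes)), 5e-3)
  co <- ecological_equilibrium(community(rbind(c(1, 1)), params = mp), mp)
  moved <- canonical_step(co, 1, mp)
  expect_true(all(moved$phenotypes < co$phenotypes))
  expect_true(all(moved$phenotypes > 0))
})

test_that("run_ad is deterministic given the seed and keeps its invariants", {
  cf <- ad_config(n_attempts = 150L, seed = 99L, snap_every = 25L)
  tr1 <- run_ad(mp, cf)
  tr2 <- run_ad(mp, cf)
  expect_identical(tr1$events, tr2$events)
  expect_identical(tr1$final, tr2$final)
  # snapshot invariants: viable abundances and small equilibrium residuals
  for (s in tr1$snapshots) {
    co <- s$community
    expect_true(all(co$abundances >= cf$min_viable))
    expect_lt(max(abs(invasion_fitness_community(co, co$phenotypes, mp))),
              1e-6)
  }
  # event times increasing and labels plausible
  expect_true(all(diff(tr1$events$time) >= 0))
})

test_that("symmetric quartic radiation converges to the 16-species grid ESC", {
  fix <- quartic_esc()
  tr <- fix$trajectory
  expect_equal(tr$termination, "esc")
  cc <- cluster_species(tr$final$phenotypes, 0.05)
  expect_equal(cc$count, 16L)
  # 4 x 4 grid: each coordinate takes 4 distinct values (tolerance 0.05)
  for (k in 1:2) {
    v <- sort(cc$centroids[, k])
    groups <- cumsum(c(1, diff(v) > 0.05))
    expect_equal(max(groups), 4L)
  }
  # final gradient norms vanish (ESS property)
  g <- selection_gradient(fix$community, mp)
  expect_lt(max(sqrt(rowSums(g^2))), 1e-4)
})
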