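mp <- model_params("quartic", sigma_alpha = 0.5)

test_that("cluster_species: base cases and the union-find/hclust oracle", {
  expect_equal(cluster_species(matrix(numeric(0), 0, 2), 0.1)$count, 0L)
  expect_equal(cluster_species(rbind(c(0, 0), c(0.05, 0)), 0.1)$count, 1L)
  expect_equal(cluster_species(rbind(c(0, 0), c(1, 1)), 0.1)$count, 2L)
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(2:60, 1)
    pts <- matrix(runif(2 * n, -1, 1), ncol = 2)
    delta <- runif(1, 0.05, 0.6)
    expect_equal(cluster_species(pts, delta)$count,
                 oracle_cluster_count(pts, delta))
  }
})

test_that("cluster_species is permutation-invariant and monotone in delta", {
  set.seed(13)
  pts <- matrix(runif(80, -1, 1), ncol = 2)
  perm <- sample(nrow(pts))
  a <- cluster_species(pts, 0.2)
  b <- cluster_species(pts[perm, ], 0.2)
  expect_equal(a$count, b$count)
  expect_equal(a$centroids[order(a$centroids[, 1]), ],
               b$centroids[order(b$centroids[, 1]), ])
  counts <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6),
                   function(d) cluster_species(pts, d)$count, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("diversity_timeseries: static series, brute-force rolling median", {
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1))
  traj <- list(times = 1:30, points = replicate(30, pts, simplify = FALSE))
  dv <- diversity_timeseries(traj, delta = 0.1, window = 5)
  expect_true(all(dv$count == 3))
  expect_true(all(dv$smoothed == 3))
  # varying series: smoothed equals a direct trailing median
  set.seed(3)
  counts <- sample(1:6, 40, replace = TRUE)
  traj2 <- list(times = 1:40,
                points = lapply(counts, function(k)
                  cbind(10 * seq_len(k), 0)))
  dv2 <- diversity_timeseries(traj2, delta = 1, window = 7)
  brute <- vapply(1:40, function(i) median(counts[max(1, i - 6):i]), 0)
  expect_equal(dv2$smoothed, brute)
})

test_that("fitness landscape: zeros at residents, saturation vs mid-radiation", {
  esc <- quartic_esc()$community
  ls <- fitness_landscape(esc, mp, n = 61)
  expect_lt(ls$max, 1e-3)  # saturated ESC leaves no positive region
  # landscape at each resident is zero to tolerance
  expect_lt(max(abs(invasion_fitness_community(esc, esc$phenotypes, mp))),
            1e-8)
  # mid-radiation monomorphic resident at the origin: positive region nearby
  co <- ecological_equilibrium(community(rbind(c(0, 0)), params = mp), mp)
  ls2 <- fitness_landscape(co, mp, n = 61)
  expect_gt(ls2$max, 0.1)
})

test_that("limit-cycle detector recovers synthetic orbits", {
  # two clusters orbiting a common centre, known period, counterclockwise
  T0 <- 37.5
  ts <- seq(0, 5 * T0, by = T0 / 80)
  mk <- function(phi0, r, cx)
    cbind(cx + r * cos(2 * pi * ts / T0 + phi0),
          r * sin(2 * pi * ts / T0 + phi0))
  a <- mk(0, 0.6, -0.5); b <- mk(pi / 3, 0.4, 0.9)
  traj <- list(times = ts,
               points = lapply(seq_along(ts), function(i)
                 rbind(a[i, ], b[i, ])))
  rep <- detect_limit_cycle(traj, delta = 0.05)
  expect_true(rep$is_cyclic)
  expect_equal(rep$direction, "counterclockwise")
  expect_lt(abs(rep$period - T0) / T0, 0.02)
  # time reversal flips the direction
  trev <- list(times = ts, points = rev(traj$points))
  rep2 <- detect_limit_cycle(trev, delta = 0.05)
  expect_true(rep2$is_cyclic)
  expect_equal(rep2$direction, "clockwise")
})

test_that("limit-cycle detector rejects stationary windows", {
  pts <- quartic_esc()$community$phenotypes
  traj <- list(times = 1:40,
               points = replicate(40, pts + 1e-9, simplify = FALSE))
  rep <- detect_limit_cycle(traj, delta = 0.05)
  expect_false(rep$is_cyclic)
})

test_that("metastability probe: zero perturbation returns with distance 0", {
  esc <- quartic_esc()$community
  set.seed(5)
  pr <- metastability_probe(esc, 0, mp, probe_time = 2, n_checkpoints = 4L)
  expect_true(pr$returned)
  # residual canonical drift of the converged state is ~1e-5
  expect_lt(pr$distance, 1e-4)
})

test_that("metastability probe: the grid ESC absorbs small perturbations", {
  esc <- quartic_esc()$community
  set.seed(6)
  pr <- metastability_probe(esc, 0.02, mp, probe_time = 60,
                            n_checkpoints = 6L, tol = 0.02)
  expect_true(pr$returned)
})
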