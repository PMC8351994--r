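mp_q <- model_params("quartic", sigma_alpha = 0.5)
mp_r <- model_params("radial", sigma_alpha = 0.5)

test_that("carrying capacities match hand evaluations and symmetry", {
  expect_equal(carrying_capacity(c(0, 0), mp_q), 1, tolerance = 1e-12)
  expect_equal(carrying_capacity(c(0, 0), mp_r), 1, tolerance = 1e-12)
  expect_equal(carrying_capacity(c(1, 1), mp_q), exp(-0.5), tolerance = 1e-12)
  # rotational symmetry of the radial kernel: equal squared radius
  expect_equal(carrying_capacity(c(sqrt(2), 0), mp_r),
               carrying_capacity(c(1, 1), mp_r), tolerance = 1e-12)
  # strictly decreasing along each axis / in radius
  xs <- seq(0.1, 2, by = 0.1)
  expect_true(all(diff(carrying_capacity(cbind(xs, 0), mp_q)) < 0))
  expect_true(all(diff(carrying_capacity(cbind(xs, xs), mp_r)) < 0))
  expect_error(carrying_capacity(c(NA, 0), mp_q), "finite")
})

test_that("competition kernel: identity, b = 0 reduction, asymmetry", {
  set.seed(7)
  # alpha(z, z) = 1 for any phenotype and any b, including asymmetric
  for (rep in 1:20) {
    b <- matrix(rnorm(4), 2, 2)
    mp <- model_params(sigma_alpha = runif(1, 0.2, 0.9), b = b)
    z <- runif(2, -2, 2)
    expect_equal(competition(z, z, mp), 1, tolerance = 1e-12)
  }
  # Gaussian reduction at b = 0
  expect_equal(competition(c(0, 0), c(1, 0), mp_q), exp(-2),
               tolerance = 1e-12)
  # exchange symmetry iff b = 0
  z1 <- c(0.4, -1.1); z2 <- c(-0.3, 0.6)
  expect_equal(competition(z1, z2, mp_q), competition(z2, z1, mp_q))
  mpb <- model_params(sigma_alpha = 0.5, b = asymmetric_b())
  expect_false(isTRUE(all.equal(competition(z1, z2, mpb),
                                competition(z2, z1, mpb))))
  expect_error(model_params(sigma_alpha = -1), "positive")
})

test_that("printed-form compatibility switch breaks the alpha(z,z)=1 identity", {
  mpp <- model_params(sigma_alpha = 0.5, b = asymmetric_b(),
                      printed_form = TRUE)
  z <- c(0.7, -0.2)
  expect_false(isTRUE(all.equal(competition(z, z, mpp), 1)))
  # but still reduces to Gaussian at b = 0
  mpp0 <- model_params(sigma_alpha = 0.5, printed_form = TRUE)
  expect_equal(competition(c(0, 0), c(1, 0), mpp0), exp(-2))
})

test_that("monomorphic invasion fitness: hand values, sign structure, underflow", {
  expect_equal(invasion_fitness(c(0.3, 0.3), c(0.3, 0.3), mp_q), 0)
  expect_equal(invasion_fitness(c(0, 0), c(1, 0), mp_q), 1 - exp(-1.75),
               tolerance = 1e-12)
  expect_equal(invasion_fitness(c(1, 0), c(0, 0), mp_q), 1 - exp(-2.25),
               tolerance = 1e-12)
  # far outside viable space K underflows; fitness must be finite large
  # negative, and the cap is flagged
  expect_warning(f <- invasion_fitness(c(0, 0), c(8, 8), mp_q), "underflow")
  expect_true(is.finite(f) && f < -1e10)
})

test_that("community invasion fitness: reductions and equilibrium zeros", {
  co0 <- community(matrix(numeric(0), 0, 2), numeric(0), integer(0))
  expect_equal(invasion_fitness_community(co0, rbind(c(0, 0), c(1, 1)), mp_q),
               c(1, 1))
  # single resident at N = K reduces to the monomorphic formula
  zr <- c(0.5, -0.4)
  co1 <- ecological_equilibrium(community(rbind(zr), params = mp_q), mp_q)
  zm <- rbind(c(0, 0), c(-1, 1), c(0.2, 0.2))
  expect_equal(invasion_fitness_community(co1, zm, mp_q),
               invasion_fitness(zr, zm, mp_q), tolerance = 1e-12)
  # zero at every resident of an equilibrated community; matches scalar oracle
  set.seed(11)
  co <- ecological_equilibrium(random_community(5, mp_q), mp_q)
  expect_lt(max(abs(invasion_fitness_community(co, co$phenotypes, mp_q))),
            1e-8)
  zm1 <- c(0.3, 0.9)
  expect_equal(invasion_fitness_community(co, zm1, mp_q),
               oracle_fitness(co$phenotypes, co$abundances, zm1, mp_q),
               tolerance = 1e-12)
  expect_error(invasion_fitness_community(co, zm1, mp_q,
                                          abundances = -co$abundances),
               "negative")
})

test_that("origin is a fitness minimum of a monomorphic resident (branching point)", {
  for (mp in list(mp_q, mp_r)) {
    co <- ecological_equilibrium(community(rbind(c(0, 0)), params = mp), mp)
    h <- 1e-3
    f <- function(z) invasion_fitness_community(co, z, mp)
    # numerical Hessian at the origin must be positive definite
    H <- matrix(0, 2, 2)
    for (k in 1:2) for (l in 1:2) {
      ek <- c(0, 0); ek[k] <- h
      el <- c(0, 0); el[l] <- h
      H[k, l] <- (f(ek + el) - f(ek - el) - f(el - ek) + f(-ek - el)) /
        (4 * h^2)
    }
    expect_true(all(eigen(H, symmetric = TRUE)$values > 0))
  }
})

test_that("analytic and finite-difference gradients agree on random communities", {
  set.seed(23)
  worst <- 0
  for (rep in 1:100) {
    b <- if (rep %% 2) matrix(0, 2, 2) else matrix(rnorm(4, 0, 0.6), 2, 2)
    mp <- model_params(sample(c("quartic", "radial"), 1),
                       sigma_alpha = runif(1, 0.3, 0.9), b = b)
    co <- ecological_equilibrium(random_community(sample(1:6, 1), mp), mp)
    ga <- selection_gradient(co, mp)
    gf <- selection_gradient(co, mp, method = "finite_difference")
    worst <- max(worst, max(abs(ga - gf)) / max(abs(ga), 1))
  }
  expect_lt(worst, 1e-6)
  # symmetry: monomorphic resident at the origin has zero gradient
  co0 <- ecological_equilibrium(community(rbind(c(0, 0)), params = mp_q), mp_q)
  expect_equal(drop(selection_gradient(co0, mp_q)), c(0, 0))
  # off-origin monomorphic: selection points back toward the origin
  co1 <- ecological_equilibrium(community(rbind(c(1, 1)), params = mp_q), mp_q)
  expect_true(all(selection_gradient(co1, mp_q) < 0))
  expect_error(selection_gradient(co1, mp_q, i = 5), "out of range")
})
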