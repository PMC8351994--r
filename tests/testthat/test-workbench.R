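mp <- model_params("quartic", sigma_alpha = 0.5)

test_that("seed_initial_community: counts, box membership, uniformity", {
  set.seed(2)
  co1 <- seed_initial_community(1)
  expect_equal(n_species(co1), 1L)
  co <- seed_initial_community(100, min_viable = 1e-4)
  expect_equal(n_species(co), 100L)
  expect_true(all(co$phenotypes >= -2 & co$phenotypes <= 2))
  expect_true(all(co$abundances == 1e-4))
  expect_equal(anyDuplicated(co$phenotypes), 0L)
  # per-axis goodness of fit against the uniform on [-2, 2]
  set.seed(4)
  big <- seed_initial_community(5000)
  for (k in 1:2) {
    p <- suppressWarnings(
      ks.test(big$phenotypes[, k], "punif", -2, 2)$p.value)
    expect_gt(p, 1e-4)
  }
  pop <- seed_initial_community(10, type = "individuals")
  expect_s3_class(pop, "ibm_population")
})

test_that("config round-trips through the text format", {
  tmp <- withr::local_tempdir()
  set.seed(9)
  for (rep in 1:20) {
    fw <- sample(c("ad", "ibm", "pde"), 1)
    model <- model_params(sample(c("quartic", "radial"), 1),
                          sigma_alpha = round(runif(1, 0.2, 0.9), 3),
                          b = matrix(round(rnorm(4), 3), 2, 2),
                          r = round(runif(1, 0.5, 2), 3))
    st <- switch(fw,
      ad = ad_config(eps_mut = round(runif(1, 0.01, 0.1), 4),
                     n_attempts = sample(100:5000, 1),
                     initial_n = sample(1:50, 1)),
      ibm = ibm_config(k_max = sample(c(50, 100, 400), 1),
                       sigma_mut_ibm = round(runif(1, 0.001, 0.05), 4)),
      NULL)
    cfg <- run_config(fw, model, st, seed = sample(1e4, 1))
    f <- file.path(tmp, paste0("cfg", rep, ".txt"))
    write_config(cfg, f)
    back <- load_config(f)
    expect_equal(back, cfg)
  }
})

test_that("config errors name the offending keys and fields", {
  tmp <- withr::local_tempfile(lines = c(
    "framework = ad", "seed = 1", "ad.eps_mut = 0.02",
    "ad.bogus_knob = 3", "model.sigma_alpha = 0.5"))
  expect_error(load_config(tmp), "ad.bogus_knob")
  tmp2 <- withr::local_tempfile(lines = c("seed = 1"))
  expect_error(load_config(tmp2), "framework")
  tmp3 <- withr::local_tempfile(lines = c("framework = ad", "garbage line"))
  expect_error(load_config(tmp3), "malformed")
})

test_that("shipped scenario configs parse, round-trip and cover the sweeps", {
  sc <- scenario_configs(seed = 3L)
  expect_setequal(names(sc),
                  c("quartic-symmetric", "radial-symmetric", "redqueen",
                    "seeding-sweep", "mutation-sweep", "kmax-sweep"))
  tmp <- withr::local_tempdir()
  for (nm in names(sc)) {
    f <- file.path(tmp, paste0(nm, ".cfg"))
    write_config(sc[[nm]], f)
    expect_equal(load_config(f), sc[[nm]])
  }
  # the default symmetric scenario carries the headline parameterisation
  q <- sc[["quartic-symmetric"]]
  expect_equal(q$model$carrying, "quartic")
  expect_equal(q$model$sigma_alpha, 0.5)
  expect_true(all(q$model$b == 0))
})

test_that("write_outputs produces a self-describing directory", {
  tr <- quartic_esc()$trajectory
  tmp <- withr::local_tempdir()
  write_outputs(tr, tmp)
  expect_true(file.exists(file.path(tmp, "trajectory.tsv")))
  expect_true(file.exists(file.path(tmp, "events.tsv")))
  expect_true(file.exists(file.path(tmp, "metadata.txt")))
  tab <- read.table(file.path(tmp, "trajectory.tsv"), header = TRUE)
  expect_named(tab, c("time", "label", "z1", "z2", "N"))
  # metadata reproduces the run bit-identically
  cfg <- load_config(file.path(tmp, "metadata.txt"))
  tr2 <- run_simulation(cfg)
  expect_identical(tr2$final, tr$final)
  expect_identical(tr2$events, tr$events)
})

test_that("sweep: single point equals a direct run; order does not matter", {
  base <- run_config("ad", mp, ad_config(n_attempts = 120L), seed = 5L)
  one <- sweep_runs(base, list(initial_n = 4), seeds = 7L)
  direct <- run_ad(mp, ad_config(n_attempts = 120L, initial_n = 4L,
                                 seed = 7L))
  expect_equal(one$final_count,
               final_diversity(direct)$count)
  multi <- sweep_runs(base, list(initial_n = c(1, 4, 9)), seeds = c(2, 5))
  expect_equal(nrow(multi), 6L)
  # rows are a pure function of (axis value, seed): permuting the grid
  # leaves each row's result unchanged
  multi_perm <- sweep_runs(base, list(initial_n = c(9, 1, 4)),
                           seeds = c(5, 2))
  key <- function(df) df[order(df$initial_n, df$seed),
                         c("initial_n", "seed", "final_count")]
  expect_equal(key(multi), key(multi_perm), ignore_attr = TRUE)
})

test_that("the CLI drives simulate, fixtures and analyze end to end", {
  tmp <- withr::local_tempdir()
  fixdir <- file.path(tmp, "fix")
  nichepack_cli(c("fixtures", "--out", fixdir))
  expect_true(file.exists(file.path(fixdir, "quartic-symmetric.cfg")))
  # a scaled-down config for a fast end-to-end pass
  cfg <- run_config("ad", mp, ad_config(n_attempts = 80L), seed = 2L)
  cf <- file.path(tmp, "small.cfg")
  write_config(cfg, cf)
  outdir <- file.path(tmp, "run1")
  out <- capture.output(nichepack_cli(c("simulate", "--config", cf,
                                        "--seed", "2", "--out", outdir)))
  expect_true(any(grepl("final_count", out)))
  expect_true(file.exists(file.path(outdir, "trajectory.tsv")))
})
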