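test_that("presets carry the protocol parameter values they document", {
  # normalized benefits convert through b1*n^alpha and b2*sum(n^alpha)
  frozen <- list(
    "equal-groups" = list(G = 8L, n = rep(10L, 8), B1 = 200, B2 = 800,
                X0 = 5, Z0 = 50, c = 1, pi0 = 1, alpha = 1,
                mu1 = 0.25, mu2 = 0.25),
    "cycling" = list(G = 4L, n = rep(10L, 4), B1 = 100, B2 = 1040, X0 = 5,
                Z0 = 50, c = 1, pi0 = 1, alpha = 1, mu1 = 0.25, mu2 = 0.25),
    "unequal-sizes" = list(G = 4L, n = c(5L, 10L, 15L, 20L), B1 = 100,
                X0 = 5, Z0 = 50, c = 1, pi0 = 1, alpha = 1),
    "focal-group" = list(G = 4L, n = c(5L, 10L, 15L, 20L), B1 = 100,
                B2 = 1500, X0 = 5, Z0 = 300, c = 1, pi0 = 1, alpha = 1))
  for (nm in names(frozen)) {
    p <- preset_params(nm)
    for (f in names(frozen[[nm]]))
      expect_equal(p[[f]], frozen[[nm]][[f]], label = paste(nm, f))
  }
  expect_error(preset_params("nonesuch"), "unknown preset")
  cv <- normalized_benefits_to_raw(b1 = 20, b2 = 10, n = rep(10, 8),
                                   alpha = 1)
  expect_equal(cv$B1, 200)
  expect_equal(cv$B2, 800)
  expect_error(normalized_benefits_to_raw(b1 = 20, n = c(5, 10), alpha = 1),
               "equal group sizes")
})

test_that("the fixture catalogue produces valid deterministic societies", {
  fx <- make_fixture("olson")
  expect_equal(fx$params$n, c(5L, 10L, 15L, 20L))
  expect_equal(fx$state$f, rep(0.25, 4))
  expect_length(validate_state(fx$state, fx$params), 0)
  fx2 <- make_fixture("two-symmetric-groups", mu1 = 0, mu2 = 0)
  expect_equal(fx2$state$f, c(0.5, 0.5))
  set.seed(1)
  st <- society_step(fx2$state, fx2$params)
  expect_equal(st$record$f_next, c(0.5, 0.5))   # Tullock fixed point
  for (nm in c("lone-cooperator", "cycling-small", "focal-n"))
    expect_length(validate_state(make_fixture(nm)$state,
                                 make_fixture(nm)$params), 0)
  expect_error(make_fixture("nope"), "catalogue")
})

test_that("sweeps are validated up front, deterministic and resumable", {
  base <- params_default(G = 2, n = 4)
  expect_error(run_sweep(base, "epsilon", c(0.1, 2)), "epsilon")
  expect_error(run_sweep(base, "nonesuch", 1), "not a model field")
  df1 <- run_sweep(base, "epsilon", c(0, 0.5), T = 30, window = 10,
                   n_runs = 2, base_seed = 3)
  df2 <- run_sweep(base, "epsilon", c(0, 0.5), T = 30, window = 10,
                   n_runs = 2, base_seed = 3)
  expect_identical(df1$mean_C, df2$mean_C)
  expect_equal(nrow(df1), 4)
  ag <- aggregate_sweep(df1)
  expect_equal(nrow(ag), 2)
  expect_true(all(ag$C_lo <= ag$C_mean & ag$C_mean <= ag$C_hi))
  # resumability: a completed sweep file short-circuits recomputation
  path <- withr::local_tempfile(fileext = ".csv")
  run_sweep(base, "epsilon", c(0, 0.5), T = 30, window = 10, n_runs = 2,
            base_seed = 3, out_csv = path)
  t0 <- Sys.time()
  df3 <- run_sweep(base, "epsilon", c(0, 0.5), T = 30, window = 10,
                   n_runs = 2, base_seed = 3, out_csv = path)
  expect_equal(nrow(df3), 4)
  expect_equal(sort(unique(df3$value)), c(0, 0.5))
})

test_that("cli drivers run from JSON configs and write their artifacts", {
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "params.json")
  writeLines(jsonlite::toJSON(
    list(G = 2, n = 4, B1 = 100, X0 = 5, B2 = 400, Z0 = 50, c = 1,
         pi0 = 1, alpha = 1, epsilon = 0.2, mu1 = 0.25, mu2 = 0.25,
         lam = "Inf"), auto_unbox = TRUE), cfg)
  s <- cli_run(cfg, dir, T = 30, window = 10, seed = 5)
  expect_true(file.exists(file.path(dir, "trajectory.csv")))
  js <- jsonlite::fromJSON(file.path(dir, "summary.json"))
  expect_equal(js$mean_C, s$mean_C)
  expect_error(cli_run(cfg, dir, T = 0), "usage error")
  # identical seeds give byte-identical trajectory files
  dir2 <- withr::local_tempdir()
  cli_run(cfg, dir2, T = 30, window = 10, seed = 5)
  expect_identical(readLines(file.path(dir, "trajectory.csv")),
                   readLines(file.path(dir2, "trajectory.csv")))
  swp <- file.path(dir, "sweep.json")
  writeLines(jsonlite::toJSON(list(
    base = list(G = 2, n = 4, B1 = 100, X0 = 5, B2 = 400, Z0 = 50, c = 1,
                pi0 = 1, alpha = 1, epsilon = 0.2, mu1 = 0.25, mu2 = 0.25,
                lam = "Inf"),
    axis = "epsilon", values = c(0, 0.4), T = 30, window = 10,
    n_runs = 2, base_seed = 1), auto_unbox = TRUE), swp)
  ag <- cli_sweep(swp, dir)
  expect_true(file.exists(file.path(dir, "sweep_runs.csv")))
  expect_true(file.exists(file.path(dir, "sweep_aggregate.csv")))
  writeLines(jsonlite::toJSON(list(axis = "epsilon"), auto_unbox = TRUE), swp)
  expect_error(cli_sweep(swp, dir), "usage error")
})
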