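test_that("broken-stick powers partition the unit interval", {
  set.seed(1)
  expect_equal(init_power_broken_stick(1), 1)
  for (G in c(2, 5, 8)) {
    f <- init_power_broken_stick(G)
    expect_length(f, G)
    expect_true(all(f >= 0))
    expect_equal(sum(f), 1, tolerance = 1e-12)
  }
  # each ordered segment has expectation 1/G
  set.seed(2)
  seg <- rowMeans(replicate(20000, init_power_broken_stick(4)))
  expect_equal(seg, rep(0.25, 4), tolerance = 0.01)
})

test_that("initial states follow the study protocol", {
  p_eq <- params_default(G = 4, n = 10)
  p_uneq <- params_default(group_sizes = c(5, 10, 15, 20), G = 4, n = NULL)
  set.seed(7)
  s_uneq <- init_state(p_uneq)
  expect_equal(s_uneq$f, rep(0.25, 4))     # unequal sizes: equal power
  s_eq <- init_state(p_eq)
  expect_false(all(s_eq$f == 0.25))        # equal sizes: broken stick
  expect_length(validate_state(s_eq, p_eq), 0)
  expect_length(validate_state(s_uneq, p_uneq), 0)
  # cooperation is initialized at probability one half
  set.seed(8)
  frac <- mean(replicate(300, mean(init_state(p_eq)$x)))
  expect_equal(frac, 0.5, tolerance = 0.02)
})

test_that("runs are deterministic given (params, T, seed)", {
  p <- params_default()
  t1 <- run_society(p, T = 50, seed = 42)
  t2 <- run_society(p, T = 50, seed = 42)
  expect_identical(t1$X, t2$X)
  expect_identical(t1$f, t2$f)
  expect_identical(t1$x, t2$x)
  t3 <- run_society(p, T = 50, seed = 43)
  expect_false(identical(t1$f, t3$f))
  expect_error(run_society(p, T = 0), "T")
})

test_that("frozen strategies leave actions constant and converge power", {
  p <- params_default(mu1 = 0, mu2 = 0, epsilon = 0.3)
  tr <- run_society(p, T = 300, seed = 9)
  expect_true(all(tr$x[rep(1L, 300), ] == tr$x))
  expect_true(all(tr$theta[rep(1L, 300), ] == tr$theta))
  # iterating only the power map converges geometrically for epsilon < 1
  expect_lt(max(abs(tr$f[300, ] - tr$f[299, ])), 1e-10)
  # a symmetric state with mu = 0 is an exact fixed point
  fx <- make_fixture("two-symmetric-groups", mu1 = 0, mu2 = 0)
  tr2 <- run_society(fx$params, T = 20, seed = 1, init = fx$state)
  expect_true(all(abs(tr2$f - 0.5) < 1e-14))
})

test_that("a single group keeps full power and obeys the step order", {
  p <- params_default(G = 1, n = 6, B2 = 0)
  tr <- run_society(p, T = 100, seed = 3)
  expect_true(all(tr$f == 1))
  expect_true(all(tr$C %in% c(0, 1)))
})

test_that("power conservation and elite rule hold along random runs", {
  set.seed(77)
  for (k in 1:10) {
    p <- params_default(G = sample(2:6, 1), n = sample(3:8, 1),
                        B1 = runif(1, 50, 300), B2 = runif(1, 0, 1200),
                        epsilon = runif(1))
    tr <- run_society(p, T = 100, seed = k)
    expect_true(all(abs(rowSums(tr$f) - 1) < 1e-12))
    expect_false(any(tr$theta == 1L & tr$X == 0))
  }
})

test_that("ensembles use disjoint seed streams and carry their seeds", {
  p <- params_default(G = 3, n = 5)
  sm <- run_ensemble(p, T = 40, n_runs = 5, base_seed = 10, window = 10)
  expect_length(sm, 5)
  expect_length(unique(vapply(sm, `[[`, 0, "seed")), 5)
  # n_runs = 1 equals a direct run + summary at the same seed
  sm1 <- run_ensemble(p, T = 40, n_runs = 1, base_seed = 4, window = 10)
  set.seed(4); sd1 <- sample.int(.Machine$integer.max - 1L, 1)
  direct <- summarize_window(run_society(p, T = 40, seed = sd1), 10)
  expect_equal(sm1[[1]]$mean_C, direct$mean_C)
  expect_equal(sm1[[1]]$f_bar, direct$f_bar)
})

test_that("trajectory CSV export is stable and rerunnable", {
  p <- params_default(G = 2, n = 3)
  tr <- run_society(p, T = 10, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- write_trajectory_csv(tr, path)
  expect_equal(names(df),
               c("t", "X_1", "X_2", "theta_1", "theta_2", "f_1", "f_2",
                 "Pi_1", "Pi_2", "C", "Q"))
  expect_equal(nrow(df), 10)
  again <- write_trajectory_csv(run_society(p, T = 10, seed = 5),
                                withr::local_tempfile(fileext = ".csv"))
  expect_identical(df, again)
})
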