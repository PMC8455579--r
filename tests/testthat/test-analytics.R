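test_that("single-group effort approximation follows its closed form", {
  expect_equal(single_group_effort(15, 20, 1, 5), 0)      # R1 < n^alpha
  expect_equal(single_group_effort(40, 10, 1, 5), 5)      # 5*(sqrt(4)-1)
  expect_equal(single_group_effort(1e8, 10, 1, 5), 10)    # capped at n
  expect_true(positive_effort_condition(20, 1, 5))
  expect_false(positive_effort_condition(6, 1, 5))        # boundary excluded
  expect_false(positive_effort_condition(12, 2, 5))       # homogeneity
  expect_true(positive_effort_condition(40, 2, 5) ==
              positive_effort_condition(20, 1, 5))
})

test_that("no-cooperation existence condition and its monotonicity", {
  expect_true(no_cooperation_exists(40, 2, 0.1, 10, 1))   # threshold 3
  expect_false(no_cooperation_exists(40, 30, 0.1, 10, 1))
  expect_error(no_cooperation_exists(5, 2, 0.1, 10, 1), "R1")
  thr <- function(R1, omega, n, alpha)
    1 + omega * R1 * (1 - sqrt(n^alpha / R1))
  expect_gt(thr(40, 0.2, 10, 1), thr(40, 0.1, 10, 1))   # grows with omega
  expect_gt(thr(80, 0.1, 10, 1), thr(40, 0.1, 10, 1))   # grows with R1
  expect_lt(thr(40, 0.1, 20, 1), thr(40, 0.1, 10, 1))   # falls with n
  expect_lt(thr(40, 0.1, 10, 1), thr(40, 0.1, 10, 0))   # falls with alpha
})

test_that("symmetric-coalition effort matches the closed form and its
           comparative statics", {
  expect_equal(symmetric_coalition_effort(8, 40, 2, 0.1, 10, 1, 5), 0)
  x <- symmetric_coalition_effort(8, 40, 30, 0.1, 10, 1, 5)
  expect_equal(x, 5 / 33 * (sqrt(15) - 1), tolerance = 1e-12)
  base <- c(C = 8, R1 = 40, R2 = 30, omega = 0.1, n = 10, alpha = 1, X0 = 5)
  at <- function(...) {
    a <- utils::modifyList(as.list(base), list(...))
    symmetric_coalition_effort(a$C, a$R1, a$R2, a$omega, a$n, a$alpha, a$X0)
  }
  expect_lt(at(C = 9), x)       # decreasing in C
  expect_lt(at(n = 12), x)      # decreasing in n
  expect_gt(at(R2 = 40), x)     # increasing in R2
  expect_lt(at(omega = 0.2), x) # decreasing in omega
})

test_that("no-defection condition behaves as a threshold in R2", {
  expect_true(no_defection_condition(8, 40, 1e9, 0.1, 10, 1))   # R2 -> Inf
  rhs <- function(R2) 10 * (8 * R2 / 4) *
    (1 + sqrt(1 + 4 / (64 * 10 * 0.1) * (1 - 1 / R2)))^2
  expect_gt(rhs(40), rhs(30))                                    # grows in R2
  expect_equal(no_defection_condition(8, 40, 30, 0.1, 10, 1), 40 < rhs(30))
  expect_warning(r <- no_defection_condition(1, 5, 0.01, 0.001, 2, 1),
                 "inapplicable")
  expect_false(r)
})

test_that("the incumbency bound matches the composed production chain", {
  p <- make_params(list(G = 8, n = 10, B1 = 200, X0 = 5, B2 = 1500,
                        Z0 = 50, c = 1, pi0 = 1, alpha = 1, epsilon = 0.2,
                        mu1 = 0.25, mu2 = 0.25, lam = Inf))
  em <- eps_max_full_coalition(p)
  # independent chain: coalition effort -> production -> club good -> bound
  Xc <- 5 / 33 * (sqrt(15) - 1)
  Ac <- 10 - Xc
  ZG <- 8 * 200 * Xc / (Xc + 5)
  QG <- 1500 * ZG / (ZG + 50)
  expect_equal(em$eps_max, Ac / (Ac + QG / 64), tolerance = 1e-10)
  expect_equal(em$X_c, Xc, tolerance = 1e-12)
  expect_equal(em$eps_max, 0.36, tolerance = 0.01)
  # monotone in G and pi0; eps_max -> 1 as the club good vanishes
  p_g <- params_default(G = 12, B1 = 200, B2 = 1500)
  expect_gt(eps_max_full_coalition(p_g)$eps_max, em$eps_max)
  p_pi <- params_default(G = 8, B1 = 200, B2 = 1500, pi0 = 2, c = 1)
  expect_gt(eps_max_full_coalition(p_pi)$eps_max, em$eps_max)
  expect_error(eps_max_full_coalition(params_default(G = 8, B2 = 1)),
               "absent")
})

test_that("power-stability probe separates stable and unstable incumbency", {
  p <- make_params(list(G = 8, n = 10, B1 = 60, X0 = 5, B2 = 1500,
                        Z0 = 50, c = 1, pi0 = 1, alpha = 1, epsilon = 0,
                        mu1 = 0.25, mu2 = 0.25, lam = Inf))
  expect_true(power_stability_probe(p, C = 8))        # epsilon = 0
  expect_true(power_stability_probe(p, C = 8, delta = 0))
  p_hi <- p; p_hi$epsilon <- 0.95
  expect_false(power_stability_probe(p_hi, C = 8))
  # the numeric boundary sits inside (0, analytic bound for C = G]
  en <- eps_max_numeric(p, 8)
  expect_gt(en, 0)
  expect_lte(en, eps_max_full_coalition(p)$eps_max + 0.05)
})

test_that("region scans trace the analytic existence boundaries", {
  base <- params_default(G = 8, n = 10, B1 = 200, B2 = 100, epsilon = 0.2)
  tab <- stability_region_scan(c(20, 40, 80), c(1, 2.9, 3.1, 10),
                               other = "R2", base = base)
  expect_equal(nrow(tab), 12)
  # boundary at R1 = 40: threshold is exactly 3
  expect_true(tab$noc_exists[tab$R1 == 40 & tab$R2 == 2.9])
  expect_false(tab$noc_exists[tab$R1 == 40 & tab$R2 == 3.1])
  # membership below the boundary is monotone in R2
  r2s <- tab[tab$R1 == 40, ]
  expect_true(all(diff(r2s$noc_exists[order(r2s$R2)]) <= 0))
  expect_equal(nrow(stability_region_scan(numeric(0), 1, "R2", base)), 0)
  # epsilon axis: full-coalition stability flips at eps_max
  base2 <- params_default(G = 8, n = 10, B1 = 60, B2 = 1500)
  em <- eps_max_full_coalition(base2)$eps_max
  tab2 <- stability_region_scan(12, c(em - 0.05, em + 0.05),
                                other = "epsilon", base = base2)
  expect_equal(tab2$full_stable, c(TRUE, FALSE))
})
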