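# Independent, from-scratch evaluation of the model's payoff equations,
# written naively (explicit loops, no reuse of package game functions) so
# it can serve as an oracle for the decision module.

oracle_group_quantities <- function(x, theta, f, p) {
  X <- numeric(p$G)
  for (k in seq_len(p$G)) X[k] <- sum(x[p$g_of == k])
  theta[X == 0] <- 0L                      # elite-membership rule
  P <- numeric(p$G)
  for (k in seq_len(p$G)) P[k] <- p$B1 * X[k] / (X[k] + p$X0)
  coop <- theta == 1L
  Z <- sum(P[coop])
  Q <- if (any(coop)) p$B2 * Z / (Z + p$Z0) else 0
  v <- numeric(p$G)
  if (any(coop)) {
    Fc <- sum(f[coop])
    v[coop] <- if (Fc > 0) f[coop] / Fc else 1 / sum(coop)
  }
  list(X = X, P = P, theta = theta, Q = Q, v = v)
}

# payoff of individual i in group j if it played a, everything else fixed
oracle_individual_payoff <- function(x, theta, f, p, j, i, a) {
  idx <- which(p$g_of == j)[i]
  x[idx] <- a
  q <- oracle_group_quantities(x, theta, f, p)
  res <- if (q$theta[j] == 1L) q$v[j] * q$Q else q$P[j]
  p$pi0 - p$c * a + res / p$n[j]^p$alpha
}

# payoff of group j if its status were s, everything else fixed
oracle_group_payoff <- function(x, theta, f, p, j, s) {
  theta[j] <- s
  q <- oracle_group_quantities(x, theta, f, p)
  res <- if (q$theta[j] == 1L) q$v[j] * q$Q else q$P[j]
  p$n[j] * p$pi0 - p$c * q$X[j] + res
}

# random micro-society consistent with the state invariants
random_micro_society <- function(G_max = 3, n_max = 4) {
  G <- sample(1:G_max, 1)
  n <- sample(2:n_max, G, replace = TRUE)
  p <- make_params(list(group_sizes = n, G = G,
                        B1 = runif(1, 10, 200), X0 = runif(1, 1, 10),
                        B2 = runif(1, 0, 500), Z0 = runif(1, 10, 100),
                        c = 1, pi0 = runif(1, 1, 3),
                        alpha = sample(c(0, 0.5, 1), 1),
                        epsilon = runif(1), mu1 = 1, mu2 = 1, lam = Inf))
  x <- as.integer(runif(p$N) < 0.6)
  theta <- as.integer(runif(G) < 0.5)
  theta[group_efforts(x, p) == 0] <- 0L
  f <- runif(G); f <- f / sum(f)
  list(params = p, state = make_state(x, theta, f, p))
}

params_default <- function(...) {
  make_params(utils::modifyList(
    list(G = 4, n = 10, B1 = 200, X0 = 5, B2 = 800, Z0 = 50, c = 1,
         pi0 = 1, alpha = 1, epsilon = 0.2, mu1 = 0.25, mu2 = 0.25,
         lam = Inf), list(...)))
}
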