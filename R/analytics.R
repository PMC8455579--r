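#' Approximate equilibrium effort of an isolated group
#'
#' Continuous approximation of the stationary number of contributors in a
#' single group playing the saturating public goods game:
#' \code{X* = 0} when \code{R1 < n^alpha}, otherwise
#' \code{X* = min(n, X0*(sqrt(R1/n^alpha) - 1))}, where
#' \code{R1 = B1/(c*X0)}.
#'
#' @param R1 Within-group benefit-to-cost ratio.
#' @param n Group size.
#' @param alpha Rivalrousness exponent.
#' @param X0 Half-effort parameter.
#' @return Predicted effort \code{X*} (continuous).
#' @export
single_group_effort <- function(R1, n, alpha, X0) {
  if (R1 < n^alpha) return(0)
  min(n, X0 * (sqrt(R1 / n^alpha) - 1))
}

#' Condition for positive effort in an isolated group
#'
#' An isolated group sustains positive effort iff the per-individual
#' maximum benefit exceeds the cost scaled by the half-effort:
#' \code{b1 > c*(1 + X0)} (strict).
#'
#' @param b1 Per-individual maximum benefit \code{B1/n^alpha}.
#' @param c Contribution cost.
#' @param X0 Half-effort parameter.
#' @return Logical.
#' @export
positive_effort_condition <- function(b1, c, X0) {
  b1 > c * (1 + X0)
}

#' Existence of the no-cooperation equilibrium
#'
#' The state with no cooperating groups (\code{C = 0}) exists iff the
#' between-group benefit-to-cost ratio is small:
#' \code{R2 < 1 + omega*R1*(1 - sqrt(n^alpha/R1))}. It is stable to small
#' power perturbations whenever \code{epsilon < 1}.
#'
#' @param R1,R2 Benefit-to-cost ratios of the two games.
#' @param omega Cost ratio \code{c*X0/Z0}.
#' @param n Group size (equal sizes assumed).
#' @param alpha Rivalrousness exponent.
#' @return Logical existence verdict.
#' @export
no_cooperation_exists <- function(R1, R2, omega, n, alpha) {
  if (R1 < n^alpha)
    stop("no_cooperation_exists requires R1 >= n^alpha ",
         "(each group must sustain positive effort)")
  R2 < 1 + omega * R1 * (1 - sqrt(n^alpha / R1))
}

#' Effort of identical cooperating groups at a symmetric equilibrium
#'
#' With \code{C} identical cooperating groups, each group's equilibrium
#' effort is \code{X_c* = X0/(omega*C*R1 + 1) * (sqrt(R1*R2/(C*n^alpha)) - 1)},
#' positive iff \code{R1*R2 > C*n^alpha} (0 returned otherwise).
#'
#' @param C Number of cooperating groups, \code{>= 1}.
#' @param R1,R2 Benefit-to-cost ratios.
#' @param omega Cost ratio.
#' @param n Group size.
#' @param alpha Rivalrousness exponent.
#' @param X0 Half-effort parameter.
#' @return Predicted per-group effort \code{X_c*} (continuous; 0 when the
#'   equilibrium does not exist).
#' @export
symmetric_coalition_effort <- function(C, R1, R2, omega, n, alpha, X0) {
  stopifnot(C >= 1)
  if (R1 * R2 <= C * n^alpha) return(0)
  X0 / (omega * C * R1 + 1) * (sqrt(R1 * R2 / (C * n^alpha)) - 1)
}

#' No-defection condition for a symmetric coalition
#'
#' A cooperating group is not motivated to withdraw iff
#' \code{R1 < n^alpha * (C*R2/4) * (1 + sqrt(1 + 4/(C^2*n^alpha*omega) *
#' (1 - 1/R2)))^2}. When the inner square root is undefined (possible for
#' \code{R2 < 1}) the condition is inapplicable and \code{FALSE} is
#' returned with a warning.
#'
#' @inheritParams symmetric_coalition_effort
#' @return Logical.
#' @export
no_defection_condition <- function(C, R1, R2, omega, n, alpha) {
  stopifnot(R2 > 0, C >= 1)
  inner <- 1 + 4 / (C^2 * n^alpha * omega) * (1 - 1 / R2)
  if (inner < 0) {
    warning("no-defection condition inapplicable: inner term negative")
    return(FALSE)
  }
  R1 < n^alpha * (C * R2 / 4) * (1 + sqrt(inner))^2
}

#' Upper incumbency bound for the full-coalition equilibrium
#'
#' For complete between-group cooperation (\code{C = G}, equal sizes) the
#' symmetric equilibrium is stable to small power perturbations iff
#' \code{epsilon < eps_max = A_c*/(A_c* + Q_G/G^2)}, where
#' \code{A_c* = Pi0 - c*X_c*} is each group's resource before the
#' between-group game and \code{Q_G} the club good produced at the
#' equilibrium. \code{Q_G} and \code{A_c*} are obtained by composing the
#' symmetric-coalition effort through the two production functions.
#'
#' @param params A \code{groupsoc_params} with equal group sizes.
#' @return List \code{(eps_max, X_c, A_c, Z_G, Q_G)}.
#' @export
eps_max_full_coalition <- function(params) {
  if (length(unique(params$n)) != 1L)
    stop("eps_max_full_coalition requires equal group sizes")
  n <- params$n[1]; G <- params$G
  Xc <- symmetric_coalition_effort(G, params$R1, params$R2, params$omega,
                                   n, params$alpha, params$X0)
  if (Xc <= 0) stop("full-coalition equilibrium absent (X_c* <= 0)")
  Ac <- n * params$pi0 - params$c * Xc
  ZG <- G * group_production(Xc, params$B1, params$X0)
  QG <- coalition_production(ZG, params$B2, params$Z0)
  list(eps_max = Ac / (Ac + QG / G^2), X_c = Xc, A_c = Ac, Z_G = ZG, Q_G = QG)
}

# Symmetric candidate state: C cooperating groups at effort Xc each,
# G - C defectors at effort Xd, powers uniform within the two classes
# scaled so cooperators hold total power wc (defaults to proportional).
.symmetric_state <- function(params, C, Xc, Xd = NULL) {
  G <- params$G; n <- params$n[1]
  if (is.null(Xd))
    Xd <- round(single_group_effort(params$R1, n, params$alpha, params$X0))
  x <- integer(0)
  theta <- integer(G)
  for (j in seq_len(G)) {
    k <- if (j <= C) round(Xc) else round(Xd)
    x <- c(x, rep(1L, k), rep(0L, n - k))
    theta[j] <- if (j <= C && k > 0) 1L else 0L
  }
  f <- rep(1 / G, G)
  structure(list(x = x, theta = theta, f = f), class = "groupsoc_state")
}

#' Numerical probe of power stability at a symmetric equilibrium
#'
#' Holds all strategies fixed at a symmetric candidate equilibrium
#' (\code{C} cooperating groups at effort \code{Xc}), perturbs one
#' cooperating group's power by \code{delta} (renormalized), and iterates
#' only the payoff-to-power map for \code{H} steps. The equilibrium is
#' judged power-stable iff the maximum deviation from the symmetric powers
#' shrinks below \code{delta/10}. This is a numerical stand-in for the
#' implicit algebraic stability bounds for partial coalitions.
#'
#' @param params A \code{groupsoc_params} with equal group sizes.
#' @param C Coalition size of the candidate equilibrium.
#' @param Xc Cooperating-group effort (defaults to the symmetric-coalition
#'   prediction).
#' @param delta Perturbation size (default 1e-3).
#' @param H Iteration horizon (default 200).
#' @return Logical: \code{TRUE} if the perturbation decays.
#' @export
power_stability_probe <- function(params, C, Xc = NULL, delta = 1e-3,
                                  H = 200) {
  if (length(unique(params$n)) != 1L)
    stop("power_stability_probe requires equal group sizes")
  if (delta == 0) return(TRUE)
  n <- params$n[1]
  if (is.null(Xc))
    Xc <- symmetric_coalition_effort(C, params$R1, params$R2, params$omega,
                                     n, params$alpha, params$X0)
  if (C >= 1 && round(Xc) < 1)
    stop("candidate equilibrium has no contributors in cooperating groups")
  st <- .symmetric_state(params, C, Xc)
  f0 <- st$f
  f <- f0
  f[1] <- f[1] + delta
  f <- f / sum(f)
  for (h in seq_len(H)) {
    s <- structure(list(x = st$x, theta = st$theta, f = f),
                   class = "groupsoc_state")
    gp <- group_payoffs(s, params)
    y <- effective_effort(gp$Pi, f, params$epsilon)
    f <- update_power(y, params$G)
  }
  max(abs(f - f0)) < delta / 10
}

#' Scan existence and stability over a parameter grid
#'
#' Evaluates, per grid point, the existence and stability verdicts of the
#' symmetric equilibria: \code{C = 0} via the no-cooperation condition
#' (stable iff \code{epsilon < 1}) and \code{C = G} via the
#' symmetric-coalition effort, the no-defection condition and the
#' incumbency bound \code{eps_max}. The grid varies \code{R1} against
#' either \code{epsilon} or \code{R2}.
#'
#' @param R1_values Numeric grid for \code{R1}.
#' @param other_values Numeric grid for the second axis.
#' @param other Which axis varies: \code{"epsilon"} or \code{"R2"}.
#' @param base A \code{groupsoc_params} supplying all fixed parameters
#'   (equal group sizes).
#' @return Data frame with one row per grid point: the axes, \code{X_c},
#'   \code{eps_max}, and logical verdicts \code{noc_exists},
#'   \code{noc_stable}, \code{full_exists}, \code{full_stable}.
#' @export
stability_region_scan <- function(R1_values, other_values,
                                  other = c("epsilon", "R2"), base) {
  other <- match.arg(other)
  if (length(R1_values) == 0 || length(other_values) == 0)
    return(data.frame())
  grid <- expand.grid(R1 = R1_values, other = other_values)
  n <- base$n[1]; G <- base$G
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    R1 <- grid$R1[k]
    R2 <- if (other == "R2") grid$other[k] else base$R2
    eps <- if (other == "epsilon") grid$other[k] else base$epsilon
    noc_exists <- if (R1 >= n^base$alpha)
      no_cooperation_exists(R1, R2, base$omega, n, base$alpha) else NA
    Xc <- symmetric_coalition_effort(G, R1, R2, base$omega, n,
                                     base$alpha, base$X0)
    full_exists <- Xc > 0 &&
      no_defection_condition(G, R1, R2, base$omega, n, base$alpha)
    eps_max <- NA_real_
    if (Xc > 0) {
      B1 <- R1 * base$c * base$X0   # grid ratios imply the raw benefits
      B2 <- R2 * base$Z0
      Ac <- n * base$pi0 - base$c * Xc
      ZG <- G * B1 * Xc / (Xc + base$X0)
      QG <- B2 * ZG / (ZG + base$Z0)
      eps_max <- Ac / (Ac + QG / G^2)
    }
    data.frame(R1 = R1, axis2 = grid$other[k], R2 = R2, epsilon = eps,
               X_c = Xc, eps_max = eps_max,
               noc_exists = noc_exists,
               noc_stable = isTRUE(noc_exists) && eps < 1,
               full_exists = full_exists,
               full_stable = full_exists && !is.na(eps_max) && eps < eps_max)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "axis2"] <- other
  out[, !duplicated(names(out))]
}

#' Bisection estimate of the stable incumbency band of a symmetric
#' coalition
#'
#' Uses \code{\link{power_stability_probe}} on a bisection over
#' \code{epsilon} in \code{[0, 1]} to locate the largest epsilon at which
#' the candidate symmetric equilibrium with \code{C} cooperating groups is
#' power-stable. For partial coalitions the analytic bounds are implicit,
#' so this numerical estimate is the package's stability boundary.
#'
#' @param params A \code{groupsoc_params} (its \code{epsilon} is ignored).
#' @param C Coalition size.
#' @param tol Bisection tolerance on epsilon (default 1e-3).
#' @return Estimated upper stability boundary for epsilon.
#' @export
eps_max_numeric <- function(params, C, tol = 1e-3) {
  probe_at <- function(eps) {
    p <- params; p$epsilon <- eps
    power_stability_probe(p, C)
  }
  lo <- 0; hi <- 1
  if (!probe_at(0)) return(0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (probe_at(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
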