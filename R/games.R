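#' Within-group production function
#'
#' Saturating (Michaelis-Menten-like) public goods production
#' \code{P = B1 * X / (X + X0)}: strictly increasing and concave in the
#' combined group effort \code{X}, bounded above by \code{B1}, with
#' \code{P(X0) = B1/2}.
#'
#' @param X Group effort (number of contributing members), \code{>= 0}.
#'   Vectorized.
#' @param B1 Maximum benefit of within-group cooperation.
#' @param X0 Half-effort parameter.
#' @return Produced resource \code{P}.
#' @export
group_production <- function(X, B1, X0) {
  stopifnot(all(X >= 0))
  B1 * X / (X + X0)
}

#' Between-group (club goods) production function
#'
#' \code{Q = B2 * Z / (Z + Z0)} for the combined contribution \code{Z} of
#' the cooperating coalition; only coalition members share \code{Q}.
#'
#' @param Z Combined coalition contribution, \code{>= 0}. Vectorized.
#' @param B2 Maximum benefit of between-group cooperation.
#' @param Z0 Half-effort parameter at the group level.
#' @return Produced resource \code{Q}.
#' @export
coalition_production <- function(Z, B2, Z0) {
  stopifnot(all(Z >= 0))
  B2 * Z / (Z + Z0)
}

#' Power shares of the cooperating coalition
#'
#' A cooperating group's share of the club good equals its relative power
#' within the coalition, \code{v_j = f_j / sum(f_k over cooperators)};
#' defectors get 0. A coalition whose total power is exactly zero (possible
#' only transiently at degenerate power states) divides equally, the
#' symmetric limit of the share rule.
#'
#' @param f Power vector (sums to 1).
#' @param theta 0/1 cooperation statuses.
#' @return Share vector \code{v}, summing to 1 over cooperators.
#' @export
power_shares <- function(f, theta) {
  coop <- theta == 1L
  if (!any(coop)) stop("empty coalition: power shares undefined")
  v <- numeric(length(f))
  Fc <- sum(f[coop])
  v[coop] <- if (Fc > 0) f[coop] / Fc else 1 / sum(coop)
  v
}

#' Group-level payoffs of the two economic games
#'
#' Computes the realized per-group payoff
#' \code{Pi_j = Pi0_j - c*X_j + P_j} for defectors and
#' \code{Pi_j = Pi0_j - c*X_j + v_j*Q} for coalition members, where
#' \code{Pi0_j = n_j*pi0} is the baseline group endowment.
#'
#' @param state A \code{groupsoc_state}.
#' @param params A \code{groupsoc_params}.
#' @return List with components \code{X}, \code{P}, \code{C}, \code{Z},
#'   \code{Q}, \code{v}, \code{Pi}.
#' @export
group_payoffs <- function(state, params) {
  X <- group_efforts(state$x, params)
  P <- group_production(X, params$B1, params$X0)
  coop <- state$theta == 1L
  C <- sum(coop)
  Z <- sum(P[coop])
  Q <- if (C > 0) coalition_production(Z, params$B2, params$Z0) else 0
  v <- if (C > 0) power_shares(state$f, state$theta) else numeric(params$G)
  Pi <- params$Pi0 - params$c * X + ifelse(coop, v * Q, P)
  list(X = X, P = P, C = C, Z = Z, Q = Q, v = v, Pi = Pi)
}

#' Individual payoffs
#'
#' Each individual receives a \code{1/n_j^alpha} share of its group's
#' resource term: \code{pi_ij = pi0 - c*x_ij + P_j/n_j^alpha} in a
#' defecting group, \code{pi0 - c*x_ij + v_j*Q/n_j^alpha} in a cooperating
#' one. With \code{alpha = 0} the goods are pure public (no per-capita
#' division); with \code{alpha = 1} they are fully rival.
#'
#' @inheritParams group_payoffs
#' @return Numeric vector of individual payoffs, in flat group order.
#' @export
individual_payoffs <- function(state, params) {
  gp <- group_payoffs(state, params)
  coop <- state$theta == 1L
  res <- ifelse(coop, gp$v * gp$Q, gp$P) / params$n_alpha
  params$pi0 - params$c * state$x + res[params$g_of]
}

#' Effective political effort
#'
#' \code{y = Pi * (1 - epsilon + epsilon*f)}: at \code{epsilon = 0} only
#' material resources matter (\code{y = Pi}); at \code{epsilon = 1} power
#' and resources combine multiplicatively (\code{y = Pi*f}). Larger
#' \code{epsilon} means weaker checks-and-balances against incumbents.
#'
#' @param Pi Group payoff(s), must be nonnegative.
#' @param f Group power(s) in \code{[0, 1]}.
#' @param epsilon Incumbency parameter in \code{[0, 1]}.
#' @return Effective effort \code{y}.
#' @export
effective_effort <- function(Pi, f, epsilon) {
  if (any(Pi < 0))
    stop("negative group payoff: political contest requires Pi >= 0")
  Pi * (1 - epsilon + epsilon * f)
}

#' Tullock contest power update
#'
#' Next-step power is proportional to effective effort,
#' \code{f'_j = y_j / sum(y)}; if all efforts are zero power resets to the
#' uniform distribution \code{1/G}.
#'
#' @param y Nonnegative effective efforts, length \code{G}.
#' @param G Number of groups (defaults to \code{length(y)}).
#' @return Updated power vector summing to 1.
#' @export
update_power <- function(y, G = length(y)) {
  if (any(y < 0)) stop("negative effort: Tullock contest undefined")
  s <- sum(y)
  if (s > 0) y / s else rep(1 / G, G)
}
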