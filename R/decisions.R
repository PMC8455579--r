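#' Hypothetical payoff of an individual action
#'
#' Myopic evaluation: the payoff individual \code{i} of group \code{j}
#' would realize this step if it played \code{a}, holding every other
#' individual's contribution, all group statuses and all powers fixed at
#' their current values. The evaluation is self-consistent: if the group
#' cooperates, its modified production enters the coalition contribution
#' \code{Z} and the club good \code{Q} is recomputed; if the change leaves
#' the group with zero collective effort, the elite rule applies inside the
#' hypothetical and the group is evaluated as a defector.
#'
#' @param state A \code{groupsoc_state}.
#' @param j Group index.
#' @param i Member index within group \code{j}.
#' @param a Hypothetical action, 0 or 1.
#' @param params A \code{groupsoc_params}.
#' @return The hypothetical individual payoff.
#' @export
individual_payoff_given_action <- function(state, j, i, a, params) {
  idx <- which(params$g_of == j)[i]
  X <- group_efforts(state$x, params)
  Xp <- X[j] - state$x[idx] + a
  P <- group_production(X, params$B1, params$X0)
  Pp <- group_production(Xp, params$B1, params$X0)
  coop <- state$theta == 1L
  if (coop[j] && Xp > 0) {
    Zp <- sum(P[coop]) - P[j] + Pp
    Qp <- coalition_production(Zp, params$B2, params$Z0)
    v <- power_shares(state$f, state$theta)
    res <- v[j] * Qp
  } else {
    res <- if (Xp > 0) Pp else 0   # elite rule: X_j = 0 => defector with P = 0
  }
  params$pi0 - params$c * a + res / params$n_alpha[j]
}

#' Hypothetical payoff of a group status
#'
#' The payoff group \code{j} would realize if its cooperation status were
#' \code{s}, holding all contributions, the other groups' statuses and all
#' powers fixed. The coalition composition, \code{Z}, \code{Q} and the
#' power shares are recomputed for the hypothetical coalition; a group
#' joining an otherwise-empty coalition gets the whole club good
#' (\code{v = 1}). \code{s = 1} with zero group effort is forced to the
#' defector evaluation (elite rule).
#'
#' @param state A \code{groupsoc_state}.
#' @param j Group index.
#' @param s Hypothetical status, 0 or 1.
#' @param params A \code{groupsoc_params}.
#' @return The hypothetical group payoff.
#' @export
group_payoff_given_status <- function(state, j, s, params) {
  X <- group_efforts(state$x, params)
  P <- group_production(X, params$B1, params$X0)
  if (X[j] == 0) s <- 0L
  theta <- state$theta
  theta[j] <- as.integer(s)
  coop <- theta == 1L
  base <- params$Pi0[j] - params$c * X[j]
  if (!coop[j]) return(base + P[j])
  Z <- sum(P[coop])
  Q <- coalition_production(Z, params$B2, params$Z0)
  Fc <- sum(state$f[coop])
  v <- if (Fc > 0) state$f[j] / Fc else 1 / sum(coop)
  base + v * Q
}

#' Logit choice probability
#'
#' Probability of choosing action 1 under quantal-response (logit) choice
#' with precision \code{lam}: \code{p = 1/(1 + exp(-lam*delta))}. At
#' \code{lam = Inf} this is exact best response with fair tie-breaking
#' (\code{p = 1} if \code{delta > 0}, \code{0} if \code{delta < 0},
#' \code{1/2} at a tie); at \code{lam = 0} the choice is uniform.
#'
#' @param delta Payoff difference, action 1 minus action 0. Vectorized.
#' @param lam Precision, \code{>= 0} or \code{Inf}.
#' @return Probability (or vector of probabilities) of action 1.
#' @export
choice_probability <- function(delta, lam) {
  if (is.infinite(lam)) {
    ifelse(delta > 0, 1, ifelse(delta < 0, 0, 0.5))
  } else {
    1 / (1 + exp(-lam * delta))
  }
}

# Per-group per-capita resource share as a function of own hypothetical
# effort, all else (other contributions, theta, f) fixed. Vectorized over
# groups: Xp is a length-G vector of hypothetical own efforts.
.share_at <- function(Xp, P, coop, vshare, Zc, params) {
  Pp <- group_production(pmax(Xp, 0), params$B1, params$X0)
  out <- Pp / params$n_alpha
  if (any(coop)) {
    Zp <- Zc - P + Pp
    Qp <- coalition_production(Zp, params$B2, params$Z0)
    out[coop] <- vshare[coop] * Qp[coop] / params$n_alpha[coop]
  }
  out[Xp <= 0] <- 0   # elite rule inside the hypothetical
  out
}

#' Synchronous individual strategy revision
#'
#' Each individual is independently selected for revision with probability
#' \code{mu1}. Every selected individual compares the payoffs of
#' contributing and not contributing against the same pre-revision state
#' (\code{\link{individual_payoff_given_action}}) and draws its new action
#' from \code{\link{choice_probability}}; unselected individuals keep their
#' action. All changes apply simultaneously. Random draws consume the RNG
#' in a fixed canonical order (all selection draws, then all action draws,
#' each in flat group-member order), so runs are reproducible from a seed.
#'
#' @param state A \code{groupsoc_state}.
#' @param params A \code{groupsoc_params}.
#' @return New contribution vector \code{x}.
#' @export
revise_individuals <- function(state, params) {
  x <- state$x
  if (params$mu1 <= 0) return(x)
  X <- group_efforts(x, params)
  P <- group_production(X, params$B1, params$X0)
  coop <- state$theta == 1L
  vshare <- numeric(params$G)
  if (any(coop)) {
    Fc <- sum(state$f[coop])
    vshare[coop] <- if (Fc > 0) state$f[coop] / Fc else 1 / sum(coop)
  }
  Zc <- sum(P[coop])
  s_base <- .share_at(X, P, coop, vshare, Zc, params)       # own effort as-is
  s_drop <- .share_at(X - 1, P, coop, vshare, Zc, params)   # a contributor leaves
  s_join <- .share_at(X + 1, P, coop, vshare, Zc, params)   # a defector joins
  d_noncontrib <- -params$c + s_join - s_base
  d_contrib <- -params$c + s_base - s_drop
  g <- params$g_of
  delta <- ifelse(x == 1L, d_contrib[g], d_noncontrib[g])
  sel <- stats::runif(params$N) < params$mu1
  act <- as.integer(stats::runif(params$N) < choice_probability(delta, params$lam))
  ifelse(sel, act, x)
}

#' Synchronous group strategy revision
#'
#' Each group is independently selected with probability \code{mu2} and
#' compares the payoffs of cooperating and defecting against the same
#' pre-revision statuses (\code{\link{group_payoff_given_status}});
#' changes apply simultaneously. After revision the elite rule forces
#' \code{theta_j = 0} wherever the group effort is zero. Draw order:
#' all selection draws, then all action draws, in group order.
#'
#' @param state A \code{groupsoc_state} (with contributions already updated
#'   this step).
#' @param params A \code{groupsoc_params}.
#' @return New status vector \code{theta}.
#' @export
revise_groups <- function(state, params) {
  theta <- state$theta
  X <- group_efforts(state$x, params)
  if (params$mu2 > 0) {
    P <- group_production(X, params$B1, params$X0)
    f <- state$f
    coop <- theta == 1L
    Zall <- sum(P[coop]); Fall <- sum(f[coop]); Call <- sum(coop)
    Zo <- Zall - ifelse(coop, P, 0)      # other cooperators' contribution
    Fo <- Fall - ifelse(coop, f, 0)      # other cooperators' power
    Co <- Call - as.integer(coop)
    Z1 <- Zo + P
    Q1 <- coalition_production(Z1, params$B2, params$Z0)
    denom <- Fo + f
    v1 <- ifelse(denom > 0, f / denom, 1 / (Co + 1))
    Pi_coop <- params$Pi0 - params$c * X + v1 * Q1
    Pi_def <- params$Pi0 - params$c * X + P
    delta <- Pi_coop - Pi_def
    sel <- stats::runif(params$G) < params$mu2
    act <- as.integer(stats::runif(params$G) <
                        choice_probability(delta, params$lam))
    theta <- ifelse(sel, act, theta)
  }
  theta[X == 0] <- 0L
  as.integer(theta)
}
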