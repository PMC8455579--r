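#' Broken-stick initial power distribution
#'
#' Partitions the unit interval by \code{G - 1} independent uniform cut
#' points; the segment lengths, taken in position order, are the initial
#' group powers. Each segment has expectation \code{1/G}.
#'
#' @param G Number of groups.
#' @return Power vector of length \code{G} summing to 1.
#' @export
init_power_broken_stick <- function(G) {
  if (G == 1L) return(1)
  cuts <- sort(stats::runif(G - 1))
  diff(c(0, cuts, 1))
}

#' Random initial society state
#'
#' Powers are drawn from the broken-stick distribution when all groups
#' have equal size; with unequal sizes (or \code{equal_power = TRUE})
#' groups start at equal power \code{1/G}. Each individual and each group
#' cooperates independently with probability 0.5; the elite rule then
#' forces \code{theta_j = 0} for groups with no contributors.
#'
#' @param params A \code{groupsoc_params}.
#' @param equal_power Force equal initial powers even for equal sizes.
#' @return A \code{groupsoc_state}.
#' @export
init_state <- function(params, equal_power = FALSE) {
  equal_sizes <- length(unique(params$n)) == 1L
  f <- if (equal_sizes && !equal_power) init_power_broken_stick(params$G)
       else rep(1 / params$G, params$G)
  x <- as.integer(stats::runif(params$N) < 0.5)
  theta <- as.integer(stats::runif(params$G) < 0.5)
  theta[group_efforts(x, params) == 0] <- 0L
  structure(list(x = x, theta = theta, f = f), class = "groupsoc_state")
}

#' Advance the society by one time step
#'
#' Step order: (1) individuals revise contributions (synchronously, myopic
#' best response with logit errors); (2) groups revise cooperation
#' statuses, then the elite rule is enforced; (3) the economic games are
#' played: group production \code{P}, coalition contribution \code{Z} and
#' club good \code{Q}, power shares \code{v}, group and individual
#' payoffs; (4) the political game converts payoffs into effective efforts
#' \code{y = Pi*(1 - epsilon + epsilon*f)} and the Tullock contest yields
#' the next power vector.
#'
#' @param state A \code{groupsoc_state}.
#' @param params A \code{groupsoc_params}.
#' @return List with \code{state} (the new state) and \code{record}, a
#'   list holding \code{X}, \code{P}, \code{C}, \code{Z}, \code{Q},
#'   \code{v}, \code{Pi}, \code{y}, \code{f_next} and the revised
#'   \code{x}, \code{theta} for this step.
#' @export
society_step <- function(state, params) {
  x_new <- revise_individuals(state, params)
  s1 <- structure(list(x = x_new, theta = state$theta, f = state$f),
                  class = "groupsoc_state")
  theta_new <- revise_groups(s1, params)
  s2 <- structure(list(x = x_new, theta = theta_new, f = state$f),
                  class = "groupsoc_state")
  gp <- group_payoffs(s2, params)
  y <- effective_effort(gp$Pi, state$f, params$epsilon)
  f_next <- update_power(y, params$G)
  new_state <- structure(list(x = x_new, theta = theta_new, f = f_next),
                         class = "groupsoc_state")
  rec <- c(gp, list(y = y, f_next = f_next, x = x_new, theta = theta_new))
  list(state = new_state, record = rec)
}

#' Run a single simulation
#'
#' Iterates \code{\link{society_step}} for \code{T} steps from a freshly
#' initialized (or supplied) state. The trajectory is fully determined by
#' \code{(params, T, seed)}.
#'
#' @param params A \code{groupsoc_params}.
#' @param T Number of time steps (default 4000).
#' @param seed Integer RNG seed.
#' @param init Optional initial \code{groupsoc_state}; drawn by
#'   \code{\link{init_state}} when missing.
#' @param store_states Keep the per-step contribution matrix (needed by
#'   \code{\link{classify_regime}}); default \code{TRUE}.
#' @param equal_power Passed to \code{\link{init_state}}.
#' @return A \code{groupsoc_trajectory}: matrices \code{X}, \code{theta},
#'   \code{f}, \code{Pi} (\code{T x G}; \code{f} is the power resulting
#'   from each step's contest), vectors \code{C}, \code{Z}, \code{Q},
#'   optional \code{x} (\code{T x N}), plus \code{params}, \code{seed} and
#'   the initial state.
#' @export
run_society <- function(params, T = 4000, seed = 1, init = NULL,
                        store_states = TRUE, equal_power = FALSE) {
  if (T < 1) stop("T must be >= 1")
  set.seed(as.integer(seed))
  state <- if (is.null(init)) init_state(params, equal_power) else init
  G <- params$G
  Xm <- matrix(0, T, G); Tm <- matrix(0L, T, G)
  Fm <- matrix(0, T, G); Pm <- matrix(0, T, G)
  Cv <- integer(T); Zv <- numeric(T); Qv <- numeric(T)
  xm <- if (store_states) matrix(0L, T, params$N) else NULL
  init_saved <- state
  for (t in seq_len(T)) {
    st <- society_step(state, params)
    r <- st$record
    Xm[t, ] <- r$X; Tm[t, ] <- r$theta; Fm[t, ] <- r$f_next
    Pm[t, ] <- r$Pi; Cv[t] <- r$C; Zv[t] <- r$Z; Qv[t] <- r$Q
    if (store_states) xm[t, ] <- r$x
    state <- st$state
  }
  structure(list(params = params, seed = seed, T = T,
                 X = Xm, theta = Tm, f = Fm, Pi = Pm,
                 C = Cv, Z = Zv, Q = Qv, x = xm, init = init_saved,
                 final = state),
            class = "groupsoc_trajectory")
}

#' @export
print.groupsoc_trajectory <- function(x, ...) {
  cat("groupsoc trajectory: G =", x$params$G, ", T =", x$T,
      ", seed =", x$seed, "\n")
  cat("  final C =", x$C[x$T], " final f =",
      paste(signif(x$f[x$T, ], 3), collapse = " "), "\n")
  invisible(x)
}

#' Run a seeded ensemble of simulations
#'
#' Independent runs with per-run seeds spawned from a master seed; each run
#' is summarized over its final window by \code{\link{summarize_window}}.
#'
#' @param params A \code{groupsoc_params}.
#' @param T Steps per run.
#' @param n_runs Number of runs.
#' @param base_seed Master seed; per-run seeds are drawn from it.
#' @param window Length of the averaging window (default \code{min(1000, T)}).
#' @param ... Passed to \code{\link{run_society}}.
#' @return List of \code{groupsoc_summary} objects (one per run), each
#'   carrying its seed.
#' @export
run_ensemble <- function(params, T = 4000, n_runs = 100, base_seed = 1,
                         window = min(1000, T), ...) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  set.seed(as.integer(base_seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  lapply(seq_len(n_runs), function(i) {
    tr <- run_society(params, T = T, seed = seeds[i], ...)
    s <- summarize_window(tr, window)
    s$seed <- seeds[i]
    s
  })
}

#' Export a trajectory as a wide CSV
#'
#' One row per step with columns \code{t}, \code{X_1..X_G},
#' \code{theta_1..theta_G}, \code{f_1..f_G}, \code{Pi_1..Pi_G}, \code{C},
#' \code{Q}.
#'
#' @param trajectory A \code{groupsoc_trajectory}.
#' @param path Output CSV path.
#' @return The data frame, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  G <- trajectory$params$G
  nm <- function(p) paste0(p, "_", seq_len(G))
  df <- data.frame(t = seq_len(trajectory$T))
  add <- function(df, m, p) { colnames(m) <- nm(p); cbind(df, m) }
  df <- add(df, trajectory$X, "X")
  df <- add(df, trajectory$theta, "theta")
  df <- add(df, trajectory$f, "f")
  df <- add(df, trajectory$Pi, "Pi")
  df$C <- trajectory$C
  df$Q <- trajectory$Q
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
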