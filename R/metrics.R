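#' Gini index
#'
#' Half of the relative mean absolute difference:
#' \code{I = sum_ij |v_i - v_j| / (2 m^2 mean(v))}. Scale- and
#' permutation-invariant, 0 for a constant vector, at most
#' \code{(m - 1)/m}.
#'
#' @param values Nonnegative numeric vector.
#' @return Gini index in \code{[0, 1]}; \code{NA} for an all-zero vector.
#' @export
gini <- function(values) {
  stopifnot(all(values >= 0))
  m <- length(values)
  mu <- mean(values)
  if (mu == 0) return(NA_real_)
  sum(abs(outer(values, values, "-"))) / (2 * m^2 * mu)
}

#' Coalition statistics of one step
#'
#' Restricted to cooperating groups: coalition size \code{C}, Gini index of
#' their powers, and the population standard deviation of their efforts.
#' With no cooperators the inequality statistics are undefined (\code{NA});
#' a singleton coalition has both equal to 0.
#'
#' @param theta 0/1 statuses.
#' @param f Power vector.
#' @param X Group efforts.
#' @return List \code{(C, gini_f, sd_X)}.
#' @export
coalition_stats <- function(theta, f, X) {
  coop <- theta == 1L
  C <- sum(coop)
  if (C == 0) return(list(C = 0L, gini_f = NA_real_, sd_X = NA_real_))
  if (C == 1) return(list(C = 1L, gini_f = 0, sd_X = 0))
  fx <- f[coop]; xx <- X[coop]
  list(C = C, gini_f = gini(fx),
       sd_X = sqrt(mean((xx - mean(xx))^2)))   # population SD
}

#' Window summary of a trajectory
#'
#' Averages the coalition statistics and the per-group observables over
#' the final \code{window} steps. Steps with an empty coalition are
#' excluded from the Gini/SD averages (inequality among cooperators is
#' undefined there), not imputed as zero.
#'
#' @param trajectory A \code{groupsoc_trajectory}.
#' @param window Number of final steps to average (default
#'   \code{min(1000, T)}).
#' @param f_tol Power tolerance passed to \code{\link{classify_regime}}.
#' @return A \code{groupsoc_summary}: \code{mean_C}, \code{gini_I},
#'   \code{sd_sigma}, per-group means \code{X_bar}, \code{theta_bar},
#'   \code{f_bar}, the \code{regime} label, \code{elite_structure} (only
#'   classified at equilibrium), and \code{window}.
#' @export
summarize_window <- function(trajectory, window = min(1000, trajectory$T),
                             f_tol = 1e-6) {
  T <- trajectory$T
  if (window > T) stop("window (", window, ") longer than trajectory (", T, ")")
  idx <- seq.int(T - window + 1L, T)
  per_step <- lapply(idx, function(t)
    coalition_stats(trajectory$theta[t, ], trajectory$f[t, ],
                    trajectory$X[t, ]))
  Cs <- vapply(per_step, `[[`, 0, "C")
  Is <- vapply(per_step, `[[`, 0, "gini_f")
  Ss <- vapply(per_step, `[[`, 0, "sd_X")
  regime <- classify_regime(trajectory, window, f_tol)
  out <- list(
    mean_C = mean(Cs),
    gini_I = if (all(is.na(Is))) NA_real_ else mean(Is, na.rm = TRUE),
    sd_sigma = if (all(is.na(Ss))) NA_real_ else mean(Ss, na.rm = TRUE),
    X_bar = colMeans(trajectory$X[idx, , drop = FALSE]),
    theta_bar = colMeans(trajectory$theta[idx, , drop = FALSE]),
    f_bar = colMeans(trajectory$f[idx, , drop = FALSE]),
    regime = regime,
    # frozen-strategy states need not be best-response equilibria and can
    # show >2 power classes; summaries record NA there instead of failing
    elite_structure = if (regime == "equilibrium")
      tryCatch(classify_elite_structure(
        theta_bar = colMeans(trajectory$theta[idx, , drop = FALSE]),
        f_bar = colMeans(trajectory$f[idx, , drop = FALSE])),
        error = function(e) NA_character_)
      else NA_character_,
    window = window)
  class(out) <- "groupsoc_summary"
  out
}

#' @export
print.groupsoc_summary <- function(x, ...) {
  cat("groupsoc run summary (window =", x$window, "steps)\n")
  cat("  mean C =", signif(x$mean_C, 4),
      " Gini I =", signif(x$gini_I, 4),
      " sigma =", signif(x$sd_sigma, 4), "\n")
  cat("  regime:", x$regime, " elites:", x$elite_structure, "\n")
  invisible(x)
}

#' Classify a run as equilibrium or non-equilibrium
#'
#' A run is at equilibrium over the window iff every individual
#' contribution and every group status is constant and every group's power
#' stays within \code{f_tol} of its window mean. Any strategy flip or
#' residual power drift marks the run non-equilibrium.
#'
#' @param trajectory A \code{groupsoc_trajectory} run with
#'   \code{store_states = TRUE}.
#' @param window Number of final steps examined.
#' @param f_tol Absolute power tolerance (default \code{1e-6}).
#' @return \code{"equilibrium"} or \code{"non-equilibrium"}.
#' @export
classify_regime <- function(trajectory, window = min(1000, trajectory$T),
                            f_tol = 1e-6) {
  T <- trajectory$T
  if (window > T) stop("window longer than trajectory")
  idx <- seq.int(T - window + 1L, T)
  if (is.null(trajectory$x))
    stop("classify_regime needs store_states = TRUE")
  xw <- trajectory$x[idx, , drop = FALSE]
  tw <- trajectory$theta[idx, , drop = FALSE]
  fw <- trajectory$f[idx, , drop = FALSE]
  const_x <- all(xw[rep(1L, nrow(xw)), ] == xw)
  const_t <- all(tw[rep(1L, nrow(tw)), ] == tw)
  fbar <- colMeans(fw)
  f_ok <- max(abs(sweep(fw, 2, fbar))) < f_tol
  if (const_x && const_t && f_ok) "equilibrium" else "non-equilibrium"
}

#' Classify the elite structure of an equilibrium
#'
#' Among cooperating groups, clusters the mean powers with absolute gap
#' tolerance \code{power_tol}: no cooperators gives \code{"none"}, one
#' power class \code{"equal"}, two classes
#' \code{"dominant-subordinate"} (the higher-power class is dominant).
#' More than two classes contradicts the equilibrium taxonomy of the model
#' (cooperating groups split into at most dominant and subordinate) and
#' raises an error, indicating misclassification upstream.
#'
#' @param theta_bar Per-group mean statuses over the window (must be 0/1 at
#'   equilibrium).
#' @param f_bar Per-group mean powers.
#' @param power_tol Gap tolerance separating power classes (default 1e-3).
#' @return One of \code{"none"}, \code{"equal"},
#'   \code{"dominant-subordinate"}.
#' @export
classify_elite_structure <- function(theta_bar, f_bar, power_tol = 1e-3) {
  if (any(theta_bar > 0 & theta_bar < 1))
    stop("elite structure is only defined for equilibrium runs")
  coop <- theta_bar == 1
  if (!any(coop)) return("none")
  fp <- sort(f_bar[coop])
  k <- 1L + sum(diff(fp) > power_tol)
  if (k == 1L) return("equal")
  if (k == 2L) return("dominant-subordinate")
  stop("more than two power classes among cooperating groups: ",
       "violates the equilibrium taxonomy (likely non-equilibrium run)")
}

#' Aggregate ensemble summaries into a tidy table
#'
#' One row per run with all scalar summary statistics; suitable for
#' rbinding across sweep points.
#'
#' @param summaries List of \code{groupsoc_summary} objects (from
#'   \code{\link{run_ensemble}}).
#' @return A data frame with columns \code{run}, \code{seed},
#'   \code{mean_C}, \code{gini_I}, \code{sd_sigma}, \code{regime},
#'   \code{elite_structure}.
#' @export
summaries_to_df <- function(summaries) {
  do.call(rbind, lapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    data.frame(run = i, seed = if (is.null(s$seed)) NA_integer_ else s$seed,
               mean_C = s$mean_C, gini_I = s$gini_I, sd_sigma = s$sd_sigma,
               regime = s$regime, elite_structure = s$elite_structure,
               stringsAsFactors = FALSE)
  }))
}

#' Mean and normal-theory confidence interval across runs
#'
#' @param x Numeric vector (one value per run); \code{NA}s dropped.
#' @param level Ignored beyond the standard 95\% convention; the interval
#'   is \code{mean +/- 1.96 SE}.
#' @return Named vector \code{(mean, lo, hi, n)}.
#' @export
ci_mean <- function(x, level = 0.95) {
  x <- x[!is.na(x)]
  n <- length(x)
  m <- mean(x)
  se <- if (n > 1) stats::sd(x) / sqrt(n) else 0
  c(mean = m, lo = m - 1.96 * se, hi = m + 1.96 * se, n = n)
}
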