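#' Convert normalized per-individual benefits to raw benefit parameters
#'
#' Experimental protocols are often stated in the normalized benefits
#' \code{b1 = B1/n^alpha} (per-individual within-group benefit, equal
#' sizes) and \code{b2 = B2/sum(n_j^alpha)} (per-individual between-group
#' benefit under equal division). This helper inverts that normalization.
#'
#' @param b1 Normalized within-group benefit (or \code{NULL}).
#' @param b2 Normalized between-group benefit (or \code{NULL}).
#' @param n Group sizes vector.
#' @param alpha Rivalrousness exponent.
#' @return List with any of \code{B1}, \code{B2} that were requested.
#' @export
normalized_benefits_to_raw <- function(b1 = NULL, b2 = NULL, n, alpha) {
  out <- list()
  if (!is.null(b1)) {
    if (length(unique(n)) != 1L)
      stop("normalized b1 requires equal group sizes")
    out$B1 <- b1 * n[1]^alpha
  }
  if (!is.null(b2)) out$B2 <- b2 * sum(n^alpha)
  out
}

# Canonical experimental protocols for the model, usable as sweep bases.
.presets <- function() list(
  "equal-groups" = list(G = 8, n = 10, b1 = 20, b2 = 10, alpha = 1, c = 1,
                pi0 = 1, X0 = 5, Z0 = 50, epsilon = 0.1,
                mu1 = 0.25, mu2 = 0.25, lam = Inf),
  "cycling" = list(G = 4, n = 10, b1 = 10, b2 = 26, alpha = 1, c = 1,
                pi0 = 1, X0 = 5, Z0 = 50, epsilon = 0.1,
                mu1 = 0.25, mu2 = 0.25, lam = Inf),
  "unequal-sizes" = list(group_sizes = c(5, 10, 15, 20), B1 = 100, B2 = 500,
                alpha = 1, c = 1, pi0 = 1, X0 = 5, Z0 = 50,
                epsilon = 0.5, mu1 = 0.25, mu2 = 0.25, lam = Inf),
  "focal-group" = list(group_sizes = c(5, 10, 15, 20), B1 = 100, B2 = 1500,
                alpha = 1, c = 1, pi0 = 1, X0 = 5, Z0 = 300,
                epsilon = 0.5, mu1 = 0.25, mu2 = 0.25, lam = Inf)
)

#' Load a study-protocol parameter preset
#'
#' Presets state benefits either normalized (\code{b1}, \code{b2}) or raw
#' (\code{B1}, \code{B2}); normalized values are converted via
#' \code{\link{normalized_benefits_to_raw}}, and overrides may use either
#' form.
#'
#' @param name Preset name: \code{"equal-groups"}, \code{"cycling"}, \code{"unequal-sizes"},
#'   \code{"focal-group"}.
#' @param ... Field overrides (e.g. \code{epsilon = 0.5}, \code{b2 = 4}).
#' @return A \code{groupsoc_params}.
#' @export
preset_params <- function(name, ...) {
  ps <- .presets()
  if (!name %in% names(ps))
    stop("unknown preset '", name, "'; available: ",
         paste(names(ps), collapse = ", "))
  raw <- utils::modifyList(ps[[name]], list(...))
  n <- if (!is.null(raw$group_sizes)) raw$group_sizes
       else rep(raw$n, raw$G)
  conv <- normalized_benefits_to_raw(raw$b1, raw$b2, n, raw$alpha)
  raw$b1 <- NULL; raw$b2 <- NULL
  raw <- utils::modifyList(raw, conv)
  make_params(raw)
}

#' Deterministic micro-society fixtures
#'
#' A catalogue of small, fully specified societies used in tests and
#' examples:
#' \describe{
#'   \item{two-symmetric-groups}{Two identical groups of 4, all
#'     contributing and cooperating, equal power (a Tullock fixed point).}
#'   \item{lone-cooperator}{Three groups of 3; only group 1 cooperates in
#'     the between-group game.}
#'   \item{cycling-small}{The four-group non-equilibrium protocol with a
#'     deterministic half-contributing start.}
#'   \item{olson}{Four groups of sizes 5, 10, 15, 20 with equal initial
#'     power 1/4 (the group-size-paradox setting).}
#'   \item{focal-n}{Groups of sizes 5, 10, 15 plus a focal group whose
#'     size defaults to 20.}
#' }
#'
#' @param name Fixture name.
#' @param ... Parameter overrides forwarded to the underlying preset.
#' @return List with elements \code{params} and \code{state}.
#' @export
make_fixture <- function(name, ...) {
  catalogue <- c("two-symmetric-groups", "lone-cooperator", "cycling-small",
                 "olson", "focal-n")
  if (!name %in% catalogue)
    stop("unknown fixture '", name, "'; catalogue: ",
         paste(catalogue, collapse = ", "))
  half_on <- function(n) unlist(lapply(n, function(k)
    rep(c(1L, 0L), length.out = k)))
  switch(name,
    "two-symmetric-groups" = {
      p <- make_params(utils::modifyList(
        list(G = 2, n = 4, B1 = 100, X0 = 5, B2 = 400, Z0 = 50, c = 1,
             pi0 = 1, alpha = 1, epsilon = 0.2, mu1 = 0.25, mu2 = 0.25,
             lam = Inf), list(...)))
      list(params = p,
           state = make_state(rep(1L, 8), c(1L, 1L), c(0.5, 0.5), p))
    },
    "lone-cooperator" = {
      p <- make_params(utils::modifyList(
        list(G = 3, n = 3, B1 = 60, X0 = 5, B2 = 300, Z0 = 50, c = 1,
             pi0 = 1, alpha = 1, epsilon = 0.2, mu1 = 0.25, mu2 = 0.25,
             lam = Inf), list(...)))
      list(params = p,
           state = make_state(c(1L, 1L, 0L, 1L, 0L, 0L, 1L, 1L, 1L),
                              c(1L, 0L, 0L), c(0.5, 0.3, 0.2), p))
    },
    "cycling-small" = {
      p <- preset_params("cycling", ...)
      x <- half_on(p$n)
      theta <- rep(1L, p$G)
      list(params = p, state = make_state(x, theta, rep(0.25, 4), p))
    },
    "olson" = {
      p <- preset_params("unequal-sizes", ...)
      x <- half_on(p$n)
      list(params = p,
           state = make_state(x, rep(0L, 4), rep(0.25, 4), p))
    },
    "focal-n" = {
      p <- preset_params("focal-group", ...)
      x <- half_on(p$n)
      list(params = p,
           state = make_state(x, rep(0L, 4), rep(0.25, 4), p))
    })
}

#' Run a full-factorial parameter sweep
#'
#' Runs an ensemble at every value of a swept parameter and collects one
#' tidy row per (value, run). When \code{out_csv} exists its completed
#' sweep values are skipped and the new rows appended, so interrupted
#' sweeps resume instead of recomputing.
#'
#' @param base A \code{groupsoc_params} supplying all fixed fields.
#' @param axis Name of the swept \code{\link{make_params}} field.
#' @param values Values to sweep (validated before any run starts).
#' @param T,window,n_runs,base_seed Protocol controls.
#' @param out_csv Optional path for the tidy per-run CSV.
#' @return Data frame: one row per (value, run) with the summary scalars.
#' @export
run_sweep <- function(base, axis, values, T = 1000, window = 250,
                      n_runs = 10, base_seed = 1, out_csv = NULL) {
  stopifnot(inherits(base, "groupsoc_params"), length(values) > 0)
  raw0 <- base[c("G", "B1", "X0", "B2", "Z0", "c", "pi0", "alpha",
                 "epsilon", "mu1", "mu2", "lam")]
  raw0$group_sizes <- base$n
  if (!axis %in% c(names(raw0)))
    stop("swept parameter '", axis, "' is not a model field")
  # validate every swept value up front
  for (v in values) {
    raw <- raw0; raw[[axis]] <- v
    make_params(raw)
  }
  done <- NULL
  if (!is.null(out_csv) && file.exists(out_csv)) {
    done <- utils::read.csv(out_csv)
    values <- setdiff(values, unique(done$value))
  }
  rows <- lapply(values, function(v) {
    raw <- raw0; raw[[axis]] <- v
    p <- make_params(raw)
    sm <- run_ensemble(p, T = T, n_runs = n_runs,
                       base_seed = base_seed + match(v, values),
                       window = window)
    df <- summaries_to_df(sm)
    cbind(axis = axis, value = v, df)
  })
  out <- do.call(rbind, c(list(done), rows))
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Aggregate sweep rows into means and confidence intervals
#'
#' @param sweep_df Output of \code{\link{run_sweep}}.
#' @return One row per swept value with mean and 95\% CI of \code{mean_C},
#'   \code{gini_I} and \code{sd_sigma} across runs.
#' @export
aggregate_sweep <- function(sweep_df) {
  do.call(rbind, lapply(split(sweep_df, sweep_df$value), function(d) {
    cc <- ci_mean(d$mean_C); gg <- ci_mean(d$gini_I); ss <- ci_mean(d$sd_sigma)
    data.frame(value = d$value[1], n_runs = nrow(d),
               C_mean = cc["mean"], C_lo = cc["lo"], C_hi = cc["hi"],
               I_mean = gg["mean"], I_lo = gg["lo"], I_hi = gg["hi"],
               sigma_mean = ss["mean"], sigma_lo = ss["lo"],
               sigma_hi = ss["hi"], row.names = NULL)
  }))
}

#' Single-run command-line driver
#'
#' Thin wrapper used by the \code{exec/groupsoc} script: runs one
#' simulation from a JSON parameter file and writes the trajectory CSV and
#' the window-summary JSON next to it.
#'
#' @param config_path JSON file of model parameters
#'   (\code{\link{params_from_json}}).
#' @param out_dir Output directory (created if needed).
#' @param T,window,seed Protocol controls.
#' @return Invisibly, the \code{groupsoc_summary}.
#' @export
cli_run <- function(config_path, out_dir, T = 4000, window = 1000,
                    seed = 1) {
  if (T < 1) stop("usage error: T must be >= 1")
  p <- params_from_json(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tr <- run_society(p, T = T, seed = seed)
  write_trajectory_csv(tr, file.path(out_dir, "trajectory.csv"))
  s <- summarize_window(tr, min(window, T))
  jsonlite::write_json(
    list(seed = seed, T = T, window = s$window, mean_C = s$mean_C,
         gini_I = s$gini_I, sd_sigma = s$sd_sigma, regime = s$regime,
         elite_structure = s$elite_structure,
         X_bar = s$X_bar, theta_bar = s$theta_bar, f_bar = s$f_bar),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(s)
}

#' Sweep command-line driver
#'
#' Runs \code{\link{run_sweep}} from a JSON configuration holding
#' \code{base} (model parameters), \code{axis}, \code{values} and optional
#' protocol fields, writing the tidy and aggregated CSVs to
#' \code{out_dir}.
#'
#' @param config_path JSON sweep configuration.
#' @param out_dir Output directory.
#' @return Invisibly, the aggregated data frame.
#' @export
cli_sweep <- function(config_path, out_dir) {
  cfg <- jsonlite::fromJSON(config_path, simplifyVector = TRUE)
  for (f in c("base", "axis", "values"))
    if (is.null(cfg[[f]])) stop("usage error: sweep config missing '", f, "'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- make_params(as.list(cfg$base))
  df <- run_sweep(base, cfg$axis, cfg$values,
                  T = if (is.null(cfg$T)) 1000 else cfg$T,
                  window = if (is.null(cfg$window)) 250 else cfg$window,
                  n_runs = if (is.null(cfg$n_runs)) 10 else cfg$n_runs,
                  base_seed = if (is.null(cfg$base_seed)) 1 else cfg$base_seed,
                  out_csv = file.path(out_dir, "sweep_runs.csv"))
  ag <- aggregate_sweep(df)
  utils::write.csv(ag, file.path(out_dir, "sweep_aggregate.csv"),
                   row.names = FALSE)
  invisible(ag)
}
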