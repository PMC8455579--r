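#' Construct and validate a model parameterization
#'
#' Builds the full, time-independent parameter set of the group-structured
#' society model: \code{G} groups of sizes \code{n_j}, a saturating
#' within-group public goods game (maximum benefit \code{B1}, half-effort
#' \code{X0}, contribution cost \code{c}), a between-group club goods game
#' (maximum benefit \code{B2}, half-effort \code{Z0}), per-capita division
#' with rivalrousness exponent \code{alpha}, a Tullock power contest with
#' incumbency strength \code{epsilon}, and logit (quantal-response) strategy
#' revision with probabilities \code{mu1} (individuals), \code{mu2} (groups)
#' and precision \code{lam} (\code{Inf} = exact best response).
#'
#' Derived quantities are attached on construction:
#' \itemize{
#'   \item \code{R1 = B1/(c*X0)}: benefit-to-cost ratio of the within-group
#'     game at half-effort;
#'   \item \code{R2 = B2/Z0}: benefit-to-cost ratio of the between-group game;
#'   \item \code{omega = c*X0/Z0}: ratio of group costs in the two games;
#'   \item \code{Pi0 = n_j*pi0}: per-group baseline endowment;
#'   \item \code{b1 = B1/n_j^alpha} and \code{b2 = B2/sum(n_j^alpha)}:
#'     normalized per-individual benefits.
#' }
#'
#' @param raw Named list of parameter values. Required fields: \code{G} or
#'   \code{group_sizes} (a scalar \code{n} with \code{G} is broadcast),
#'   \code{B1}, \code{X0}, \code{B2}, \code{Z0}, \code{c}, \code{pi0},
#'   \code{alpha}, \code{epsilon}, \code{mu1}, \code{mu2}, \code{lam}.
#'   \code{lam} may be the string \code{"Inf"} (e.g. from JSON). Unknown
#'   fields are an error.
#' @return An object of class \code{groupsoc_params}.
#' @examples
#' p <- make_params(list(G = 8, n = 10, B1 = 200, X0 = 5, B2 = 1500,
#'                       Z0 = 50, c = 1, pi0 = 1, alpha = 1, epsilon = 0.2,
#'                       mu1 = 0.25, mu2 = 0.25, lam = Inf))
#' p$R1  # 40
#' @export
make_params <- function(raw) {
  stopifnot(is.list(raw))
  known <- c("G", "n", "group_sizes", "B1", "X0", "B2", "Z0", "c", "pi0",
             "alpha", "epsilon", "mu1", "mu2", "lam")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))

  if (!is.null(raw$group_sizes)) {
    n <- as.integer(raw$group_sizes)
    G <- if (!is.null(raw$G)) as.integer(raw$G) else length(n)
    if (length(n) == 1L && G > 1L) n <- rep(n, G)
    if (length(n) != G)
      stop("group_sizes must have length G (", G, "), got ", length(n))
  } else if (!is.null(raw$n)) {
    if (is.null(raw$G)) stop("scalar n requires G")
    G <- as.integer(raw$G)
    n <- as.integer(raw$n)
    if (length(n) == 1L) n <- rep(n, G)
    if (length(n) != G)
      stop("n must be scalar or length G (", G, "), got ", length(n))
  } else stop("missing required field: group_sizes (or n with G)")

  need <- c("B1", "X0", "B2", "Z0", "c", "pi0", "alpha", "epsilon",
            "mu1", "mu2", "lam")
  miss <- need[!need %in% names(raw)]
  if (length(miss) > 0)
    stop("missing required field(s): ", paste(miss, collapse = ", "))

  lam <- raw$lam
  if (is.character(lam)) lam <- as.numeric(lam)  # JSON "Inf"
  chk <- function(val, field, lo, hi = Inf, strict_lo = TRUE) {
    if (!is.numeric(val) || length(val) != 1L || is.na(val))
      stop("field ", field, " must be a single number")
    ok_lo <- if (strict_lo) val > lo else val >= lo
    if (!ok_lo || val > hi)
      stop("field ", field, " out of bounds: must be in ",
           if (strict_lo) "(" else "[", lo, ", ", hi, "], got ", val)
    as.numeric(val)
  }
  if (G < 1L) stop("field G out of bounds: must be >= 1, got ", G)
  if (any(n < 1L)) stop("field group_sizes out of bounds: all n_j must be >= 1")

  B1 <- chk(raw$B1, "B1", 0)
  X0 <- chk(raw$X0, "X0", 0)
  B2 <- chk(raw$B2, "B2", 0, strict_lo = FALSE)
  Z0 <- chk(raw$Z0, "Z0", 0)
  pi0 <- chk(raw$pi0, "pi0", 0)
  cc <- chk(raw$c, "c", 0)
  if (cc > pi0) stop("field c out of bounds: requires 0 < c <= pi0")
  alpha <- chk(raw$alpha, "alpha", 0, 1, strict_lo = FALSE)
  epsilon <- chk(raw$epsilon, "epsilon", 0, 1, strict_lo = FALSE)
  mu1 <- chk(raw$mu1, "mu1", 0, 1, strict_lo = FALSE)
  mu2 <- chk(raw$mu2, "mu2", 0, 1, strict_lo = FALSE)
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0)
    stop("field lam out of bounds: must be >= 0 (Inf allowed)")

  g_of <- rep.int(seq_len(G), n)   # group index of each individual
  p <- list(
    G = G, n = n, B1 = B1, X0 = X0, B2 = B2, Z0 = Z0,
    c = cc, pi0 = pi0, alpha = alpha, epsilon = epsilon,
    mu1 = mu1, mu2 = mu2, lam = lam,
    # derived
    R1 = B1 / (cc * X0), R2 = B2 / Z0, omega = cc * X0 / Z0,
    Pi0 = n * pi0, n_alpha = n^alpha,
    b1 = B1 / n^alpha, b2 = B2 / sum(n^alpha),
    N = sum(n), g_of = g_of
  )
  class(p) <- "groupsoc_params"
  p
}

#' Load model parameters from a JSON file
#'
#' Keys must exactly match \code{\link{make_params}} field names; unknown
#' keys raise an error so sweep-configuration typos are caught early.
#'
#' @param path Path to a JSON document.
#' @return A \code{groupsoc_params} object.
#' @export
params_from_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  make_params(as.list(raw))
}

#' @export
print.groupsoc_params <- function(x, ...) {
  cat("Group-structured society parameters\n")
  cat("  G =", x$G, " sizes:", paste(x$n, collapse = ","), "\n")
  cat("  within-group PGG:  B1 =", x$B1, " X0 =", x$X0, " c =", x$c,
      " pi0 =", x$pi0, "\n")
  cat("  between-group CGG: B2 =", x$B2, " Z0 =", x$Z0, "\n")
  cat("  alpha =", x$alpha, " epsilon =", x$epsilon, "\n")
  cat("  revision: mu1 =", x$mu1, " mu2 =", x$mu2, " lambda =", x$lam, "\n")
  cat("  derived: R1 =", x$R1, " R2 =", x$R2, " omega =", x$omega, "\n")
  invisible(x)
}

#' Construct a society state
#'
#' A state holds each individual's contribution decision \code{x} (binary,
#' stored as a flat vector in group order), each group's cooperation status
#' \code{theta} (binary, \code{theta = 1} means membership in the elite
#' coalition) and the power vector \code{f} (nonnegative, summing to one).
#'
#' @param x Integer vector of 0/1 contributions, length \code{sum(n_j)}.
#' @param theta Integer vector of 0/1 statuses, length \code{G}.
#' @param f Numeric power vector, length \code{G}.
#' @param params A \code{groupsoc_params} object.
#' @return An object of class \code{groupsoc_state}.
#' @export
make_state <- function(x, theta, f, params) {
  s <- structure(list(x = as.integer(x), theta = as.integer(theta),
                      f = as.numeric(f)), class = "groupsoc_state")
  v <- validate_state(s, params)
  if (length(v) > 0) stop("invalid state: ", paste(v, collapse = "; "))
  s
}

#' Per-group contribution totals
#'
#' @param x Flat 0/1 contribution vector.
#' @param params A \code{groupsoc_params} object.
#' @return Numeric vector of group efforts \code{X_j}.
#' @export
group_efforts <- function(x, params) {
  as.vector(rowsum(as.numeric(x), params$g_of, reorder = TRUE))
}

#' Validate a society state against its parameterization
#'
#' Checks the structural invariants: shapes; \code{x}, \code{theta} binary;
#' \code{0 <= f_j <= 1} with \code{sum(f) = 1} to absolute tolerance 1e-12;
#' and the elite-membership rule that a group with zero collective effort
#' (\code{X_j = 0}) can never cooperate in the between-group game
#' (\code{theta_j} must be 0). States are never silently repaired.
#'
#' @param state A \code{groupsoc_state}.
#' @param params A \code{groupsoc_params}.
#' @return Character vector of violations; empty if the state is valid.
#' @export
validate_state <- function(state, params) {
  if (length(state$x) != params$N)
    stop("shape mismatch: x has length ", length(state$x),
         ", expected ", params$N)
  if (length(state$theta) != params$G || length(state$f) != params$G)
    stop("shape mismatch: theta/f must have length G = ", params$G)
  out <- character(0)
  if (!all(state$x %in% c(0L, 1L))) out <- c(out, "x not binary")
  if (!all(state$theta %in% c(0L, 1L))) out <- c(out, "theta not binary")
  if (any(state$f < 0 | state$f > 1))
    out <- c(out, paste0("power out of [0,1] at j=",
                         which(state$f < 0 | state$f > 1)[1]))
  if (abs(sum(state$f) - 1) > 1e-12)
    out <- c(out, "power sum != 1")
  X <- group_efforts(state$x, params)
  bad <- which(X == 0 & state$theta == 1L)
  if (length(bad) > 0)
    out <- c(out, paste0("elite rule violated at j=", bad))
  out
}
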