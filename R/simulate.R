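# Simulation of relaxation experiments: numerical integration of the full
# mass-action rate equations (via the reduced two-variable system) and
# additive Gaussian measurement noise.

# Evaluate expr with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Default mixing initial condition: all ligand free, no complex, unbound
# protein conformers pre-equilibrated (IF: all protein in P1; CS: P1:P2 =
# k_r:k_e), as for a protein stock at conformational equilibrium.
default_initial <- function(scheme, P0, L0) {
  switch(scheme$mechanism,
    IF = c(P1 = P0, L = L0, P1L = 0, P2L = 0),
    CS = {
      we <- scheme$k_e / (scheme$k_e + scheme$k_r)
      c(P1 = (1 - we) * P0, P2 = we * P0, L = L0, P2L = 0)
    },
    elementary = c(P = P0, L = L0, PL = 0))
}

reduce_state <- function(scheme, state) {
  switch(scheme$mechanism,
    IF = c(state[["L"]], state[["P2L"]]),
    CS = c(state[["P2"]], state[["L"]]),
    elementary = state[["PL"]])
}

# Default time grid: logarithmic from t_min to cover the slow tail
# (10 relaxation times of the predicted dominant rate).  1000 points: the
# relaxation of the second-order schemes carries weak harmonic overtones of
# the dominant rate, and resolving them against the measurement noise is
# what keeps the extracted dominant rate unbiased.
default_time_grid <- function(scheme, P0, L0, n = 1000L, t_min = 1e-4) {
  kobs <- relaxation_rates(scheme, P0, L0)$kobs_per_s
  exp(seq(log(t_min), log(10 / kobs), length.out = n))
}

#' Simulate a noiseless relaxation curve
#'
#' Integrates the reduced mass-action rate equations with a stiff solver
#' (deSolve, lsoda) and records the total bound-complex concentration
#' (P1L + P2L for induced fit, P2L for conformational selection, PL for the
#' elementary scheme), which by ligand conservation equals L0 - L(t).
#'
#' @param scheme a \code{\link{binding_scheme}}.
#' @param P0,L0 total concentrations (uM).
#' @param times time grid (s); default: 400 logarithmically spaced points
#'   from 1e-4 s to 10 / kobs.
#' @param initial optional named full species state at t = 0 (uM).  Must be
#'   consistent with the conservation laws for \code{P0}, \code{L0}.
#'   Default: free ligand, no complex, unbound conformers pre-equilibrated.
#' @param rtol,atol integrator tolerances.
#' @return An object of class \code{"relaxation_curve"}: list with
#'   \code{times} (s), \code{observed} (bound complex, uM) and \code{meta}
#'   (mechanism, rates, conditions, noise amplitude, seed).
#' @examples
#' cs <- binding_scheme("CS", 10, 100, 100, 1)
#' curve <- simulate_relaxation(cs, P0 = 0.5, L0 = 2)
#' @export
simulate_relaxation <- function(scheme, P0, L0, times = NULL, initial = NULL,
                                rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(scheme, "binding_scheme"))
  check_conditions(P0, L0)
  if (is.null(times)) times <- default_time_grid(scheme, P0, L0)
  if (is.null(initial)) initial <- default_initial(scheme, P0, L0)
  tol <- 1e-8 * max(P0, L0, 1)
  if (any(initial < -tol) ||
      abs(sum(initial[grep("^P", names(initial))]) - P0) > tol ||
      abs(sum(initial[grep("L", names(initial))]) - L0) > tol)
    stop("invalid input: initial state violates the conservation laws",
         call. = FALSE)
  y0 <- reduce_state(scheme, initial)
  rhs <- function(t, y, parms) list(reduced_rhs(scheme, P0, L0, y))
  tgrid <- times
  prepend <- tgrid[1] > 0
  if (prepend) tgrid <- c(0, tgrid)
  sol <- deSolve::ode(y = y0, times = tgrid, func = rhs, parms = NULL,
                      rtol = rtol, atol = atol)
  if (prepend) sol <- sol[-1, , drop = FALSE]
  L <- switch(scheme$mechanism, IF = sol[, 2], CS = sol[, 3],
              elementary = L0 - sol[, 2])
  structure(
    list(times = times, observed = L0 - L,
         meta = list(mechanism = scheme$mechanism, k_e = scheme$k_e,
                     k_r = scheme$k_r, k_plus = scheme$k_plus,
                     k_minus = scheme$k_minus, P0 = P0, L0 = L0,
                     noise_amplitude = 0, seed = NA_integer_,
                     initial = as.list(initial))),
    class = "relaxation_curve")
}

#' @export
print.relaxation_curve <- function(x, ...) {
  m <- x$meta
  cat(sprintf("Relaxation curve (%s): P0 = %g uM, L0 = %g uM, %d points\n",
              m$mechanism, m$P0, m$L0, length(x$times)))
  cat(sprintf("  t in [%g, %g] s; noise sd %g uM\n",
              min(x$times), max(x$times), m$noise_amplitude))
  invisible(x)
}

#' @export
plot.relaxation_curve <- function(x, ...) {
  graphics::plot(x$times, x$observed, log = "x", xlab = "time (s)",
                 ylab = "bound complex (uM)", pch = 20, cex = 0.4, ...)
  invisible(x)
}

#' Add Gaussian measurement noise to a relaxation curve
#'
#' Adds iid Gaussian noise of the given standard deviation to the observed
#' bound-complex concentration.  No truncation is applied (negative observed
#' values are allowed).  The caller's RNG state is left untouched.
#'
#' @param curve a \code{"relaxation_curve"}.
#' @param amplitude noise standard deviation (uM), >= 0.
#' @param seed integer seed; recorded in \code{meta} so the curve is
#'   reproducible.
#' @return The noisy \code{"relaxation_curve"}.
#' @export
add_noise <- function(curve, amplitude, seed = 1L) {
  stopifnot(inherits(curve, "relaxation_curve"))
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0)
    stop("invalid parameter: 'amplitude' must be a single number >= 0",
         call. = FALSE)
  if (amplitude == 0) return(curve)
  eps <- with_local_seed(seed, stats::rnorm(length(curve$observed),
                                            sd = amplitude))
  curve$observed <- curve$observed + eps
  curve$meta$noise_amplitude <- amplitude
  curve$meta$seed <- as.integer(seed)
  curve
}

fixture_designs <- list(
  fig2 = list(mechanism = "CS", k_e = 10, k_r = 100, k_plus = 100,
              k_minus = 1, P0 = c(0.5, 1.0, 1.5), noise = 0.002),
  fig3 = list(mechanism = "IF", k_e = 1, k_r = 10, k_plus = 100,
              k_minus = 100, P0 = c(1, 2, 3), noise = 0.004))

#' Generate the packaged synthetic relaxation experiments
#'
#' Reproduces the package's two reference numerical experiments: noisy
#' relaxation curves for a conformational-selection process (\code{"fig2"}:
#' k_e = 10, k_r = 100, k_+ = 100, k_- = 1; P0 = 0.5, 1.0, 1.5 uM; noise sd
#' 0.002 uM) and for an induced-fit process (\code{"fig3"}: k_+ = 100,
#' k_- = 100, k_e = 1, k_r = 10; P0 = 1, 2, 3 uM; noise sd 0.004 uM), each
#' on a logarithmic ligand grid spanning 0.1-10 uM.
#'
#' @param figure \code{"fig2"} or \code{"fig3"}.
#' @param seed base integer seed; each curve uses a distinct seed derived
#'   from it (recorded in the curve's \code{meta}).
#' @param P0 optional subset/override of total protein concentrations (uM).
#' @param n_L0 number of ligand concentrations (log-spaced in
#'   \code{L0_range}); default 16.
#' @param L0_range range of total ligand concentrations (uM).
#' @return A list of \code{"relaxation_curve"} objects (one per (P0, L0)
#'   pair), with attributes \code{scheme} and \code{design}.
#' @export
make_fixture <- function(figure = c("fig2", "fig3"), seed = 1L, P0 = NULL,
                         n_L0 = 16L, L0_range = c(0.1, 10)) {
  figure <- match.arg(figure)
  des <- fixture_designs[[figure]]
  if (is.null(P0)) P0 <- des$P0
  scheme <- binding_scheme(des$mechanism, k_e = des$k_e, k_r = des$k_r,
                           k_plus = des$k_plus, k_minus = des$k_minus)
  L0 <- exp(seq(log(L0_range[1]), log(L0_range[2]), length.out = n_L0))
  grid <- expand.grid(L0 = L0, P0 = P0)[, c("P0", "L0")]
  curves <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cv <- simulate_relaxation(scheme, grid$P0[i], grid$L0[i])
    curves[[i]] <- add_noise(cv, des$noise, seed = seed + i - 1L)
  }
  structure(curves, scheme = scheme,
            design = list(figure = figure, P0 = P0, L0 = L0,
                          noise = des$noise, seed = seed))
}

#' Write / read relaxation curves as delimited text
#'
#' \code{write_relaxation_curve} writes tab-separated columns \code{time_s},
#' \code{bound_uM} plus a JSON sidecar \code{<path>.json} holding the curve
#' metadata (mechanism, rates, conditions, noise, seed), from which the
#' curve can be regenerated.  \code{read_relaxation_curve} reads both back.
#'
#' @param curve a \code{"relaxation_curve"}.
#' @param path file path for the delimited text.
#' @return \code{write_relaxation_curve}: \code{path}, invisibly;
#'   \code{read_relaxation_curve}: a \code{"relaxation_curve"}.
#' @export
write_relaxation_curve <- function(curve, path) {
  stopifnot(inherits(curve, "relaxation_curve"))
  utils::write.table(
    data.frame(time_s = curve$times, bound_uM = curve$observed),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(jsonlite::toJSON(curve$meta, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_relaxation_curve
#' @export
read_relaxation_curve <- function(path) {
  tab <- utils::read.delim(path)
  if (!all(c("time_s", "bound_uM") %in% names(tab)))
    stop("curve file must have columns time_s and bound_uM", call. = FALSE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::fromJSON(meta_path) else
    list(mechanism = NA_character_, P0 = NA_real_, L0 = NA_real_,
         noise_amplitude = NA_real_, seed = NA_integer_)
  structure(list(times = tab$time_s, observed = tab$bound_uM, meta = meta),
            class = "relaxation_curve")
}
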