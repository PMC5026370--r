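# Closed-form relaxation rates.  The internal workhorses are parameterized by
# (k_e, k_r, k_minus, Kd) with the bimolecular rate derived from Kd, because
# that is the parameterization used when fitting k_obs data with Kd fixed.
# They are fully vectorized over all arguments (recycling), which the
# Monte-Carlo marginal likelihood relies on.

kobs_if_closed <- function(k_e, k_r, k_minus, Kd, P0, L0, both = FALSE) {
  k_plus <- k_minus * k_e / (Kd * (k_e + k_r))
  delta <- delta_term(P0, L0, Kd)
  gamma <- -k_e - k_r + k_minus + k_plus * (delta - Kd)
  root <- sqrt(gamma^2 + 4 * k_minus * k_r)
  k2 <- k_e + k_r + gamma / 2 + root / 2
  # dominant (small) root via det(-J)/k2: the direct difference form
  # k_e + k_r + gamma/2 - root/2 cancels catastrophically when kobs << k2;
  # det(-J) = k_e k_- + (k_e + k_r) k_+ (delta - Kd) is a sum of positive
  # terms (delta > Kd always), so this form is exact and stable.
  kobs <- (k_e * k_minus + (k_e + k_r) * k_plus * (delta - Kd)) / k2
  if (!both) return(kobs)
  list(kobs = kobs, k2 = k2, gamma = gamma, delta = delta)
}

kobs_cs_closed <- function(k_e, k_r, k_minus, Kd, P0, L0, both = FALSE) {
  delta <- delta_term(P0, L0, Kd)
  # alpha = trace(-J) - 2 k_e, beta = trace^2 - 4 det - alpha^2, written via
  # the equilibrium concentrations L_eq and P2_eq = k_-(P0-L0-Kd+delta)/(2 Kd k_+)
  k_plus <- k_minus * (k_e + k_r) / (Kd * k_e)
  L_eq <- ligand_eq(P0, L0, Kd)
  kp_P2eq <- k_minus * (delta + P0 - L0 - Kd) / (2 * Kd)
  alpha <- k_r - k_e + k_minus + k_plus * L_eq + kp_P2eq
  beta <- 4 * k_r * (k_e - k_minus - kp_P2eq)
  root <- sqrt(pmax(alpha^2 + beta, 0))
  k2 <- k_e + alpha / 2 + root / 2
  # stable small root: det(-J) = (k_e + k_r)(k_- + k_+ [P2]_eq) +
  # k_e k_+ [L]_eq (all positive), divided by the large root.
  kobs <- ((k_e + k_r) * (k_minus + kp_P2eq) + k_e * k_plus * L_eq) / k2
  if (!both) return(kobs)
  list(kobs = kobs, k2 = k2, alpha = alpha, beta = beta, delta = delta)
}

kobs_elementary_closed <- function(k_minus, Kd, P0, L0, both = FALSE) {
  k_plus <- k_minus / Kd
  kobs <- k_plus * delta_term(P0, L0, Kd)
  if (!both) return(kobs)
  list(kobs = kobs, k2 = rep(NA_real_, length(kobs)),
       delta = delta_term(P0, L0, Kd))
}

# Dominant relaxation rate as a function of mechanism and the fitting
# parameterization (Kd fixed, k_plus implied).  Used by the inference module.
kobs_model <- function(mechanism, k_e, k_r, k_minus, Kd, P0, L0) {
  switch(mechanism,
    IF = kobs_if_closed(k_e, k_r, k_minus, Kd, P0, L0),
    CS = kobs_cs_closed(k_e, k_r, k_minus, Kd, P0, L0),
    elementary = kobs_elementary_closed(k_minus, Kd, P0, L0))
}

#' Jacobian of the reduced rate equations at equilibrium
#'
#' The 2x2 Jacobian of the reduced mass-action vector field, evaluated at the
#' equilibrium state (for the elementary scheme a 1x1 matrix).  The two
#' near-equilibrium relaxation rates are the eigenvalues of minus this
#' matrix.
#'
#' @param scheme a \code{\link{binding_scheme}}.
#' @param P0,L0 total concentrations (uM).
#' @return A square numeric matrix (units 1/s).
#' @export
jacobian_at_equilibrium <- function(scheme, P0, L0) {
  stopifnot(inherits(scheme, "binding_scheme"))
  check_conditions(P0, L0)
  eq <- equilibrium_state(scheme, P0, L0)
  with(scheme, switch(scheme$mechanism,
    IF = matrix(c(k_plus * (L0 - 2 * eq$L_eq - P0) - k_minus, -k_minus,
                  -k_r, -k_e - k_r),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("L", "P2L"), c("L", "P2L"))),
    CS = matrix(c(-(k_r + k_e + k_plus * eq$L_eq),
                  -(-k_e + k_minus + k_plus * eq$P2),
                  -k_plus * eq$L_eq, -(k_minus + k_plus * eq$P2)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("P2", "L"), c("P2", "L"))),
    elementary = matrix(-k_plus * (eq$P + eq$L) - k_minus,
                        dimnames = list("PL", "PL"))))
}

#' Near-equilibrium relaxation rates
#'
#' Closed-form relaxation spectrum of a binding scheme at given totals: the
#' dominant (smallest) rate \code{kobs} that governs the final approach to
#' equilibrium, the second rate \code{k2}, and the diagnostic intermediates
#' (\code{gamma}, \code{delta} for induced fit; \code{alpha}, \code{beta},
#' \code{delta} for conformational selection).  The two rates are the
#' eigenvalues of minus the equilibrium Jacobian; the closed forms hold for
#' all total concentrations, not only in the pseudo-first-order regime.
#' Vectorized over \code{L0}.
#'
#' @param scheme a \code{\link{binding_scheme}}.
#' @param P0 total protein concentration (uM).
#' @param L0 total ligand concentration(s) (uM).
#' @return A data.frame with one row per \code{L0} and columns \code{P0_uM},
#'   \code{L0_uM}, \code{kobs_per_s}, \code{k2_per_s} plus the mechanism's
#'   intermediates.
#' @examples
#' cs <- binding_scheme("CS", 10, 100, 100, 1)
#' relaxation_rates(cs, P0 = 0.5, L0 = c(0.1, 1, 10))
#' @export
relaxation_rates <- function(scheme, P0, L0) {
  stopifnot(inherits(scheme, "binding_scheme"))
  check_conditions(P0, L0)
  Kd <- scheme$Kd
  sp <- switch(scheme$mechanism,
    IF = kobs_if_closed(scheme$k_e, scheme$k_r, scheme$k_minus, Kd, P0, L0,
                        both = TRUE),
    CS = kobs_cs_closed(scheme$k_e, scheme$k_r, scheme$k_minus, Kd, P0, L0,
                        both = TRUE),
    elementary = kobs_elementary_closed(scheme$k_minus, Kd, P0, L0,
                                        both = TRUE))
  out <- data.frame(P0_uM = P0, L0_uM = L0,
                    kobs_per_s = sp$kobs, k2_per_s = sp$k2)
  for (nm in setdiff(names(sp), c("kobs", "k2"))) out[[nm]] <- sp[[nm]]
  out
}

#' Zero-ligand limit of the dominant relaxation rate (conformational selection)
#'
#' As L0 -> 0 the dominant rate of conformational-selection binding tends to
#' k_e + k_r for protein concentrations above the threshold
#' Kd (k_e + k_r - k_-)/k_-, and to k_-(P0 + Kd)/Kd below it; the two
#' branches agree at the threshold.
#'
#' @param scheme a \code{\link{binding_scheme}} with mechanism \code{"CS"}.
#' @param P0 total protein concentration (uM).
#' @return Limiting rate (1/s).
#' @export
kobs_zero_ligand_limit <- function(scheme, P0) {
  stopifnot(inherits(scheme, "binding_scheme"))
  if (scheme$mechanism != "CS")
    stop("unsupported operation: zero-ligand limit formula applies to the ",
         "conformational-selection scheme only", call. = FALSE)
  check_conditions(P0, 0)
  Kd <- scheme$Kd
  thr <- Kd * (scheme$k_e + scheme$k_r - scheme$k_minus) / scheme$k_minus
  ifelse(P0 > thr, scheme$k_e + scheme$k_r,
         scheme$k_minus * (P0 + Kd) / Kd)
}

#' Location of the minimum of kobs(L0)
#'
#' Induced fit: the dominant rate is exactly symmetric in L0 about
#' \code{P0 - Kd} and minimal there, provided \code{P0 > Kd}; otherwise no
#' minimum exists.  Conformational selection: for \code{k_e > k_minus} a
#' minimum exists at sufficiently large P0, located approximately at
#' \code{(k_e + k_minus)/(k_e - k_minus) * P0 - Kd} (a quasi-steady-state
#' result, accurate for \code{k_r >> k_e}); for \code{k_e < k_minus} the rate
#' decreases monotonically and no minimum exists.
#'
#' @param scheme a \code{\link{binding_scheme}} (\code{"IF"} or \code{"CS"}).
#' @param P0 total protein concentration (uM).
#' @param numeric_refine for CS, also minimize the exact closed form
#'   numerically (always reported when the formula is flagged approximate).
#' @return A list with \code{exists} (logical), \code{L0_min} (uM or NA),
#'   and for CS \code{L0_min_formula}, \code{approximate} (TRUE when
#'   \code{k_r < 10 k_e}, where the formula is only indicative) and
#'   \code{L0_min_numeric}.
#' @export
kobs_minimum_location <- function(scheme, P0, numeric_refine = TRUE) {
  stopifnot(inherits(scheme, "binding_scheme"))
  check_conditions(P0, 0)
  Kd <- scheme$Kd
  if (scheme$mechanism == "IF") {
    if (P0 > Kd)
      return(list(exists = TRUE, L0_min = P0 - Kd))
    return(list(exists = FALSE, L0_min = NA_real_))
  }
  if (scheme$mechanism != "CS")
    stop("unsupported operation: minimum-location formulas exist for the ",
         "IF and CS schemes only", call. = FALSE)
  k_e <- scheme$k_e; k_m <- scheme$k_minus
  if (k_e <= k_m)
    return(list(exists = FALSE, L0_min = NA_real_))
  L0f <- (k_e + k_m) / (k_e - k_m) * P0 - Kd
  if (L0f <= 0)
    return(list(exists = FALSE, L0_min = NA_real_))
  approx_flag <- scheme$k_r < 10 * k_e
  out <- list(exists = TRUE, L0_min = L0f, L0_min_formula = L0f,
              approximate = approx_flag)
  if (numeric_refine || approx_flag) {
    f <- function(l) relaxation_rates(scheme, P0, l)$kobs_per_s
    opt <- stats::optimize(f, interval = c(1e-6, 10 * (L0f + P0 + Kd)))
    out$L0_min_numeric <- opt$minimum
    if (approx_flag) out$L0_min <- opt$minimum
  }
  out
}

#' Quasi-steady-state dominant rate of conformational-selection binding
#'
#' Treating the unbound excited conformer P2 as stationary reduces the CS
#' scheme to one equation in the free ligand; linearizing it about
#' equilibrium gives \code{kobs_qssa = k_- k_e delta / (k_e Kd + k_- L_eq)}.
#' Its derivative in L0 vanishes exactly at the approximate minimum location
#' returned by \code{\link{kobs_minimum_location}}.  A good approximation of
#' the exact dominant rate when transitions out of P2 are much faster than
#' those into it (k_r >> k_e).
#'
#' @param scheme a \code{\link{binding_scheme}} with mechanism \code{"CS"}.
#' @param P0 total protein concentration (uM).
#' @param L0 total ligand concentration(s) (uM).
#' @return Rate(s) in 1/s.
#' @export
qssa_kobs <- function(scheme, P0, L0) {
  stopifnot(inherits(scheme, "binding_scheme"))
  if (scheme$mechanism != "CS")
    stop("unsupported operation: the quasi-steady-state rate is defined for ",
         "the conformational-selection scheme", call. = FALSE)
  check_conditions(P0, L0)
  Kd <- scheme$Kd
  delta <- delta_term(P0, L0, Kd)
  L_eq <- ligand_eq(P0, L0, Kd)
  scheme$k_minus * scheme$k_e * delta /
    (scheme$k_e * Kd + scheme$k_minus * L_eq)
}

#' Export a kobs(L0) curve as delimited text
#'
#' Writes columns \code{P0_uM, L0_uM, kobs_per_s, k2_per_s} (tab-separated).
#'
#' @param scheme a \code{\link{binding_scheme}}.
#' @param P0 total protein concentration(s) (uM); the curve is computed for
#'   each value.
#' @param L0 total ligand concentrations (uM).
#' @param path output file path.
#' @return The exported data.frame, invisibly.
#' @export
write_kobs_curve <- function(scheme, P0, L0, path) {
  tab <- do.call(rbind, lapply(P0, function(p)
    relaxation_rates(scheme, p, L0)[, c("P0_uM", "L0_uM",
                                        "kobs_per_s", "k2_per_s")]))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(tab)
}
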