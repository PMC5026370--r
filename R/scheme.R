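#' Define a protein-ligand binding scheme
#'
#' Constructs a three-state binding scheme with a conformational step, or the
#' one-step elementary scheme.  Two three-state mechanisms are supported:
#' \describe{
#'   \item{induced fit (\code{"IF"})}{P1 + L <-> P1L <-> P2L: the protein
#'     changes conformation \emph{after} ligand binding.  The bound
#'     intermediate P1L relaxes into the bound ground state P2L with rate
#'     \code{k_r} and is re-excited with rate \code{k_e}.}
#'   \item{conformational selection (\code{"CS"})}{P1 <-> P2; P2 + L <-> P2L:
#'     the conformational change precedes binding.  The unbound intermediate
#'     P2 is excited from the unbound ground state P1 with rate \code{k_e} and
#'     relaxes back with rate \code{k_r}.}
#' }
#' The elementary scheme P + L <-> PL has no conformational step; \code{k_e}
#' and \code{k_r} are ignored there.
#'
#' Units are fixed throughout the package: concentrations in uM, time in s,
#' first-order rates in 1/s and the bimolecular rate \code{k_plus} in
#' 1/(uM s).
#'
#' @param mechanism one of \code{"IF"}, \code{"CS"}, \code{"elementary"}
#'   (case-insensitive; \code{"induced_fit"} and
#'   \code{"conformational_selection"} are accepted aliases).
#' @param k_e conformational excitation rate (1/s).
#' @param k_r conformational relaxation rate (1/s).
#' @param k_plus bimolecular binding rate (1/(uM s)).
#' @param k_minus unbinding rate (1/s).
#' @return An object of class \code{"binding_scheme"}: a list with the rate
#'   constants, the mechanism tag and the overall dissociation constant
#'   \code{Kd} (uM).
#' @examples
#' cs <- binding_scheme("CS", k_e = 10, k_r = 100, k_plus = 100, k_minus = 1)
#' cs$Kd  # 0.11 uM
#' @export
binding_scheme <- function(mechanism, k_e = NULL, k_r = NULL, k_plus, k_minus) {
  mechanism <- normalize_mechanism(mechanism)
  check_rate(k_plus, "k_plus")
  check_rate(k_minus, "k_minus")
  if (mechanism != "elementary") {
    check_rate(k_e, "k_e")
    check_rate(k_r, "k_r")
  } else {
    k_e <- NA_real_
    k_r <- NA_real_
  }
  obj <- structure(
    list(mechanism = mechanism, k_e = k_e, k_r = k_r,
         k_plus = k_plus, k_minus = k_minus),
    class = "binding_scheme")
  obj$Kd <- dissociation_constant(obj)
  obj
}

normalize_mechanism <- function(mechanism) {
  if (!is.character(mechanism) || length(mechanism) != 1L)
    stop("'mechanism' must be a single string", call. = FALSE)
  key <- tolower(mechanism)
  map <- c(`if` = "IF", induced_fit = "IF", `induced-fit` = "IF",
           cs = "CS", conformational_selection = "CS",
           `conformational-selection` = "CS",
           elementary = "elementary")
  if (!key %in% names(map))
    stop("unknown mechanism '", mechanism, "'", call. = FALSE)
  unname(map[[key]])
}

check_rate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop("invalid parameter: '", name,
         "' must be a single strictly positive finite number", call. = FALSE)
  invisible(x)
}

check_conditions <- function(P0, L0) {
  if (!is.numeric(P0) || length(P0) != 1L || !is.finite(P0) || P0 <= 0)
    stop("invalid parameter: 'P0' must be a single positive number",
         call. = FALSE)
  if (!is.numeric(L0) || any(!is.finite(L0)) || any(L0 < 0))
    stop("invalid parameter: 'L0' must be finite and >= 0", call. = FALSE)
  invisible(NULL)
}

#' @export
print.binding_scheme <- function(x, ...) {
  label <- c(IF = "induced fit", CS = "conformational selection",
             elementary = "elementary (one-step)")[[x$mechanism]]
  cat("Binding scheme:", label, "\n")
  if (x$mechanism != "elementary")
    cat(sprintf("  k_e = %g 1/s, k_r = %g 1/s\n", x$k_e, x$k_r))
  cat(sprintf("  k_+ = %g 1/(uM s), k_- = %g 1/s\n", x$k_plus, x$k_minus))
  cat(sprintf("  overall Kd = %g uM\n", x$Kd))
  invisible(x)
}

#' Overall dissociation constant of a binding scheme
#'
#' For induced fit the bound intermediate lowers the apparent affinity of the
#' one-step binding by the equilibrium weight of the bound ground state,
#' Kd = k_- k_e / (k_+ (k_e + k_r)); for conformational selection only the
#' excited conformer binds, Kd = k_- (k_e + k_r) / (k_+ k_e); for the
#' elementary scheme Kd = k_-/k_+.
#'
#' @param scheme a \code{\link{binding_scheme}}.
#' @return Dissociation constant in uM.
#' @export
dissociation_constant <- function(scheme) {
  stopifnot(inherits(scheme, "binding_scheme"))
  with(scheme, switch(mechanism,
    IF = k_minus * k_e / (k_plus * (k_e + k_r)),
    CS = k_minus * (k_e + k_r) / (k_plus * k_e),
    elementary = k_minus / k_plus))
}

# sqrt((L0 - P0 + Kd)^2 + 4 P0 Kd): the discriminant term through which the
# totals enter every closed-form rate expression.
delta_term <- function(P0, L0, Kd) {
  sqrt((L0 - P0 + Kd)^2 + 4 * P0 * Kd)
}

# Equilibrium free-ligand concentration of the overall binding isotherm,
# Leq = (L0 - P0 - Kd + delta)/2, evaluated in the conjugate form
# 2 Kd L0 / (delta - (L0 - P0 - Kd)) when the direct form would cancel
# catastrophically (L0 << P0).  Vectorized over L0.
ligand_eq <- function(P0, L0, Kd) {
  a <- L0 - P0 - Kd
  d <- delta_term(P0, L0, Kd)
  ifelse(a < 0, 2 * Kd * L0 / (d - a), (a + d) / 2)
}

#' Equilibrium state of a binding scheme
#'
#' Closed-form equilibrium concentrations of all species for given total
#' protein and ligand concentrations.  The two-step schemes share the
#' one-step binding isotherm in the overall dissociation constant; the
#' conformer populations follow from detailed balance of the conformational
#' step.
#'
#' @param scheme a \code{\link{binding_scheme}}.
#' @param P0 total protein concentration (uM), > 0.
#' @param L0 total ligand concentration (uM), >= 0.
#' @return A list with the species concentrations (uM) of the active scheme
#'   (IF: \code{P1, L, P1L, P2L}; CS: \code{P1, P2, L, P2L}; elementary:
#'   \code{P, L, PL}), plus \code{L_eq}, \code{bound} (total bound complex)
#'   and \code{Kd}.
#' @examples
#' sch <- binding_scheme("elementary", k_plus = 1, k_minus = 1)
#' equilibrium_state(sch, P0 = 1, L0 = 1)$PL  # (3 - sqrt(5))/2
#' @export
equilibrium_state <- function(scheme, P0, L0) {
  stopifnot(inherits(scheme, "binding_scheme"))
  check_conditions(P0, L0)
  Kd <- scheme$Kd
  L_eq <- ligand_eq(P0, L0, Kd)
  bound <- L0 - L_eq
  out <- list(L_eq = L_eq, bound = bound, Kd = Kd)
  if (scheme$mechanism == "IF") {
    w <- scheme$k_r / (scheme$k_e + scheme$k_r)  # bound ground-state weight
    out <- c(list(P1 = P0 - bound, L = L_eq,
                  P1L = (1 - w) * bound, P2L = w * bound), out)
  } else if (scheme$mechanism == "CS") {
    unbound <- P0 - bound
    we <- scheme$k_e / (scheme$k_e + scheme$k_r)  # excited conformer weight
    out <- c(list(P1 = (1 - we) * unbound, P2 = we * unbound,
                  L = L_eq, P2L = bound), out)
    out$P2_eq <- out$P2
  } else {
    out <- c(list(P = P0 - bound, L = L_eq, PL = bound), out)
    out$PL_eq <- out$PL
  }
  out
}

#' Reduced mass-action rate equations
#'
#' Right-hand side of the two non-redundant rate equations obtained after
#' eliminating the conserved totals.  The reduced coordinates are
#' \code{c(L, P2L)} for induced fit, \code{c(P2, L)} for conformational
#' selection and \code{PL} for the elementary scheme.
#'
#' @param scheme a \code{\link{binding_scheme}}.
#' @param P0,L0 total concentrations (uM).
#' @param state numeric vector: the reduced state (length 2, or 1 for the
#'   elementary scheme).
#' @return Time derivatives of the reduced state (uM/s).
#' @export
reduced_rhs <- function(scheme, P0, L0, state) {
  stopifnot(inherits(scheme, "binding_scheme"))
  check_conditions(P0, L0)
  with(scheme, switch(scheme$mechanism,
    IF = {
      L <- state[[1]]; P2L <- state[[2]]
      c(-k_plus * (L - L0 + P0) * L + k_minus * (L0 - L - P2L),
        k_r * (L0 - L - P2L) - k_e * P2L)
    },
    CS = {
      P2 <- state[[1]]; L <- state[[2]]
      c(k_e * (P0 - P2) - (k_r + k_plus * L) * P2 +
          (k_minus - k_e) * (L0 - L),
        k_minus * (L0 - L) - k_plus * P2 * L)
    },
    elementary = {
      PL <- state[[1]]
      k_plus * (P0 - PL) * (L0 - PL) - k_minus * PL
    }))
}

#' Reconstruct the full species state from reduced coordinates
#'
#' Applies the protein and ligand conservation laws to recover all species
#' concentrations from a reduced state, so conservation holds exactly.
#'
#' @inheritParams reduced_rhs
#' @return Named numeric vector of all species concentrations (uM).
#' @export
full_state <- function(scheme, P0, L0, state) {
  stopifnot(inherits(scheme, "binding_scheme"))
  switch(scheme$mechanism,
    IF = {
      L <- state[[1]]; P2L <- state[[2]]
      P1L <- L0 - L - P2L
      c(P1 = P0 - P1L - P2L, L = L, P1L = P1L, P2L = P2L)
    },
    CS = {
      P2 <- state[[1]]; L <- state[[2]]
      P2L <- L0 - L
      c(P1 = P0 - P2 - P2L, P2 = P2, L = L, P2L = P2L)
    },
    elementary = {
      PL <- state[[1]]
      c(P = P0 - PL, L = L0 - PL, PL = PL)
    })
}

#' Serialize a scheme and mixing conditions to JSON
#'
#' @param scheme a \code{\link{binding_scheme}}.
#' @param P0,L0 total concentrations (uM).
#' @param path optional file path; if \code{NULL} the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
scheme_to_json <- function(scheme, P0 = NULL, L0 = NULL, path = NULL) {
  stopifnot(inherits(scheme, "binding_scheme"))
  x <- list(mechanism = scheme$mechanism, k_e = scheme$k_e, k_r = scheme$k_r,
            k_plus = scheme$k_plus, k_minus = scheme$k_minus)
  if (!is.null(P0)) x$P0 <- P0
  if (!is.null(L0)) x$L0 <- L0
  js <- jsonlite::toJSON(x[!vapply(x, function(v) is.null(v) || all(is.na(v)),
                                   logical(1))],
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a scheme (and optional mixing conditions) from JSON
#'
#' @param path file path or a JSON string.
#' @return A list with \code{scheme} (a \code{\link{binding_scheme}}) and,
#'   when present in the JSON, \code{P0} and \code{L0}.
#' @export
scheme_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  scheme <- binding_scheme(x$mechanism, k_e = x$k_e, k_r = x$k_r,
                           k_plus = x$k_plus, k_minus = x$k_minus)
  list(scheme = scheme, P0 = x$P0, L0 = x$L0)
}
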