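# Exact relaxation of the elementary one-step binding scheme P + L <-> PL.
# The analytic solution justifies describing second-order relaxation as a
# (truncated) sum of exponentials whose exponents are integer multiples of
# the dominant rate.

#' Exponents of the exact elementary-binding solution
#'
#' For the initial condition PL(0) = 0 the bound-complex kinetics of the
#' one-step scheme is a ratio of exponentials with the two exponents
#' lambda_{1,2} = -(k_+/2) (S -+/+ R), S = P0 + L0 + Kd,
#' R = sqrt(S^2 - 4 P0 L0).  Both are negative, lambda_1 <= lambda_2, and the
#' dominant relaxation rate is kobs = lambda_2 - lambda_1 =
#' k_+ sqrt((L0 - P0 + Kd)^2 + 4 Kd P0), identical to the rate obtained by
#' linearization about equilibrium.
#'
#' @param scheme a \code{\link{binding_scheme}} with mechanism
#'   \code{"elementary"}.
#' @param P0,L0 total concentrations (uM).
#' @return A list with \code{lambda_1}, \code{lambda_2} (1/s, both negative,
#'   \code{lambda_1 <= lambda_2}) and \code{kobs = lambda_2 - lambda_1}.
#' @export
elementary_rates <- function(scheme, P0, L0) {
  stopifnot(inherits(scheme, "binding_scheme"),
            scheme$mechanism == "elementary")
  check_conditions(P0, L0)
  Kd <- scheme$Kd
  S <- P0 + L0 + Kd
  R <- sqrt(S^2 - 4 * P0 * L0)
  lambda_1 <- -scheme$k_plus * (S + R) / 2
  lambda_2 <- -scheme$k_plus * (S - R) / 2
  list(lambda_1 = lambda_1, lambda_2 = lambda_2, kobs = lambda_2 - lambda_1)
}

#' Exact bound-complex kinetics of the elementary scheme
#'
#' Closed-form PL(t) for PL(0) = 0:
#' \deqn{PL(t) = -\lambda_1 (e^{(\lambda_1-\lambda_2)t} - 1) /
#'   (k_+ (e^{(\lambda_1-\lambda_2)t} - \lambda_1/\lambda_2))}
#' which rises from 0 to the equilibrium value \code{-lambda_2/k_plus}.
#'
#' @param scheme a \code{\link{binding_scheme}} with mechanism
#'   \code{"elementary"}.
#' @param P0,L0 total concentrations (uM).
#' @param t time(s), s, >= 0.
#' @return A list with \code{PL} (uM, same length as \code{t}) and the
#'   \code{\link{elementary_rates}} components.
#' @examples
#' el <- binding_scheme("elementary", k_plus = 1, k_minus = 1)
#' elementary_solution(el, 1, 1, t = c(0, 1, 10))$PL
#' @export
elementary_solution <- function(scheme, P0, L0, t) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("invalid input: 't' must be finite and >= 0", call. = FALSE)
  er <- elementary_rates(scheme, P0, L0)
  e <- exp((er$lambda_1 - er$lambda_2) * t)
  PL <- -er$lambda_1 * (e - 1) / (scheme$k_plus * (e - er$lambda_1 / er$lambda_2))
  c(list(PL = PL), er)
}

#' Harmonic-series representation of the elementary solution
#'
#' Expanding the exact solution in the geometric ratio
#' q = exp(-kobs t) lambda_2/lambda_1 gives
#' \deqn{PL(t) = -\frac{1}{k_+}\Big[\lambda_2 + (\lambda_2-\lambda_1)
#'   \sum_{n\ge1} e^{-n k_{obs} t} (\lambda_2/\lambda_1)^n\Big]}
#' a sum of exponentials whose exponents are integer multiples of the
#' dominant rate (higher harmonics).  The prefactors decay geometrically
#' because 0 < lambda_2/lambda_1 < 1, so the series can be truncated; the
#' truncation error after N terms is bounded by the geometric tail
#' (lambda_2 - lambda_1)/k_+ * q^(N+1)/(1-q).
#'
#' @inheritParams elementary_solution
#' @param N number of harmonics retained (default 20).
#' @return A list with \code{PL} (uM), \code{tail_bound} (uM, same length)
#'   and \code{N}.
#' @export
elementary_harmonics <- function(scheme, P0, L0, t, N = 20L) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("invalid input: 't' must be finite and >= 0", call. = FALSE)
  stopifnot(N >= 1)
  er <- elementary_rates(scheme, P0, L0)
  ratio <- er$lambda_2 / er$lambda_1  # in (0, 1)
  s <- 0
  for (n in seq_len(N)) s <- s + exp(-n * er$kobs * t) * ratio^n
  PL <- -(er$lambda_2 + (er$lambda_2 - er$lambda_1) * s) / scheme$k_plus
  q <- exp(-er$kobs * t) * ratio
  tail_bound <- (er$lambda_2 - er$lambda_1) / scheme$k_plus *
    q^(N + 1) / (1 - q)
  list(PL = PL, tail_bound = tail_bound, N = N)
}
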