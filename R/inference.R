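# Mechanism inference from k_obs(L0) data: constrained weighted least
# squares of the closed-form IF/CS rate expressions (Kd fixed from
# equilibrium data), Bayes-factor model comparison, and a shape-based
# classification report.

check_kobs_data <- function(data) {
  need <- c("P0_uM", "L0_uM", "kobs_per_s", "sigma_per_s")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    stop("k_obs data must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (length(unique(data$L0_uM)) < 3)
    stop("k_obs data must span at least 3 distinct ligand concentrations",
         call. = FALSE)
  if (any(data$sigma_per_s <= 0) || any(!is.finite(data$sigma_per_s)))
    stop("all k_obs uncertainties must be positive", call. = FALSE)
  invisible(data)
}

# Moore-Penrose inverse via SVD (for near-singular J'J when a parameter
# direction is unidentified, e.g. k_r in CS fits).
pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d)
  d <- ifelse(pos, 1 / s$d, 0)
  s$v %*% (d * t(s$u))
}

# parameter transform: theta (ke, kr, kminus) <-> unconstrained u.
# With constraint n > 0, kr = n * ke * exp(u2) with u2 >= 0 enforced as a
# box bound; without a constraint all three are log-parameterized.
theta_to_u <- function(theta, n) {
  if (n > 0)
    c(log(theta[1]), max(log(theta[2] / (n * theta[1])), 0), log(theta[3]))
  else log(theta)
}
u_to_theta <- function(u, n) {
  if (n > 0) c(exp(u[1]), n * exp(u[1] + u[2]), exp(u[3]))
  else exp(u)
}

#' Fit the closed-form kobs(L0) expression to relaxation-rate data
#'
#' Weighted least squares (weights 1/sigma_i^2) of the general dominant-rate
#' expression of the chosen mechanism to a table of k_obs estimates versus
#' total ligand concentration, jointly over all protein-concentration groups.
#' The overall dissociation constant Kd is held fixed (known from
#' equilibrium data), so the free parameters are the conformational
#' excitation and relaxation rates k_e, k_r and the unbinding rate k_-; the
#' bimolecular rate is implied by Kd.  An optional hard constraint
#' k_r >= n k_e bounds the excited-state occupancy Pe = k_e/(k_e + k_r)
#' below 1/(n+1).
#'
#' Optimization uses Levenberg-Marquardt from a grid of starting points in
#' log-rate space; standard errors come from the linearized covariance
#' (J' J)^-1 of the weighted residuals (sigma_i treated as known), via a
#' pseudo-inverse when a direction is unidentified (CS fits are often
#' insensitive to k_r; its reported standard error is then very large or
#' NA).
#'
#' @param data data.frame with columns \code{P0_uM}, \code{L0_uM},
#'   \code{kobs_per_s}, \code{sigma_per_s} (e.g. from
#'   \code{\link{fit_kobs_table}}).
#' @param mechanism \code{"IF"} or \code{"CS"}.
#' @param Kd overall dissociation constant (uM), fixed.
#' @param constraint_n constraint multiplier n in k_r >= n k_e (0 = none).
#' @param start optional named start values \code{c(k_e=, k_r=, k_minus=)}.
#' @param scale_errors if TRUE (default), the parameter covariance is scaled
#'   by the reduced chi-square max(1, chisq/dof), the conventional
#'   error-variance estimate of weighted nonlinear fitting software; this
#'   absorbs small systematic misfit of the stated per-point errors.
#' @return An object of class \code{"kobs_fit"} with methods \code{print},
#'   \code{summary}, \code{coef}, \code{vcov}, \code{confint},
#'   \code{predict}, \code{residuals}, \code{fitted}, \code{logLik},
#'   \code{plot} and \code{simulate}.
#' @examples
#' cs <- binding_scheme("CS", 10, 100, 100, 1)
#' L0 <- c(0.2, 0.5, 1, 2, 5)
#' kobs <- relaxation_rates(cs, 0.5, L0)$kobs_per_s
#' dat <- data.frame(P0_uM = 0.5, L0_uM = L0, kobs_per_s = kobs,
#'                   sigma_per_s = 0.05)
#' fit <- fit_kobs_curve(dat, "CS", Kd = cs$Kd)
#' coef(fit)
#' @export
fit_kobs_curve <- function(data, mechanism, Kd, constraint_n = 0,
                           start = NULL, scale_errors = TRUE) {
  mechanism <- normalize_mechanism(mechanism)
  if (!mechanism %in% c("IF", "CS"))
    stop("mechanism must be 'IF' or 'CS'", call. = FALSE)
  check_kobs_data(data)
  check_rate(Kd, "Kd")
  n <- constraint_n
  w <- 1 / data$sigma_per_s
  resid_u <- function(u) {
    th <- u_to_theta(u, n)
    w * (data$kobs_per_s -
           kobs_model(mechanism, th[1], th[2], th[3], Kd,
                      data$P0_uM, data$L0_uM))
  }
  lower <- c(-Inf, if (n > 0) 0 else -Inf, -Inf)
  starts <- if (!is.null(start)) {
    list(theta_to_u(unname(start[c("k_e", "k_r", "k_minus")]), n))
  } else {
    g <- log(c(0.1, 1, 10, 100))
    gr <- expand.grid(g, g, g)
    lapply(seq_len(nrow(gr)), function(i)
      pmax(as.numeric(gr[i, ]), lower))
  }
  best <- NULL
  for (u0 in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = u0, fn = resid_u, lower = lower,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best_rss) {
      best <- fit
      best_rss <- rss
    }
  }
  if (is.null(best))
    fit_failure("kobs-curve fit did not converge from any start")
  theta <- u_to_theta(best$par, n)
  names(theta) <- c("k_e", "k_r", "k_minus")
  # covariance in rate space from a numeric Jacobian of the weighted
  # residuals wrt log-rates (delta method)
  resid_theta <- function(lt) {
    th <- exp(lt)
    w * (data$kobs_per_s -
           kobs_model(mechanism, th[1], th[2], th[3], Kd,
                      data$P0_uM, data$L0_uM))
  }
  lt <- log(theta)
  h <- 1e-6
  J <- vapply(1:3, function(j) {
    e <- replace(numeric(3), j, h)
    (resid_theta(lt + e) - resid_theta(lt - e)) / (2 * h)
  }, numeric(nrow(data)))
  cov_log <- pinv(crossprod(J))
  vc <- diag(theta) %*% cov_log %*% diag(theta)
  dimnames(vc) <- list(names(theta), names(theta))
  chisq <- sum(resid_theta(lt)^2)
  dof <- max(nrow(data) - 3L, 1L)
  if (scale_errors) vc <- vc * max(1, chisq / dof)
  structure(
    list(mechanism = mechanism, coefficients = theta,
         se = sqrt(pmax(diag(vc), 0)), vcov = vc, Kd = Kd,
         constraint_n = n, chisq = chisq,
         df.residual = nrow(data) - 3L,
         Pe = unname(theta[1] / (theta[1] + theta[2])),
         data = data,
         fitted.values = unname(
           kobs_model(mechanism, theta[1], theta[2], theta[3], Kd,
                      data$P0_uM, data$L0_uM))),
    class = "kobs_fit")
}

#' @export
print.kobs_fit <- function(x, digits = 4, ...) {
  cat(sprintf("kobs(L0) fit, %s mechanism (Kd fixed at %g uM%s)\n",
              c(IF = "induced-fit", CS = "conformational-selection")[x$mechanism],
              x$Kd,
              if (x$constraint_n > 0)
                sprintf("; constraint k_r >= %g k_e", x$constraint_n) else ""))
  print(signif(x$coefficients, digits))
  cat(sprintf("chi-square %.4g on %d residual d.o.f.; Pe = %.3g\n",
              x$chisq, x$df.residual, x$Pe))
  invisible(x)
}

#' @export
coef.kobs_fit <- function(object, ...) object$coefficients

#' @export
vcov.kobs_fit <- function(object, ...) object$vcov

#' @export
fitted.kobs_fit <- function(object, ...) object$fitted.values

#' Confidence intervals for kobs-curve fits
#'
#' \code{method = "profile"} (default) inverts the profile chi-square: the
#' interval for each rate is the set where the chi-square, minimized over
#' the other rates, stays within \code{qchisq(level, 1)} (scaled by the
#' reduced chi-square when the fit scales its errors) of the minimum.
#' Profile intervals remain meaningful for weakly identified parameters
#' (e.g. k_r of conformational-selection fits), where the quadratic Wald
#' interval is misleading; they can be one-sidedly unbounded (Inf).
#'
#' @param object a \code{"kobs_fit"}.
#' @param parm parameter names (default all three rates).
#' @param level confidence level.
#' @param method \code{"profile"} or \code{"wald"}.
#' @param ... unused.
#' @return Matrix with lower and upper bounds.
#' @export
confint.kobs_fit <- function(object, parm = names(object$coefficients),
                             level = 0.95,
                             method = c("profile", "wald"), ...) {
  method <- match.arg(method)
  cn <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  if (method == "wald") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    est <- object$coefficients[parm]
    se <- object$se[match(parm, names(object$coefficients))]
    out <- cbind(est - z * se, est + z * se)
    colnames(out) <- cn
    return(out)
  }
  d <- object$data
  w <- 1 / d$sigma_per_s
  scale <- max(1, object$chisq / max(object$df.residual, 1))
  thr <- object$chisq + stats::qchisq(level, 1) * scale
  all_par <- names(object$coefficients)
  prof_chisq <- function(name, value) {
    others <- setdiff(all_par, name)
    th0 <- log(object$coefficients[others])
    f <- function(u) {
      th <- stats::setNames(numeric(3), all_par)
      th[name] <- value
      th[others] <- exp(u)
      if (object$constraint_n > 0 &&
          th["k_r"] < object$constraint_n * th["k_e"]) return(1e12)
      sum((w * (d$kobs_per_s -
                  kobs_model(object$mechanism, th["k_e"], th["k_r"],
                             th["k_minus"], object$Kd,
                             d$P0_uM, d$L0_uM)))^2)
    }
    stats::optim(th0, f)$value
  }
  bound <- function(name, dir) {
    # clamp the starting point into a physical rate window so that runaway
    # estimates of unidentified parameters still yield sensible bounds
    est <- min(max(object$coefficients[[name]], 1e-8), 1e12)
    lim <- if (dir > 0) 1e12 else 1e-8
    # march geometrically until the profile crosses the threshold
    lo <- est
    hi <- est
    step <- 1.6
    repeat {
      hi <- if (dir > 0) hi * step else hi / step
      if ((dir > 0 && hi > lim) || (dir < 0 && hi < lim))
        return(if (dir > 0) Inf else 0)
      pc <- prof_chisq(name, hi)
      if (is.nan(pc) || pc > thr) break
      lo <- hi
    }
    for (i in 1:25) {
      mid <- sqrt(lo * hi)
      pc <- prof_chisq(name, mid)
      if (is.nan(pc) || pc > thr) hi <- mid else lo <- mid
    }
    sqrt(lo * hi)
  }
  out <- t(vapply(parm, function(nm) c(bound(nm, -1), bound(nm, 1)),
                  numeric(2)))
  colnames(out) <- cn
  out
}

#' @export
residuals.kobs_fit <- function(object, type = c("pearson", "response"),
                               ...) {
  type <- match.arg(type)
  r <- object$data$kobs_per_s - object$fitted.values
  if (type == "pearson") r <- r / object$data$sigma_per_s
  r
}

#' @export
logLik.kobs_fit <- function(object, ...) {
  val <- -0.5 * object$chisq -
    sum(log(object$data$sigma_per_s)) -
    0.5 * nrow(object$data) * log(2 * pi)
  structure(val, df = 3L, nobs = nrow(object$data), class = "logLik")
}

#' @export
predict.kobs_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  th <- object$coefficients
  kobs_model(object$mechanism, th[1], th[2], th[3], object$Kd,
             newdata$P0_uM, newdata$L0_uM)
}

#' @export
summary.kobs_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(fit = object, coefficients = tab),
            class = "summary.kobs_fit")
}

#' @export
print.summary.kobs_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
plot.kobs_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$L0_uM, d$kobs_per_s, log = "xy",
                 xlab = "[L]0 (uM)", ylab = "kobs (1/s)",
                 pch = 20, ...)
  graphics::arrows(d$L0_uM, d$kobs_per_s - d$sigma_per_s,
                   d$L0_uM, d$kobs_per_s + d$sigma_per_s,
                   angle = 90, code = 3, length = 0.02)
  for (p in unique(d$P0_uM)) {
    L <- exp(seq(log(min(d$L0_uM)), log(max(d$L0_uM)), length.out = 200))
    graphics::lines(L, predict(x, data.frame(P0_uM = p, L0_uM = L)))
  }
  invisible(x)
}

#' @export
simulate.kobs_fit <- function(object, nsim = 1, seed = 1L, ...) {
  with_local_seed(seed, lapply(seq_len(nsim), function(i) {
    d <- object$data
    d$kobs_per_s <- object$fitted.values +
      stats::rnorm(nrow(d), sd = d$sigma_per_s)
    d
  }))
}

#' Equilibrium occupancy of the excited conformation
#'
#' Pe = k_e / (k_e + k_r): the equilibrium fraction of protein in the
#' higher-energy conformation connected by the conformational exchange step.
#'
#' @param k_e,k_r conformational excitation and relaxation rates (1/s), > 0.
#' @return Occupancy as a fraction in (0, 1).
#' @examples
#' excited_state_occupancy(33, 990)  # 0.032
#' @export
excited_state_occupancy <- function(k_e, k_r) {
  if (any(k_e <= 0) || any(k_r <= 0) || any(!is.finite(c(k_e, k_r))))
    stop("invalid parameter: rates must be positive and finite",
         call. = FALSE)
  k_e / (k_e + k_r)
}

#' Log-likelihood of a parameter set for k_obs data
#'
#' Gaussian errors: log L = -1/2 sum_i (kobs_i - kobs_M(theta, L0_i))^2 /
#' sigma_i^2 (up to an additive constant), with the model rate from the
#' closed-form IF or CS expression (Kd and P0 fixed).  Outside the
#' constraint k_r > n k_e the likelihood is zero (-Inf returned).
#'
#' @param mechanism \code{"IF"} or \code{"CS"}.
#' @param theta numeric vector \code{(k_e, k_r, k_minus)} (1/s).
#' @param data k_obs data.frame (see \code{\link{fit_kobs_curve}}).
#' @param Kd fixed dissociation constant (uM).
#' @param constraint_n constraint multiplier n (0 = none).
#' @return Log-likelihood value (residual term only).
#' @export
log_likelihood <- function(mechanism, theta, data, Kd, constraint_n = 0) {
  mechanism <- normalize_mechanism(mechanism)
  check_kobs_data(data)
  if (theta[2] <= constraint_n * theta[1]) return(-Inf)
  m <- kobs_model(mechanism, theta[1], theta[2], theta[3], Kd,
                  data$P0_uM, data$L0_uM)
  -0.5 * sum(((data$kobs_per_s - m) / data$sigma_per_s)^2)
}

#' Prior specification for Bayes-factor integrals
#'
#' Independent priors on the rates k_e, k_r, k_minus, uniform either in the
#' logarithm of the rate (default) or in the rate itself, on a common
#' bounded support.
#'
#' @param lower,upper support bounds (1/s), 0 < lower < upper.
#' @param measure \code{"log"} or \code{"linear"}.
#' @return An object of class \code{"prior_spec"}.
#' @export
prior_spec <- function(lower = 1e-2, upper = 1e4,
                       measure = c("log", "linear")) {
  measure <- match.arg(measure)
  if (!(lower > 0 && upper > lower))
    stop("prior bounds must satisfy 0 < lower < upper", call. = FALSE)
  structure(list(lower = lower, upper = upper, measure = measure),
            class = "prior_spec")
}

sample_prior <- function(prior, n) {
  draw <- function()
    if (prior$measure == "log")
      exp(stats::runif(n, log(prior$lower), log(prior$upper)))
    else stats::runif(n, prior$lower, prior$upper)
  list(k_e = draw(), k_r = draw(), k_minus = draw())
}

log_lik_vec <- function(mechanism, th, data, Kd) {
  ll <- 0
  for (i in seq_len(nrow(data)))
    ll <- ll - 0.5 * ((data$kobs_per_s[i] -
                         kobs_model(mechanism, th$k_e, th$k_r, th$k_minus,
                                    Kd, data$P0_uM[i], data$L0_uM[i])) /
                        data$sigma_per_s[i])^2
  ll
}

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(mean(exp(x - m)))
}

#' Bayes factor comparing conformational selection to induced fit
#'
#' Monte-Carlo estimate of K = p(data | CS) / p(data | IF): both marginal
#' likelihoods are simple averages of the Gaussian likelihood over draws
#' from the same prior on (k_e, k_r, k_minus) (Kd and P0 fixed).  When a
#' constraint k_r > n k_e is imposed, draws violating it are rejected, which
#' renormalizes the prior over the constrained region identically for both
#' models.  A Monte-Carlo standard error of log10 K is reported (delta
#' method, accounting for the shared draws); values above 0.2 raise a
#' warning flag.
#'
#' @param data k_obs data.frame (see \code{\link{fit_kobs_curve}}).
#' @param Kd fixed dissociation constant (uM).
#' @param constraint_n constraint multiplier n (0 = none).
#' @param prior a \code{\link{prior_spec}}.
#' @param ndraws number of prior draws (before constraint rejection).
#' @param seed integer seed (reproducible).
#' @param swap if TRUE, report induced fit relative to conformational
#'   selection instead (the exact reciprocal for the same seed).
#' @return An object of class \code{"bayes_comparison"}: \code{K},
#'   \code{log10_K}, \code{se_log10_K}, \code{ndraws_used},
#'   \code{warning_flag}, plus the prior and constraint used.
#' @export
bayes_factor <- function(data, Kd, constraint_n = 0, prior = prior_spec(),
                         ndraws = 2e5, seed = 1L, swap = FALSE) {
  check_kobs_data(data)
  th <- with_local_seed(seed, sample_prior(prior, ndraws))
  if (constraint_n > 0) {
    keep <- th$k_r > constraint_n * th$k_e
    th <- lapply(th, `[`, keep)
  }
  n_used <- length(th$k_e)
  if (n_used < 100)
    stop("too few prior draws satisfy the constraint", call. = FALSE)
  ll_cs <- log_lik_vec("CS", th, data, Kd)
  ll_if <- log_lik_vec("IF", th, data, Kd)
  log_ml_cs <- log_mean_exp(ll_cs)
  log_ml_if <- log_mean_exp(ll_if)
  wc <- exp(ll_cs - max(ll_cs))
  wi <- exp(ll_if - max(ll_if))
  var_log <- (stats::var(wc) / mean(wc)^2 + stats::var(wi) / mean(wi)^2 -
                2 * stats::cov(wc, wi) / (mean(wc) * mean(wi))) / n_used
  logK <- log_ml_cs - log_ml_if
  if (swap) logK <- -logK
  se10 <- sqrt(max(var_log, 0)) / log(10)
  structure(
    list(K = exp(logK), log10_K = logK / log(10), se_log10_K = se10,
         log_ml_cs = log_ml_cs, log_ml_if = log_ml_if,
         ndraws_used = n_used, prior = prior, constraint_n = constraint_n,
         swap = swap, warning_flag = se10 > 0.2),
    class = "bayes_comparison")
}

#' @export
print.bayes_comparison <- function(x, ...) {
  num <- if (x$swap) "IF vs CS" else "CS vs IF"
  cat(sprintf("Bayes factor (%s): K = %.3g, log10 K = %.2f (MC se %.3f)\n",
              num, x$K, x$log10_K, x$se_log10_K))
  if (x$warning_flag)
    cat("  warning: Monte-Carlo standard error of log10 K exceeds 0.2\n")
  invisible(x)
}

# weighted PAVA chi-square of the best monotone fit (direction = 1
# increasing, -1 decreasing), using isoreg on the (possibly negated) rates.
isotonic_rss <- function(L0, kobs, direction) {
  ord <- order(L0)
  y <- direction * kobs[ord]
  fit <- stats::isoreg(seq_along(y), y)
  sum((y - fit$yf)^2)
}

#' Classify the binding mechanism from k_obs(L0) data
#'
#' Produces a structured report combining the diagnostic shape features of
#' the dominant-rate curve with model fits and a Bayes factor:
#' (i) monotonicity of k_obs versus L0 at the largest protein concentration
#' (residual comparison of increasing vs decreasing isotonic fits -- a
#' monotone decrease indicates conformational selection with k_e < k_-);
#' (ii) presence and location of an interior minimum; (iii) a symmetry score
#' about the minimum (weighted mean absolute difference of linearly
#' interpolated rates at mirrored ligand concentrations -- induced fit is
#' exactly symmetric); (iv) weighted fits of both mechanisms with their
#' chi-squares; (v) the Bayes factor.  The verdict is decisive
#' (\code{"CS"} or \code{"IF"}) iff |log10 K| >= 2, else
#' \code{"inconclusive"}.
#'
#' @param data k_obs data.frame with at least 5 ligand concentrations at the
#'   largest protein concentration.
#' @param Kd fixed dissociation constant (uM).
#' @param constraint_n constraint multiplier n for fits and Bayes factor.
#' @param prior,ndraws,seed passed to \code{\link{bayes_factor}}.
#' @return An object of class \code{"mechanism_report"}.
#' @export
classify_mechanism <- function(data, Kd, constraint_n = 0,
                               prior = prior_spec(), ndraws = 2e5,
                               seed = 1L) {
  check_kobs_data(data)
  Pmax <- max(data$P0_uM)
  top <- data[data$P0_uM == Pmax, ]
  top <- top[order(top$L0_uM), ]
  if (nrow(top) < 5)
    stop("insufficient data: need >= 5 ligand concentrations at the ",
         "largest protein concentration", call. = FALSE)
  rss_inc <- isotonic_rss(top$L0_uM, top$kobs_per_s, 1)
  rss_dec <- isotonic_rss(top$L0_uM, top$kobs_per_s, -1)
  # chi-square of the decreasing monotone fit against the stated errors
  ord <- seq_len(nrow(top))
  dec_fit <- -stats::isoreg(ord, -top$kobs_per_s)$yf
  dec_chisq <- sum(((top$kobs_per_s - dec_fit) / top$sigma_per_s)^2)
  monotone_decreasing <- rss_dec < rss_inc &&
    dec_chisq <= stats::qchisq(0.95, nrow(top))
  # interior minimum
  i_min <- which.min(top$kobs_per_s)
  k_min <- top$kobs_per_s[i_min]
  has_minimum <- i_min > 1 && i_min < nrow(top) &&
    top$kobs_per_s[1] > k_min + 2 * top$sigma_per_s[i_min] &&
    top$kobs_per_s[nrow(top)] > k_min + 2 * top$sigma_per_s[i_min]
  L0_min <- if (has_minimum) top$L0_uM[i_min] else NA_real_
  # symmetry score about the minimum (linear interpolation, matched pairs)
  symmetry <- NA_real_
  if (has_minimum) {
    xmax <- min(L0_min - min(top$L0_uM), max(top$L0_uM) - L0_min)
    if (xmax > 0) {
      x <- seq(xmax / 20, xmax, length.out = 20)
      kp <- stats::approx(top$L0_uM, top$kobs_per_s, xout = L0_min + x)$y
      km <- stats::approx(top$L0_uM, top$kobs_per_s, xout = L0_min - x)$y
      keep <- is.finite(kp) & is.finite(km)
      symmetry <- stats::weighted.mean(abs(kp - km)[keep], x[keep])
    }
  }
  fit_cs <- fit_kobs_curve(data, "CS", Kd, constraint_n)
  fit_if <- fit_kobs_curve(data, "IF", Kd, constraint_n)
  bc <- bayes_factor(data, Kd, constraint_n, prior, ndraws, seed)
  verdict <- if (bc$log10_K >= 2) "CS" else if (bc$log10_K <= -2) "IF" else
    "inconclusive"
  structure(
    list(verdict = verdict,
         monotone_decreasing = monotone_decreasing,
         cs_consistent = monotone_decreasing,
         isotonic_rss = c(increasing = rss_inc, decreasing = rss_dec),
         has_minimum = has_minimum, L0_min = L0_min,
         symmetry_score = symmetry,
         fit_cs = fit_cs, fit_if = fit_if,
         chisq = c(CS = fit_cs$chisq, IF = fit_if$chisq),
         bayes = bc, Kd = Kd, constraint_n = constraint_n,
         P0_used = Pmax, n_points = nrow(data)),
    class = "mechanism_report")
}

#' @export
print.mechanism_report <- function(x, ...) {
  cat("Mechanism classification report\n")
  cat(sprintf("  verdict: %s (decisive iff |log10 K| >= 2)\n", x$verdict))
  cat(sprintf("  kobs(L0) at P0 = %g uM: %s%s\n", x$P0_used,
              if (x$monotone_decreasing)
                "monotone decreasing (CS-consistent, k_e < k_-)"
              else "not monotone decreasing",
              if (x$has_minimum)
                sprintf("; interior minimum near L0 = %.3g uM", x$L0_min)
              else ""))
  if (is.finite(x$symmetry_score %||% NA))
    cat(sprintf("  symmetry score about the minimum: %.4g 1/s\n",
                x$symmetry_score))
  cat(sprintf("  chi-square: CS %.4g | IF %.4g\n",
              x$chisq["CS"], x$chisq["IF"]))
  print(x$bayes)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a mechanism report as JSON
#'
#' Serializes the numeric content of a \code{"mechanism_report"} (verdict,
#' shape diagnostics, fitted parameters with standard errors, chi-squares,
#' Bayes factor) to a JSON file; the \code{print} method is the
#' human-readable counterpart.
#'
#' @param report a \code{"mechanism_report"}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "mechanism_report"))
  x <- list(
    verdict = report$verdict,
    monotone_decreasing = report$monotone_decreasing,
    has_minimum = report$has_minimum, L0_min = report$L0_min,
    symmetry_score = report$symmetry_score,
    isotonic_rss = as.list(report$isotonic_rss),
    chisq = as.list(report$chisq),
    fits = list(
      CS = list(estimate = as.list(coef(report$fit_cs)),
                se = as.list(report$fit_cs$se), Pe = report$fit_cs$Pe),
      IF = list(estimate = as.list(coef(report$fit_if)),
                se = as.list(report$fit_if$se), Pe = report$fit_if$Pe)),
    bayes = list(K = report$bayes$K, log10_K = report$bayes$log10_K,
                 se_log10_K = report$bayes$se_log10_K,
                 ndraws_used = report$bayes$ndraws_used,
                 constraint_n = report$bayes$constraint_n),
    Kd_uM = report$Kd, constraint_n = report$constraint_n,
    P0_used_uM = report$P0_used, n_points = report$n_points)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null"), path)
  invisible(path)
}
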