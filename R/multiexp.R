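# Multi-exponential fitting of relaxation curves:
#   bound(t) = A0 + sum_n A_n exp(-k_n t),  k_n > 0.
# Global search by classic differential evolution (DE/rand/1/bin) over the
# decay rates with the amplitudes solved linearly (variable projection),
# repeated over a sweep of the DE weighting factor F; local polish and
# parameter covariance by Levenberg-Marquardt (minpack.lm).  The number of
# exponentials is chosen by small-sample corrected AIC.

fit_failure <- function(msg) {
  stop(structure(class = c("chemrelax_fit_failure", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# exp(-k t) with the exponent clamped above the denormal range: denormal
# design-matrix entries make the QR in .lm.fit return NaN residuals.
exp_decay <- function(t, k) exp(pmax(-t %o% k, -700))

# Residual sum of squares of the best amplitudes for given rates
# (variable projection).
varpro_rss <- function(logk, t, y) {
  X <- cbind(1, exp_decay(t, 10^logk))
  r <- .lm.fit(X, y)$residuals
  sum(r * r)
}

# Classic DE/rand/1/bin minimizer on a box.  'init' rows are used to seed
# part of the initial population.
de_optimize <- function(fn, lower, upper, NP = 15L, maxgen = 80L, F = 0.5,
                        CR = 0.9, seed = 1L, init = NULL, stall = 15L) {
  d <- length(lower)
  with_local_seed(seed, {
    pop <- matrix(stats::runif(NP * d, lower, upper), nrow = NP, ncol = d,
                  byrow = TRUE)
    if (!is.null(init)) {
      init <- matrix(pmin(pmax(t(init), lower), upper), ncol = d,
                     byrow = TRUE)
      pop[seq_len(min(nrow(init), NP)), ] <- init[seq_len(min(nrow(init),
                                                              NP)), ]
    }
    cost <- apply(pop, 1, fn)
    best <- min(cost)
    since <- 0L
    for (gen in seq_len(maxgen)) {
      r <- replicate(3, sample.int(NP, NP, replace = FALSE))
      mut <- pop[r[, 1], , drop = FALSE] +
        F * (pop[r[, 2], , drop = FALSE] - pop[r[, 3], , drop = FALSE])
      mut <- pmin(pmax(mut, rep(lower, each = NP)), rep(upper, each = NP))
      cross <- matrix(stats::runif(NP * d) < CR, NP, d)
      jrand <- cbind(seq_len(NP), sample.int(d, NP, replace = TRUE))
      cross[jrand] <- TRUE
      trial <- ifelse(cross, mut, pop)
      for (i in seq_len(NP)) {
        ci <- fn(trial[i, ])
        if (ci <= cost[i]) {
          cost[i] <- ci
          pop[i, ] <- trial[i, ]
        }
      }
      newbest <- min(cost)
      if (newbest < best * (1 - 1e-10)) since <- 0L else since <- since + 1L
      best <- newbest
      if (since >= stall) break
    }
    i <- which.min(cost)
    list(par = pop[i, ], value = cost[i], pop = pop, cost = cost)
  })
}

# Pick up to n_keep mutually distinct members (sorted rate vectors further
# than min_dist apart in log10) from a DE population, best first.  The
# population holds near-optimal alternative decompositions; the best one is
# often 'singular' under the discard rules while a slightly worse valid one
# exists.
distinct_members <- function(pop, cost, n_keep = 5L, min_dist = 0.05) {
  ord <- order(cost)
  kept <- list()
  for (i in ord) {
    x <- sort(pop[i, ])
    dup <- any(vapply(kept, function(z) max(abs(z - x)) < min_dist,
                      logical(1)))
    if (!dup) kept[[length(kept) + 1]] <- x
    if (length(kept) >= n_keep) break
  }
  kept
}

# Analytic Jacobian of the multi-exponential model wrt (A0, A_1..A_N,
# k_1..k_N).
multiexp_jacobian <- function(par, t, N) {
  A <- par[2:(N + 1)]
  k <- par[(N + 2):(2 * N + 1)]
  E <- exp_decay(t, k)
  cbind(1, E, -E * rep(A, each = length(t)) * t)
}

multiexp_model <- function(par, t, N) {
  A0 <- par[1]
  A <- par[2:(N + 1)]
  k <- par[(N + 2):(2 * N + 1)]
  A0 + drop(exp_decay(t, k) %*% A)
}

# Levenberg-Marquardt polish of a full parameter vector; returns parameters,
# RSS and the linearized covariance (J'J)^-1 * RSS/(n-p), or NULL when the
# normal equations are singular.
polish_multiexp <- function(par, t, y, N, k_bounds) {
  rng <- range(y)
  span <- diff(rng)
  lower <- c(rng[1] - span, rep(-2 * span, N), rep(k_bounds[1], N))
  upper <- c(rng[2] + span, rep(2 * span, N), rep(k_bounds[2], N))
  # maxiter warnings only flag flat valleys after convergence in the
  # well-determined directions
  fit <- try(suppressWarnings(minpack.lm::nls.lm(
    par = pmin(pmax(par, lower), upper),
    fn = function(p) y - multiexp_model(p, t, N),
    jac = function(p) -multiexp_jacobian(p, t, N),
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 120))), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  p <- fit$par
  rss <- sum(fit$fvec^2)
  n <- length(y)
  J <- multiexp_jacobian(p, t, N)
  s2 <- rss / max(n - length(p), 1)
  cov <- try(solve(crossprod(J)) * s2, silent = TRUE)
  if (inherits(cov, "try-error") || any(!is.finite(cov))) return(NULL)
  list(par = p, rss = rss, cov = cov)
}

aicc_value <- function(rss, n, p) {
  rss <- max(rss, 1e-300)
  n * log(rss / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

# Order parameters as (A0, A sorted by rate, k ascending) and check the
# singularity discard rules.
finalize_multiexp <- function(pol, N, n, F_used) {
  p <- pol$par
  A0 <- p[1]
  A <- p[2:(N + 1)]
  k <- p[(N + 2):(2 * N + 1)]
  ord <- order(k)
  A <- A[ord]
  k <- k[ord]
  idx <- c(1, 1 + ord, 1 + N + ord)
  cov <- pol$cov[idx, idx, drop = FALSE]
  kcov <- cov[(N + 2):(2 * N + 1), (N + 2):(2 * N + 1), drop = FALSE]
  se_k <- sqrt(pmax(diag(kcov), 0))
  ci <- cbind(lower = k - 1.96 * se_k, upper = k + 1.96 * se_k)
  valid <- TRUE
  # a rate consistent with 0 at 95%
  if (any(ci[, "lower"] <= 0)) valid <- FALSE
  # two rates coinciding within 95% confidence intervals: each rate lies
  # inside the other's interval (a weakly determined harmonic with a wide CI
  # may cover a sharply determined rate without duplicating it, so one-sided
  # coverage is not treated as singular)
  coincident <- matrix(FALSE, N, N)
  if (N > 1)
    for (i in seq_len(N - 1))
      for (j in (i + 1):N) {
        d <- abs(k[j] - k[i])
        if (d <= 1.96 * se_k[i] && d <= 1.96 * se_k[j]) {
          valid <- FALSE
          coincident[i, j] <- coincident[j, i] <- TRUE
        }
      }
  # effective dominant rate of this decomposition: amplitude-weighted mean
  # over the slowest chain of mutually coincident rates (for a non-singular
  # fit this is just the smallest rate) -- a degenerate slow pair resolves
  # only as a combination, not as its individual members
  m <- 1L
  while (m < N && coincident[m, m + 1]) m <- m + 1L
  kmin_eff <- stats::weighted.mean(k[1:m], abs(A[1:m]))
  structure(
    list(A0 = A0, amplitudes = A, rates = k, se_rates = se_k, ci = ci,
         cov = cov, rss = pol$rss, n = n, N = N,
         aicc = aicc_value(pol$rss, n, 2 * N + 1),
         F_used = F_used, valid = valid, kmin_eff = kmin_eff),
    class = "multiexp_fit")
}

#' @export
print.multiexp_fit <- function(x, ...) {
  cat(sprintf("Multi-exponential fit: N = %d, RSS = %.4g, AICc = %.2f\n",
              x$N, x$rss, x$aicc))
  tab <- data.frame(rate_per_s = x$rates, se = x$se_rates,
                    amplitude_uM = x$amplitudes)
  print(tab, digits = 4)
  invisible(x)
}

#' Fit a relaxation curve with a fixed number of exponentials
#'
#' Global least-squares fit of \code{A0 + sum_n A_n exp(-k_n t)} by
#' differential evolution over the decay rates (amplitudes projected out
#' linearly), run once for each value of the DE weighting factor F in
#' \code{F_values}, followed by a Levenberg-Marquardt polish of all
#' parameters.  Runs whose polished fit is singular -- two rates coinciding
#' within their 95\% confidence intervals, or a rate consistent with 0 at
#' 95\% -- are discarded; among the remaining runs the fit with the smallest
#' residual sum of squares is returned.
#'
#' @param curve a \code{"relaxation_curve"}.
#' @param N number of exponentials (>= 1); the curve must have more than
#'   2N + 2 points.
#' @param F_values DE weighting factors swept (default 0.1, 0.2, ..., 1.0).
#' @param seed integer; the DE run for each (N, F) is deterministically
#'   seeded from it.
#' @param k_bounds search bounds for the rates (1/s).
#' @param NP,maxgen DE population size and generation budget.
#' @return An object of class \code{"multiexp_fit"}: offset \code{A0},
#'   \code{amplitudes}, \code{rates} (ascending) with standard errors and
#'   95\% confidence intervals, \code{rss}, \code{aicc}, \code{N}.
#' @seealso \code{\link{select_model_order}}, \code{\link{extract_kobs}}
#' @export
fit_multiexponential <- function(curve, N, F_values = seq(0.1, 1, by = 0.1),
                                 seed = 1L, k_bounds = c(1e-3, 1e5),
                                 NP = NULL, maxgen = NULL) {
  res <- fit_multiexp_core(curve, N, F_values, seed, k_bounds, NP, maxgen)
  if (is.null(res$best))
    fit_failure(sprintf("no non-singular %d-exponential fit found", N))
  res$best
}

# Workhorse behind fit_multiexponential: returns the best non-singular fit
# (or NULL) together with all near-optimal polished candidate
# decompositions, singular ones included -- the candidates of an order with
# no surviving fit still inform the slow-rate ambiguity.
fit_multiexp_core <- function(curve, N, F_values = seq(0.1, 1, by = 0.1),
                              seed = 1L, k_bounds = c(1e-3, 1e5),
                              NP = NULL, maxgen = NULL) {
  # search effort grows with the number of rates: high orders have crowded
  # near-degenerate optima (harmonic stacks) that a small population misses
  if (is.null(NP)) NP <- max(12L, 6L * N)
  if (is.null(maxgen)) maxgen <- 50L + 20L * N
  stopifnot(inherits(curve, "relaxation_curve"), N >= 1)
  t <- curve$times
  y <- curve$observed
  n <- length(y)
  if (n <= 2 * N + 2)
    stop("curve must have more than 2N + 2 points", call. = FALSE)
  # a decay slower than about the observation window is indistinguishable
  # from the offset A0, so such rates are excluded from the search
  k_bounds[1] <- max(k_bounds[1], 0.5 / max(t))
  lower <- rep(log10(k_bounds[1]), N)
  upper <- rep(log10(k_bounds[2]), N)
  # the DE stage only needs to locate the basin; on dense curves it runs on
  # a thinned subsample, and the full data are used for the polish
  sub <- if (n > 450) round(seq(1L, n, length.out = 300L)) else seq_len(n)
  ts <- t[sub]
  ys <- y[sub]
  # heuristic seeds: rates spanning the observed time window
  span <- log10(c(1 / max(t), 1 / max(min(t), 1e-12)))
  init <- rbind(seq(span[1], span[2], length.out = N),
                seq(span[1], mean(span), length.out = N))
  best <- NULL
  cands <- list()
  polished <- list()  # starts already polished (across the whole F sweep)
  for (F in F_values) {
    de <- de_optimize(function(lk) varpro_rss(lk, ts, ys),
                      lower, upper, NP = NP, maxgen = maxgen, F = F,
                      seed = seed * 1009L + N * 101L + round(100 * F),
                      init = init)
    # polish several distinct candidate decompositions from this run, not
    # just the run optimum: the least-squares optimum is frequently a
    # singular result (to be discarded), while a near-optimal non-singular
    # decomposition survives.  Starts already polished in an earlier run
    # are skipped.
    for (lk in distinct_members(de$pop, de$cost)) {
      if (any(vapply(polished, function(z) max(abs(z - lk)) < 0.05,
                     logical(1)))) next
      polished[[length(polished) + 1]] <- lk
      k <- sort(10^lk)
      X <- cbind(1, exp_decay(t, k))
      beta <- .lm.fit(X, y)$coefficients
      pol <- polish_multiexp(c(beta[1], beta[-1], k), t, y, N, k_bounds)
      if (is.null(pol)) next
      fit <- finalize_multiexp(pol, N, n, F)
      # a slowest rate pinned at the window-identifiability bound is a
      # baseline artifact, not an alternative placement of the slow mode
      if (fit$kmin_eff > 1.3 * k_bounds[1])
        cands[[length(cands) + 1]] <-
          c(rss = fit$rss, aicc = fit$aicc, kmin = fit$kmin_eff)
      if (!fit$valid) next
      if (is.null(best) || fit$rss < best$rss) best <- fit
    }
  }
  cm <- do.call(rbind, cands)
  if (!is.null(cm))
    cm <- cm[cm[, "rss"] <= min(cm[, "rss"]) * (1 + 20 / n), , drop = FALSE]
  if (!is.null(best)) {
    best$candidates <- cm
    best$slow_candidates <-
      if (!is.null(cm)) cm[, c("kmin", "aicc"), drop = FALSE] else NULL
  }
  list(best = best, candidates = cm)
}

#' Choose the number of exponentials by corrected AIC
#'
#' Fits the curve with N = 1, ..., \code{N_max} exponentials and returns the
#' valid fit minimizing AICc = n ln(RSS/n) + 2p + 2p(p+1)/(n-p-1) with
#' p = 2N + 1 parameters.  Orders for which no non-singular fit exists are
#' skipped; the scan stops early once AICc has worsened on two consecutive
#' orders.
#'
#' @inheritParams fit_multiexponential
#' @param N_max largest number of exponentials tried (default 5).
#' @param ... passed to \code{\link{fit_multiexponential}}.
#' @return The selected \code{"multiexp_fit"}.
#' @export
select_model_order <- function(curve, N_max = 5L, seed = 1L, ...) {
  best <- NULL
  pools <- list()
  worse <- 0L
  for (N in seq_len(N_max)) {
    res <- fit_multiexp_core(curve, N, seed = seed, ...)
    pools[[length(pools) + 1]] <- res$candidates
    fit <- res$best
    if (is.null(fit)) next
    if (is.null(best) || fit$aicc < best$aicc) {
      best <- fit
      worse <- 0L
    } else {
      worse <- worse + 1L
      if (worse >= 2L) break
    }
  }
  if (is.null(best))
    fit_failure("no valid multi-exponential fit at any order")
  # pool the dominant-rate candidates of every order tried -- singular fits
  # included -- keeping those with substantial AICc support (delta AICc <= 4
  # relative to the best candidate anywhere): model-order and decomposition
  # ambiguity is part of the slow rate's uncertainty
  cm <- do.call(rbind, pools)
  if (!is.null(cm))
    best$slow_candidates <-
      cm[cm[, "aicc"] <= min(cm[, "aicc"]) + 4, c("kmin", "aicc"),
         drop = FALSE]
  best
}

#' Extract the dominant relaxation rate from a multi-exponential fit
#'
#' The dominant rate k_obs is identified as the smallest fitted rate.  Its
#' 1-sigma uncertainty combines the standard error from the fit covariance
#' with the spread of the dominant rate over near-optimal non-singular fits
#' (different optimizer restarts and AICc-supported model orders), which
#' captures the basin ambiguity of weakly resolved slow modes.
#'
#' @param fit a \code{"multiexp_fit"}.
#' @param P0,L0 mixing conditions the curve was recorded at (uM); carried
#'   into the estimate.
#' @return A list with \code{kobs} (1/s), \code{sigma} (1/s), \code{P0},
#'   \code{L0} and \code{N}.
#' @export
extract_kobs <- function(fit, P0 = NA_real_, L0 = NA_real_) {
  stopifnot(inherits(fit, "multiexp_fit"))
  i <- which.min(fit$rates)
  sigma <- fit$se_rates[i]
  # add the dominant-rate spread over near-optimal valid fits (restart
  # schedule and supported model orders) in quadrature: when the slow mode
  # is weakly resolved, neighbouring decompositions of almost equal
  # residual place it differently, and the single-optimum standard error
  # understates the uncertainty
  sc <- fit$slow_candidates
  if (!is.null(sc) && nrow(sc) > 1) {
    # Akaike-weighted rms deviation of the candidate dominant rates from
    # the estimate: candidates with little information-criterion support
    # contribute little
    w <- exp(-(sc[, "aicc"] - min(sc[, "aicc"])) / 2)
    dev2 <- sum(w * (sc[, "kmin"] - fit$rates[i])^2) / sum(w)
    sigma <- sqrt(sigma^2 + dev2)
  }
  list(kobs = fit$rates[i], sigma = sigma, P0 = P0, L0 = L0, N = fit$N)
}

#' Build a k_obs table from a set of relaxation curves
#'
#' Runs AICc model selection on every curve and collects the dominant rate
#' and its uncertainty, together with the curve's mixing conditions.
#'
#' @param curves list of \code{"relaxation_curve"} objects (e.g. from
#'   \code{\link{make_fixture}}).
#' @param N_max,seed,... passed to \code{\link{select_model_order}}; each
#'   curve gets a distinct deterministic seed derived from \code{seed}.
#' @return A data.frame with columns \code{P0_uM}, \code{L0_uM},
#'   \code{kobs_per_s}, \code{sigma_per_s}, \code{N_selected}.
#' @export
fit_kobs_table <- function(curves, N_max = 5L, seed = 1L, ...) {
  rows <- lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    fit <- select_model_order(cv, N_max = N_max, seed = seed + 7L * i, ...)
    est <- extract_kobs(fit, P0 = cv$meta$P0, L0 = cv$meta$L0)
    data.frame(P0_uM = est$P0, L0_uM = est$L0, kobs_per_s = est$kobs,
               sigma_per_s = est$sigma, N_selected = est$N)
  })
  do.call(rbind, rows)
}

#' Write / read a k_obs table as delimited text
#'
#' Tab-separated columns \code{P0_uM, L0_uM, kobs_per_s, sigma_per_s}
#' (optionally \code{N_selected}).
#'
#' @param table a data.frame as returned by \code{\link{fit_kobs_table}}.
#' @param path file path.
#' @return \code{write_kobs_table}: \code{path} invisibly;
#'   \code{read_kobs_table}: the data.frame.
#' @export
write_kobs_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_kobs_table
#' @export
read_kobs_table <- function(path) {
  tab <- utils::read.delim(path)
  need <- c("P0_uM", "L0_uM", "kobs_per_s", "sigma_per_s")
  if (!all(need %in% names(tab)))
    stop("k_obs table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  tab
}
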