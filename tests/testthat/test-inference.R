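test_that("excited-state occupancy arithmetic", {
  expect_equal(100 * excited_state_occupancy(33, 990), 3.2,
               tolerance = 0.01)
  expect_equal(100 * excited_state_occupancy(23, 920), 2.4,
               tolerance = 0.02)
  expect_equal(excited_state_occupancy(1, 10), 1 / 11)
  expect_equal(excited_state_occupancy(1, 40), 1 / 41)
  expect_equal(excited_state_occupancy(5, 5), 0.5)
  expect_error(excited_state_occupancy(-1, 2), "invalid")
  expect_error(excited_state_occupancy(1, 0), "invalid")
})

test_that("exact closed-form data are recovered exactly", {
  L0 <- 10^seq(-1, 1, length.out = 8)
  for (mech in c("CS", "IF")) {
    sch <- if (mech == "CS") cs_ref() else if_ref()
    tab <- kobs_table_closed_form(sch, P0 = c(0.5, 1.5), L0 = L0,
                                  rel_sigma = 0)
    tab$sigma_per_s <- 0.01  # nominal weights; data are exact
    fit <- fit_kobs_curve(tab, mech, Kd = sch$Kd)
    expect_lt(fit$chisq, 1e-6)
    expect_equal(unname(coef(fit)),
                 c(sch$k_e, sch$k_r, sch$k_minus), tolerance = 1e-3)
    expect_equal(fit$Pe, sch$k_e / (sch$k_e + sch$k_r), tolerance = 1e-3)
  }
})

test_that("noisy closed-form data are recovered within profile intervals", {
  sch <- cs_ref()
  L0 <- 10^seq(-1, 1, length.out = 10)
  truth <- c(k_e = 10, k_r = 100, k_minus = 1)
  kr_cover <- 0
  for (s in c(5, 14, 23)) {
    tab <- kobs_table_closed_form(sch, P0 = c(0.5, 1, 1.5), L0 = L0,
                                  rel_sigma = 0.02, seed = s)
    fit <- fit_kobs_curve(tab, "CS", Kd = sch$Kd)
    ci <- confint(fit)
    # the sharply identified rates are covered every time
    expect_true(all(ci[c("k_e", "k_minus"), 1] <= truth[c(1, 3)] &
                      truth[c(1, 3)] <= ci[c("k_e", "k_minus"), 2]))
    kr_cover <- kr_cover +
      (ci["k_r", 1] <= 100 && 100 <= ci["k_r", 2])
    # the reduced chi-square is of order one for honest errors
    expect_lt(fit$chisq / fit$df.residual, 3)
  }
  # k_r is weakly identified (near quasi-steady state); its 95% profile
  # interval covers the generating value in most replicates
  expect_gte(kr_cover, 2)
})

test_that("the constraint k_r >= n k_e is enforced as a hard bound", {
  sch <- if_ref()  # truth k_r = 10 k_e
  L0 <- 10^seq(-1, 1, length.out = 8)
  tab <- kobs_table_closed_form(sch, P0 = 2, L0 = L0, rel_sigma = 0)
  tab$sigma_per_s <- 0.01
  fit <- fit_kobs_curve(tab, "IF", sch$Kd, constraint_n = 40)
  expect_gte(coef(fit)[["k_r"]], 40 * coef(fit)[["k_e"]] * (1 - 1e-9))
  # unconstrained fit prefers the true ratio of 10
  fit0 <- fit_kobs_curve(tab, "IF", sch$Kd)
  expect_equal(coef(fit0)[["k_r"]] / coef(fit0)[["k_e"]], 10,
               tolerance = 0.01)
  expect_lt(fit0$chisq, fit$chisq)
})

test_that("kobs_fit behaves like a standard modelling object", {
  sch <- cs_ref()
  tab <- kobs_table_closed_form(sch, P0 = 1, L0 = 10^seq(-1, 1, 0.25),
                                rel_sigma = 0.02, seed = 3)
  fit <- fit_kobs_curve(tab, "CS", sch$Kd)
  expect_s3_class(fit, "kobs_fit")
  expect_named(coef(fit), c("k_e", "k_r", "k_minus"))
  expect_equal(dim(vcov(fit)), c(3, 3))
  expect_length(fitted(fit), nrow(tab))
  expect_length(residuals(fit), nrow(tab))
  expect_equal(sum(residuals(fit, "pearson")^2), fit$chisq,
               tolerance = 1e-10)
  pr <- predict(fit, data.frame(P0_uM = 1, L0_uM = c(0.5, 5)))
  expect_length(pr, 2)
  expect_true(all(pr > 0))
  out <- capture.output(print(summary(fit)))
  expect_true(any(grepl("chi-square", out)))
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$kobs_per_s, sims[[2]]$kobs_per_s))
  expect_s3_class(logLik(fit), "logLik")
})

test_that("log-likelihood follows the Gaussian error model", {
  sch <- cs_ref()
  tab <- kobs_table_closed_form(sch, P0 = 1, L0 = c(0.2, 1, 5),
                                rel_sigma = 0)
  tab$sigma_per_s <- 0.05
  th <- c(10, 100, 1)
  expect_equal(log_likelihood("CS", th, tab, sch$Kd), 0)
  expect_lt(log_likelihood("CS", c(12, 100, 1), tab, sch$Kd), 0)
  # constraint indicator zeroes the likelihood
  expect_identical(log_likelihood("CS", c(10, 100, 1), tab, sch$Kd,
                                  constraint_n = 40), -Inf)
  # quadrupling errors scales the residual term by 1/4
  ll1 <- log_likelihood("CS", c(12, 100, 1), tab, sch$Kd)
  tab2 <- tab
  tab2$sigma_per_s <- 2 * tab$sigma_per_s
  expect_equal(log_likelihood("CS", c(12, 100, 1), tab2, sch$Kd),
               ll1 / 4)
})

test_that("Bayes factors are reciprocal under swapping and seeded", {
  sch <- cs_ref()
  tab <- kobs_table_closed_form(sch, P0 = c(0.5, 1.5),
                                L0 = 10^seq(-1, 1, length.out = 8),
                                rel_sigma = 0.05, seed = 2)
  b1 <- bayes_factor(tab, sch$Kd, ndraws = 2e4, seed = 7)
  b2 <- bayes_factor(tab, sch$Kd, ndraws = 2e4, seed = 7)
  expect_identical(b1$K, b2$K)
  bswap <- bayes_factor(tab, sch$Kd, ndraws = 2e4, seed = 7, swap = TRUE)
  expect_equal(bswap$K, 1 / b1$K, tolerance = 1e-12)
  # CS-generated data favour CS
  expect_gt(b1$log10_K, 0)
})

test_that("Monte-Carlo error of log10 K shrinks with the draw count", {
  sch <- cs_ref()
  tab <- kobs_table_closed_form(sch, P0 = 1,
                                L0 = 10^seq(-1, 1, length.out = 6),
                                rel_sigma = 0.1, seed = 4)
  se1 <- bayes_factor(tab, sch$Kd, ndraws = 1e4, seed = 3)$se_log10_K
  se2 <- bayes_factor(tab, sch$Kd, ndraws = 8e4, seed = 3)$se_log10_K
  expect_lt(se2, se1)
})

test_that("Bayes factors calibrate to the generating mechanism", {
  # over seeded replicates, IF data give K < 1 and CS data K > 1
  L0 <- 10^seq(-1, 1, length.out = 8)
  n_cs <- 0
  n_if <- 0
  for (s in 1:5) {
    tcs <- kobs_table_closed_form(cs_ref(), P0 = c(0.5, 1.5), L0 = L0,
                                  rel_sigma = 0.05, seed = 100 + s)
    n_cs <- n_cs + (bayes_factor(tcs, 0.11, ndraws = 2e4,
                                 seed = s)$log10_K > 0)
    tif <- kobs_table_closed_form(if_ref(), P0 = c(1, 3), L0 = L0,
                                  rel_sigma = 0.05, seed = 200 + s)
    n_if <- n_if + (bayes_factor(tif, 1 / 11, ndraws = 2e4,
                                 seed = s)$log10_K < 0)
  }
  expect_gte(n_cs, 4)
  expect_gte(n_if, 4)
})

test_that("classification refuses insufficient data", {
  sch <- cs_ref()
  tab <- kobs_table_closed_form(sch, P0 = 1, L0 = c(0.3, 1, 3),
                                rel_sigma = 0.02)
  expect_error(classify_mechanism(tab, sch$Kd), "insufficient|at least 3")
})

test_that("monotone decreasing kobs flags conformational selection", {
  sch_dec <- binding_scheme("CS", k_e = 1, k_r = 100, k_plus = 100,
                            k_minus = 10)  # k_e < k_-: monotone decrease
  tab <- kobs_table_closed_form(sch_dec, P0 = 2,
                                L0 = 10^seq(-1, 1, length.out = 10),
                                rel_sigma = 0.02, seed = 6)
  rep <- classify_mechanism(tab, sch_dec$Kd, ndraws = 2e4, seed = 2)
  expect_true(rep$monotone_decreasing)
  expect_true(rep$cs_consistent)
  expect_false(rep$has_minimum)
})

test_that("classification separates the two reference mechanisms", {
  L0 <- 10^seq(-1, 1, length.out = 10)
  tcs <- kobs_table_closed_form(cs_ref(), P0 = c(0.5, 1.5), L0 = L0,
                                rel_sigma = 0.03, seed = 31)
  rcs <- classify_mechanism(tcs, 0.11, ndraws = 5e4, seed = 8)
  expect_identical(rcs$verdict, "CS")
  expect_lt(rcs$chisq[["CS"]], rcs$chisq[["IF"]])
  tif <- kobs_table_closed_form(if_ref(), P0 = c(1, 3), L0 = L0,
                                rel_sigma = 0.03, seed = 32)
  rif <- classify_mechanism(tif, 1 / 11, ndraws = 5e4, seed = 8)
  expect_identical(rif$verdict, "IF")
  expect_lt(rif$chisq[["IF"]], rif$chisq[["CS"]])
  # induced fit shows an interior minimum with a small symmetry score
  expect_true(rif$has_minimum)
  expect_lt(rif$symmetry_score,
            0.2 * diff(range(tif$kobs_per_s)))
  # report serialization
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_report(rif, path)
  js <- jsonlite::fromJSON(path)
  expect_identical(js$verdict, "IF")
  expect_equal(js$fits$IF$estimate$k_r, coef(rif$fit_if)[["k_r"]])
})

test_that("prior specification validates its bounds", {
  expect_error(prior_spec(0, 10), "bounds")
  expect_error(prior_spec(10, 1), "bounds")
  p <- prior_spec(1e-2, 1e4, "linear")
  expect_identical(p$measure, "linear")
})
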