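test_that("closed-form rates equal the eigenvalues of minus the Jacobian", {
  set.seed(42)
  for (i in 1:250) {
    for (mech in c("IF", "CS")) {
      sch <- random_scheme(mech)
      P0 <- 10^runif(1, -2, 2)
      L0 <- 10^runif(1, -3, 3)
      ev <- eigen_rates(sch, P0, L0)
      rr <- relaxation_rates(sch, P0, L0)
      expect_equal(rr$kobs_per_s, ev[1], tolerance = 1e-10)
      expect_equal(rr$k2_per_s, ev[2], tolerance = 1e-10)
    }
  }
})

test_that("kobs and k2 satisfy the trace and determinant identities", {
  set.seed(43)
  for (i in 1:100) {
    mech <- sample(c("IF", "CS"), 1)
    sch <- random_scheme(mech)
    P0 <- 10^runif(1, -2, 2)
    L0 <- 10^runif(1, -3, 3)
    J <- jacobian_at_equilibrium(sch, P0, L0)
    rr <- relaxation_rates(sch, P0, L0)
    expect_equal(rr$kobs_per_s + rr$k2_per_s, sum(diag(-J)),
                 tolerance = 1e-9)
    expect_equal(rr$kobs_per_s * rr$k2_per_s, det(-J), tolerance = 1e-9)
  }
})

test_that("analytic Jacobian matches central finite differences", {
  set.seed(44)
  for (i in 1:25) {
    mech <- sample(c("IF", "CS"), 1)
    sch <- random_scheme(mech, spread = c(-1, 2))
    P0 <- 10^runif(1, -1, 1)
    L0 <- 10^runif(1, -1, 1)
    eq <- equilibrium_state(sch, P0, L0)
    x0 <- switch(mech, IF = c(eq$L, eq$P2L), CS = c(eq$P2, eq$L))
    J <- jacobian_at_equilibrium(sch, P0, L0)
    h <- 1e-6 * max(P0, L0)
    for (j in 1:2) {
      e <- replace(numeric(2), j, h)
      fd <- (reduced_rhs(sch, P0, L0, x0 + e) -
               reduced_rhs(sch, P0, L0, x0 - e)) / (2 * h)
      expect_equal(unname(J[, j]), fd,
                   tolerance = 1e-5 * max(abs(J)) / max(abs(J[, j])))
    }
  }
})

test_that("the printed induced-fit Jacobian entries are reproduced", {
  sch <- if_ref()
  P0 <- 1.3
  L0 <- 0.7
  eq <- equilibrium_state(sch, P0, L0)
  J <- jacobian_at_equilibrium(sch, P0, L0)
  expect_equal(unname(J[1, ]),
               c(sch$k_plus * (L0 - 2 * eq$L_eq - P0) - sch$k_minus,
                 -sch$k_minus))
  expect_equal(unname(J[2, ]), c(-sch$k_r, -sch$k_e - sch$k_r))
})

test_that("induced-fit kobs at its minimum matches the worked value", {
  sch <- if_ref()
  L0min <- 1 - sch$Kd
  expect_equal(relaxation_rates(sch, 1, L0min)$kobs_per_s, 4.198,
               tolerance = 1e-3)
  # at the minimum, delta = 2 sqrt(P0 Kd)
  expect_equal(relaxation_rates(sch, 1, L0min)$delta, 2 * sqrt(sch$Kd),
               tolerance = 1e-12)
})

test_that("induced-fit kobs is exactly symmetric about L0 = P0 - Kd", {
  set.seed(45)
  for (i in 1:30) {
    sch <- random_scheme("IF")
    P0 <- sch$Kd * 10^runif(1, 0.2, 1.5)  # ensure P0 > Kd
    L0min <- P0 - sch$Kd
    x <- runif(1, 0, L0min)
    kp <- relaxation_rates(sch, P0, L0min + x)$kobs_per_s
    km <- relaxation_rates(sch, P0, L0min - x)$kobs_per_s
    expect_equal(kp, km, tolerance = 1e-12)
  }
})

test_that("induced-fit kobs plateaus at k_e + k_r from below", {
  sch <- if_ref()
  ks <- relaxation_rates(sch, 1, c(1e2, 1e3, 1e4, 1e5))$kobs_per_s
  expect_true(all(diff(ks) > 0))
  expect_true(all(ks < sch$k_e + sch$k_r))
  expect_equal(ks[4], sch$k_e + sch$k_r, tolerance = 1e-3)
})

test_that("conformational-selection limits at small and large L0", {
  sch <- cs_ref()
  # large-ligand limit is the excitation rate
  expect_equal(relaxation_rates(sch, 0.5, 1e4)$kobs_per_s, sch$k_e,
               tolerance = 0.01)
  expect_equal(relaxation_rates(sch, 20, 1e4)$kobs_per_s, sch$k_e,
               tolerance = 0.01)
  # zero-ligand limit: piecewise in P0, against the eigenvalue oracle
  expect_equal(kobs_zero_ligand_limit(sch, 0.5),
               sch$k_minus * (0.5 + sch$Kd) / sch$Kd)
  expect_equal(kobs_zero_ligand_limit(sch, 0.5), 5.545, tolerance = 1e-3)
  expect_equal(kobs_zero_ligand_limit(sch, 20), sch$k_e + sch$k_r)
  for (P0 in c(0.2, 0.5, 2, 5, 11.99, 20, 50)) {
    expect_equal(kobs_zero_ligand_limit(sch, P0),
                 relaxation_rates(sch, P0, 1e-9)$kobs_per_s,
                 tolerance = 1e-3)
  }
  # continuity at the threshold protein concentration
  thr <- sch$Kd * (sch$k_e + sch$k_r - sch$k_minus) / sch$k_minus
  expect_equal(kobs_zero_ligand_limit(sch, thr * (1 + 1e-9)),
               kobs_zero_ligand_limit(sch, thr * (1 - 1e-9)),
               tolerance = 1e-6)
  expect_error(kobs_zero_ligand_limit(if_ref(), 1), "unsupported")
})

test_that("kobs(0) can greatly exceed kobs(infinity) for k_e > k_minus", {
  sch <- cs_ref()
  expect_gt(relaxation_rates(sch, 20, 1e-9)$kobs_per_s,
            5 * relaxation_rates(sch, 20, 1e4)$kobs_per_s)
})

test_that("minimum locations match the closed forms", {
  expect_equal(kobs_minimum_location(if_ref(), 2)$L0_min, 2 - 1 / 11)
  expect_false(kobs_minimum_location(if_ref(), 0.05)$exists)
  mcs <- kobs_minimum_location(cs_ref(), 1.5)
  expect_true(mcs$exists)
  expect_equal(mcs$L0_min_formula, (11 / 9) * 1.5 - 0.11,
               tolerance = 1e-12)
  # numerical minimum of the exact expression agrees within a few percent
  expect_equal(mcs$L0_min_numeric, mcs$L0_min_formula, tolerance = 0.05)
  # monotone decrease (no minimum) when k_e < k_minus
  sch_dec <- binding_scheme("CS", k_e = 1, k_r = 100, k_plus = 100,
                            k_minus = 10)
  expect_false(kobs_minimum_location(sch_dec, 5)$exists)
  ks <- relaxation_rates(sch_dec, 5, 10^seq(-2, 3, length.out = 40))
  expect_true(all(diff(ks$kobs_per_s) < 0))
})

test_that("quasi-steady-state rate behaves as derived", {
  sch <- cs_ref()
  # large-L0 limit is k_e
  expect_equal(qssa_kobs(sch, 1.5, 1e6), sch$k_e, tolerance = 1e-3)
  # derivative vanishes at the closed-form minimum location
  L0min <- (11 / 9) * 1.5 - 0.11
  h <- 1e-5
  d <- (qssa_kobs(sch, 1.5, L0min + h) - qssa_kobs(sch, 1.5, L0min - h)) /
    (2 * h)
  expect_lt(abs(d), 1e-5)
  # argmin of the qssa expression equals the formula
  am <- optimize(function(l) qssa_kobs(sch, 1.5, l), c(1e-3, 30))$minimum
  expect_equal(am, L0min, tolerance = 1e-4)
  # good approximation of the exact rate for k_r >> k_e
  L0 <- 10^seq(log10(0.1), 1, length.out = 25)
  expect_equal(qssa_kobs(sch, 1.5, L0),
               relaxation_rates(sch, 1.5, L0)$kobs_per_s,
               tolerance = 0.1)
  expect_error(qssa_kobs(if_ref(), 1, 1), "unsupported")
})

test_that("pseudo-first-order limits of the intermediates are recovered", {
  P0 <- 0.01
  L0 <- 50
  sch_if <- if_ref()
  rr <- relaxation_rates(sch_if, P0, L0)
  expect_equal(rr$gamma,
               -sch_if$k_e - sch_if$k_r + sch_if$k_minus +
                 sch_if$k_plus * L0,
               tolerance = 0.01)
  sch_cs <- cs_ref()
  rc <- relaxation_rates(sch_cs, P0, L0)
  expect_equal(rc$alpha,
               -sch_cs$k_e + sch_cs$k_r + sch_cs$k_minus +
                 sch_cs$k_plus * L0, tolerance = 0.01)
  expect_equal(rc$beta, 4 * sch_cs$k_r * (sch_cs$k_e - sch_cs$k_minus),
               tolerance = 0.01)
})

test_that("kobs curve export writes the documented columns", {
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  tab <- write_kobs_curve(cs_ref(), P0 = c(0.5, 1), L0 = c(0.1, 1, 10),
                          path = path)
  back <- utils::read.delim(path)
  expect_identical(names(back),
                   c("P0_uM", "L0_uM", "kobs_per_s", "k2_per_s"))
  expect_equal(nrow(back), 6)
  expect_equal(back$kobs_per_s, tab$kobs_per_s, tolerance = 1e-12)
})
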