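# Elasticity, damage, hardening, yield surface and Perzyna viscosity.

test_that("stiffness reduces to the isotropic Lame form in the degenerate limit", {
  E <- 12000; nu <- 0.25
  C <- build_stiffness(iso_elastic(E, nu))
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C_iso <- matrix(0, 6, 6)
  C_iso[1:3, 1:3] <- lambda
  diag(C_iso) <- c(rep(lambda + 2 * mu, 3), rep(mu, 3))
  expect_equal(unname(C), C_iso, tolerance = 1e-12)
})

test_that("cortical stiffness is SPD with axis 1 stiffest and matches the compliance-inversion oracle", {
  C <- build_stiffness(cortical$elastic)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_gt(C[1, 1], C[2, 2])
  expect_equal(C[2, 2], C[3, 3], tolerance = 1e-10)

  # independent oracle: assemble the textbook orthotropic compliance from
  # the engineering constants and invert it numerically
  e <- cortical$elastic
  S <- diag(c(1 / e$E1, 1 / e$E2, 1 / e$E3, 1 / e$G12, 1 / e$G23, 1 / e$G31))
  S[1, 2] <- S[2, 1] <- -e$nu12 / e$E1
  S[2, 3] <- S[3, 2] <- -e$nu23 / e$E2
  S[1, 3] <- S[3, 1] <- -e$nu31 / e$E1
  expect_equal(unname(C), unname(solve(S)), tolerance = 1e-10)
})

test_that("compliance is the symmetric inverse of stiffness for both presets", {
  for (p in list(cortical, trabecular)) {
    S <- build_compliance(p$elastic)
    C <- build_stiffness(p$elastic)
    expect_equal(unname(S %*% C), diag(6), tolerance = 1e-10)
    expect_lt(max(abs(S - t(S))), 1e-12 * max(abs(S)))
    expect_equal(S[1, 1], 1 / p$elastic$E1)
  }
})

test_that("inadmissible elastic sets are rejected with an eigenvalue diagnostic", {
  expect_error(
    elastic_parameters(100, 100, 100, 0.7, 0.7, 0.7, 40, 40, 40),
    "positive definite", class = "bonevpd_elasticity_error")
})

test_that("damage follows the thresholded exponential law and is monotone in [0,1)", {
  dp <- damage_parameters(k0 = 1e-4, kp = 5)
  expect_identical(damage_value(0, dp), 0)
  expect_identical(damage_value(1e-4, dp), 0)
  expect_equal(damage_value(1e-4 + log(2) / 5, dp), 0.5, tolerance = 1e-12)
  k <- seq(0, 2, length.out = 200)
  D <- damage_value(k, dp)
  expect_true(all(diff(D) >= 0))
  expect_true(all(D >= 0 & D < 1))
  expect_error(damage_value(-0.1, dp), class = "bonevpd_state_error")
})

test_that("hardening starts at 1, saturates at yr, and softens continuously past ks", {
  hp <- cortical$hardening  # yr=5, sh=10.5, ks=0.01, ss=1.5
  expect_identical(hardening_value(0, hp, "original"), 1)
  expect_identical(hardening_value(0, hp, "softening"), 1)
  expect_equal(hardening_value(100, hp, "original"), hp$yr, tolerance = 1e-12)
  # direct evaluation of the first branch at the softening onset
  expect_equal(hardening_value(hp$ks, hp, "softening"),
               1 + 4 * (1 - exp(-0.105)), tolerance = 1e-12)
  # continuity at ks and exponential decay beyond
  eps <- 1e-10
  expect_equal(hardening_value(hp$ks + eps, hp, "softening"),
               hardening_value(hp$ks, hp, "softening"), tolerance = 1e-6)
  k <- seq(0, 0.5, length.out = 300)
  r_orig <- hardening_value(k, hp, "original")
  r_soft <- hardening_value(k, hp, "softening")
  expect_true(all(diff(r_orig) >= 0))
  expect_true(all(r_orig >= 1 & r_orig <= hp$yr))
  # softening branch: bounded by the value at ks, strictly decaying past it
  expect_lte(max(r_soft), hardening_value(hp$ks, hp, "softening") + 1e-12)
  expect_true(all(diff(r_soft[k > hp$ks]) < 0))
  expect_lt(hardening_value(5, hp, "softening"), 1e-2)
})

test_that("yield surface passes through all six uniaxial calibration states for both presets", {
  for (p in list(cortical, trabecular)) {
    yt <- build_yield_tensors(p$yield, p$elastic)
    E <- c(p$elastic$E1, p$elastic$E2, p$elastic$E3)
    for (i in 1:3) {
      for (s in c(E[i] * p$yield$eps0p, -E[i] * p$yield$eps0m)) {
        sig <- replace(rep(0, 6), i, s)
        expect_lt(abs(yield_value(sig, 0, yt, p$hardening)), 1e-8)
      }
    }
  }
})

test_that("symmetric yield strains with no interaction give a centred surface", {
  sc <- symmetric_yield_case()
  expect_equal(sc$yt$A, rep(0, 6), tolerance = 1e-12)
  expect_equal(yield_value(rep(0, 6), 0, sc$yt,
                           cortical$hardening), -1, tolerance = 1e-12)
})

test_that("the fourth-order yield tensor is symmetric positive semidefinite", {
  for (p in list(cortical, trabecular)) {
    AF <- build_yield_tensors(p$yield, p$elastic)$Afour
    expect_equal(AF, t(AF), tolerance = 1e-12)
    ev <- eigen(AF, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-15 * max(ev))
  }
})

test_that("an over-strong interaction coefficient is rejected as non-convex", {
  expect_error(
    build_yield_tensors(yield_parameters(0.002, 0.002, 1.5), iso_elastic()),
    "indefinite", class = "bonevpd_yield_error")
})

test_that("yield value is degree-1 homogeneous about the centre", {
  sc <- symmetric_yield_case()
  sig_y <- c(10000 * 0.002, 0, 0, 0, 0, 0)  # on the surface (A = 0, r = 1)
  expect_lt(abs(yield_value(sig_y, 0, sc$yt, cortical$hardening)), 1e-8)
  expect_equal(yield_value(0.5 * sig_y, 0, sc$yt, cortical$hardening), -0.5,
               tolerance = 1e-10)
})

test_that("yield gradient matches central finite differences at random admissible states", {
  set.seed(42)
  yt <- build_yield_tensors(cortical$yield, cortical$elastic)
  hp <- cortical$hardening
  for (rep in 1:100) {
    sig <- stats::rnorm(6, sd = 50)
    kap <- stats::runif(1, 0, 0.02)
    g <- yield_gradient(sig, kap, yt, hp)
    g_fd <- vapply(1:6, function(i) {
      h <- 1e-3
      sp <- sig; sp[i] <- sig[i] + h
      sm <- sig; sm[i] <- sig[i] - h
      (yield_value(sp, kap, yt, hp) - yield_value(sm, kap, yt, hp)) / (2 * h)
    }, numeric(1))
    expect_equal(g, g_fd, tolerance = 1e-6)
  }
})

test_that("yield gradient is degree-0 homogeneous and radial for the centred case", {
  yt <- build_yield_tensors(cortical$yield, cortical$elastic)
  hp <- cortical$hardening
  sig <- c(40, 5, -3, 2, 0, 1)
  r <- hardening_value(0.005, hp)
  d <- sig - r * yt$A
  g1 <- yield_gradient(sig, 0.005, yt, hp)
  g2 <- yield_gradient(r * yt$A + 2 * d, 0.005, yt, hp)
  expect_equal(g1, g2, tolerance = 1e-12)
  expect_error(yield_gradient(r * yt$A, 0.005, yt, hp),
               class = "bonevpd_yield_error")
  # centred symmetric surface: gradient parallel to the stress direction
  sc <- symmetric_yield_case()
  g <- yield_gradient(c(5, 0, 0, 0, 0, 0), 0, sc$yt, hp)
  expect_equal(g[2:6] / g[1], as.numeric(sc$yt$Afour[2:6, 1] / sc$yt$Afour[1, 1]),
               tolerance = 1e-10)
})

test_that("yield evaluation is invariant under a joint rotation of fabric and stress", {
  set.seed(7)
  for (rep in 1:5) {
    Q <- random_rotation()
    yp_rot <- yield_parameters(cortical$yield$eps0p, cortical$yield$eps0m,
                               cortical$yield$xi0,
                               m1 = Q[1, ], m2 = Q[2, ], m3 = Q[3, ])
    yt0 <- build_yield_tensors(cortical$yield, cortical$elastic)
    ytR <- build_yield_tensors(yp_rot, cortical$elastic)
    M <- bonevpd:::bond_stress_matrix(Q)
    sig_m <- stats::rnorm(6, sd = 30)       # stress in the material frame
    sig_g <- solve(M, sig_m)                # same stress in global frame
    expect_equal(yield_value(sig_g, 0.003, ytR, cortical$hardening),
                 yield_value(sig_m, 0.003, yt0, cortical$hardening),
                 tolerance = 1e-9)
  }
})

test_that("Perzyna rate and the overstress function are exact inverses", {
  vp <- cortical$viscosity  # m = 5, eta = 0.01
  expect_identical(perzyna_rate(0, vp), 0)
  expect_equal(perzyna_rate(0.1, vp), 51, tolerance = 1e-12)
  expect_equal(overstress_phi(51, vp), 0.1, tolerance = 1e-12)
  expect_identical(overstress_phi(0, vp), 0)
  for (Y in c(0.01, 0.1, 1, 10)) {
    expect_equal(overstress_phi(perzyna_rate(Y, vp), vp), Y, tolerance = 1e-12)
  }
  # monotone in Y
  Yg <- seq(0, 10, length.out = 200)
  expect_true(all(diff(perzyna_rate(Yg, vp)) > 0))
  # property: inverse pair over random positive (m, eta)
  set.seed(3)
  for (rep in 1:25) {
    vpr <- viscosity_parameters(stats::runif(1, 0.1, 20), stats::runif(1, 1e-4, 1))
    Y <- stats::runif(1, 0, 5)
    expect_equal(overstress_phi(perzyna_rate(Y, vpr), vpr), Y, tolerance = 1e-10)
  }
  expect_error(perzyna_rate(-0.1, vp), class = "bonevpd_state_error")
  expect_error(overstress_phi(-1, vp), class = "bonevpd_state_error")
})

test_that("generalized yield equals Y below the surface at zero flow", {
  sig <- c(5, 0, 0, 0, 0, 0)  # well inside the cortical elastic domain
  yt <- build_yield_tensors(cortical$yield, cortical$elastic)
  Y <- yield_value(sig, 0, yt, cortical$hardening)
  expect_lt(Y, 0)
  expect_equal(generalized_yield(sig, 0, 0, cortical), Y, tolerance = 1e-12)
})
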