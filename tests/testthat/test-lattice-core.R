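test_that("stencils satisfy the quadrature constraints", {
  for (d in c(2L, 3L)) {
    st <- build_stencil(d)
    expect_equal(st$Q, if (d == 2L) 9L else 27L)
    expect_equal(sum(st$weights), 1)
    expect_equal(colSums(st$weights * st$velocities), rep(0, d),
                 ignore_attr = TRUE)
    # second moment isotropy: sum w c c^T = cs2 I
    M <- t(st$velocities) %*% (st$weights * st$velocities)
    expect_equal(M, diag(1 / 3, d), ignore_attr = TRUE, tolerance = 1e-14)
    expect_true(all(st$velocities %in% -1:1))
  }
  expect_error(build_stencil(4), "unsupported")
})

test_that("relaxation frequencies follow the viscous and magic formulas", {
  for (d in c(2L, 3L)) {
    st <- build_stencil(d)
    for (tau in c(0.6, 1)) {
      rv <- relaxation_frequencies(tau, st)
      expect_length(rv$omega, st$Q)
      expect_true(all(rv$omega > 0 & rv$omega < 2))
      expect_equal(unname(rv$omega[rv$roles == "viscous"]),
                   rep(1 / tau, sum(rv$roles == "viscous")))
      s <- 1 / tau
      expect_equal(unname(rv$omega[rv$roles == "magic"]),
                   rep(8 * (2 - s) / (8 - s), sum(rv$roles == "magic")))
    }
    # tau = 1: viscous entries 1, magic entries 8/7
    rv1 <- relaxation_frequencies(1, st)
    expect_equal(unname(rv1$omega[rv1$roles == "magic"][1]), 8 / 7)
  }
  expect_error(relaxation_frequencies(0.5, build_stencil(2)), "tau")
  expect_error(relaxation_frequencies(0.4, build_stencil(3)), "tau")
})

test_that("viscosity follows nu = cs2 (tau - 1/2)", {
  expect_equal(viscosity(1), 1 / 6)
  expect_equal(viscosity(2), 0.5)
  expect_equal(viscosity(0.6), 1 / 30)
  expect_error(viscosity(0.5), "tau")
})

test_that("equilibrium has the exact conserved moments", {
  for (d in c(2L, 3L)) {
    st <- build_stencil(d)
    # at rest: f = w * rho
    expect_equal(equilibrium(2.5, numeric(d), st), 2.5 * st$weights)
    set.seed(42)
    for (rep in 1:5) {
      rho <- runif(1, 0.5, 2)
      u <- runif(d, -0.1, 0.1)
      f <- equilibrium(rho, u, st)
      expect_equal(sum(f), rho, tolerance = 1e-14)
      expect_equal(colSums(st$velocities * f), rho * u,
                   ignore_attr = TRUE, tolerance = 1e-13)
    }
  }
  expect_error(equilibrium(-1, c(0, 0), build_stencil(2)), "positive")
})

test_that("central-moment transform matches the dense-matrix oracle and inverts", {
  set.seed(7)
  for (d in c(2L, 3L)) {
    st <- build_stencil(d)
    for (rep in 1:5) {
      f <- runif(st$Q)
      u <- runif(d, -0.2, 0.2)
      k <- to_central_moments(f, u, st)
      T <- oracle_cm_matrix(u, st)
      expect_equal(unname(k), as.vector(T %*% f), tolerance = 1e-12)
      # zeroth moment is the density regardless of the shift
      expect_equal(unname(k[1]), sum(f), tolerance = 1e-12)
      # bijection
      expect_equal(from_central_moments(k, u, st), f, tolerance = 1e-12)
    }
    # at u = 0 central moments equal raw moments
    f <- runif(st$Q)
    k0 <- to_central_moments(f, numeric(d), st)
    expect_equal(unname(k0), as.vector(oracle_cm_matrix(numeric(d), st) %*% f),
                 tolerance = 1e-13)
  }
})

test_that("collision conserves invariants and fixes the equilibrium", {
  set.seed(11)
  for (d in c(2L, 3L)) {
    st <- build_stencil(d)
    rv <- relaxation_frequencies(0.8, st)
    # equilibrium is a fixed point
    u0 <- runif(d, -0.05, 0.05)
    feq <- equilibrium(1.2, u0, st)
    expect_equal(collide(feq, u0, rv), feq, tolerance = 1e-13)
    # with all omegas 1 the output is the equilibrium
    rv1 <- rv; rv1$omega[] <- 1
    f <- runif(st$Q)
    u <- colSums(st$velocities * f) / sum(f)
    out1 <- collide(f, u, rv1)
    expect_equal(out1, equilibrium(sum(f), u, st), tolerance = 1e-12)
    # mass and momentum conserved for random states
    for (rep in 1:5) {
      f <- runif(st$Q)
      u <- colSums(st$velocities * f) / sum(f)
      out <- collide(f, u, rv)
      expect_equal(sum(out), sum(f), tolerance = 1e-12)
      expect_equal(colSums(st$velocities * out), colSums(st$velocities * f),
                   tolerance = 1e-12)
    }
  }
})

test_that("uniform relaxation reduces the central-moment operator to BGK", {
  set.seed(13)
  for (d in c(2L, 3L)) {
    st <- build_stencil(d)
    for (tau in c(0.7, 1.3)) {
      rv <- relaxation_frequencies(tau, st)
      rv$omega[] <- 1 / tau
      for (rep in 1:3) {
        f <- runif(st$Q, 0.1, 1)
        F <- runif(d, -1e-4, 1e-4)
        rho <- sum(f)
        u <- (colSums(st$velocities * f) + F / 2) / rho
        cm <- apply_force(collide(f, u, rv), F, rho, u, rv)$f
        bgk <- oracle_bgk_step(f, tau, F, st)
        expect_equal(cm, bgk, tolerance = 1e-12)
      }
    }
  }
})

test_that("the force step adds exactly F of momentum and none at F = 0", {
  set.seed(17)
  for (d in c(2L, 3L)) {
    st <- build_stencil(d)
    rv <- relaxation_frequencies(0.9, st)
    f <- runif(st$Q, 0.1, 1)
    rho <- sum(f)
    F0 <- numeric(d)
    u <- colSums(st$velocities * f) / rho
    expect_equal(apply_force(f, F0, rho, u, rv)$f, f)
    F <- runif(d, -1e-3, 1e-3)
    u <- (colSums(st$velocities * f) + F / 2) / rho
    fc <- collide(f, u, rv)
    ff <- apply_force(fc, F, rho, u, rv)$f
    expect_equal(colSums(st$velocities * ff) - colSums(st$velocities * f), F,
                 tolerance = 1e-10)
    expect_equal(sum(ff), sum(f), tolerance = 1e-13)
  }
})

test_that("streaming is a mass-preserving permutation with single-cell moves", {
  geom <- pore_geometry(array(FALSE, c(4, 5)))
  field <- lbm_field(geom)
  st <- field$stencil
  # uniform populations are unchanged
  streamed <- stream(field)
  expect_equal(streamed$f, field$f)
  # a single population moves exactly one cell along its velocity
  field2 <- field
  field2$f[,, ] <- 0
  field2$f[2, 3, 6] <- 1   # q = 6 -> (a, b) = (0, 1) wait; check below
  ci <- st$velocities[6, ]
  out <- stream(field2)
  expect_equal(out$f[2 + ci[1], 3 + ci[2], 6], 1)
  expect_equal(sum(out$f), 1)
  # random field: total per-direction mass conserved under periodic wrap
  set.seed(3)
  field3 <- field
  field3$f <- array(runif(length(field$f)), dim = dim(field$f))
  out3 <- stream(field3)
  for (q in seq_len(st$Q)) {
    expect_equal(sum(out3$f[, , q]), sum(field3$f[, , q]), tolerance = 1e-12)
  }
})

test_that("macroscopics recover the imposed state and P = rho/3", {
  geom <- pore_geometry(array(FALSE, c(4, 4)))
  field <- lbm_field(geom, rho = 1.3)
  m <- macroscopics(field)
  expect_equal(as.vector(m$rho), rep(1.3, 16), tolerance = 1e-14)
  expect_equal(max(abs(m$u[[1]])), 0)
  expect_equal(m$P, m$rho / 3)
})
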