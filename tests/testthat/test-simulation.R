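test_that("the fused engine reproduces the composed node-level operations", {
  set.seed(23)
  solid <- random_mask(c(6, 5), 0.25, seed = 23)
  geom <- pore_geometry(solid)
  F <- c(1e-4, -5e-5)
  tau <- 0.8
  # engine, 3 iterations
  res <- poreflow:::cpp_run_lbm(geom$solid, dim(geom$solid), tau, F,
                                1e-300, 1L, 3L, 10, TRUE)
  # composed R reference
  field <- lbm_field(geom)
  for (i in 1:3) field <- r_reference_step(field, tau, F)
  fmat <- matrix(field$f, ncol = field$stencil$Q)
  for (k in seq_len(nrow(res$f))) {
    g <- res$coords[k, 1] + (res$coords[k, 2] - 1) * dim(solid)[1]
    expect_equal(unname(res$f[k, ]), unname(fmat[g, ]), tolerance = 1e-12)
  }
})

test_that("an enclosed fluid region conserves mass under bounce-back", {
  solid <- array(TRUE, c(8, 8))
  solid[3:6, 3:6] <- FALSE
  geom <- pore_geometry(solid)
  res <- poreflow:::cpp_run_lbm(geom$solid, dim(geom$solid), 0.7, c(0, 0),
                                1e-300, 100L, 1000L, 10, TRUE)
  expect_equal(sum(res$f), 16, tolerance = 1e-12)  # 16 nodes at rho = 1
})

test_that("l2_error matches closed forms", {
  x <- matrix(runif(20), 4)
  expect_equal(l2_error(x, x), 0)
  expect_equal(l2_error(x * 1.05, x), 0.05, tolerance = 1e-12)
  expect_equal(l2_error(-x, x), 2)
  expect_error(l2_error(x, x * 0), "zero")
})

test_that("unit conversion applies the mlt rules", {
  expect_equal(convert_units(3, "length", 1), 3)
  dx <- 18.7e-6
  expect_equal(convert_units(1, "permeability", dx), dx^2)
  # permeability conversion is independent of dt
  expect_equal(convert_units(2, "permeability", dx, dt = 1),
               convert_units(2, "permeability", dx, dt = 99))
  expect_equal(convert_units(1, "velocity", 2, 4), 0.5)
  expect_equal(convert_units(1, "kinematic_viscosity", 2, 4), 1)
  expect_equal(convert_units(9.869233e-13, "permeability_darcy", 1), 1)
  expect_error(convert_units(1, "banana", 1), "unknown kind")
})

test_that("a quiescent all-fluid box converges immediately with u = 0", {
  geom <- pore_geometry(array(FALSE, c(6, 6)))
  cfg <- simulation_config(tau = 1, force = 0, flow_axis = 1,
                           check_every = 10L)
  sol <- run_to_steady_state(geom, cfg)
  expect_true(sol$converged)
  expect_lte(sol$iterations, 20L)
  expect_equal(max(abs(sol$u[[1]])), 0)
  expect_error(darcy_permeability(sol, geom, cfg), "undefined")
})

test_that("divergence raises a distinct condition", {
  geom <- make_channel(8, 8)
  cfg <- simulation_config(tau = 0.51, force = 0.4, flow_axis = 1,
                           check_every = 10L, max_iter = 2000L)
  expect_error(run_to_steady_state(geom, cfg),
               class = "poreflow_divergence")
})

test_that("channel flow matches the Poiseuille parabola and slit permeability", {
  geom <- make_channel(12, 26)
  H <- 24
  tau <- 0.8
  nu <- viscosity(tau)
  umax <- nu / H                       # Re = 1 scale
  Fmag <- 8 * umax * nu / H^2
  cfg <- simulation_config(tau = tau, force = Fmag, flow_axis = 1L)
  sol <- run_to_steady_state(geom, cfg)
  expect_true(sol$converged)
  err <- poreflow:::poiseuille_l2_error(sol, geom, umax)
  expect_lt(err, 1e-6)
  # slit permeability: pore-space k = H^2/12, superficial k multiplies by
  # the open fraction; discrete node-centre average of the parabola adds
  # the standard + 1/(2 H^2) correction
  perm <- darcy_permeability(sol, geom, cfg)
  k_expect <- H^2 / 12 * (1 + 1 / (2 * H^2)) * H / 26
  expect_equal(perm$k_lattice, k_expect, tolerance = 1e-5)
  expect_equal(perm$k_SI, perm$k_lattice * (geom$voxel_um * 1e-6)^2)
  expect_equal(perm$k_darcy, perm$k_SI / 9.869233e-13)
})

test_that("channel permeability is independent of tau under the magic set", {
  ks <- vapply(c(0.6, 0.8, 1.0), function(tau) {
    geom <- make_channel(6, 18)
    cfg <- simulation_config(tau = tau, force = 1e-8, flow_axis = 1L)
    sol <- run_to_steady_state(geom, cfg)
    darcy_permeability(sol, geom, cfg)$k_lattice
  }, numeric(1))
  expect_lt(diff(range(ks)) / mean(ks), 0.005)
})

test_that("permeability is linear in the driving force (Darcy regime)", {
  geom <- generate_foam(small_foam_params(5, shape = c(40, 40),
                                          perforation_prob = 1))
  cfg1 <- simulation_config(tau = 1, force = 1e-6, flow_axis = 1L)
  cfg2 <- simulation_config(tau = 1, force = 2e-6, flow_axis = 1L)
  s1 <- run_to_steady_state(geom, cfg1)
  s2 <- run_to_steady_state(geom, cfg2)
  p1 <- darcy_permeability(s1, geom, cfg1)
  p2 <- darcy_permeability(s2, geom, cfg2)
  expect_equal(p2$Ud / p1$Ud, 2, tolerance = 1e-3)
  expect_equal(p2$k_lattice / p1$k_lattice, 1, tolerance = 1e-3)
  # Reynolds doubles with the force in the linear regime
  expect_equal(p2$Re / p1$Re, 2, tolerance = 1e-3)
})

test_that("permeability is invariant under periodic translation of the geometry", {
  geom <- generate_foam(small_foam_params(9, shape = c(40, 40),
                                          perforation_prob = 1))
  shift <- c(7, 13)
  solid2 <- geom$solid
  idx <- lapply(1:2, function(d) {
    n <- dim(solid2)[d]
    ((seq_len(n) - 1 - shift[d]) %% n) + 1
  })
  geom2 <- pore_geometry(solid2[idx[[1]], idx[[2]]], geom$voxel_um)
  cfg <- simulation_config(tau = 1, force = 1e-6, flow_axis = 1L)
  k1 <- darcy_permeability(run_to_steady_state(geom, cfg), geom, cfg)$k_lattice
  k2 <- darcy_permeability(run_to_steady_state(geom2, cfg), geom2, cfg)$k_lattice
  expect_equal(k1, k2, tolerance = 1e-6)
})

test_that("flow reverses exactly: k(+x) agrees with k(-x)", {
  geom <- generate_foam(small_foam_params(3, shape = c(48, 48),
                                          perforation_prob = 0.8))
  cfgp <- simulation_config(tau = 1, force = 1e-6, flow_axis = 1L, flow_sign = 1)
  cfgm <- simulation_config(tau = 1, force = 1e-6, flow_axis = 1L, flow_sign = -1)
  kp <- darcy_permeability(run_to_steady_state(geom, cfgp), geom, cfgp)$k_lattice
  km <- darcy_permeability(run_to_steady_state(geom, cfgm), geom, cfgm)$k_lattice
  expect_equal(kp, km, tolerance = 1e-3)
})

test_that("total pressure head decreases along the mean-flow direction", {
  geom <- generate_foam(small_foam_params(11, shape = c(48, 48),
                                          perforation_prob = 1))
  cfg <- simulation_config(tau = 1, force = 1e-6, flow_axis = 1L)
  sol <- run_to_steady_state(geom, cfg)
  # LBM pressure plus the equivalent linear driving head -F*x
  P <- sol$rho / 3
  fluid <- sol$rho > 0
  nx <- dim(P)[1]
  head <- vapply(seq_len(nx), function(i) {
    mean(P[i, ][fluid[i, ]]) - cfg$force * i
  }, numeric(1))
  # gradual decrease: net drop across the domain, and decreasing on the
  # large majority of transverse planes (structure causes local wiggles)
  expect_lt(head[nx], head[1])
  expect_gt(mean(diff(head) < 0), 0.75)
})

test_that("solver output exposes history and glance diagnostics", {
  geom <- make_channel(6, 12)
  cfg <- simulation_config(tau = 1, force = 1e-7, flow_axis = 1L)
  sol <- run_to_steady_state(geom, cfg)
  expect_s3_class(sol$history, "tbl_df")
  expect_true(all(c("iteration", "el2") %in% names(sol$history)))
  g <- glance(sol)
  expect_true(g$converged)
  expect_equal(g$n_fluid, 6 * 10)
  tmp <- tempfile(fileext = ".csv")
  write_convergence_csv(sol, geom, tmp)
  expect_true(file.exists(tmp))
  hist <- utils::read.csv(tmp)
  expect_equal(nrow(hist), nrow(sol$history))
  # running k estimate converges to the reported permeability
  kfinal <- darcy_permeability(sol, geom, cfg)$k_lattice
  expect_equal(hist$k_lattice_running[nrow(hist)], kfinal, tolerance = 1e-6)
  tmpv <- tempfile(fileext = ".vtk")
  write_vtk(sol, tmpv)
  expect_true(any(grepl("STRUCTURED_POINTS", readLines(tmpv, n = 5))))
})
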