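test_that("channel geometry has one-voxel walls and the nominal porosity", {
  geom <- make_channel(12, 10)
  expect_equal(sum(!geom$solid), 12 * 8)
  expect_equal(porosity(geom), 8 / 10)
  expect_true(all(geom$solid[, c(1, 10)]))
  expect_error(make_channel(2, 10), "degenerate")
  g3 <- make_channel(6, 10, 4)
  expect_equal(porosity(g3), 8 / 10)
})

test_that("hexagonal array porosity matches the two-disk analytic value", {
  nx <- 222; ny <- 128
  for (R in c(20, 35)) {
    geom <- make_hexagonal_array(nx, ny, R)
    expect_equal(porosity(geom), 1 - 2 * pi * R^2 / (nx * ny),
                 tolerance = 5e-3)
  }
  # R -> 0 gives porosity -> 1
  expect_gt(porosity(make_hexagonal_array(222, 128, 1)), 0.999)
  expect_error(make_hexagonal_array(100, 60, 40), "overlap")
})

test_that("FCC voxel porosity converges to the analytic void fraction", {
  expect_equal(fcc_porosity(), 1 - pi / (3 * sqrt(2)), tolerance = 1e-15)
  expect_equal(round(fcc_porosity(), 5), 0.25952)
  phis <- vapply(c(32L, 64L, 128L), function(L) porosity(make_fcc(L)),
                 numeric(1))
  errs <- abs(phis - fcc_porosity())
  expect_lt(errs[3], 0.002 * fcc_porosity() + 5e-4)
  expect_lt(errs[3], errs[1])
  expect_error(make_fcc(17), "even")
})

test_that("gebart closed form vanishes at touching porosity and increases", {
  phi_touch <- 1 - pi / (2 * sqrt(3))
  expect_equal(gebart_reference(phi_touch), 0, tolerance = 1e-12)
  # independent evaluation of the printed formula at phi = 0.8
  direct <- 16 / (9 * pi * sqrt(6)) *
    (sqrt(pi / (2 * sqrt(3) * 0.2)) - 1)^(5 / 2)
  expect_equal(gebart_reference(0.8), direct)
  phis <- seq(0.2, 0.9, by = 0.1)
  expect_true(all(diff(gebart_reference(phis)) > 0))
  expect_error(gebart_reference(0.05), "touching")
})

test_that("poiseuille reference obeys its endpoint, midpoint and mean", {
  expect_equal(poiseuille_reference(0, 2, 10), 0)
  expect_equal(poiseuille_reference(10, 2, 10), 0)
  expect_equal(poiseuille_reference(5, 2, 10), 2)
  m <- stats::integrate(poiseuille_reference, 0, 10, umax = 3, L = 10)$value / 10
  expect_equal(m, 2, tolerance = 1e-8)
})

test_that("coarsening follows the strict >50% solid rule", {
  # all-solid block stays solid (needs some fluid elsewhere)
  m <- array(FALSE, c(4, 4))
  m[1:2, 1:2] <- TRUE
  g <- coarsen(pore_geometry(m, 10), 2)
  expect_equal(dim(g$solid), c(2L, 2L))
  expect_true(g$solid[1, 1])
  expect_false(any(g$solid[2, ]))
  expect_equal(g$voxel_um, 20)
  # exact 50% ties become fluid
  m2 <- array(FALSE, c(2, 2))
  m2[1, ] <- TRUE   # 2 of 4 solid
  g2 <- coarsen(pore_geometry(m2, 10), 2)
  expect_false(g2$solid[1, 1])
  # non-divisible dimensions pad with a warning
  m3 <- array(FALSE, c(5, 4)); m3[1, 1] <- TRUE
  expect_warning(coarsen(pore_geometry(m3), 2), "padding")
})

test_that("centred crops share centres and preserve statistics", {
  solid <- random_mask(c(40, 40), 0.4, seed = 31)
  geom <- pore_geometry(solid)
  full <- extract_rev(geom, 40)
  expect_equal(full$solid, geom$solid)
  crop <- extract_rev(geom, 20)
  expect_equal(dim(crop$solid), c(20L, 20L))
  # nested crops share their centre
  inner <- extract_rev(geom, 10)
  expect_equal(extract_rev(crop, 10)$solid, inner$solid)
  # porosity of a crop of a homogeneous random medium is close to the bulk
  # (binomial sampling: sd = sqrt(p(1-p)/n) ~ 0.025 at n = 400)
  expect_lt(abs(porosity(crop) - porosity(geom)), 4 * sqrt(0.6 * 0.4 / 400))
  expect_error(extract_rev(geom, 50), "exceeds")
})

test_that("foam generation is seeded, porosity-accurate and perforation-driven", {
  p <- small_foam_params(7, perforation_prob = 0.5)
  g1 <- generate_foam(p)
  g2 <- generate_foam(p)
  expect_identical(g1$solid, g2$solid)
  # porosity within 0.01 of target across seeds
  for (s in 1:5) {
    g <- generate_foam(small_foam_params(s))
    expect_lt(abs(porosity(g) - 0.70), 0.01)
  }
  # different seeds differ
  expect_false(identical(generate_foam(small_foam_params(1))$solid,
                         generate_foam(small_foam_params(2))$solid))
  # no perforations: many isolated bubbles, usually no spanning path
  # (below the Boolean-disc percolation threshold, ~0.68 area fraction)
  g0 <- generate_foam(small_foam_params(13, perforation_prob = 0,
                                        target_porosity = 0.55))
  g1 <- generate_foam(small_foam_params(13, perforation_prob = 1,
                                        target_porosity = 0.55))
  lab0 <- label_components(g0)
  lab1 <- label_components(g1)
  expect_gt(max(lab0), max(lab1))
  conn0 <- connectivity_flags(lab0, 1L)
  conn1 <- connectivity_flags(lab1, 1L)
  expect_gte(conn1[["main"]], conn0[["main"]])
  expect_equal(conn1[["main"]], 1L)
  expect_true(nrow(attr(g1, "bubbles")) > 3)
})

test_that("TIFF round trip preserves the mask and voxel size", {
  solid <- random_mask(c(12, 9), 0.3, seed = 41)
  geom <- pore_geometry(solid, voxel_um = 25)
  tmp <- tempfile(fileext = ".tif")
  write_geometry_tiff(geom, tmp)
  back <- read_geometry_tiff(tmp)
  expect_identical(back$solid, geom$solid)
  expect_equal(back$voxel_um, 25)
  # 3D stack
  s3 <- random_mask(c(8, 7, 5), 0.3, seed = 43)
  g3 <- pore_geometry(s3, voxel_um = 18.7)
  tmp3 <- tempfile(fileext = ".tif")
  write_geometry_tiff(g3, tmp3)
  b3 <- read_geometry_tiff(tmp3)
  expect_identical(b3$solid, g3$solid)
})
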