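test_that("porosity handles the trivial cases", {
  expect_equal(porosity(pore_geometry(array(FALSE, c(5, 5)))), 1)
  checker <- pore_geometry(outer(1:6, 1:6, function(i, j) (i + j) %% 2 == 0))
  expect_equal(porosity(checker), 0.5)
})

test_that("component labelling matches a flood-fill oracle and is face-connected", {
  # two pores separated by a wall
  m <- array(TRUE, c(7, 5))
  m[2, 2:4] <- FALSE
  m[6, 2:4] <- FALSE
  lab <- label_components(pore_geometry(m))
  expect_equal(max(lab), 2L)
  # diagonal-only touching pores stay separate
  m2 <- array(TRUE, c(4, 4))
  m2[2, 2] <- FALSE
  m2[3, 3] <- FALSE
  expect_equal(max(label_components(pore_geometry(m2))), 2L)
  # random images against the oracle (2D and 3D)
  for (seed in 1:3) {
    s2 <- random_mask(c(9, 8), 0.5, seed)
    lab2 <- label_components(pore_geometry(s2))
    oracle <- oracle_flood_fill(s2)
    expect_equal(max(lab2), max(oracle))
    # same partition: labels must be a bijection of oracle labels
    expect_equal(length(unique(paste(lab2[lab2 > 0], oracle[oracle > 0]))),
                 max(oracle))
    s3 <- random_mask(c(6, 5, 4), 0.5, seed + 10)
    expect_equal(max(label_components(pore_geometry(s3))),
                 max(oracle_flood_fill(s3)))
  }
  # deterministic ordering: label 1 is the largest component
  sizes <- attr(label_components(pore_geometry(random_mask(c(9, 8), 0.5, 1))),
                "sizes")
  expect_true(all(diff(sizes) <= 0))
})

test_that("connectivity flags detect spanning paths per axis", {
  m <- array(TRUE, c(8, 6))
  m[, 3] <- FALSE              # full-width channel along x
  lab <- label_components(pore_geometry(m))
  expect_equal(connectivity_flags(lab, 1L), c(main = 1L, secondary = 0L))
  # channel along y only
  m2 <- array(TRUE, c(8, 6))
  m2[4, ] <- FALSE
  lab2 <- label_components(pore_geometry(m2))
  expect_equal(connectivity_flags(lab2, 1L), c(main = 0L, secondary = 1L))
  # invariance under flip along the flow axis
  lab2f <- label_components(pore_geometry(m2[8:1, ]))
  expect_equal(connectivity_flags(lab2f, 1L), connectivity_flags(lab2, 1L))
})

test_that("effective porosity is the spanning-cluster fraction", {
  m <- array(TRUE, c(10, 6))
  m[, 3] <- FALSE              # spanning channel: 10 voxels
  m[5, 5] <- FALSE             # isolated closed pore
  geom <- pore_geometry(m)
  expect_equal(effective_porosity(geom), 10 / 60)
  expect_lte(effective_porosity(geom), porosity(geom))
  # only isolated pores -> EP = 0
  m0 <- array(TRUE, c(6, 6)); m0[3, 3] <- FALSE
  expect_equal(effective_porosity(pore_geometry(m0)), 0)
  # single spanning component -> EP = porosity
  ch <- make_channel(8, 8)
  expect_equal(effective_porosity(ch), porosity(ch))
})

test_that("local thickness matches slabs, spheres and the exhaustive oracle", {
  # slab of width w: thickness w everywhere to within one voxel of
  # centre-to-centre discretisation
  for (w in c(3, 6)) {
    m <- array(TRUE, c(10, w + 2))
    m[, 2:(w + 1)] <- FALSE
    th <- local_thickness(pore_geometry(m), units = "voxel")
    vals <- unique(as.vector(th[, 2:(w + 1)]))
    expect_length(vals, 1)
    expect_lte(abs(vals - w), 1)
  }
  # disk pore of diameter ~d: maximum thickness ~d
  m <- array(TRUE, c(15, 15))
  ctr <- c(8, 8)
  for (i in 1:15) for (j in 1:15) {
    if (sum((c(i, j) - ctr)^2) <= 4^2) m[i, j] <- FALSE
  }
  th <- local_thickness(pore_geometry(m), units = "voxel")
  expect_equal(max(th, na.rm = TRUE), 2 * (sqrt(min(
    sapply(which(m), function(g) {
      p <- arrayInd(g, dim(m)); sum((p - ctr)^2)
    }))) - 0.5), tolerance = 1e-6)
  # random small images against the exhaustive-sphere oracle
  for (seed in 1:3) {
    s2 <- random_mask(c(12, 10), 0.45, seed + 100)
    th2 <- local_thickness(pore_geometry(s2), units = "voxel")
    expect_equal(th2, oracle_local_thickness(s2), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  s3 <- random_mask(c(7, 6, 6), 0.45, 77)
  th3 <- local_thickness(pore_geometry(s3), units = "voxel")
  expect_equal(th3, oracle_local_thickness(s3), tolerance = 1e-10,
               ignore_attr = TRUE)
  # units scale with voxel size
  g <- pore_geometry(random_mask(c(10, 10), 0.4, 5), voxel_um = 20)
  expect_equal(local_thickness(g),
               local_thickness(g, units = "voxel") * 0.02)
})

test_that("PSD quantiles are volume-weighted, ordered and scale linearly", {
  th <- c(rep(2, 50), rep(6, 50))
  q <- psd_quantiles(th)
  expect_true(q[["D10"]] <= q[["D50"]], q[["D50"]] <= q[["D90"]])
  expect_equal(as.numeric(q[c("D10", "D90")]), c(2, 6))
  expect_gte(q[["D50"]], 2); expect_lte(q[["D50"]], 6)
  # uniform thickness: all quantiles equal it
  expect_equal(as.numeric(psd_quantiles(rep(3.5, 10))), rep(3.5, 3))
  # doubling the voxel size doubles the quantiles
  expect_equal(as.numeric(psd_quantiles(2 * th)),
               2 * as.numeric(psd_quantiles(th)))
  expect_error(psd_quantiles(rep(NA_real_, 4)), "empty")
})

test_that("upsampling an image doubles its D50 within discretisation error", {
  s <- generate_foam(small_foam_params(8, shape = c(32, 32),
                                       perforation_prob = 0.5))$solid
  g1 <- pore_geometry(s, voxel_um = 10)
  up <- s[rep(seq_len(nrow(s)), each = 2), rep(seq_len(ncol(s)), each = 2)]
  g2 <- pore_geometry(up, voxel_um = 10)
  d1 <- psd_quantiles(local_thickness(g1, units = "voxel"))[["D50"]]
  d2 <- psd_quantiles(local_thickness(g2, units = "voxel"))[["D50"]]
  expect_equal(d2 / d1, 2, tolerance = 0.35)
})

test_that("skeletons of canonical shapes give the expected graphs", {
  # straight channel: single straight branch, tortuosity 1
  m <- array(TRUE, c(20, 9))
  m[, 4:6] <- FALSE
  g <- skeletonize(pore_geometry(m))
  expect_true(all(!g$skeleton | !pore_geometry(m)$solid))  # subset of pore
  br <- g$branches[g$branches$valid, ]
  expect_equal(nrow(br), 1)
  expect_equal(br$tortuosity, 1, tolerance = 1e-12)
  # right-angle L: two arms -> tortuosity sqrt(2) for the traced branch
  mL <- array(TRUE, c(12, 12))
  mL[2:11, 2] <- FALSE
  mL[11, 2:11] <- FALSE
  gL <- skeletonize(pore_geometry(mL))
  brL <- gL$branches[gL$branches$valid, ]
  expect_equal(nrow(brL), 1)
  expect_equal(brL$tortuosity, brL$arc / brL$chord)
  expect_equal(brL$tortuosity, sqrt(2), tolerance = 0.12)
  expect_gte(min(gL$branches$tortuosity, na.rm = TRUE), 1)
  # Y shape: one triple point
  mY <- array(TRUE, c(15, 15))
  mY[8, 1:8] <- FALSE
  mY[8:14, 8] <- FALSE
  mY[2:8, 8] <- FALSE
  gY <- skeletonize(pore_geometry(mY))
  jc <- junction_counts(gY)
  expect_equal(jc[["triple"]], 1L)
  expect_equal(jc[["quadruple"]], 0L)
  # X shape: one quadruple point
  mX <- array(TRUE, c(15, 15))
  mX[8, ] <- FALSE
  mX[, 8] <- FALSE
  gX <- skeletonize(pore_geometry(mX))
  jcX <- junction_counts(gX)
  expect_equal(jcX[["quadruple"]], 1L)
  # two disjoint channels: no junctions, component count preserved
  m2 <- array(TRUE, c(12, 9))
  m2[, 2] <- FALSE
  m2[, 7] <- FALSE
  g2 <- skeletonize(pore_geometry(m2))
  expect_equal(unname(junction_counts(g2)), c(0L, 0L))
  skel_geom <- pore_geometry(!g2$skeleton)
  expect_equal(max(label_components(skel_geom)),
               max(label_components(pore_geometry(m2))))
})

test_that("branch tortuosity is >= 1 and rotation-invariant on average", {
  geom <- generate_foam(small_foam_params(21, shape = c(48, 48),
                                          perforation_prob = 1))
  g <- skeletonize(geom)
  expect_true(all(g$branches$tortuosity[g$branches$valid] >= 1 - 1e-12))
  # 90 degree rotation leaves the mean unchanged
  rot <- pore_geometry(t(geom$solid)[, ], geom$voxel_um)
  grot <- skeletonize(rot)
  # sequential thinning is only approximately rotation-equivariant
  expect_equal(mean_tortuosity(grot), mean_tortuosity(g), tolerance = 0.05)
  expect_error(branch_tortuosity(list(arc = 3, chord = 0)), "loop")
})

test_that("the full pore-network report assembles consistent descriptors", {
  geom <- generate_foam(small_foam_params(33, shape = c(48, 48),
                                          perforation_prob = 1))
  rep <- pore_network_report(geom, flow_axis = 1L)
  expect_s3_class(rep, "tbl_df")
  expect_equal(nrow(rep), 1)
  expect_lte(rep$effective_porosity, rep$porosity)
  expect_true(rep$D10 <= rep$D50 && rep$D50 <= rep$D90)
  expect_gte(rep$mean_tortuosity, 1)
  expect_true(rep$main_connectivity %in% 0:1)
})

test_that("REV analysis returns a tidy size table with sane curves", {
  geom <- generate_foam(small_foam_params(44, shape = c(72, 72),
                                          perforation_prob = 1))
  cfg <- simulation_config(tau = 1, force = 1e-6)
  out <- rev_analysis(geom, sizes = c(24, 48, 72), cfg = cfg, axes = 1L)
  expect_s3_class(out, "tbl_df")
  expect_equal(out$size, c(24, 48, 72))
  expect_true(all(is.finite(out$porosity)))
  expect_true(all(out$k_darcy_x >= 0, na.rm = TRUE))
  # single full size equals whole-domain values
  one <- rev_analysis(geom, sizes = 72, cfg = cfg, axes = 1L)
  expect_equal(one$porosity, porosity(geom))
})
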