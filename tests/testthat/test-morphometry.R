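test_that("volume is voxel counting and is additive over components", {
  v <- array(FALSE, c(5, 5, 5)); v[3, 3, 3] <- TRUE
  m <- cell_mask(v, c(1, 1, 1))
  expect_equal(unname(volume_and_surface(m)["volume"]), 1)
  # two disjoint balls: volumes add
  s1 <- simulate_cell_mask(shape_ball(6), seed = 1)
  v2 <- array(FALSE, dim(s1$mask$voxels) + c(40, 0, 0))
  v2[seq_len(dim(s1$mask$voxels)[1]), , ] <- s1$mask$voxels
  v2[40 + seq_len(dim(s1$mask$voxels)[1]), , ] <- s1$mask$voxels
  m2 <- cell_mask(v2, c(1, 1, 1))
  expect_equal(unname(volume_and_surface(m2)["volume"]),
               2 * unname(volume_and_surface(s1$mask)["volume"]))
  # feature extraction never mutates the mask
  before <- s1$mask$voxels
  invisible(extract_features(s1$mask))
  expect_identical(s1$mask$voxels, before)
})

test_that("a digital ball matches the analytic sphere", {
  sim <- simulate_cell_mask(shape_ball(20), seed = 1)
  vs <- volume_and_surface(sim$mask)
  expect_equal(unname(vs["volume"]), 4 / 3 * pi * 20^3, tolerance = 0.01)
  expect_equal(unname(vs["surface_area"]), 4 * pi * 20^2, tolerance = 0.03)
  expect_gte(sphericity(vs["volume"], vs["surface_area"]), 0.97)
  # discretization convergence: sphericity approaches 1 with radius
  sph <- vapply(c(8, 14, 20), function(r) {
    v <- volume_and_surface(simulate_cell_mask(shape_ball(r), seed = 2)$mask)
    sphericity(v["volume"], v["surface_area"])
  }, numeric(1))
  expect_true(all(diff(sph) > 0) || sph[3] > 0.995)
  radii <- inertia_ellipsoid_radii(sim$mask)
  expect_equal(unname(radii), c(20, 20, 20), tolerance = 0.02)
})

test_that("sphericity is the isoperimetric ratio", {
  r <- 12
  expect_equal(sphericity(4 / 3 * pi * r^3, 4 * pi * r^2), 1)
  expect_error(sphericity(0, 10), "positive")
  # an elongated rod is less spherical than the ball of equal volume
  rod <- simulate_cell_mask(shape_rod(60, 4), seed = 3)
  vr <- volume_and_surface(rod$mask)
  expect_lt(sphericity(vr["volume"], vr["surface_area"]), 0.9)
})

test_that("surface-to-volume of digital balls falls as 3/r", {
  for (r in c(10, 15, 20)) {
    vs <- volume_and_surface(simulate_cell_mask(shape_ball(r), seed = 4)$mask)
    expect_equal(unname(vs["surface_area"] / vs["volume"]), 3 / r,
                 tolerance = 0.05)
  }
})

test_that("inertia ellipsoid semi-axes match the analytic solid ellipsoid", {
  sim <- simulate_cell_mask(shape_ellipsoid(30, 20, 10), seed = 5)
  radii <- inertia_ellipsoid_radii(sim$mask)
  expect_equal(unname(radii), c(30, 20, 10), tolerance = 0.03)
  expect_equal(unname(radii[3]), 10, tolerance = 0.03)
  # axis permutation (a rotation of the mask) leaves the radii unchanged
  rot <- cell_mask(aperm(sim$mask$voxels, c(3, 1, 2)),
                   sim$mask$voxel_size[c(3, 1, 2)])
  expect_equal(unname(inertia_ellipsoid_radii(rot)), unname(radii),
               tolerance = 0.02)
  # coplanar voxels are flagged as degenerate
  flat <- array(FALSE, c(6, 6, 3)); flat[2:5, 2:5, 2] <- TRUE
  expect_warning(inertia_ellipsoid_radii(cell_mask(flat, c(1, 1, 1))),
                 "coplanar")
})

test_that("isotropic masks give axis-permutation-invariant features", {
  sim <- simulate_cell_mask(shape_rod(40, 5), seed = 6)
  f1 <- volume_and_surface(sim$mask)
  rot <- cell_mask(aperm(sim$mask$voxels, c(2, 3, 1)), c(1, 1, 1))
  f2 <- volume_and_surface(rot)
  expect_equal(unname(f2["volume"]), unname(f1["volume"]))
  expect_equal(unname(f2["surface_area"]), unname(f1["surface_area"]),
               tolerance = 0.03)
})

test_that("skeletons of canonical shapes have the stated topology", {
  # straight 1-px rod of 101 px: one edge of length 100 x pixel size
  v <- array(FALSE, c(110, 5, 1)); v[3:103, 3, 1] <- TRUE
  sk <- mip_skeleton(cell_mask(v, c(0.5, 0.5, 1)))
  st <- skeleton_stats(sk)
  expect_equal(sk$n_endpoints, 2)
  expect_equal(sk$n_junctions, 0)
  expect_equal(unname(st["total_skeleton_length"]), 100 * 0.5)
  expect_equal(unname(st["longest_shortest_path"]), 100 * 0.5)
  # plus-shaped cross: 4 endpoints, 1 junction
  v <- array(FALSE, c(21, 21, 1)); v[3:19, 11, 1] <- TRUE
  v[11, 3:19, 1] <- TRUE
  skc <- mip_skeleton(cell_mask(v, c(1, 1, 1)))
  expect_equal(skc$n_endpoints, 4)
  expect_equal(skc$n_junctions, 1)
  expect_error(mip_skeleton(cell_mask(array(TRUE, c(2, 2, 1)),
                                      c(1, 2, 1))), "square")
})

test_that("a Y-shaped skeleton has additive arm lengths and diameter", {
  # arms 50, 40 and 30 um from one junction: total 120, diameter 90
  v <- array(FALSE, c(120, 120, 1))
  v[10:60, 60, 1] <- TRUE
  v[60, 60:100, 1] <- TRUE
  v[60, 30:60, 1] <- TRUE
  st <- skeleton_stats(mip_skeleton(cell_mask(v, c(1, 1, 1))))
  expect_equal(unname(st["total_skeleton_length"]), 120, tolerance = 0.01)
  expect_equal(unname(st["longest_shortest_path"]), 90, tolerance = 0.01)
})

test_that("the voxelized 3-segment tree recovers its constructed length", {
  for (s in 1:5) {
    sim <- simulate_cell_mask(shape_tree(), seed = s)
    st <- skeleton_stats(mip_skeleton(sim$mask))
    expect_equal(unname(st["total_skeleton_length"]),
                 sim$expected$skeleton_length, tolerance = 0.05)
  }
})

test_that("skeleton diameter equals brute-force all-pairs enumeration", {
  set.seed(17)
  for (rep in 1:6) {
    # random planar tree drawn as 1-px segments from grown tips
    v <- array(FALSE, c(80, 80, 1))
    pts <- matrix(c(40, 40), ncol = 2)
    for (b in seq_len(sample(3:6, 1))) {
      from <- pts[sample(nrow(pts), 1), ]
      ang <- sample(seq(0, 315, 45), 1) * pi / 180
      len <- sample(8:20, 1)
      dxy <- round(c(cos(ang), sin(ang)))
      to <- from + dxy * len
      if (any(to < 3) || any(to > 78)) next
      line <- cbind(round(seq(from[1], to[1], length.out = len + 1)),
                    round(seq(from[2], to[2], length.out = len + 1)))
      v[cbind(line, 1)] <- TRUE
      pts <- rbind(pts, to)
    }
    if (sum(v) < 5) next
    sk <- mip_skeleton(cell_mask(v, c(1, 1, 1)))
    if (igraph::ecount(sk$graph) == 0 ||
        igraph::ecount(sk$graph) > 12) next
    st <- skeleton_stats(sk)
    expect_equal(unname(st["longest_shortest_path"]),
                 brute_force_diameter(sk$graph), tolerance = 1e-9)
  }
})
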