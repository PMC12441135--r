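test_that("ring volume follows the cylindrical annulus identity", {
  expect_equal(ring_volume(50, 20, 20), 125663.7061, tolerance = 1e-9)
  set.seed(5)
  for (i in 1:20) {
    w <- runif(1, 1, 40)
    r <- runif(1, w / 2 + 0.1, 300)
    s <- runif(1, 5, 100)
    expect_equal(ring_volume(r, w, s),
                 s * pi * ((r + w / 2)^2 - (r - w / 2)^2), tolerance = 1e-12)
    expect_equal(ring_volume(r, w, 2 * s), 2 * ring_volume(r, w, s))
  }
  expect_error(ring_volume(10, 20, 30), "radius")
})

test_that("coverage fraction is exact on symmetric cases and matches MC", {
  # annulus fully inside
  expect_equal(coverage_fraction(c(325, 325), 50, 20, c(650, 650)), 1)
  # center on the edge of a half-plane-like footprint: exactly bisected
  expect_equal(coverage_fraction(c(0, 5000), 50, 20, c(1e4, 1e4)), 0.5,
               tolerance = 1e-9)
  expect_equal(coverage_fraction(c(0, 5000), 50, 20, c(1e4, 1e4),
                                 method = "quadrature"), 0.5,
               tolerance = 1e-3)
  # random configurations against a Monte Carlo area oracle
  set.seed(77)
  for (i in 1:8) {
    cx <- runif(1, -100, 750); cy <- runif(1, -100, 750)
    r <- runif(1, 15, 300)
    a <- coverage_fraction(c(cx, cy), r, 20, c(650, 650))
    q <- coverage_fraction(c(cx, cy), r, 20, c(650, 650),
                           method = "quadrature")
    n <- 2e5
    rho <- sqrt(runif(n, (r - 10)^2, (r + 10)^2))
    th <- runif(n, 0, 2 * pi)
    px <- cx + rho * cos(th); py <- cy + rho * sin(th)
    m <- mean(px >= 0 & px <= 650 & py >= 0 & py <= 650)
    expect_lt(abs(a - m), 3 * sqrt(m * (1 - m) / n) + 1e-6)
    expect_lt(abs(q - a), 1e-3)
  }
})

test_that("same-color ring densities follow the half-open interval rule", {
  # an isolated cell has zero density at every radius
  st <- mk_stack(rbind(c(500, 500, 15)), "YFP")
  expect_true(all(stack_ring_densities(st) == 0))
  # two same-color cells exactly 50 um apart: counted in rings r = 40
  # (interval (30, 50]) and r = 50 ((40, 60]), nowhere else
  st2 <- mk_stack(rbind(c(400, 500, 15), c(450, 500, 15)), c("RFP", "RFP"))
  d <- stack_ring_densities(st2)
  g <- ring_grid()
  expected <- rep(0, length(g$radii))
  expected[match(40, g$radii)] <- 1 / ring_volume(40, 20, 30)
  expected[match(50, g$radii)] <- 1 / ring_volume(50, 20, 30)
  expect_equal(unname(d[1, ]), expected)
  expect_equal(unname(d[2, ]), expected)
  # different colors never count
  st3 <- mk_stack(rbind(c(400, 500, 15), c(450, 500, 15)), c("RFP", "YFP"))
  expect_true(all(stack_ring_densities(st3) == 0))
  # the scalar accessor agrees and validates membership
  expect_equal(same_color_ring_density(st2, st2$cells$cell_id[1],
                                       match(40, g$radii)),
               1 / ring_volume(40, 20, 30))
  expect_error(same_color_ring_density(st2, "nope", 1), "belong")
})

test_that("accelerated densities equal brute force exactly on random stacks", {
  for (s in 1:3) {
    st <- simulate_random_pattern(25000, c(350, 350, 30), seed = 30 + s)
    fast <- stack_ring_densities(st)
    expect_identical(unname(fast), brute_force_densities(st))
  }
})

test_that("densities are covariant under scaling and color permutation", {
  st <- simulate_random_pattern(20000, c(300, 300, 30), seed = 41)
  g <- ring_grid(seq(20, 100, 10), 20)
  d0 <- stack_ring_densities(st, g)
  # scale coordinates, extents, radii and width by alpha: density ~ alpha^-3
  alpha <- 2
  st2 <- st
  st2$cells$x <- st$cells$x * alpha
  st2$cells$y <- st$cells$y * alpha
  st2$cells$z <- st$cells$z * alpha
  st2$x_extent <- st$x_extent * alpha
  st2$y_extent <- st$y_extent * alpha
  st2$z_height <- st$z_height * alpha
  g2 <- ring_grid(g$radii * alpha, g$width * alpha)
  expect_equal(stack_ring_densities(st2, g2), d0 / alpha^3,
               tolerance = 1e-12, ignore_attr = TRUE)
  # permuting the color names leaves every density unchanged
  perm <- c(mCFP = "RFP", nGFP = "YFP", YFP = "mCFP", RFP = "nGFP")
  st3 <- st
  st3$cells$color <- unname(perm[st$cells$color])
  expect_equal(unname(stack_ring_densities(st3, g)), unname(d0))
})

test_that("profile averaging is the unweighted nested mean", {
  # single cell: group profile equals the cell profile
  one <- matrix(1:5, nrow = 1)
  avg <- average_profiles(one, "i1", c(i1 = "m1"))
  expect_equal(avg$group, as.numeric(1:5))
  # two mice with mouse-level values 2 and 4 average to 3 regardless of
  # how many cells each mouse contributed
  profs <- rbind(matrix(2, 3, 1), matrix(4, 1, 1))
  avg2 <- average_profiles(profs, c("a", "a", "a", "b"),
                           c(a = "mA", b = "mB"))
  expect_equal(unname(avg2$group), 3)
  expect_equal(unname(avg2$n_contributing), c(4, 2, 2))
  # image order is irrelevant
  profs3 <- matrix(c(1, 5, 3, 7), ncol = 1)
  im <- c("i1", "i2", "i1", "i2")
  a1 <- average_profiles(profs3, im, c(i1 = "m1", i2 = "m2"))
  ord <- c(2, 4, 1, 3)
  a2 <- average_profiles(profs3[ord, , drop = FALSE], im[ord],
                         c(i1 = "m1", i2 = "m2"))
  expect_equal(a1$group, a2$group)
  expect_error(average_profiles(matrix(0, 0, 3), character(0), c()), "empty")
})

test_that("label bootstrap fixes positions and resamples labels", {
  st <- simulate_random_pattern(20000, c(300, 300, 30), seed = 50)
  rel <- bootstrap_relabel(st, c("YFP"), seed = 1)
  expect_true(all(rel$cells$color == "YFP"))
  expect_identical(rel$cells[, c("x", "y", "z")],
                   st$cells[, c("x", "y", "z")])
  # sampled label frequencies match the sampling vector
  sv <- c(rep("YFP", 3), "RFP")
  big <- simulate_random_pattern(26000, c(650, 650, 100), seed = 51)
  n <- nrow(big$cells)
  expect_gt(n, 1e3)
  draws <- unlist(lapply(1:10, function(s) {
    bootstrap_relabel(big, sv, seed = s)$cells$color
  }))
  expect_lt(abs(mean(draws == "YFP") - 0.75),
            3 * sqrt(0.75 * 0.25 / length(draws)))
  expect_error(bootstrap_relabel(st, character(0), 1), "nonempty")
})

test_that("a one-replicate band with (0,100) percentiles collapses onto it", {
  st <- simulate_null_group(n_mice = 1, stacks_per_mouse = 1,
                            intensity = 8000, bounds = c(200, 200, 30),
                            seed = 61)
  mc <- monte_carlo_band(st, n_sims = 1, percentiles = c(0, 100), seed = 62,
                         keep_sims = TRUE)
  expect_equal(unname(mc$lower), unname(mc$sims[1, ]))
  expect_equal(unname(mc$upper), unname(mc$sims[1, ]))
  expect_error(monte_carlo_band(study_table(list()), seed = 1), "cells|empty")
})

test_that("clonality calls use a strict upper-bound exceedance", {
  fake <- list(radii = c(20, 30, 40), recorded = c(1, 2, 3),
               upper = c(1, 2, 3))
  expect_false(any(clonality_call(fake)$flags))
  fake$recorded <- c(2, 2, 3)   # exceeds only at r = 20
  cc <- clonality_call(fake)
  expect_equal(sum(cc$flags), 1)
  expect_equal(cc$flagged_radii, 20)
  expect_equal(cc$max_excess_ratio, 2)
  expect_true(cc$clonal)
})

test_that("clustered groups are flagged while random groups are not", {
  cg <- simulate_clonal_group(
    clonal_sim_config(dispersion_sigma = 15, offspring_mean = 5),
    seed = 71)
  mc <- monte_carlo_band(cg$study, n_sims = 100, seed = 72)
  cc <- clonality_call(mc)
  expect_true(all(cc$flags[mc$radii <= 60]))
  ng <- simulate_null_group(seed = 73)
  mc0 <- monte_carlo_band(ng, n_sims = 100, seed = 74)
  cc0 <- clonality_call(mc0)
  expect_lt(mean(cc0$flags), 0.2)
})
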