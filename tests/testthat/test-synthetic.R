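test_that("generators are pure functions of config and seed", {
  a <- simulate_random_pattern(1653, seed = 11)
  b <- simulate_random_pattern(1653, seed = 11)
  expect_identical(a, b)
  cfg <- clonal_sim_config()
  expect_identical(simulate_clonal_pattern(cfg, seed = 4),
                   simulate_clonal_pattern(cfg, seed = 4))
  p <- ephys_params(g_out = 5)
  expect_identical(simulate_iv_recording(p, step_protocol(-70), 5, seed = 2),
                   simulate_iv_recording(p, step_protocol(-70), 5, seed = 2))
  expect_identical(simulate_cell_mask(shape_ball(8), seed = 6),
                   simulate_cell_mask(shape_ball(8), seed = 6))
})

test_that("random pattern matches its Poisson intensity", {
  expect_equal(nrow(simulate_random_pattern(0, seed = 1)$cells), 0)
  # 1653 cells/mm^3 in a 0.4 x 0.4 x 0.03 mm box: mean count 7.93
  counts <- vapply(1:200, function(s) {
    nrow(simulate_random_pattern(1653, c(400, 400, 30), seed = s)$cells)
  }, numeric(1))
  mu <- 1653 * 0.4 * 0.4 * 0.03
  se <- sqrt(mu / 200)
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("color frequencies follow the configured multinomial", {
  st <- simulate_random_pattern(1e5, c(650, 650, 250),
                                color_freqs = c(0.1, 0.2, 0.3, 0.4),
                                seed = 21)
  expect_gt(nrow(st$cells), 1e4)
  tab <- table(factor(st$cells$color, levels = confetti_colors()))
  p <- stats::chisq.test(tab, p = c(0.1, 0.2, 0.3, 0.4))$p.value
  expect_gt(p, 0.01)
})

test_that("clonal pattern honors its construction invariants", {
  cfg <- clonal_sim_config(parent_intensity = 1500, background_intensity = 200)
  sim <- simulate_clonal_pattern(cfg, seed = 8)
  truth <- sim$truth
  # all members of a clone share one color
  for (cl in names(truth$clone_sizes)) {
    members <- names(truth$clone_assignment)[truth$clone_assignment == cl]
    expect_length(unique(sim$stack$cells$color[
      match(members, sim$stack$cells$cell_id)]), 1)
    expect_length(members, truth$clone_sizes[[cl]])
  }
  # offspring_mean = 1 gives only singleton clones
  sim1 <- simulate_clonal_pattern(
    clonal_sim_config(offspring_mean = 1, background_intensity = 0),
    seed = 9)
  expect_true(all(sim1$truth$clone_sizes == 1L))
  # realized clone size converges to offspring_mean (law of large numbers)
  sizes <- unlist(lapply(1:100, function(s) {
    simulate_clonal_pattern(cfg, seed = s)$truth$clone_sizes
  }))
  se <- stats::sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - cfg$offspring_mean), 3 * se)
})

test_that("with no parents the clustered process reduces to the random one", {
  cfg <- clonal_sim_config(parent_intensity = 0, background_intensity = 1653)
  n_clonal <- vapply(1:150, function(s) {
    nrow(simulate_clonal_pattern(cfg, seed = s)$stack$cells)
  }, numeric(1))
  n_random <- vapply(1:150, function(s) {
    nrow(simulate_random_pattern(1653, seed = 1000 + s)$cells)
  }, numeric(1))
  mu <- 1653 * prod(c(650, 650, 30)) / 1e9
  expect_lt(abs(mean(n_clonal) - mu), 3 * sqrt(mu / 150))
  # Poisson counts: variance tracks the mean for both processes
  expect_lt(abs(var(n_clonal) / mu - 1), 0.5)
  expect_lt(abs(var(n_random) / mu - 1), 0.5)
})

test_that("Ki-67 assignment is Bernoulli with the clone-size probability", {
  cfg <- clonal_sim_config(parent_intensity = 2000)
  sim <- simulate_clonal_pattern(cfg, seed = 12)
  all0 <- assign_ki67(sim$stack, sim$truth, function(s) 0, seed = 1)
  expect_true(all(!all0$cells$ki67))
  all1 <- assign_ki67(sim$stack, sim$truth, function(s) 1, seed = 1)
  expect_true(all(all1$cells$ki67))
  # p = 0.5 everywhere: binomial check on >= 1000 cells
  big <- simulate_clonal_pattern(
    clonal_sim_config(parent_intensity = 4000, bounds = c(650, 650, 150)),
    seed = 13)
  half <- assign_ki67(big$stack, big$truth, function(s) 0.5, seed = 14)
  n <- nrow(half$cells)
  expect_gt(n, 1000)
  expect_lt(abs(mean(half$cells$ki67) - 0.5), 3 * sqrt(0.25 / n))
  expect_error(assign_ki67(sim$stack, sim$truth, function(s) 1.5, seed = 1),
               "0, 1")
})

test_that("voltage-step generator matches its analytic building blocks", {
  # pure leak: post-transient current is exactly (V - V_rev)/R_m
  p <- ephys_params(R_m = 2000, C_m = 20, R_s = 10, V_rev = -60)
  rec <- simulate_iv_recording(p, step_protocol(-70))
  late <- rec$t >= 20   # transient tau is 0.2 ms; 20 ms is >> 5 tau
  for (V in c(-170, -70, 0, 60)) {
    j <- match(V, rec$protocol$step_levels)
    expect_equal(unname(rec$traces[late, j]),
                 rep(1000 * (V - (-60)) / 2000, sum(late)),
                 tolerance = 1e-9)
  }
  # a step of Delta V = 0 has no capacitive transient
  j0 <- match(-70, rec$protocol$step_levels)
  expect_equal(unname(rec$traces[1, j0]), 1000 * (-70 + 60) / 2000,
               tolerance = 1e-9)
  # closed-form Kv state equals the numerically integrated gating ODE
  skip_if_not_installed("deSolve")
  p2 <- ephys_params(g_out = 10)
  V <- 20
  out <- deSolve::ode(
    y = c(n = kv_n_inf(-70, p2)), times = seq(0, 50, 0.5),
    func = function(t, y, parms) list((kv_n_inf(V, p2) - y) / kv_tau(V, p2)),
    rtol = 1e-12, atol = 1e-12)
  expect_equal(kv_state(out[, "time"], V, -70, p2), unname(out[, "n"]),
               tolerance = 1e-6)
})

test_that("voxelized shapes carry correct analytic ground truth", {
  ball <- simulate_cell_mask(shape_ball(20), seed = 1)
  expect_equal(sum(ball$mask$voxels) / (4 / 3 * pi * 20^3), 1,
               tolerance = 0.01)
  ell <- simulate_cell_mask(shape_ellipsoid(30, 20, 10), seed = 2)
  expect_equal(ell$expected$ellipsoid_radii, c(30, 20, 10))
  tree <- shape_tree()
  expect_equal(tree$expected$skeleton_length, 100)
  expect_equal(sort(tree$expected$segment_lengths), c(30, 30, 40))
  expect_error(simulate_cell_mask(shape_ball(600), seed = 1), "bounds")
})
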