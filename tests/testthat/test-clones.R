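test_that("the epsilon rule groups and separates cell pairs as stated", {
  s49 <- mk_stack(rbind(c(0, 0, 0), c(49, 0, 0)), c("YFP", "YFP"))
  cs <- detect_clones(s49)
  expect_length(cs$clones, 1)
  expect_equal(unname(clone_sizes(cs)), 2L)
  s51 <- mk_stack(rbind(c(0, 0, 0), c(51, 0, 0)), c("YFP", "YFP"))
  cs51 <- detect_clones(s51)
  expect_length(cs51$clones, 0)
  expect_equal(sum(cs51$assignment == "singlet"), 2)
  # transitive chaining: 0, 40, 80 um is one clone of 3
  chain <- mk_stack(rbind(c(0, 0, 0), c(40, 0, 0), c(80, 0, 0)),
                    rep("RFP", 3))
  expect_equal(unname(clone_sizes(detect_clones(chain))), 3L)
  # clustering is per color: close cells of different colors stay singlets
  mixed <- mk_stack(rbind(c(0, 0, 0), c(10, 0, 0)), c("YFP", "RFP"))
  expect_equal(sum(detect_clones(mixed)$assignment == "singlet"), 2)
})

test_that("clone sets satisfy the partition and color-purity invariants", {
  cg <- simulate_clonal_pattern(clonal_sim_config(), seed = 5)
  cs <- detect_clones(cg$stack)
  sizes <- clone_sizes(cs)
  expect_true(all(sizes >= 2))
  members <- unlist(cs$clones)
  expect_false(anyDuplicated(members) > 0)
  colors <- stats::setNames(cg$stack$cells$color, cg$stack$cells$cell_id)
  for (id in names(cs$clones)) {
    expect_length(unique(colors[cs$clones[[id]]]), 1)
  }
  expect_setequal(names(cs$assignment), cg$stack$cells$cell_id)
})

test_that("DBSCAN at minPts 2 equals single-linkage components per color", {
  for (s in c(3, 14, 27)) {
    st <- simulate_random_pattern(30000, c(300, 300, 30), seed = s)
    det <- sort(unname(clone_sizes(detect_clones(st))))
    expect_equal(as.integer(det), single_linkage_sizes(st))
    # and in xy metric too
    det2 <- sort(unname(clone_sizes(
      detect_clones(st, clone_params(metric = "xy")))))
    expect_equal(as.integer(det2), single_linkage_sizes(st, metric = "xy"))
  }
})

test_that("enlarging epsilon can only merge clones, never split them", {
  st <- simulate_random_pattern(25000, c(300, 300, 30), seed = 33)
  n_prev <- Inf
  for (eps in c(20, 35, 50, 80, 120)) {
    nc <- length(detect_clones(st, clone_params(epsilon = eps))$clones) +
      sum(detect_clones(st, clone_params(epsilon = eps))$assignment ==
            "singlet")
    expect_lte(nc, n_prev)
    n_prev <- nc
  }
})

test_that("clone density and size summaries are exact arithmetic", {
  st <- mk_stack(rbind(c(0, 0, 0), c(10, 0, 0), c(200, 200, 0),
                       c(210, 200, 0), c(220, 200, 0)),
                 rep("YFP", 5), extent = c(1000, 1000, 6))
  cs <- detect_clones(st)
  expect_length(cs$clones, 2)
  expect_equal(clone_density(cs), 2 / 0.006)
  cs$imaged_volume <- cs$imaged_volume / 2
  expect_equal(clone_density(cs), 2 * 2 / 0.006)
  summ <- clone_size_summary(list(detect_clones(st)))
  expect_equal(sort(summ$sizes), c(2L, 3L))
  expect_equal(summ$mean_size, 2.5)
  expect_true(is.na(clone_size_summary(list())$mean_size))
  # sizes {2,2,5} -> mean 3
  fake <- structure(list(clones = list(a = 1:2, b = 3:4, c = 5:9)),
                    class = "clone_set")
  expect_equal(clone_size_summary(list(fake))$mean_size, 3)
})

test_that("singlet fraction behaves as the nearest-neighbor rule implies", {
  all_singlets <- mk_stack(rbind(c(0, 0, 0), c(200, 0, 0), c(400, 0, 0)),
                           rep("YFP", 3))
  expect_equal(singlet_fraction(detect_clones(all_singlets)), 1)
  none <- mk_stack(rbind(c(0, 0, 0), c(10, 0, 0)), c("YFP", "YFP"))
  expect_equal(singlet_fraction(detect_clones(none)), 0)
  # under CSR the singlet fraction grows as intensity falls (nearest
  # neighbor distances stretch)
  frac <- vapply(c(8000, 2000, 500), function(int) {
    mean(vapply(1:10, function(s) {
      st <- simulate_random_pattern(int, c(650, 650, 30), seed = 100 * int + s)
      if (!nrow(st$cells)) return(NA_real_)
      singlet_fraction(detect_clones(st))
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
})

test_that("proliferation indices are exact rationals and validate flags", {
  ki67 <- stats::setNames(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                          paste0("c", 1:6))
  expect_equal(proliferation_index(paste0("c", 1:6), ki67), 1 / 3)
  expect_equal(proliferation_index(paste0("c", 3:6), ki67), 0)
  ki67["c2"] <- NA
  expect_error(proliferation_index(paste0("c", 1:6), ki67), "c2")
})

test_that("decreasing Ki-67 probability yields a negative size-index trend", {
  neg <- 0L
  for (s in 1:10) {
    cfg <- clonal_sim_config(parent_intensity = 2500,
                             background_intensity = 100)
    sim <- simulate_clonal_pattern(cfg, seed = 200 + s)
    stack <- assign_ki67(sim$stack, sim$truth,
                         function(sz) min(0.95, 1.8 / sz), seed = 300 + s)
    tab <- clone_table(stack)
    tab <- tab[!is.na(tab$proliferation_index), ]
    rho <- stats::cor(tab$size, tab$proliferation_index, method = "spearman")
    if (!is.na(rho) && rho < 0) neg <- neg + 1L
  }
  expect_gte(neg, 9L)
})

test_that("study-level clone statistics aggregate per mouse then per group", {
  cg <- simulate_clonal_group(n_mice = 2, stacks_per_mouse = 2, seed = 91)
  stats_ <- study_clone_stats(cg$study)
  expect_equal(nrow(stats_$per_mouse), 2)
  expect_equal(sort(unique(stats_$per_stack$mouse_id)),
               sort(stats_$per_mouse$mouse_id))
  m1 <- stats_$per_stack$clones_per_mm3[
    stats_$per_stack$mouse_id == stats_$per_mouse$mouse_id[1]]
  expect_equal(stats_$per_mouse$clones_per_mm3[1], mean(m1))
})
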