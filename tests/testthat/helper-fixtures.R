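# Shared builders for small in-code fixtures.

# minimal stack with explicit coordinates/colors
mk_stack <- function(xyz, colors, extent = c(1000, 1000, 30),
                     image_id = "i1", mouse_id = "m1",
                     condition = "stroke", timepoint = "2w",
                     ki67 = NA) {
  xyz <- matrix(xyz, ncol = 3)
  image_stack(image_id, mouse_id, condition, timepoint,
              extent[1], extent[2], extent[3],
              data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                         color = colors, ki67 = ki67,
                         stringsAsFactors = FALSE))
}

# independent O(n^2) brute-force ring densities (the oracle for Eq.-style
# counts: strict lower / inclusive upper interval, same-color, q != n)
brute_force_densities <- function(stack, grid = ring_grid(),
                                  edge_correction = TRUE) {
  cells <- stack$cells
  n <- nrow(cells)
  out <- matrix(NA_real_, n, length(grid$radii))
  for (i in seq_len(n)) {
    d <- sqrt((cells$x - cells$x[i])^2 + (cells$y - cells$y[i])^2)
    same <- cells$color == cells$color[i]
    for (j in seq_along(grid$radii)) {
      r <- grid$radii[j]; w <- grid$width
      cnt <- sum(same & seq_len(n) != i & d > r - w / 2 & d <= r + w / 2)
      vol <- ring_volume(r, w, stack$z_height)
      if (edge_correction) {
        vol <- vol * coverage_fraction(c(cells$x[i], cells$y[i]), r, w,
                                       c(stack$x_extent, stack$y_extent))
      }
      # a ring wholly outside the footprint has no defined density
      out[i, j] <- if (vol > 0) cnt / vol else NA_real_
    }
  }
  out
}

# brute-force single-linkage clone sizes per color at cutoff eps
single_linkage_sizes <- function(stack, eps = 50, metric = "3d") {
  sizes <- integer(0)
  for (col in confetti_colors()) {
    idx <- which(stack$cells$color == col)
    if (length(idx) < 2) next
    cols <- if (metric == "3d") c("x", "y", "z") else c("x", "y")
    hc <- stats::hclust(stats::dist(stack$cells[idx, cols]),
                        method = "single")
    lab <- stats::cutree(hc, h = eps)
    tab <- table(lab)
    sizes <- c(sizes, as.integer(tab[tab >= 2]))
  }
  sort(sizes)
}

# all simple paths between two nodes of a small undirected weighted graph;
# used as the brute-force diameter oracle for skeleton trees
brute_force_diameter <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  wt <- igraph::E(g)$weight
  adj <- lapply(seq_len(n), function(v) {
    hits <- which(el[, 1] == v | el[, 2] == v)
    data.frame(to = ifelse(el[hits, 1] == v, el[hits, 2], el[hits, 1]),
               w = wt[hits])
  })
  best_between <- function(a, b) {
    best <- Inf
    walk <- function(v, seen, acc) {
      if (v == b) {
        best <<- min(best, acc)
        return(invisible())
      }
      for (k in seq_len(nrow(adj[[v]]))) {
        u <- adj[[v]]$to[k]
        if (u %in% seen) next
        walk(u, c(seen, u), acc + adj[[v]]$w[k])
      }
    }
    walk(a, a, 0)
    best
  }
  best <- 0
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    d <- best_between(a, b)
    if (is.finite(d)) best <- max(best, d)
  }
  best
}

# full synthetic pipeline input set (cells + traces + one mask) and config
build_pipeline_inputs <- function(dir, seed = 42) {
  ctr <- simulate_null_group(n_mice = 2, stacks_per_mouse = 2,
                             seed = seed, timepoint = "2w",
                             condition = "contralateral", prefix = "ctr")
  cg <- simulate_clonal_group(n_mice = 2, stacks_per_mouse = 2,
                              seed = seed + 1, timepoint = "2w",
                              condition = "stroke", prefix = "str")
  stroke_stacks <- lapply(names(study_stacks(cg$study)), function(id) {
    assign_ki67(get_stack(cg$study, id), cg$truth[[id]],
                function(s) min(0.9, 1.8 / s), seed = seed + 2)
  })
  study <- study_table(c(study_stacks(ctr), stroke_stacks))
  cells <- file.path(dir, "cells.csv")
  write_cell_table(study, cells)
  coh <- simulate_ephys_cohort(2, noise_sd = 0, seed = seed + 3)
  traces <- file.path(dir, "traces.csv")
  write_iv_recordings(unlist(lapply(coh, function(x) list(x$rec20, x$rec70)),
                             recursive = FALSE), traces)
  mask <- file.path(dir, "ball.tif")
  write_cell_mask(simulate_cell_mask(shape_ball(8), seed = seed)$mask, mask)
  pipeline_config(cells = cells, traces = traces,
                  masks = list(ball = list(path = mask,
                                           voxel_size = c(1, 1, 1))),
                  seed = seed, ring = list(n_sims = 30))
}
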