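# Seeded generators for multicolor point patterns with ground truth.
#
# The homogeneous generator emulates the contralateral (homeostatic) case:
# complete spatial randomness of labeled cells with independent colors. The
# clustered generator is a Thomas-type (Neyman-Scott) process: Poisson
# parents, >= 1 Gaussian-dispersed offspring per parent, all offspring of a
# parent sharing the parent's color, plus independent background singlets.

#' Simulate a homogeneous random multicolor pattern
#'
#' Homogeneous Poisson point process in the stack box with i.i.d. multinomial
#' colors; emulates the random Confetti labeling of the non-ischemic
#' hemisphere.
#'
#' @param intensity Expected cells per mm^3.
#' @param bounds Numeric `(x_extent, y_extent, z_height)` in um.
#' @param color_freqs Four color probabilities summing to 1 (order of
#'   [confetti_colors()]).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param image_id,mouse_id,condition,timepoint Stack metadata.
#' @return An [image_stack()].
#' @export
simulate_random_pattern <- function(intensity, bounds = c(650, 650, 30),
                                    color_freqs = rep(0.25, 4), seed,
                                    image_id = "img1", mouse_id = "m1",
                                    condition = "contralateral",
                                    timepoint = "2w") {
  stopifnot(intensity >= 0, length(bounds) == 3)
  if (!all(bounds > 0)) stop("degenerate bounds")
  check_color_freqs(color_freqs)
  set.seed(as.integer(seed))
  vol_mm3 <- prod(bounds) / 1e9
  n <- stats::rpois(1, intensity * vol_mm3)
  cells <- data.frame(
    x = stats::runif(n, 0, bounds[1]),
    y = stats::runif(n, 0, bounds[2]),
    z = stats::runif(n, 0, bounds[3]),
    color = sample(confetti_colors(), n, replace = TRUE, prob = color_freqs),
    stringsAsFactors = FALSE
  )
  image_stack(image_id, mouse_id, condition, timepoint,
              bounds[1], bounds[2], bounds[3], cells)
}

check_color_freqs <- function(p) {
  if (length(p) != 4 || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("color_freqs must be 4 non-negative probabilities summing to 1")
  }
  invisible(TRUE)
}

#' Configuration of the clustered (clonal) pattern generator
#'
#' Defaults represent the peak post-stroke striatal field: clone seeds at
#' 2272 parents per mm^3 (the peak clone density reported for ischemic
#' striatum) with a mean clone size of 5 cells (about 11,400 labeled cells
#' per mm^3, matching the 1-week cell count) dispersed isotropically with
#' sigma = 15 um, over a background of 300 unrelated singlet cells per mm^3
#' in a 650 x 650 x 30 um box.
#'
#' @param parent_intensity Clone parents per mm^3.
#' @param offspring_mean Mean cells per clone (>= 1); counts are drawn as
#'   `1 + Poisson(offspring_mean - 1)` so every clone has at least one cell.
#' @param dispersion_sigma Isotropic Gaussian spread of offspring around the
#'   parent, um.
#' @param background_intensity Unclustered singlet cells per mm^3.
#' @param color_freqs Four color probabilities summing to 1.
#' @param bounds Numeric `(x_extent, y_extent, z_height)` in um.
#' @param min_parent_spacing Optional hard-core distance between parents, um;
#'   0 disables. Parents violating the spacing are resampled (sequential
#'   rejection), giving well-separated clones for recovery experiments.
#' @return An object of class `clonal_sim_config`.
#' @export
clonal_sim_config <- function(parent_intensity = 2272, offspring_mean = 5,
                              dispersion_sigma = 15,
                              background_intensity = 300,
                              color_freqs = rep(0.25, 4),
                              bounds = c(650, 650, 30),
                              min_parent_spacing = 0) {
  stopifnot(parent_intensity >= 0, background_intensity >= 0,
            offspring_mean >= 1, dispersion_sigma > 0,
            min_parent_spacing >= 0, length(bounds) == 3, all(bounds > 0))
  check_color_freqs(color_freqs)
  structure(list(parent_intensity = parent_intensity,
                 offspring_mean = offspring_mean,
                 dispersion_sigma = dispersion_sigma,
                 background_intensity = background_intensity,
                 color_freqs = color_freqs,
                 bounds = as.numeric(bounds),
                 min_parent_spacing = min_parent_spacing),
            class = "clonal_sim_config")
}

#' Simulate a clustered (clonal) multicolor pattern with ground truth
#'
#' Thomas-type cluster process. Parent positions are Poisson in the box
#' (optionally hard-core, see [clonal_sim_config()]); each parent receives
#' `1 + Poisson(offspring_mean - 1)` offspring displaced by an isotropic
#' Gaussian and sharing one color; offspring falling outside the box are
#' resampled (rejection), preserving isotropy near edges. Independent
#' background singlets are added with i.i.d. colors.
#'
#' @param cfg A [clonal_sim_config()].
#' @param seed Integer seed.
#' @param image_id,mouse_id,condition,timepoint Stack metadata.
#' @return A list with `stack` (an [image_stack()]) and `truth`, itself a
#'   list with `clone_assignment` (named character: cell_id -> clone id or
#'   `"singlet"`) and `clone_sizes` (named integer per clone).
#' @export
simulate_clonal_pattern <- function(cfg, seed, image_id = "img1",
                                    mouse_id = "m1", condition = "stroke",
                                    timepoint = "2w") {
  stopifnot(inherits(cfg, "clonal_sim_config"))
  set.seed(as.integer(seed))
  b <- cfg$bounds
  vol_mm3 <- prod(b) / 1e9
  n_parents <- stats::rpois(1, cfg$parent_intensity * vol_mm3)
  parents <- draw_parents(n_parents, b, cfg$min_parent_spacing)

  xs <- ys <- zs <- numeric(0)
  colors <- character(0)
  clone_of <- character(0)
  clone_sizes <- integer(0)
  if (n_parents > 0) {
    counts <- 1L + stats::rpois(n_parents, cfg$offspring_mean - 1)
    clone_colors <- sample(confetti_colors(), n_parents, replace = TRUE,
                           prob = cfg$color_freqs)
    for (k in seq_len(n_parents)) {
      pos <- offspring_positions(parents[k, ], counts[k],
                                 cfg$dispersion_sigma, b)
      xs <- c(xs, pos[, 1]); ys <- c(ys, pos[, 2]); zs <- c(zs, pos[, 3])
      colors <- c(colors, rep(clone_colors[k], counts[k]))
      clone_of <- c(clone_of, rep(sprintf("clone%03d", k), counts[k]))
    }
    clone_sizes <- stats::setNames(as.integer(counts),
                                   sprintf("clone%03d", seq_len(n_parents)))
  }
  n_bg <- stats::rpois(1, cfg$background_intensity * vol_mm3)
  if (n_bg > 0) {
    xs <- c(xs, stats::runif(n_bg, 0, b[1]))
    ys <- c(ys, stats::runif(n_bg, 0, b[2]))
    zs <- c(zs, stats::runif(n_bg, 0, b[3]))
    colors <- c(colors, sample(confetti_colors(), n_bg, replace = TRUE,
                               prob = cfg$color_freqs))
    clone_of <- c(clone_of, rep("singlet", n_bg))
  }
  cell_id <- if (length(xs)) paste0(image_id, "_c", seq_along(xs)) else character(0)
  stack <- image_stack(image_id, mouse_id, condition, timepoint,
                       b[1], b[2], b[3],
                       data.frame(cell_id = cell_id, x = xs, y = ys, z = zs,
                                  color = colors, stringsAsFactors = FALSE))
  list(stack = stack,
       truth = list(clone_assignment = stats::setNames(clone_of, cell_id),
                    clone_sizes = clone_sizes))
}

draw_parents <- function(n, bounds, min_spacing) {
  pts <- matrix(numeric(0), ncol = 3)
  if (n == 0) return(pts)
  if (min_spacing <= 0) {
    return(cbind(stats::runif(n, 0, bounds[1]),
                 stats::runif(n, 0, bounds[2]),
                 stats::runif(n, 0, bounds[3])))
  }
  pts <- matrix(NA_real_, nrow = n, ncol = 3)
  placed <- 0L
  tries <- 0L
  while (placed < n && tries < 10000L * n) {
    tries <- tries + 1L
    cand <- c(stats::runif(1, 0, bounds[1]), stats::runif(1, 0, bounds[2]),
              stats::runif(1, 0, bounds[3]))
    ok <- placed == 0L ||
      min(sqrt(colSums((t(pts[seq_len(placed), , drop = FALSE]) - cand)^2))) >=
        min_spacing
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- cand
    }
  }
  if (placed < n) {
    stop("could not place parents at the requested hard-core spacing")
  }
  pts
}

offspring_positions <- function(parent, count, sigma, bounds) {
  out <- matrix(NA_real_, nrow = count, ncol = 3)
  for (i in seq_len(count)) {
    repeat {
      p <- parent + stats::rnorm(3, 0, sigma)
      inside <- p[1] >= 0 && p[1] <= bounds[1] &&
        p[2] >= 0 && p[2] <= bounds[2] &&
        p[3] >= 0 && p[3] <= bounds[3]
      if (inside) break
    }
    out[i, ] <- p
  }
  out
}

#' Assign Ki-67 positivity per clone
#'
#' Sets each cell's `ki67` flag by a Bernoulli draw with a probability that
#' depends on the size of the cell's ground-truth clone (singlets count as
#' size 1). A decreasing size-to-probability mapping emulates the observed
#' inverse relationship between proliferation index and clone size.
#'
#' @param stack An [image_stack()].
#' @param truth Ground truth as returned by [simulate_clonal_pattern()].
#' @param p_by_clone_size Either a function `size -> probability` or a
#'   numeric vector indexed by clone size (sizes beyond its length reuse the
#'   last element).
#' @param seed Integer seed.
#' @return The stack with `ki67` filled in for every cell.
#' @export
assign_ki67 <- function(stack, truth, p_by_clone_size, seed) {
  stopifnot(inherits(stack, "image_stack"))
  ids <- stack$cells$cell_id
  assign <- truth$clone_assignment
  if (!all(ids %in% names(assign))) {
    stop("every cell must be covered by the ground truth or marked singlet")
  }
  sizes <- ifelse(assign[ids] == "singlet", 1L,
                  truth$clone_sizes[assign[ids]])
  p_fun <- if (is.function(p_by_clone_size)) {
    p_by_clone_size
  } else {
    function(s) p_by_clone_size[pmin(s, length(p_by_clone_size))]
  }
  p <- vapply(as.integer(sizes), function(s) as.numeric(p_fun(s)), numeric(1))
  if (any(p < 0 | p > 1 | is.na(p))) {
    stop("p_by_clone_size must give probabilities in [0, 1]")
  }
  set.seed(as.integer(seed))
  stack$cells$ki67 <- stats::runif(length(p)) < p
  stack
}

#' Simulate one (timepoint, condition) group of stacks
#'
#' Convenience wrappers assembling the per-stack generators into the study
#' layout used throughout: `n_mice` animals with `stacks_per_mouse` images
#' each, all sharing one timepoint and condition. Per-stack seeds are derived
#' deterministically from `seed`.
#'
#' @param n_mice,stacks_per_mouse Group layout.
#' @param intensity Cells per mm^3 (null group).
#' @param bounds Stack box `(x, y, z)` um.
#' @param color_freqs Four color probabilities.
#' @param timepoint,condition Group labels.
#' @param seed Integer seed.
#' @param prefix Identifier prefix for mice/images.
#' @return `simulate_null_group()`: a [study_table()].
#' @export
simulate_null_group <- function(n_mice = 3, stacks_per_mouse = 3,
                                intensity = 1653, bounds = c(650, 650, 30),
                                color_freqs = rep(0.25, 4),
                                timepoint = "2w", condition = "contralateral",
                                seed = 1, prefix = "null") {
  stacks <- list()
  k <- 0L
  for (m in seq_len(n_mice)) {
    for (j in seq_len(stacks_per_mouse)) {
      k <- k + 1L
      stacks[[k]] <- simulate_random_pattern(
        intensity, bounds, color_freqs,
        seed = derive_seed(seed, k),
        image_id = sprintf("%s_m%d_s%d", prefix, m, j),
        mouse_id = sprintf("%s_m%d", prefix, m),
        condition = condition, timepoint = timepoint)
    }
  }
  study_table(stacks)
}

#' @rdname simulate_null_group
#' @param cfg A [clonal_sim_config()] for the clustered group.
#' @return `simulate_clonal_group()`: a list with `study` (a
#'   [study_table()]) and `truth` (per-image ground truth list).
#' @export
simulate_clonal_group <- function(cfg = clonal_sim_config(), n_mice = 3,
                                  stacks_per_mouse = 3, timepoint = "2w",
                                  condition = "stroke", seed = 1,
                                  prefix = "clonal") {
  stacks <- list()
  truths <- list()
  k <- 0L
  for (m in seq_len(n_mice)) {
    for (j in seq_len(stacks_per_mouse)) {
      k <- k + 1L
      id <- sprintf("%s_m%d_s%d", prefix, m, j)
      sim <- simulate_clonal_pattern(
        cfg, seed = derive_seed(seed, k), image_id = id,
        mouse_id = sprintf("%s_m%d", prefix, m),
        condition = condition, timepoint = timepoint)
      stacks[[k]] <- sim$stack
      truths[[id]] <- sim$truth
    }
  }
  list(study = study_table(stacks), truth = truths)
}

# Deterministic per-substream seed derivation, kept below 2^31 (modular
# arithmetic in double precision to avoid 32-bit overflow).
derive_seed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 2147483562) * 1009 +
                97 * as.numeric(k)) %% 2147483562)
}
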