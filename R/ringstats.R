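# Monte Carlo concentric-ring clonality statistic.
#
# Around every labeled cell, overlapping concentric rings (radii 20..300 um
# in 10 um steps, fixed width 20 um) are placed in the xy plane. The density
# of same-colored cells per ring, normalized by the cylindrical ring volume
# (ring area x stack height) and corrected for partial coverage of the ring
# by the rectangular image footprint, is averaged cell -> image -> mouse ->
# group. A label-permutation null (colors resampled with replacement from
# each animal's label pool, positions fixed) yields a percentile envelope;
# recorded densities above the upper percentile indicate clonality.

#' Concentric ring grid
#'
#' @param radii Strictly increasing ring radii in um. The default
#'   20, 30, ..., 300 um with width 20 um gives overlapping rings (step
#'   smaller than width).
#' @param width Ring width w in um; each ring spans `(r - w/2, r + w/2]`.
#' @return An object of class `ring_grid`.
#' @export
ring_grid <- function(radii = seq(20, 300, by = 10), width = 20) {
  stopifnot(length(radii) >= 1, width > 0)
  if (any(diff(radii) <= 0)) stop("radii must be strictly increasing")
  if (any(radii <= width / 2)) stop("all radii must exceed width/2")
  structure(list(radii = as.numeric(radii), width = as.numeric(width)),
            class = "ring_grid")
}

#' Cylindrical ring volume
#'
#' Volume of the full annulus of radius `r` and width `w` extended through
#' the z-stack height `s`: `s * 2 * pi * r * w`, identical to
#' `s * pi * ((r + w/2)^2 - (r - w/2)^2)`.
#'
#' @param r Ring radius, um (vectorized).
#' @param w Ring width, um.
#' @param s Stack height, um.
#' @return Ring volume(s) in um^3.
#' @export
ring_volume <- function(r, w, s) {
  if (any(r <= w / 2)) stop("ring radius must exceed half the ring width")
  if (w <= 0 || s <= 0) stop("width and stack height must be positive")
  s * 2 * pi * r * w
}

# Exact area of a circle of radius R centered at (cx, cy) intersected with
# the rectangle [0, xe] x [0, ye]; corner decomposition of the circle
# integral. Fully vectorized over cx, cy, R.
circle_rect_area <- function(cx, cy, R, xe, ye) {
  quad <- function(x, y, R) {
    # area of circle (radius R, centre origin) within [0,x] x [0,y], x,y >= 0
    H <- function(u) {
      0.5 * (u * sqrt(pmax(R^2 - u^2, 0)) +
               R^2 * asin(pmin(pmax(u / R, -1), 1)))
    }
    a <- pmin(x, R)
    u1 <- pmin(a, sqrt(pmax(R^2 - y^2, 0)))
    out <- y * u1 + H(a) - H(u1)
    out[x <= 0 | y <= 0 | R <= 0] <- 0
    out
  }
  F2 <- function(x, y, R) sign(x) * sign(y) * quad(abs(x), abs(y), R)
  x0 <- -cx; x1 <- xe - cx
  y0 <- -cy; y1 <- ye - cy
  F2(x1, y1, R) - F2(x0, y1, R) - F2(x1, y0, R) + F2(x0, y0, R)
}

#' Fraction of a ring covered by the image footprint
#'
#' Planar fraction of the annulus `(r - w/2, r + w/2]` around `center` that
#' lies inside the rectangular footprint `[0, xe] x [0, ye]`; used to adjust
#' the ring volume when a ring is only partially covered by the image.
#'
#' @param center Numeric `(x, y)` of the ring center, um.
#' @param r Ring radius, um.
#' @param w Ring width, um.
#' @param footprint Numeric `(xe, ye)` footprint extents, um.
#' @param method `"analytic"` (exact circle-rectangle intersection, the
#'   default) or `"quadrature"` (deterministic midpoint polar rule with
#'   `n_angular` x `n_radial` samples, absolute error <= 1e-3).
#' @param n_angular,n_radial Quadrature resolution.
#' @return Coverage fraction in `[0, 1]` (0 if the annulus lies entirely
#'   outside the footprint).
#' @export
coverage_fraction <- function(center, r, w, footprint,
                              method = c("analytic", "quadrature"),
                              n_angular = 3600, n_radial = 8) {
  method <- match.arg(method)
  stopifnot(length(center) == 2, length(footprint) == 2, all(footprint > 0))
  if (method == "analytic") {
    return(annulus_coverage(center[1], center[2], r, w,
                            footprint[1], footprint[2]))
  }
  theta <- (seq_len(n_angular) - 0.5) * 2 * pi / n_angular
  rho <- r - w / 2 + (seq_len(n_radial) - 0.5) * w / n_radial
  px <- center[1] + outer(rho, cos(theta))
  py <- center[2] + outer(rho, sin(theta))
  inside <- px >= 0 & px <= footprint[1] & py >= 0 & py <= footprint[2]
  sum(rho * rowSums(inside)) / (n_angular * sum(rho))
}

annulus_coverage <- function(cx, cy, r, w, xe, ye) {
  outer_a <- circle_rect_area(cx, cy, r + w / 2, xe, ye)
  inner_a <- circle_rect_area(cx, cy, r - w / 2, xe, ye)
  full <- pi * ((r + w / 2)^2 - (r - w / 2)^2)
  pmin(pmax((outer_a - inner_a) / full, 0), 1)
}

# Precompute the label-independent structure of a stack's ring densities:
# which cell pairs fall into which rings (half-open interval
# (r - w/2, r + w/2], the comparisons shared verbatim with the brute-force
# oracle) and the per-cell per-ring denominator volume.
ring_density_precompute <- function(stack, grid = ring_grid(),
                                    distance = c("xy", "3d"),
                                    edge_correction = TRUE) {
  distance <- match.arg(distance)
  cells <- stack$cells
  n <- nrow(cells)
  radii <- grid$radii
  w <- grid$width
  nr <- length(radii)

  if (n >= 2) {
    ia0 <- rep(seq_len(n - 1), times = (n - 1):1)
    ib0 <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
    dx <- cells$x[ia0] - cells$x[ib0]
    dy <- cells$y[ia0] - cells$y[ib0]
    d <- if (distance == "xy") sqrt(dx^2 + dy^2) else {
      dz <- cells$z[ia0] - cells$z[ib0]
      sqrt(dx^2 + dy^2 + dz^2)
    }
    keep <- d <= radii[nr] + w / 2
    ia0 <- ia0[keep]; ib0 <- ib0[keep]; d <- d[keep]
    hit <- outer(d, radii, function(dd, r) dd > r - w / 2 & dd <= r + w / 2)
    idx <- which(hit, arr.ind = TRUE)
    pa <- ia0[idx[, 1]]
    pb <- ib0[idx[, 1]]
    ring <- idx[, 2]
  } else {
    pa <- pb <- ring <- integer(0)
  }

  if (distance == "xy") {
    denom <- matrix(rep(ring_volume(radii, w, stack$z_height), each = n),
                    nrow = n)
    if (edge_correction && n > 0) {
      cov <- sapply(radii, function(r) {
        annulus_coverage(cells$x, cells$y, r, w, stack$x_extent,
                         stack$y_extent)
      })
      cov <- matrix(cov, nrow = n)
      denom <- denom * cov
    }
  } else {
    shell <- (4 / 3) * pi * ((radii + w / 2)^3 - (radii - w / 2)^3)
    denom <- matrix(rep(shell, each = n), nrow = n)
  }
  denom[denom <= 0] <- NA_real_

  list(n = n, nr = nr, pa = pa, pb = pb, ring = ring, denom = denom,
       colors = cells$color, cell_ids = cells$cell_id, grid = grid)
}

# Per-cell per-ring same-color densities for an arbitrary label vector.
densities_from_labels <- function(pre, labels) {
  counts <- matrix(0L, nrow = pre$n, ncol = pre$nr)
  if (length(pre$pa)) {
    same <- labels[pre$pa] == labels[pre$pb]
    if (any(same)) {
      idx <- c((pre$ring[same] - 1L) * pre$n + pre$pa[same],
               (pre$ring[same] - 1L) * pre$n + pre$pb[same])
      counts <- matrix(tabulate(idx, nbins = pre$n * pre$nr), nrow = pre$n)
    }
  }
  counts / pre$denom
}

#' Per-cell same-color ring densities for one stack
#'
#' Computes, for every cell `n` and ring radius `r_i`, the number of other
#' cells with the same color at distance `d` with
#' `r_i - w/2 < d <= r_i + w/2`, divided by the (coverage-adjusted) ring
#' volume.
#'
#' @param stack An [image_stack()].
#' @param grid A [ring_grid()].
#' @param distance `"xy"` (planar distance with cylindrical ring volumes,
#'   the default consistent with the stack-height normalization) or `"3d"`
#'   (Euclidean distance with spherical-shell volumes, for sensitivity
#'   analysis; no edge correction).
#' @param edge_correction Adjust ring volumes for partial coverage by the
#'   image footprint (xy mode only).
#' @return Numeric matrix (cells x radii) of densities in cells/um^3; `NA`
#'   where the ring lies entirely outside the footprint. Row names are cell
#'   ids, column names the radii.
#' @export
stack_ring_densities <- function(stack, grid = ring_grid(),
                                 distance = c("xy", "3d"),
                                 edge_correction = TRUE) {
  distance <- match.arg(distance)
  pre <- ring_density_precompute(stack, grid, distance, edge_correction)
  d <- densities_from_labels(pre, pre$colors)
  dimnames(d) <- list(pre$cell_ids, grid$radii)
  d
}

#' Same-color ring density for one cell and ring
#'
#' @param stack An [image_stack()].
#' @param cell_id Id of the focal cell (must belong to the stack).
#' @param ring_index Index into `grid$radii`.
#' @inheritParams stack_ring_densities
#' @return Density in cells/um^3.
#' @export
same_color_ring_density <- function(stack, cell_id, ring_index,
                                    grid = ring_grid(),
                                    distance = c("xy", "3d"),
                                    edge_correction = TRUE) {
  i <- match(cell_id, stack$cells$cell_id)
  if (is.na(i)) stop(sprintf("cell '%s' does not belong to the stack", cell_id))
  stopifnot(ring_index >= 1, ring_index <= length(grid$radii))
  d <- stack_ring_densities(stack, grid, match.arg(distance), edge_correction)
  unname(d[i, ring_index])
}

#' Average per-cell profiles through the study hierarchy
#'
#' Unweighted nested means: cells within an image, then images within a
#' mouse, then mice within the group. A mouse with many cells therefore
#' carries the same weight as a mouse with few.
#'
#' @param cell_profiles Matrix (cells x radii) of per-cell densities.
#' @param image_of_cell Character vector: image id per row of
#'   `cell_profiles`.
#' @param mouse_of_image Named character vector mapping image id -> mouse id.
#' @return List with `group` (radius-long numeric vector), `mouse` and
#'   `image` (matrices with one row per mouse/image), and `n_contributing`
#'   (cells, images, mice).
#' @export
average_profiles <- function(cell_profiles, image_of_cell, mouse_of_image) {
  stopifnot(nrow(cell_profiles) == length(image_of_cell))
  if (!nrow(cell_profiles)) stop("empty group: no cell profiles to average")
  nc <- ncol(cell_profiles)
  images <- unique(image_of_cell)
  img_mat <- matrix(NA_real_, length(images), nc,
                    dimnames = list(images, colnames(cell_profiles)))
  for (im in images) {
    img_mat[im, ] <- colMeans(cell_profiles[image_of_cell == im, ,
                                            drop = FALSE], na.rm = TRUE)
  }
  mice <- unique(unname(mouse_of_image[images]))
  mouse_mat <- matrix(NA_real_, length(mice), nc,
                      dimnames = list(mice, colnames(cell_profiles)))
  for (mo in mice) {
    mouse_mat[mo, ] <- colMeans(img_mat[mouse_of_image[images] == mo, ,
                                        drop = FALSE], na.rm = TRUE)
  }
  list(group = colMeans(mouse_mat, na.rm = TRUE),
       mouse = mouse_mat, image = img_mat,
       n_contributing = c(cells = nrow(cell_profiles),
                          images = length(images), mice = length(mice)))
}

#' Randomize a stack's labels from a sampling vector
#'
#' Positions stay fixed; each cell's color is drawn independently with
#' replacement from `sampling_vector` (typically all labels of the
#' corresponding animal).
#'
#' @param stack An [image_stack()].
#' @param sampling_vector Nonempty character vector of labels to sample from.
#' @param seed Integer seed.
#' @return The relabeled [image_stack()].
#' @export
bootstrap_relabel <- function(stack, sampling_vector, seed) {
  if (!length(sampling_vector)) stop("sampling vector must be nonempty")
  set.seed(as.integer(seed))
  n <- nrow(stack$cells)
  stack$cells$color <- sample(sampling_vector, n, replace = TRUE)
  stack
}

#' Monte Carlo clonality band for one group
#'
#' For one (timepoint, condition) group: builds a per-mouse sampling vector
#' from all its labeled cells in the group, relabels every stack `n_sims`
#' times (positions fixed, labels drawn with replacement from the animal's
#' vector), recomputes the same-color ring densities and the nested group
#' average for every replicate, and returns the per-radius percentile
#' envelope together with the recorded curve.
#'
#' @param study A [study_table()] restricted to one group (see
#'   [subset_group()]).
#' @param grid A [ring_grid()].
#' @param n_sims Number of label-randomization replicates.
#' @param percentiles Lower/upper percentile pair of the envelope.
#' @param seed Integer seed (single stream; replicates are drawn in a fixed
#'   deterministic order).
#' @inheritParams stack_ring_densities
#' @param keep_sims Keep the matrix of replicate group curves.
#' @return An object of class `ring_mc`: list with `radii`, `recorded`,
#'   `lower`, `upper`, `n_sims`, `percentiles`, `n_contributing`, and
#'   optionally `sims` (n_sims x radii).
#' @export
monte_carlo_band <- function(study, grid = ring_grid(), n_sims = 1000,
                             percentiles = c(2, 98), seed = 1,
                             distance = c("xy", "3d"),
                             edge_correction = TRUE, keep_sims = FALSE) {
  distance <- match.arg(distance)
  stopifnot(inherits(study, "study_table"), n_sims >= 1,
            length(percentiles) == 2, percentiles[1] <= percentiles[2])
  if (!nrow(study$cells)) stop("group contains no cells")
  image_ids <- sort(study$stacks$image_id)
  stacks <- lapply(image_ids, function(i) get_stack(study, i))
  names(stacks) <- image_ids
  pres <- lapply(stacks, ring_density_precompute, grid = grid,
                 distance = distance, edge_correction = edge_correction)
  mouse_of_image <- stats::setNames(study$stacks$mouse_id,
                                    study$stacks$image_id)
  sampling <- split(study$cells$color,
                    mouse_of_image[study$cells$image_id])
  image_of_cell <- unlist(lapply(image_ids,
                                 function(i) rep(i, pres[[i]]$n)),
                          use.names = FALSE)

  group_curve <- function(label_list) {
    mats <- lapply(image_ids, function(i) {
      densities_from_labels(pres[[i]], label_list[[i]])
    })
    average_profiles(do.call(rbind, mats), image_of_cell,
                     mouse_of_image)$group
  }

  recorded_avg <- {
    mats <- lapply(image_ids, function(i) {
      densities_from_labels(pres[[i]], pres[[i]]$colors)
    })
    average_profiles(do.call(rbind, mats), image_of_cell, mouse_of_image)
  }

  set.seed(as.integer(seed))
  sims <- matrix(NA_real_, nrow = n_sims, ncol = length(grid$radii))
  for (k in seq_len(n_sims)) {
    labels <- lapply(image_ids, function(i) {
      sv <- sampling[[mouse_of_image[i]]]
      sample(sv, pres[[i]]$n, replace = TRUE)
    })
    names(labels) <- image_ids
    sims[k, ] <- group_curve(labels)
  }
  band <- apply(sims, 2, stats::quantile, probs = percentiles / 100,
                type = 7, na.rm = TRUE)
  out <- list(radii = grid$radii, recorded = recorded_avg$group,
              lower = band[1, ], upper = band[2, ], n_sims = n_sims,
              percentiles = percentiles,
              n_contributing = recorded_avg$n_contributing)
  if (keep_sims) out$sims <- sims
  structure(out, class = "ring_mc")
}

#' @export
print.ring_mc <- function(x, ...) {
  cc <- clonality_call(x)
  cat(sprintf(
    "<ring_mc> %d radii (%g-%g um), %d sims, band %g-%g%%; %d/%d radii above upper band\n",
    length(x$radii), min(x$radii), max(x$radii), x$n_sims,
    x$percentiles[1], x$percentiles[2], sum(cc$flags), length(x$radii)))
  invisible(x)
}

#' Clonality call from a recorded curve and its null band
#'
#' A radius is flagged when the recorded density lies strictly above the
#' upper percentile of the label-randomized envelope, i.e. same-colored
#' cells are closer together than random labeling allows.
#'
#' @param mc A `ring_mc` object from [monte_carlo_band()], or a list with
#'   `radii`, `recorded`, `upper`.
#' @return List with `flags` (logical per radius), `flagged_radii`,
#'   `max_excess_ratio` (max recorded/upper), and `clonal` (any flag).
#' @export
clonality_call <- function(mc) {
  flags <- !is.na(mc$recorded) & !is.na(mc$upper) & mc$recorded > mc$upper
  ratio <- mc$recorded / mc$upper
  ratio[!is.finite(ratio)] <- NA_real_
  list(flags = stats::setNames(flags, mc$radii),
       flagged_radii = mc$radii[flags],
       max_excess_ratio = if (all(is.na(ratio))) NA_real_ else
         max(ratio, na.rm = TRUE),
       clonal = any(flags))
}
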