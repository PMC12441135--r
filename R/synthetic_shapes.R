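# Voxelized synthetic cell shapes with analytic ground truth.
#
# Shapes are continuous solids (ball, ellipsoid, capsule rod, branched tree
# of capsules) voxelized by a center-inclusion test; expected features come
# from the continuous geometry (analytic for ball/ellipsoid/rod, by
# construction for the tree skeleton).

#' Continuous shape specifications
#'
#' @param r Ball radius, um.
#' @return An object of class `shape_spec` with an `inside(points)`
#'   predicate, a bounding box, and analytic `expected` features.
#' @export
shape_ball <- function(r) {
  stopifnot(r > 0)
  structure(list(
    kind = "ball",
    inside = function(p) rowSums(p^2) <= r^2,
    bbox = rbind(-c(r, r, r), c(r, r, r)),
    expected = list(volume = 4 / 3 * pi * r^3,
                    surface_area = 4 * pi * r^2,
                    sphericity = 1,
                    ellipsoid_radii = c(r, r, r))
  ), class = "shape_spec")
}

#' @rdname shape_ball
#' @param a,b,c Ellipsoid semi-axes, um.
#' @export
shape_ellipsoid <- function(a, b, c) {
  stopifnot(a > 0, b > 0, c > 0)
  # Thomsen approximation for the ellipsoid surface (relative error < 1.1%)
  p <- 1.6075
  sa <- 4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
  structure(list(
    kind = "ellipsoid",
    inside = function(pt) {
      (pt[, 1] / a)^2 + (pt[, 2] / b)^2 + (pt[, 3] / c)^2 <= 1
    },
    bbox = rbind(-c(a, b, c), c(a, b, c)),
    expected = list(volume = 4 / 3 * pi * a * b * c,
                    surface_area = sa,
                    ellipsoid_radii = sort(c(a, b, c), decreasing = TRUE))
  ), class = "shape_spec")
}

# squared distance from points to a segment [p0, p1]
segment_dist2 <- function(pts, p0, p1) {
  v <- p1 - p0
  L2 <- sum(v^2)
  w <- sweep(pts, 2, p0)
  tt <- pmin(pmax((w %*% v) / L2, 0), 1)
  proj <- outer(as.vector(tt), v)
  rowSums((w - proj)^2)
}

#' @rdname shape_ball
#' @param length Rod length (between cap centers), um.
#' @param radius Rod radius, um.
#' @export
shape_rod <- function(length, radius) {
  stopifnot(length > 0, radius > 0)
  p0 <- c(0, 0, 0); p1 <- c(length, 0, 0)
  structure(list(
    kind = "rod",
    inside = function(p) segment_dist2(p, p0, p1) <= radius^2,
    bbox = rbind(c(-radius, -radius, -radius),
                 c(length + radius, radius, radius)),
    expected = list(volume = pi * radius^2 * length + 4 / 3 * pi * radius^3,
                    surface_area = 2 * pi * radius * length + 4 * pi * radius^2,
                    skeleton_length = length)
  ), class = "shape_spec")
}

#' @rdname shape_ball
#' @param segments List of segments, each `list(from, to)` in um (3D), or
#'   `NULL` for the default Y-shaped tree of three segments of 40, 30 and
#'   30 um (total skeleton length 100 um) lying in the xy plane.
#' @param radius Branch radius, um.
#' @export
shape_tree <- function(segments = NULL, radius = 2) {
  if (is.null(segments)) {
    a <- 30 / sqrt(2)
    segments <- list(
      list(from = c(0, 0, 0), to = c(40, 0, 0)),
      list(from = c(40, 0, 0), to = c(40 + a, a, 0)),
      list(from = c(40, 0, 0), to = c(40 + a, -a, 0))
    )
  }
  stopifnot(radius > 0, length(segments) >= 1)
  pts <- do.call(rbind, lapply(segments, function(s) rbind(s$from, s$to)))
  lens <- vapply(segments, function(s) {
    sqrt(sum((s$to - s$from)^2))
  }, numeric(1))
  structure(list(
    kind = "tree",
    segments = segments,
    inside = function(p) {
      hit <- rep(FALSE, nrow(p))
      for (s in segments) {
        hit <- hit | segment_dist2(p, s$from, s$to) <= radius^2
      }
      hit
    },
    bbox = rbind(apply(pts, 2, min) - radius, apply(pts, 2, max) + radius),
    expected = list(skeleton_length = sum(lens),
                    segment_lengths = lens)
  ), class = "shape_spec")
}

#' Voxelize a continuous shape into a binary cell mask
#'
#' A voxel is foreground when its center lies inside the continuous shape.
#' The shape is placed with a deterministic sub-voxel offset drawn from the
#' seed, so repeated voxelizations probe different lattice alignments.
#'
#' @param shape A `shape_spec` ([shape_ball()] and friends).
#' @param voxel_size Numeric `(dx, dy, dz)` um.
#' @param seed Integer seed (controls only the sub-voxel offset).
#' @param padding Background voxels added around the shape on every side.
#' @param jitter Apply the random sub-voxel offset (default `TRUE`).
#' @return List with `mask` (a [cell_mask()]) and `expected` (the shape's
#'   analytic feature values).
#' @export
simulate_cell_mask <- function(shape, voxel_size = c(1, 1, 1), seed = 1,
                               padding = 3, jitter = TRUE) {
  stopifnot(inherits(shape, "shape_spec"), all(voxel_size > 0))
  set.seed(as.integer(seed))
  offset <- if (jitter) stats::runif(3) * voxel_size else c(0, 0, 0)
  span <- shape$bbox[2, ] - shape$bbox[1, ]
  dims <- ceiling(span / voxel_size) + 2 * padding + 1
  if (any(dims > 512)) stop("shape exceeds the supported array bounds")
  origin <- shape$bbox[1, ] - padding * voxel_size - offset
  cx <- origin[1] + (seq_len(dims[1]) - 0.5) * voxel_size[1]
  cy <- origin[2] + (seq_len(dims[2]) - 0.5) * voxel_size[2]
  cz <- origin[3] + (seq_len(dims[3]) - 0.5) * voxel_size[3]
  pts <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  vox <- array(shape$inside(pts), dim = dims)
  list(mask = cell_mask(vox, voxel_size), expected = shape$expected)
}
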