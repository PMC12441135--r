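# DBSCAN-based clone detection and clone statistics.
#
# Cells sharing a Confetti color and lying within epsilon = 50 um of another
# cell of that color (transitively) form a clone; cells with no same-color
# neighbor within epsilon are singlets and are excluded from clone counts
# and sizes. At minPts = 2 the core/border distinction collapses and DBSCAN
# equals single-linkage connected components at cutoff epsilon, which the
# test suite exploits as an independent oracle.

#' Clone detection parameters
#'
#' @param epsilon Neighborhood radius in um (default 50).
#' @param min_cells Minimum cells per clone (default 2).
#' @param metric `"3d"` Euclidean (default) or planar `"xy"`.
#' @return An object of class `clone_params`.
#' @export
clone_params <- function(epsilon = 50, min_cells = 2,
                         metric = c("3d", "xy")) {
  stopifnot(epsilon > 0, min_cells >= 2)
  structure(list(epsilon = epsilon, min_cells = as.integer(min_cells),
                 metric = match.arg(metric)),
            class = "clone_params")
}

# Plain DBSCAN on a coordinate matrix. Core points have >= min_pts points
# (self included) within eps; clusters are connected components of core
# points with border points attached to a neighboring core's cluster.
dbscan_labels <- function(coords, eps, min_pts) {
  n <- nrow(coords)
  if (n == 0) return(integer(0))
  d <- as.matrix(stats::dist(coords))
  nb <- d <= eps
  n_nb <- rowSums(nb)                      # includes self
  core <- n_nb >= min_pts
  labels <- rep(0L, n)                     # 0 = noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      if (!core[p]) next
      for (q in which(nb[p, ])) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

#' Detect clones in one image stack
#'
#' Runs DBSCAN independently per color label on the cell coordinates; noise
#' points are singlets. Deterministic at `min_cells = 2` (no border-point
#' tie sensitivity).
#'
#' @param stack An [image_stack()].
#' @param params A [clone_params()].
#' @return An object of class `clone_set`: list with `assignment` (named
#'   character: cell_id -> clone id or `"singlet"`), `clones` (named list of
#'   member cell ids, all one color), `clone_colors`, `imaged_volume` (mm^3),
#'   and `params`.
#' @export
detect_clones <- function(stack, params = clone_params()) {
  stopifnot(inherits(stack, "image_stack"), inherits(params, "clone_params"))
  cells <- stack$cells
  assignment <- stats::setNames(rep("singlet", nrow(cells)), cells$cell_id)
  clones <- list()
  clone_colors <- character(0)
  k <- 0L
  for (col in confetti_colors()) {
    idx <- which(cells$color == col)
    if (!length(idx)) next
    coords <- as.matrix(cells[idx, if (params$metric == "3d")
      c("x", "y", "z") else c("x", "y")])
    labels <- dbscan_labels(coords, params$epsilon, params$min_cells)
    for (cl in setdiff(unique(labels), 0L)) {
      members <- cells$cell_id[idx[labels == cl]]
      if (length(members) < params$min_cells) next
      k <- k + 1L
      id <- sprintf("%s_%s_clone%03d", stack$image_id, col, k)
      clones[[id]] <- members
      clone_colors[id] <- col
      assignment[members] <- id
    }
  }
  structure(list(assignment = assignment, clones = clones,
                 clone_colors = clone_colors,
                 imaged_volume = stack$x_extent * stack$y_extent *
                   stack$z_height / 1e9,
                 params = params),
            class = "clone_set")
}

#' @export
print.clone_set <- function(x, ...) {
  cat(sprintf("<clone_set> %d clones, %d singlets of %d cells in %.4g mm^3\n",
              length(x$clones), sum(x$assignment == "singlet"),
              length(x$assignment), x$imaged_volume))
  invisible(x)
}

#' Clone sizes of a clone set
#'
#' @param cloneset A `clone_set` from [detect_clones()].
#' @return Named integer vector of member counts per clone.
#' @export
clone_sizes <- function(cloneset) {
  vapply(cloneset$clones, length, integer(1))
}

#' Clone density (clones per mm^3)
#'
#' Singlets are excluded: only clones of `min_cells` or more count.
#'
#' @param cloneset A `clone_set`.
#' @return Clones per mm^3 of imaged volume.
#' @export
clone_density <- function(cloneset) {
  if (!isTRUE(cloneset$imaged_volume > 0)) stop("imaged volume must be > 0")
  length(cloneset$clones) / cloneset$imaged_volume
}

#' Singlet fraction of a clone set
#'
#' @param cloneset A `clone_set`.
#' @return Fraction of cells with no same-color neighbor within epsilon.
#' @export
singlet_fraction <- function(cloneset) {
  n <- length(cloneset$assignment)
  if (n == 0) stop("empty stack: no cells")
  sum(cloneset$assignment == "singlet") / n
}

#' Clone-size summary over a group of clone sets
#'
#' Unweighted mean over all clones pooled across the group's clone sets
#' (every clone counts once, regardless of animal), plus the full size
#' distribution and per-stack sizes.
#'
#' @param clonesets A list of `clone_set` objects (one per image of the
#'   group).
#' @return List with `mean_size`, `n_clones`, `sizes` (integer vector over
#'   all clones), and `by_stack` (named list). With zero clones the summary
#'   is empty (`mean_size = NA`), not an error.
#' @export
clone_size_summary <- function(clonesets) {
  if (inherits(clonesets, "clone_set")) clonesets <- list(clonesets)
  sizes <- unlist(lapply(clonesets, clone_sizes))
  list(mean_size = if (length(sizes)) mean(sizes) else NA_real_,
       n_clones = length(sizes),
       sizes = as.integer(if (is.null(sizes)) integer(0) else sizes),
       by_stack = lapply(clonesets, clone_sizes))
}

#' Proliferation index of a clone
#'
#' Number of Ki-67 positive members divided by the clone size; an exact
#' rational fraction.
#'
#' @param members Character vector of member cell ids (nonempty).
#' @param ki67 Named logical vector of Ki-67 flags covering all members.
#' @return Fraction in `[0, 1]`.
#' @export
proliferation_index <- function(members, ki67) {
  if (!length(members)) stop("clone has no members")
  flags <- ki67[members]
  if (any(is.na(flags))) {
    stop(sprintf("cell %s has no Ki-67 flag",
                 members[which(is.na(flags))[1]]))
  }
  sum(flags) / length(members)
}

#' Per-clone table for one stack
#'
#' @param stack An [image_stack()].
#' @param cloneset Matching `clone_set`; computed if missing.
#' @param params A [clone_params()] (used when `cloneset` is missing).
#' @return `data.frame` with one row per clone: `clone_id`, `color`, `size`,
#'   and `proliferation_index` (`NA` when any member lacks a Ki-67 flag).
#' @export
clone_table <- function(stack, cloneset = NULL, params = clone_params()) {
  if (is.null(cloneset)) cloneset <- detect_clones(stack, params)
  ki67 <- stats::setNames(stack$cells$ki67, stack$cells$cell_id)
  ids <- names(cloneset$clones)
  data.frame(
    image_id = rep(stack$image_id, length(ids)),
    clone_id = ids,
    color = unname(cloneset$clone_colors[ids]),
    size = unname(clone_sizes(cloneset)[ids]),
    proliferation_index = vapply(ids, function(i) {
      m <- cloneset$clones[[i]]
      if (any(is.na(ki67[m]))) NA_real_ else proliferation_index(m, ki67)
    }, numeric(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Clone statistics for every stack of a study
#'
#' Runs clone detection per image and aggregates the paper's reporting
#' hierarchy: per-hemisphere-per-mouse means of clone density first, then
#' group means; clone sizes pooled over all clones of a group.
#'
#' @param study A [study_table()].
#' @param params A [clone_params()].
#' @return List with `per_clone` (table over all images), `per_stack`
#'   (clone count, density, singlet fraction per image), and `per_mouse`
#'   (mean clones per mm^3 per mouse x condition x timepoint).
#' @export
study_clone_stats <- function(study, params = clone_params()) {
  stacks <- study_stacks(study)
  sets <- lapply(stacks, detect_clones, params = params)
  per_clone <- do.call(rbind, lapply(names(stacks), function(i) {
    clone_table(stacks[[i]], sets[[i]])
  }))
  if (is.null(per_clone)) {
    per_clone <- data.frame(image_id = character(0), clone_id = character(0),
                            color = character(0), size = integer(0),
                            proliferation_index = numeric(0))
  }
  per_stack <- data.frame(
    image_id = names(stacks),
    mouse_id = study$stacks$mouse_id[match(names(stacks),
                                           study$stacks$image_id)],
    condition = study$stacks$condition[match(names(stacks),
                                             study$stacks$image_id)],
    timepoint = study$stacks$timepoint[match(names(stacks),
                                             study$stacks$image_id)],
    n_cells = vapply(sets, function(s) length(s$assignment), integer(1)),
    n_clones = vapply(sets, function(s) length(s$clones), integer(1)),
    clones_per_mm3 = vapply(sets, clone_density, numeric(1)),
    singlet_fraction = vapply(sets, function(s) {
      if (length(s$assignment)) singlet_fraction(s) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  agg <- stats::aggregate(clones_per_mm3 ~ mouse_id + condition + timepoint,
                          data = per_stack, FUN = mean)
  list(per_clone = per_clone, per_stack = per_stack, per_mouse = agg,
       clonesets = sets)
}
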