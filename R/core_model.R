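# Domain types and CSV/TIFF interchange shared by all analysis stages.
#
# Coordinates are stack-local, continuous micrometres, origin at the stack
# corner. Each image stack is an axis-aligned box [0, x_extent] x
# [0, y_extent] x [0, z_height].

#' The four Confetti reporter labels
#'
#' Multicolor fate mapping stochastically assigns each recombined cell one of
#' four heritable fluorescent reporters: membrane-tagged CFP, nuclear GFP,
#' cytoplasmic YFP, and cytoplasmic RFP.
#'
#' @return Character vector of the four label names.
#' @export
confetti_colors <- function() c("mCFP", "nGFP", "YFP", "RFP")

#' Default study vocabularies
#'
#' Timepoints and hemisphere conditions accepted by [validate_study()] unless
#' a custom vocabulary is supplied.
#'
#' @return A list with elements `timepoints` and `conditions`.
#' @export
default_vocabulary <- function() {
  list(
    timepoints = c("2d", "1w", "2w", "4w", "8w", "12w"),
    conditions = c("stroke", "contralateral")
  )
}

cell_columns <- function() {
  c("cell_id", "image_id", "x", "y", "z", "color", "ki67")
}

stack_columns <- function() {
  c("image_id", "mouse_id", "condition", "timepoint",
    "x_extent", "y_extent", "z_height")
}

#' Construct a single image stack
#'
#' @param image_id Unique identifier of the image stack.
#' @param mouse_id Identifier of the animal the stack belongs to.
#' @param condition Hemisphere condition (e.g. `"stroke"`, `"contralateral"`).
#' @param timepoint Timepoint label (e.g. `"2w"`).
#' @param x_extent,y_extent Lateral extents of the imaged box in um.
#' @param z_height Height of the z-stack in um.
#' @param cells `data.frame` with columns `cell_id`, `x`, `y`, `z`, `color`
#'   and optionally `ki67` (logical, may be `NA`).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(image_id, mouse_id, condition, timepoint,
                        x_extent, y_extent, z_height,
                        cells = empty_cells()) {
  stopifnot(length(image_id) == 1, length(mouse_id) == 1)
  if (!(x_extent > 0 && y_extent > 0 && z_height > 0)) {
    stop("stack extents must be strictly positive")
  }
  cells <- as.data.frame(cells)
  if (is.null(cells$ki67)) cells$ki67 <- rep(NA, nrow(cells))
  if (is.null(cells$cell_id)) {
    cells$cell_id <- if (nrow(cells)) {
      paste0(image_id, "_c", seq_len(nrow(cells)))
    } else {
      character(0)
    }
  }
  cells <- cells[, c("cell_id", "x", "y", "z", "color", "ki67"), drop = FALSE]
  cells$ki67 <- as.logical(cells$ki67)
  obj <- structure(
    list(image_id = as.character(image_id),
         mouse_id = as.character(mouse_id),
         condition = as.character(condition),
         timepoint = as.character(timepoint),
         x_extent = as.numeric(x_extent),
         y_extent = as.numeric(y_extent),
         z_height = as.numeric(z_height),
         cells = cells),
    class = "image_stack"
  )
  bad_color <- !(cells$color %in% confetti_colors())
  if (any(bad_color)) {
    stop(sprintf("cell %s: color '%s' is not one of %s",
                 cells$cell_id[which(bad_color)[1]],
                 cells$color[which(bad_color)[1]],
                 paste(confetti_colors(), collapse = "/")))
  }
  out <- cells$x < 0 | cells$x > x_extent |
    cells$y < 0 | cells$y > y_extent |
    cells$z < 0 | cells$z > z_height
  if (any(out)) {
    stop(sprintf("cell %s lies outside the stack bounds",
                 cells$cell_id[which(out)[1]]))
  }
  obj
}

empty_cells <- function() {
  data.frame(cell_id = character(0), x = numeric(0), y = numeric(0),
             z = numeric(0), color = character(0), ki67 = logical(0),
             stringsAsFactors = FALSE)
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack %s> mouse %s, %s/%s, %g x %g x %g um, %d cells\n",
              x$image_id, x$mouse_id, x$condition, x$timepoint,
              x$x_extent, x$y_extent, x$z_height, nrow(x$cells)))
  invisible(x)
}

#' Assemble a study table from image stacks
#'
#' A study table holds every labeled cell of a study together with the stack
#' geometry and animal/condition/timepoint metadata needed by the ring
#' statistic (which averages cell -> image -> mouse -> group) and by clone
#' detection.
#'
#' @param stacks A list of [image_stack()] objects.
#' @return An object of class `study_table` with components `cells` (one row
#'   per cell) and `stacks` (one row per image).
#' @export
study_table <- function(stacks) {
  if (inherits(stacks, "image_stack")) stacks <- list(stacks)
  stopifnot(all(vapply(stacks, inherits, logical(1), "image_stack")))
  ids <- vapply(stacks, `[[`, character(1), "image_id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate image_id '%s'", ids[duplicated(ids)][1]))
  }
  meta <- do.call(rbind, lapply(stacks, function(s) {
    data.frame(image_id = s$image_id, mouse_id = s$mouse_id,
               condition = s$condition, timepoint = s$timepoint,
               x_extent = s$x_extent, y_extent = s$y_extent,
               z_height = s$z_height, stringsAsFactors = FALSE)
  }))
  if (is.null(meta)) {
    meta <- data.frame(image_id = character(0), mouse_id = character(0),
                       condition = character(0), timepoint = character(0),
                       x_extent = numeric(0), y_extent = numeric(0),
                       z_height = numeric(0), stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, lapply(stacks, function(s) {
    if (!nrow(s$cells)) return(NULL)
    cbind(data.frame(cell_id = s$cells$cell_id,
                     image_id = s$image_id, stringsAsFactors = FALSE),
          s$cells[, c("x", "y", "z", "color", "ki67"), drop = FALSE])
  }))
  if (is.null(cells)) {
    cells <- data.frame(cell_id = character(0), image_id = character(0),
                        x = numeric(0), y = numeric(0), z = numeric(0),
                        color = character(0), ki67 = logical(0),
                        stringsAsFactors = FALSE)
  }
  rownames(cells) <- NULL
  rownames(meta) <- NULL
  structure(list(cells = cells, stacks = meta), class = "study_table")
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("<study_table> %d stacks, %d mice, %d cells\n",
              nrow(x$stacks), length(unique(x$stacks$mouse_id)),
              nrow(x$cells)))
  invisible(x)
}

#' Extract one image stack from a study table
#'
#' @param study A [study_table()].
#' @param image_id Identifier of the stack to extract.
#' @return An [image_stack()].
#' @export
get_stack <- function(study, image_id) {
  i <- match(image_id, study$stacks$image_id)
  if (is.na(i)) stop(sprintf("no stack with image_id '%s'", image_id))
  m <- study$stacks[i, ]
  cells <- study$cells[study$cells$image_id == image_id,
                       c("cell_id", "x", "y", "z", "color", "ki67"),
                       drop = FALSE]
  rownames(cells) <- NULL
  image_stack(m$image_id, m$mouse_id, m$condition, m$timepoint,
              m$x_extent, m$y_extent, m$z_height, cells)
}

#' Split a study table into image stacks
#'
#' @param study A [study_table()].
#' @return Named list of [image_stack()] objects (names = image ids).
#' @export
study_stacks <- function(study) {
  ids <- study$stacks$image_id
  stats::setNames(lapply(ids, function(i) get_stack(study, i)), ids)
}

#' Restrict a study table to one (timepoint, condition) group
#'
#' @param study A [study_table()].
#' @param timepoint,condition Group labels; `NULL` keeps all levels.
#' @return A [study_table()] with the matching stacks only.
#' @export
subset_group <- function(study, timepoint = NULL, condition = NULL) {
  keep <- rep(TRUE, nrow(study$stacks))
  if (!is.null(timepoint)) keep <- keep & study$stacks$timepoint == timepoint
  if (!is.null(condition)) keep <- keep & study$stacks$condition == condition
  ids <- study$stacks$image_id[keep]
  structure(list(
    cells = study$cells[study$cells$image_id %in% ids, , drop = FALSE],
    stacks = study$stacks[keep, , drop = FALSE]
  ), class = "study_table")
}

#' Read a cell table from CSV
#'
#' The interchange format is one comma-separated UTF-8 file with a header and
#' one row per cell: `cell_id, image_id, mouse_id, condition, timepoint,
#' x_um, y_um, z_um, color, ki67, x_extent_um, y_extent_um, z_height_um`.
#' Stack geometry is embedded per row (constant within an `image_id`);
#' `ki67` may be empty.
#'
#' @param path Path to the CSV file.
#' @return A validated [study_table()]; row order within each stack is
#'   preserved.
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(df$ki67)) df$ki67 <- as.logical(df$ki67)
  required <- c("cell_id", "image_id", "mouse_id", "condition", "timepoint",
                "x_um", "y_um", "z_um", "color",
                "x_extent_um", "y_extent_um", "z_height_um")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("cell table is missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  if (is.null(df$ki67)) df$ki67 <- NA
  bad <- !(df$color %in% confetti_colors())
  if (any(bad)) {
    stop(sprintf("row %d: color '%s' is not one of %s",
                 which(bad)[1], df$color[which(bad)[1]],
                 paste(confetti_colors(), collapse = "/")))
  }
  if (!nrow(df)) return(study_table(list()))
  stacks <- lapply(split(df, factor(df$image_id, levels = unique(df$image_id))),
                   function(g) {
    image_stack(g$image_id[1], g$mouse_id[1], g$condition[1], g$timepoint[1],
                g$x_extent_um[1], g$y_extent_um[1], g$z_height_um[1],
                data.frame(cell_id = g$cell_id, x = g$x_um, y = g$y_um,
                           z = g$z_um, color = g$color, ki67 = g$ki67,
                           stringsAsFactors = FALSE))
  })
  study_table(unname(stacks))
}

#' Write a cell table to CSV
#'
#' Inverse of [read_cell_table()]; the round trip is lossless for every
#' field including absent `ki67`. Stacks without cells cannot be represented
#' in the one-row-per-cell format and are dropped with a warning.
#'
#' @param study A [study_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(study, path) {
  stopifnot(inherits(study, "study_table"))
  m <- study$stacks[match(study$cells$image_id, study$stacks$image_id), ]
  empty <- setdiff(study$stacks$image_id, study$cells$image_id)
  if (length(empty)) {
    warning(sprintf("dropping %d stack(s) without cells: %s",
                    length(empty), paste(empty, collapse = ", ")))
  }
  out <- data.frame(
    cell_id = study$cells$cell_id,
    image_id = study$cells$image_id,
    mouse_id = m$mouse_id,
    condition = m$condition,
    timepoint = m$timepoint,
    x_um = study$cells$x,
    y_um = study$cells$y,
    z_um = study$cells$z,
    color = study$cells$color,
    ki67 = study$cells$ki67,
    x_extent_um = m$x_extent,
    y_extent_um = m$y_extent,
    z_height_um = m$z_height,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Validate a study table
#'
#' Checks every type invariant (unique image ids, positive extents, colors in
#' the four-label vocabulary, cells within bounds, condition/timepoint in the
#' declared vocabulary) without mutating the study.
#'
#' @param study A [study_table()].
#' @param vocabulary List with `timepoints` and `conditions` character
#'   vectors; defaults to [default_vocabulary()].
#' @return Character vector of violations (empty if the study is valid), each
#'   naming the offending entity and rule.
#' @export
validate_study <- function(study, vocabulary = default_vocabulary()) {
  v <- character(0)
  st <- study$stacks
  dup <- unique(st$image_id[duplicated(st$image_id)])
  for (d in dup) v <- c(v, sprintf("stack %s: duplicate image_id", d))
  for (i in seq_len(nrow(st))) {
    s <- st[i, ]
    if (!(s$x_extent > 0 && s$y_extent > 0 && s$z_height > 0)) {
      v <- c(v, sprintf("stack %s: non-positive extent", s$image_id))
    }
    if (!s$condition %in% vocabulary$conditions) {
      v <- c(v, sprintf("stack %s: condition '%s' not in vocabulary",
                        s$image_id, s$condition))
    }
    if (!s$timepoint %in% vocabulary$timepoints) {
      v <- c(v, sprintf("stack %s: timepoint '%s' not in vocabulary",
                        s$image_id, s$timepoint))
    }
  }
  cs <- study$cells
  orphan <- !(cs$image_id %in% st$image_id)
  for (i in which(orphan)) {
    v <- c(v, sprintf("cell %s: unknown image_id '%s'",
                      cs$cell_id[i], cs$image_id[i]))
  }
  bad_color <- !(cs$color %in% confetti_colors())
  for (i in which(bad_color)) {
    v <- c(v, sprintf("cell %s: color '%s' outside the four labels",
                      cs$cell_id[i], cs$color[i]))
  }
  m <- st[match(cs$image_id, st$image_id), ]
  out <- !orphan & (cs$x < 0 | cs$x > m$x_extent |
                    cs$y < 0 | cs$y > m$y_extent |
                    cs$z < 0 | cs$z > m$z_height)
  for (i in which(out)) {
    v <- c(v, sprintf("cell %s: position outside stack bounds", cs$cell_id[i]))
  }
  dup_cell <- unique(cs$cell_id[duplicated(cs$cell_id)])
  for (d in dup_cell) v <- c(v, sprintf("cell %s: duplicate cell_id", d))
  v
}

#' Construct a binary 3D cell mask
#'
#' @param voxels Logical or 0/1 3D array (x, y, z order).
#' @param voxel_size Numeric length-3 vector `(dx, dy, dz)` in um.
#' @return An object of class `cell_mask`.
#' @export
cell_mask <- function(voxels, voxel_size) {
  voxels <- array(as.logical(voxels), dim = dim(voxels))
  stopifnot(length(dim(voxels)) == 3, length(voxel_size) == 3)
  if (!all(voxel_size > 0)) stop("voxel_size must be strictly positive")
  if (!any(voxels)) stop("cell mask has no foreground voxel")
  structure(list(voxels = voxels, voxel_size = as.numeric(voxel_size)),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> %s voxels of %s um, %d foreground\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x"),
              sum(x$voxels)))
  invisible(x)
}

#' Read a binary cell mask from a multi-page TIFF
#'
#' Pages are z-planes; pixel values > 0.5 are foreground. The voxel size is
#' not stored in the file and must be supplied.
#'
#' @param path TIFF file path.
#' @param voxel_size Numeric `(dx, dy, dz)` in um.
#' @return A [cell_mask()].
#' @export
read_cell_mask <- function(path, voxel_size) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  d <- dim(pages[[1]])
  vox <- array(FALSE, dim = c(d[2], d[1], nz))  # rows = y, cols = x
  for (k in seq_len(nz)) vox[, , k] <- t(pages[[k]] > 0.5)
  cell_mask(vox, voxel_size)
}

#' Write a binary cell mask to a multi-page TIFF
#'
#' @param mask A [cell_mask()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_cell_mask <- function(mask, path) {
  stopifnot(inherits(mask, "cell_mask"))
  d <- dim(mask$voxels)
  pages <- lapply(seq_len(d[3]), function(k) {
    t(mask$voxels[, , k]) * 1
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}
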