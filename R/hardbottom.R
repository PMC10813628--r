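#' Boulder density classes and the geogenic hard-substrate rule
#'
#' Boulder detections (point coordinates from side-scan mosaics) are binned
#' into per-cell counts on a 50 x 50 m grid and mapped to three density
#' classes: class 1 (no boulders), class 2 (1-5 boulders), class 3 (more than
#' 5 boulders). A cell carries geogenic hard substrate when it is class 3, or
#' class 2 on lag sediment; all other cells are soft substrate. Outside
#' hydroacoustically surveyed detail areas, hard substrate comes from reef
#' polygons only.
#'
#' @name hard-bottom
NULL

#' Grid geometry
#'
#' Axis-aligned grid; row 1 is the northernmost row. Cell (i, j) covers the
#' half-open square
#' `[xmin + (j-1)c, xmin + jc) x [ymin + (nrow-i)c, ymin + (nrow-i+1)c)`,
#' so each point belongs to exactly one cell and points on the outer
#' top/right boundary fall outside.
#'
#' @param xmin,ymin south-west corner (m).
#' @param nrow,ncol grid dimensions.
#' @param cell_size cell edge length (m).
#' @return an object of class `grid_geometry`.
#' @export
grid_geometry <- function(xmin, ymin, nrow, ncol, cell_size) {
  stopifnot(nrow >= 1, ncol >= 1, cell_size > 0)
  structure(list(xmin = xmin, ymin = ymin, nrow = nrow, ncol = ncol,
                 cell_size = cell_size),
            class = "grid_geometry")
}

#' Locate points on a grid
#'
#' @param geom a [grid_geometry()].
#' @param x,y point coordinates.
#' @return data.frame with columns `row`, `col`; NA for points outside.
#' @export
locate_cells <- function(geom, x, y) {
  c0 <- geom$cell_size
  col <- floor((x - geom$xmin) / c0) + 1L
  row_from_s <- floor((y - geom$ymin) / c0) + 1L
  row <- geom$nrow - row_from_s + 1L
  inside <- col >= 1L & col <= geom$ncol & row >= 1L & row <= geom$nrow
  data.frame(row = ifelse(inside, row, NA_integer_),
             col = ifelse(inside, col, NA_integer_))
}

#' Cell-centre coordinates
#'
#' @inheritParams locate_cells
#' @param row,col cell indices.
#' @return data.frame with columns `x`, `y`.
#' @export
cell_centres <- function(geom, row, col) {
  c0 <- geom$cell_size
  data.frame(x = geom$xmin + (col - 0.5) * c0,
             y = geom$ymin + (geom$nrow - row + 0.5) * c0)
}

#' Count boulder points per grid cell
#'
#' Each point is counted in exactly one cell (half-open convention); points
#' outside the grid extent are excluded with a warning, and the number
#' excluded is recorded in attribute `n_excluded`.
#'
#' @param points data.frame with columns `x`, `y`.
#' @param geom a [grid_geometry()].
#' @return integer matrix (nrow x ncol) of counts.
#' @export
grid_boulder_counts <- function(points, geom) {
  counts <- matrix(0L, geom$nrow, geom$ncol)
  if (nrow(points)) {
    loc <- locate_cells(geom, points$x, points$y)
    out <- is.na(loc$row)
    if (any(out)) {
      warning(sum(out), " boulder point(s) outside grid extent excluded",
              call. = FALSE)
    }
    loc <- loc[!out, , drop = FALSE]
    if (nrow(loc)) {
      tab <- table(factor(loc$row, levels = seq_len(geom$nrow)),
                   factor(loc$col, levels = seq_len(geom$ncol)))
      counts <- matrix(as.integer(tab), geom$nrow, geom$ncol)
    }
    attr(counts, "n_excluded") <- sum(out)
  } else {
    attr(counts, "n_excluded") <- 0L
  }
  counts
}

#' Bin boulder counts into density classes
#'
#' Class 1: no boulders; class 2: 1-5 boulders; class 3: more than 5.
#'
#' @param count non-negative integer vector (or matrix) of per-cell counts.
#' @return integer vector/matrix of classes in \{1, 2, 3\}; NA passes through.
#' @examples
#' classify_boulder_density(c(0, 5, 6))  # 1 2 3
#' @export
classify_boulder_density <- function(count) {
  if (any(!is.na(count) & count < 0)) {
    stop("boulder count must be non-negative", call. = FALSE)
  }
  cls <- ifelse(is.na(count), NA_integer_,
                ifelse(count == 0, 1L, ifelse(count <= 5, 2L, 3L)))
  if (is.matrix(count)) cls <- matrix(cls, nrow(count), ncol(count))
  cls
}

#' Apply the geogenic hard-substrate rule
#'
#' A cell is hard substrate iff its boulder class is 3, or its class is 2 and
#' its sediment is lag sediment; otherwise it is soft substrate. The result
#' carries attribute `provenance` set to `"boulder_rule"`.
#'
#' @param boulder_class integer vector/matrix of classes in \{1, 2, 3\}.
#' @param sediment_class character vector/matrix of BSH level A classes.
#' @return logical vector/matrix; TRUE = hard substrate.
#' @export
assign_hard_substrate <- function(boulder_class, sediment_class) {
  ok <- is.na(boulder_class) | boulder_class %in% 1:3
  if (!all(ok)) stop("boulder class must be 1, 2 or 3", call. = FALSE)
  hard <- boulder_class == 3L |
    (boulder_class == 2L & sediment_class == "LagSed")
  if (is.matrix(boulder_class)) {
    hard <- matrix(hard, nrow(boulder_class), ncol(boulder_class))
  }
  attr(hard, "provenance") <- "boulder_rule"
  hard
}

#' Combine the boulder rule with reef polygons into a hard-substrate mask
#'
#' Inside the surveyed footprint the boulder rule decides; outside it, a cell
#' is hard substrate only when its centre lies inside a reef polygon. A
#' character provenance matrix (`"boulder_rule"`/`"reef_polygon"`/NA) is
#' attached as attribute `provenance`.
#'
#' @param boulder_class integer matrix of boulder classes (NA outside the
#'   surveyed footprint).
#' @param sediment_class character matrix of BSH level A classes.
#' @param geom a [grid_geometry()].
#' @param reef_polygons optional list of polygons (see [polygon_area()]).
#' @return logical matrix with attribute `provenance`.
#' @export
hard_substrate_mask <- function(boulder_class, sediment_class, geom,
                                reef_polygons = NULL) {
  hard <- matrix(FALSE, geom$nrow, geom$ncol)
  prov <- matrix(NA_character_, geom$nrow, geom$ncol)
  surveyed <- !is.na(boulder_class)
  rule <- assign_hard_substrate(boulder_class, sediment_class)
  hard[surveyed] <- rule[surveyed]
  prov[surveyed & hard] <- "boulder_rule"
  if (!is.null(reef_polygons) && length(reef_polygons)) {
    idx <- which(!surveyed, arr.ind = TRUE)
    if (nrow(idx)) {
      ctr <- cell_centres(geom, idx[, 1], idx[, 2])
      inside <- rep(FALSE, nrow(idx))
      for (poly in reef_polygons) {
        inside <- inside | point_in_polygon(ctr$x, ctr$y, poly)
      }
      hard[idx[inside, , drop = FALSE]] <- TRUE
      prov[idx[inside, , drop = FALSE]] <- "reef_polygon"
    }
  }
  attr(hard, "provenance") <- prov
  hard
}
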