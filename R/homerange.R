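## Minimum convex polygon home ranges on planar (projected) coordinates, a
## fixed-origin raster of each range, and the summed other-group male-density
## overlap used downstream as a log offset. No geodesy: the study site is a
## small island and coordinates are metres.

#' Minimum convex polygon of location points
#'
#' @param points `data.frame` with numeric columns `x` and `y` (daily group
#'   location records).
#' @return `data.frame(x, y)` of hull vertices in counterclockwise order,
#'   class `"home_range_polygon"`.
#' @export
minimum_convex_polygon <- function(points) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  pts <- unique(points[, c("x", "y")])
  if (nrow(pts) < 3L) stop("minimum_convex_polygon: need >= 3 distinct points", call. = FALSE)
  h <- grDevices::chull(pts$x, pts$y)
  if (length(h) < 3L) stop("minimum_convex_polygon: points are collinear", call. = FALSE)
  out <- pts[rev(h), c("x", "y")]  # chull is clockwise; reverse to CCW
  rownames(out) <- NULL
  class(out) <- c("home_range_polygon", "data.frame")
  out
}

#' Polygon area by the shoelace formula
#' @param poly A `home_range_polygon` (or any `x`,`y` vertex data.frame in order).
#' @return Numeric area.
#' @export
polygon_area <- function(poly) {
  x <- poly$x; y <- poly$y
  n <- length(x)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

## Inclusive point-in-convex-polygon test: a point is inside when it lies on
## the interior side of (or on) every edge of the CCW-ordered hull.
.points_in_convex <- function(px, py, poly) {
  x <- poly$x; y <- poly$y
  n <- length(x)
  scale <- max(abs(c(x, y)), 1)
  eps <- 1e-9 * scale * scale
  inside <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cross <- (x[j] - x[i]) * (py - y[i]) - (y[j] - y[i]) * (px - x[i])
    inside <- inside & (cross >= -eps)
  }
  inside
}

#' Rasterize a home range onto a fixed grid
#'
#' The grid is anchored at `origin` with square cells of side `cell_size`;
#' a cell belongs to the range when its center lies inside or on the polygon
#' boundary. A fixed shared origin makes cells comparable across groups. Cell
#' counts near the boundary depend mildly on the anchor; the anchor used is
#' recorded in the attributes.
#'
#' @param poly A [minimum_convex_polygon()] result.
#' @param cell_size Cell side length (same units as coordinates). Default 25.
#' @param origin Numeric length-2 grid anchor. Default `c(0, 0)`.
#' @return `data.frame(ix, iy, cx, cy)` of occupied cells (indices and
#'   centers), with attributes `cell_size` and `origin`.
#' @export
rasterize_range <- function(poly, cell_size = 25, origin = c(0, 0)) {
  stopifnot(cell_size > 0, length(origin) == 2L)
  ix_lo <- floor((min(poly$x) - origin[1]) / cell_size)
  ix_hi <- ceiling((max(poly$x) - origin[1]) / cell_size) - 1L
  iy_lo <- floor((min(poly$y) - origin[2]) / cell_size)
  iy_hi <- ceiling((max(poly$y) - origin[2]) / cell_size) - 1L
  grid <- expand.grid(ix = seq.int(ix_lo, max(ix_lo, ix_hi)),
                      iy = seq.int(iy_lo, max(iy_lo, iy_hi)))
  cx <- origin[1] + (grid$ix + 0.5) * cell_size
  cy <- origin[2] + (grid$iy + 0.5) * cell_size
  keep <- .points_in_convex(cx, cy, poly)
  out <- data.frame(ix = grid$ix[keep], iy = grid$iy[keep],
                    cx = cx[keep], cy = cy[keep])
  attr(out, "cell_size") <- cell_size
  attr(out, "origin") <- origin
  out
}

#' Male density of a home range
#'
#' @param n_males Number of (breeding) males in the group.
#' @param n_cells Number of grid cells in the group's home range.
#' @return Males per grid cell.
#' @export
male_density <- function(n_males, n_cells) {
  stopifnot(n_males >= 0, n_cells >= 1)
  n_males / n_cells
}

#' Summed other-group male density over a focal home range
#'
#' For every grid cell of the focal group's range, the male densities of all
#' other groups whose ranges occupy that cell are summed; the overlap index
#' is the total over the focal range. It is additive over other groups and
#' deliberately asymmetric between group pairs.
#'
#' @param focal_group Focal group identifier.
#' @param ranges Named list (one element per group) of
#'   `list(cells = rasterize_range() result, density = males per cell)`.
#' @return `list(group, overlap_index, per_group)` where `per_group` is each
#'   other group's contribution.
#' @export
overlap_index <- function(focal_group, ranges) {
  stopifnot(focal_group %in% names(ranges))
  foc <- ranges[[focal_group]]$cells
  key <- function(cells) paste(cells$ix, cells$iy, sep = ":")
  fk <- key(foc)
  others <- setdiff(names(ranges), focal_group)
  per <- vapply(others, function(g) {
    hit <- sum(fk %in% key(ranges[[g]]$cells))
    hit * ranges[[g]]$density
  }, numeric(1))
  list(group = focal_group, overlap_index = sum(per), per_group = per)
}

#' Home-range overlap offsets for one season
#'
#' Builds each group's minimum convex polygon from its location records,
#' rasterizes it on a shared grid, and computes the summed other-group male
#' density over each focal range. A zero overlap would break the downstream
#' log offset, so it is an error unless a positive `zero_floor` is supplied
#' explicitly.
#'
#' @param locations `data.frame(group, x, y)` of daily location records for
#'   the season.
#' @param n_males Named vector of (breeding) male counts per group.
#' @param cell_size Grid cell size. Default 25.
#' @param origin Grid anchor. Default `c(0, 0)`.
#' @param zero_floor Optional positive value substituted for a zero overlap
#'   index (explicit opt-in). Default `NULL` = error on zero.
#' @return `data.frame(group, n_cells, density, overlap)`.
#' @export
season_overlap <- function(locations, n_males, cell_size = 25, origin = c(0, 0),
                           zero_floor = NULL) {
  groups <- sort(unique(locations$group))
  stopifnot(all(groups %in% names(n_males)))
  ranges <- lapply(groups, function(g) {
    poly <- minimum_convex_polygon(locations[locations$group == g, c("x", "y")])
    cells <- rasterize_range(poly, cell_size, origin)
    list(cells = cells, density = male_density(n_males[[g]], nrow(cells)))
  })
  names(ranges) <- groups
  ov <- vapply(groups, function(g) overlap_index(g, ranges)$overlap_index, numeric(1))
  if (any(ov == 0)) {
    if (is.null(zero_floor)) {
      stop("season_overlap: zero overlap index for group(s) ",
           paste(groups[ov == 0], collapse = ", "),
           "; a log offset needs a positive value (set zero_floor to opt in)",
           call. = FALSE)
    }
    stopifnot(zero_floor > 0)
    ov[ov == 0] <- zero_floor
  }
  data.frame(group = groups,
             n_cells = vapply(groups, function(g) nrow(ranges[[g]]$cells), integer(1)),
             density = vapply(groups, function(g) ranges[[g]]$density, numeric(1)),
             overlap = ov, stringsAsFactors = FALSE)
}
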