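# Areal spline bases. For each city: lay a regular 100 x 100 grid of points
# over the minimum bounding rectangle of the city's polygons, evaluate a 2D
# tensor-product B-spline basis at those points, then average the basis
# values over the grid points falling inside each region polygon. The basis
# count is L = floor(r * N) where N is the number of regions and r the
# spline ratio.

#' Regular grid of points over the bounding rectangle of a city
#'
#' @param city_polygons list of polygons (one per region).
#' @param n_side points per side (default 100, i.e. 10,000 points).
#' @return n_side^2 x 2 matrix of coordinates, corners included; the
#'   bounding rectangle is attached as attribute `"bbox"`.
#' @export
grid_points <- function(city_polygons, n_side = 100) {
  bb <- polygons_bbox(city_polygons)
  if (bb["xmax"] <= bb["xmin"] || bb["ymax"] <= bb["ymin"]) {
    stop("degenerate (zero-area) bounding rectangle")
  }
  gx <- seq(bb["xmin"], bb["xmax"], length.out = n_side)
  gy <- seq(bb["ymin"], bb["ymax"], length.out = n_side)
  pts <- cbind(x = rep(gx, each = n_side), y = rep(gy, times = n_side))
  attr(pts, "bbox") <- bb
  pts
}

# Univariate B-spline basis with m functions on [a, b]: order min(4, m)
# (constant, linear, quadratic, cubic as m grows), equally spaced interior
# knots, full boundary-knot multiplicity. Partition of unity by construction.
axis_basis <- function(x, a, b, m) {
  if (m == 1) return(matrix(1, length(x), 1))
  ord <- min(4L, m)
  n_interior <- m - ord
  interior <- if (n_interior > 0) {
    seq(a, b, length.out = n_interior + 2)[-c(1, n_interior + 2)]
  } else numeric(0)
  knots <- c(rep(a, ord), interior, rep(b, ord))
  splines::splineDesign(knots, pmin(pmax(x, a), b), ord = ord)
}

#' Tensor-product spline basis values at points
#'
#' Builds the 2D basis for target count `L`: per-axis count
#' `m = ceiling(sqrt(L))`, tensor the two axes, keep the first `L` products
#' in row-major order (x-index major). The full `m^2` tensor is a partition
#' of unity; truncation to `L < m^2` drops that property but keeps
#' nonnegativity and compact support.
#'
#' @param points k x 2 coordinate matrix; the spanning rectangle is taken
#'   from attribute `"bbox"` if present, else from the coordinate ranges.
#' @param L number of basis functions (>= 1).
#' @return k x L matrix of basis values; the basis definition is attached as
#'   attribute `"basis_def"` so values can be re-evaluated at new points.
#' @export
cubic_basis_values <- function(points, L) {
  if (L < 1) stop("L must be >= 1")
  bb <- attr(points, "bbox")
  if (is.null(bb)) {
    bb <- c(xmin = min(points[, 1]), ymin = min(points[, 2]),
            xmax = max(points[, 1]), ymax = max(points[, 2]))
  }
  m <- ceiling(sqrt(L))
  def <- list(bbox = bb, m = m, L = L)
  out <- eval_tensor_basis(def, points)
  attr(out, "basis_def") <- def
  out
}

eval_tensor_basis <- function(def, points) {
  bb <- def$bbox; m <- def$m; L <- def$L
  bx <- axis_basis(points[, 1], bb["xmin"], bb["xmax"], m)
  by <- axis_basis(points[, 2], bb["ymin"], bb["ymax"], m)
  out <- matrix(0, nrow(points), L)
  for (l in seq_len(L)) {
    i <- (l - 1) %/% m + 1
    j <- (l - 1) %% m + 1
    out[, l] <- bx[, i] * by[, j]
  }
  out
}

#' Average basis values over grid points inside each region
#'
#' Implements the evaluate-then-average construction
#' `B[j, l] = mean of basis l over grid points falling in region j`.
#' Regions containing no grid point fall back to the basis value at a
#' representative interior point (with a warning); an error is raised only
#' if that also fails.
#'
#' @param basis_at_points k x L matrix from [cubic_basis_values()].
#' @param points the k x 2 grid the basis was evaluated at.
#' @param region_polygons list of polygons, one per region.
#' @param grid optional fast-path descriptor for axis-aligned unit-cell
#'   cities: list(origin = c(x0, y0), cell = size, dim = cells per side,
#'   cell_index = region's (col-major) cell number). Uses closed-left /
#'   open-right edges so each grid point lands in exactly one cell.
#' @return N x L matrix of region-averaged basis values.
#' @export
integrate_over_regions <- function(basis_at_points, points, region_polygons,
                                   grid = NULL) {
  L <- ncol(basis_at_points)
  N <- length(region_polygons)
  B <- matrix(0, N, L)
  if (!is.null(grid)) {
    d <- grid$dim
    ix <- pmin(pmax(floor((points[, 1] - grid$origin[1]) / grid$cell), 0), d - 1)
    iy <- pmin(pmax(floor((points[, 2] - grid$origin[2]) / grid$cell), 0), d - 1)
    cell_of_point <- ix * d + iy + 1
    for (j in seq_len(N)) {
      sel <- cell_of_point == grid$cell_index[j]
      B[j, ] <- colMeans(basis_at_points[sel, , drop = FALSE])
    }
    return(B)
  }
  def <- attr(basis_at_points, "basis_def")
  for (j in seq_len(N)) {
    sel <- points_in_polygon(region_polygons[[j]], points)
    if (!any(sel)) {
      if (is.null(def)) {
        stop("region ", j, " contains no grid point and basis definition ",
             "is unavailable for fallback")
      }
      warning("region ", j, " contains no grid point; ",
              "using representative interior point")
      rp <- matrix(representative_point(region_polygons[[j]]), ncol = 2)
      B[j, ] <- eval_tensor_basis(def, rp)
    } else {
      B[j, ] <- colMeans(basis_at_points[sel, , drop = FALSE])
    }
  }
  B
}

#' Build the areal spline basis for one city
#'
#' Composes [grid_points()], [cubic_basis_values()] and
#' [integrate_over_regions()] with `L = floor(r * N)`. At ratio 0 the basis
#' is empty (no spatial term).
#'
#' @param table a [region_table()] with geometry attached, or a city
#'   geometry object from [make_grid_cities()].
#' @param city_id which city to build the basis for.
#' @param r spline ratio in `[0, 1]`.
#' @param n_side integration grid resolution per side (default 100).
#' @return An object of class `basis_matrix`: list with `city`, `L`, `B`
#'   (N x L), `ratio`, `regions`, `n_side`.
#' @export
make_basis <- function(table, city_id, r, n_side = 100) {
  if (r < 0 || r > 1) stop("r must be in [0, 1]")
  if (inherits(table, "city_geometry")) {
    geom <- table
  } else {
    geom <- city_geometry_from_table(table, city_id)
  }
  N <- length(geom$polys)
  L <- floor(r * N)
  if (r > 0 && L < 1) L <- 1L
  if (L == 0) {
    return(structure(list(city = geom$city, L = 0L,
                          B = matrix(0, N, 0), ratio = r,
                          regions = geom$region, n_side = n_side),
                     class = "basis_matrix"))
  }
  pts <- grid_points(geom$polys, n_side = n_side)
  bv <- cubic_basis_values(pts, L)
  B <- integrate_over_regions(bv, pts, geom$polys, grid = geom$grid)
  structure(list(city = geom$city, L = as.integer(L), B = B, ratio = r,
                 regions = geom$region, n_side = n_side),
            class = "basis_matrix")
}

city_geometry_from_table <- function(table, city_id) {
  cities <- attr(table, "cities")
  if (!is.null(cities)) {
    for (cg in cities) if (cg$city == city_id) return(cg)
  }
  geom <- attr(table, "geometry")
  if (is.null(geom)) stop("no geometry available for city ", city_id)
  sel <- which(table$city == city_id)
  if (length(sel) == 0) stop("unknown city ", city_id)
  structure(list(city = city_id, region = table$region[sel],
                 polys = geom[sel], grid = NULL),
            class = "city_geometry")
}

#' Build bases for all cities in a table
#'
#' @inheritParams make_basis
#' @return named list of `basis_matrix`, one per city (names = city ids).
#' @export
make_bases <- function(table, r, n_side = 100) {
  ids <- sort(unique(table$city))
  out <- lapply(ids, function(ci) make_basis(table, ci, r, n_side = n_side))
  names(out) <- ids
  out
}

#' @export
print.basis_matrix <- function(x, ...) {
  cat(sprintf("basis_matrix: city %s, %d regions x %d bases (ratio %.2f)\n",
              x$city, nrow(x$B), x$L, x$ratio))
  invisible(x)
}

#' Write per-city basis matrices to a long-format CSV
#'
#' Columns `city,region,l,value,ratio`, so users without geometry can supply
#' a precomputed basis directly.
#'
#' @param bases named list of `basis_matrix` (from [make_bases()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_basis_csv <- function(bases, path) {
  rows <- do.call(rbind, lapply(bases, function(b) {
    if (b$L == 0) {
      return(data.frame(city = b$city, region = b$regions, l = 0L,
                        value = 0, ratio = b$ratio))
    }
    data.frame(city = b$city,
               region = rep(b$regions, times = b$L),
               l = rep(seq_len(b$L), each = nrow(b$B)),
               value = as.vector(b$B),
               ratio = b$ratio)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read basis matrices written by [write_basis_csv()]
#'
#' @param path CSV path.
#' @return named list of `basis_matrix`.
#' @export
read_basis_csv <- function(path) {
  df <- utils::read.csv(path)
  out <- list()
  for (ci in sort(unique(df$city))) {
    d <- df[df$city == ci, ]
    regions <- sort(unique(d$region))
    L <- max(d$l)
    if (L == 0) {
      B <- matrix(0, length(regions), 0)
      L <- 0L
    } else {
      B <- matrix(0, length(regions), L)
      B[cbind(match(d$region, regions), d$l)] <- d$value
    }
    out[[as.character(ci)]] <- structure(
      list(city = ci, L = as.integer(L), B = B, ratio = d$ratio[1],
           regions = regions, n_side = NA_integer_),
      class = "basis_matrix")
  }
  out
}
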