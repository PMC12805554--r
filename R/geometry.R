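# Lightweight planar polygon handling. A "polygon" is a list of rings, each
# ring a k x 2 coordinate matrix (closed or open; closure is implied). Rings
# beyond the first are interpreted with even-odd parity (holes), matching
# mgcv::in.out(). Coordinates are assumed planar/projected; no CRS logic.

as_polygon <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    storage.mode(r) <- "double"
    if (ncol(r) != 2) stop("ring must be a k x 2 matrix")
    r
  })
  structure(rings, class = "spc_polygon")
}

rect_polygon <- function(xmin, ymin, xmax, ymax) {
  as_polygon(matrix(c(xmin, ymin, xmax, ymin, xmax, ymax, xmin, ymax,
                      xmin, ymin), ncol = 2, byrow = TRUE))
}

polygon_bbox <- function(poly) {
  xy <- do.call(rbind, unclass(poly))
  c(xmin = min(xy[, 1]), ymin = min(xy[, 2]),
    xmax = max(xy[, 1]), ymax = max(xy[, 2]))
}

#' Bounding box of a set of polygons
#' @param polys list of polygons.
#' @return named vector `xmin, ymin, xmax, ymax`.
#' @keywords internal
polygons_bbox <- function(polys) {
  bb <- sapply(polys, polygon_bbox)
  c(xmin = min(bb["xmin", ]), ymin = min(bb["ymin", ]),
    xmax = max(bb["xmax", ]), ymax = max(bb["ymax", ]))
}

# Even-odd point-in-polygon on all rings jointly, via mgcv::in.out with
# NA-separated boundary loops. Points exactly on an edge follow mgcv's
# convention; grid-city cells use an exact index fast path instead.
points_in_polygon <- function(poly, pts) {
  bnd <- NULL
  for (r in unclass(poly)) {
    r <- close_ring(r)
    bnd <- if (is.null(bnd)) r else rbind(bnd, c(NA, NA), r)
  }
  inside <- rep(FALSE, nrow(pts))
  bb <- polygon_bbox(poly)
  cand <- pts[, 1] >= bb["xmin"] & pts[, 1] <= bb["xmax"] &
    pts[, 2] >= bb["ymin"] & pts[, 2] <= bb["ymax"]
  if (any(cand)) {
    inside[cand] <- mgcv::in.out(bnd, pts[cand, , drop = FALSE])
  }
  inside
}

close_ring <- function(r) {
  if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])
  r
}

# Representative interior point: ring centroid if inside, else densified
# fallback over interior candidates.
representative_point <- function(poly) {
  r <- unclass(poly)[[1]]
  cen <- matrix(colMeans(close_ring(r)[-1, , drop = FALSE]), ncol = 2)
  if (points_in_polygon(poly, cen)) return(cen[1, ])
  bb <- polygon_bbox(poly)
  for (k in c(5, 11, 31)) {
    gx <- seq(bb["xmin"], bb["xmax"], length.out = k + 2)[-c(1, k + 2)]
    gy <- seq(bb["ymin"], bb["ymax"], length.out = k + 2)[-c(1, k + 2)]
    pts <- as.matrix(expand.grid(x = gx, y = gy))
    hit <- points_in_polygon(poly, pts)
    if (any(hit)) return(pts[which(hit)[1], ])
  }
  stop("no interior point found for polygon")
}

#' Read polygons from a GeoJSON FeatureCollection
#'
#' Each feature must carry `city` and `region` properties and a Polygon or
#' MultiPolygon geometry in planar coordinates.
#'
#' @param path GeoJSON file path.
#' @return named list of polygons, names `"city:region"`.
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection")
  }
  out <- list()
  for (f in gj$features) {
    props <- f$properties
    if (is.null(props$city) || is.null(props$region)) {
      stop("feature missing city/region properties")
    }
    g <- f$geometry
    rings <- switch(g$type,
      Polygon = lapply(g$coordinates, coords_to_ring),
      MultiPolygon = unlist(lapply(g$coordinates, function(pg) {
        lapply(pg, coords_to_ring)
      }), recursive = FALSE),
      stop("unsupported geometry type: ", g$type)
    )
    out[[paste(as.integer(props$city), as.integer(props$region), sep = ":")]] <-
      as_polygon(rings)
  }
  out
}

coords_to_ring <- function(coords) {
  do.call(rbind, lapply(coords, function(pt) c(pt[[1]], pt[[2]])))
}

#' Write polygons to a GeoJSON FeatureCollection
#'
#' @param polys list of polygons parallel to `city`/`region`.
#' @param city,region integer vectors identifying each polygon.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(polys, city, region, path) {
  features <- lapply(seq_along(polys), function(i) {
    rings <- lapply(unclass(polys[[i]]), function(r) {
      r <- close_ring(r)
      lapply(seq_len(nrow(r)), function(k) c(r[k, 1], r[k, 2]))
    })
    list(type = "Feature",
         properties = list(city = city[i], region = region[i]),
         geometry = list(type = "Polygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
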