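#' Construct a validated region table
#'
#' A region table holds one row per areal unit: a city identifier, a region
#' identifier unique within its city, a continuous outcome, a treatment
#' (binary 0/1 or a grade among "A","B","C","D"), and `p` numeric proxy
#' columns `w1..wp` that measure the latent non-spatial confounder with
#' error. Geometry (one polygon per row) may be attached, or omitted when a
#' precomputed basis matrix will be supplied directly.
#'
#' @param df data.frame with columns `city`, `region`, `outcome`, `treatment`
#'   and `w1..wp`.
#' @param geometry optional list of polygons (see [read_geojson()]), parallel
#'   to the rows of `df`, or `NULL`.
#' @return An object of class `region_table` (a data.frame with attributes
#'   `p` and `geometry`).
#' @export
region_table <- function(df, geometry = NULL) {
  req <- c("city", "region", "outcome", "treatment")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  wcols <- grep("^w[0-9]+$", names(df), value = TRUE)
  if (length(wcols) == 0) stop("no proxy columns w1..wp found")
  wcols <- paste0("w", seq_along(wcols))
  if (!all(wcols %in% names(df))) {
    stop("proxy columns must be consecutively numbered w1..wp")
  }

  df$city <- as.integer(df$city)
  df$region <- as.integer(df$region)
  key <- paste(df$city, df$region, sep = ":")
  if (anyDuplicated(key)) {
    stop("duplicate (city, region) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  for (cn in c("outcome", wcols)) {
    bad <- which(!is.finite(df[[cn]]))
    if (length(bad) > 0) {
      stop("non-finite value in column '", cn, "' at row ", bad[1])
    }
  }
  tr <- df$treatment
  if (is.numeric(tr)) {
    if (!all(tr %in% c(0, 1))) stop("binary treatment must be 0 or 1")
  } else {
    tr <- as.character(tr)
    bad <- setdiff(unique(tr), c("A", "B", "C", "D"))
    if (length(bad) > 0) stop("unknown treatment grade(s): ",
                              paste(bad, collapse = ", "))
    df$treatment <- tr
  }
  if (!is.null(geometry) && length(geometry) != nrow(df)) {
    stop("geometry list length must equal number of rows")
  }
  df <- df[order(df$city, df$region), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            p = length(wcols),
            geometry = geometry,
            class = c("region_table", "data.frame"))
}

#' @export
print.region_table <- function(x, ...) {
  cat(sprintf("region_table: %d regions, %d cities, p = %d proxies, geometry %s\n",
              nrow(x), length(unique(x$city)), attr(x, "p"),
              if (is.null(attr(x, "geometry"))) "absent" else "attached"))
  NextMethod()
}

#' Load a region table from CSV (and optional GeoJSON geometry)
#'
#' The CSV must have header columns `city,region,outcome,treatment,w1..wp`.
#' The optional GeoJSON is a FeatureCollection whose features carry `city`
#' and `region` properties; each feature's polygon is attached to the
#' matching CSV row. Coordinates must already be planar/projected; no CRS
#' handling is done.
#'
#' @param path_csv path to the CSV file.
#' @param path_geojson optional path to a GeoJSON FeatureCollection.
#' @return A [region_table()].
#' @export
load_region_table <- function(path_csv, path_geojson = NULL) {
  df <- utils::read.csv(path_csv, stringsAsFactors = FALSE)
  geometry <- NULL
  if (!is.null(path_geojson)) {
    gj <- read_geojson(path_geojson)
    key_df <- paste(as.integer(df$city), as.integer(df$region), sep = ":")
    idx <- match(names(gj), key_df)
    if (anyNA(idx)) {
      stop("geometry key(s) with no CSV row: ",
           paste(names(gj)[is.na(idx)], collapse = ", "))
    }
    geometry <- vector("list", nrow(df))
    geometry[idx] <- gj
  }
  tab <- region_table(df, geometry = NULL)
  if (!is.null(geometry)) {
    # region_table() reorders rows; re-match geometry on the sorted keys
    key_sorted <- paste(tab$city, tab$region, sep = ":")
    key_orig <- paste(as.integer(df$city), as.integer(df$region), sep = ":")
    attr(tab, "geometry") <- geometry[match(key_sorted, key_orig)]
  }
  tab
}

#' Write a region table to CSV (and optional GeoJSON)
#'
#' @param table a [region_table()].
#' @param path_csv output CSV path.
#' @param path_geojson optional output GeoJSON path (requires geometry).
#' @return `path_csv`, invisibly.
#' @export
write_region_table <- function(table, path_csv, path_geojson = NULL) {
  utils::write.csv(as.data.frame(table), path_csv, row.names = FALSE)
  if (!is.null(path_geojson)) {
    geom <- attr(table, "geometry")
    if (is.null(geom)) stop("table has no geometry to write")
    write_geojson(geom, table$city, table$region, path_geojson)
  }
  invisible(path_csv)
}

#' Center columns by city mean
#'
#' Subtracts the within-city mean from each named column, the preprocessing
#' applied to outcomes and proxies before model fitting so that city-level
#' shifts do not masquerade as treatment effects.
#'
#' @param table a [region_table()].
#' @param columns character vector of numeric column names to center.
#' @return The table with the named columns centered within every city.
#' @export
center_by_city <- function(table, columns) {
  unknown <- setdiff(columns, names(table))
  if (length(unknown) > 0) stop("unknown column(s): ",
                                paste(unknown, collapse = ", "))
  for (cn in columns) {
    if (!is.numeric(table[[cn]])) stop("column '", cn, "' is not numeric")
    table[[cn]] <- table[[cn]] - stats::ave(table[[cn]], table$city)
  }
  table
}

#' Box-Cox power transform
#'
#' `(v^lambda - 1) / lambda` for `lambda != 0`, `log(v)` for `lambda = 0`.
#' Values must be strictly positive; callers with exact zeros should add a
#' small offset first (see [boxcox_offset()]).
#'
#' @param values strictly positive numeric vector.
#' @param lambda power parameter; if `NULL` (default) it is estimated by
#'   profile-likelihood maximization via [boxcox_lambda()].
#' @return Transformed vector, with the lambda used in attribute `"lambda"`.
#' @export
boxcox <- function(values, lambda = NULL) {
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("boxcox requires strictly positive finite values; ",
         "add an offset for zeros (see boxcox_offset)")
  }
  if (is.null(lambda)) lambda <- boxcox_lambda(values)
  out <- if (abs(lambda) < .Machine$double.eps^0.5) {
    log(values)
  } else {
    (values^lambda - 1) / lambda
  }
  attr(out, "lambda") <- lambda
  out
}

#' Default additive offset for zero-valued observations
#'
#' Half the smallest positive value, the conventional choice when a
#' nonnegative rate variable with exact zeros is to be power-transformed.
#'
#' @param values nonnegative numeric vector.
#' @return Scalar offset (0 when there are no zeros).
#' @export
boxcox_offset <- function(values) {
  if (any(values < 0)) stop("values must be nonnegative")
  if (!any(values == 0)) return(0)
  pos <- values[values > 0]
  if (length(pos) == 0) stop("all values are zero")
  min(pos) / 2
}

#' Profile-likelihood estimate of the Box-Cox lambda
#'
#' Maximizes the profile log-likelihood of the normal model for the
#' transformed data (including the Jacobian term) over `interval`.
#'
#' @param values strictly positive numeric vector.
#' @param interval search interval for lambda.
#' @return Scalar lambda estimate.
#' @export
boxcox_lambda <- function(values, interval = c(-2, 2)) {
  if (any(values <= 0)) stop("values must be strictly positive")
  n <- length(values)
  slog <- sum(log(values))
  prof <- function(lam) {
    z <- if (abs(lam) < 1e-10) log(values) else (values^lam - 1) / lam
    s2 <- stats::var(z) * (n - 1) / n
    -n / 2 * log(s2) + (lam - 1) * slog
  }
  stats::optimize(prof, interval = interval, maximum = TRUE)$maximum
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles of their (Blom-offset) fractional ranks:
#' `qnorm((rank - 3/8) / (n + 1/4))`. Ties receive the average rank, so a
#' point mass (e.g. a zero-inflated proxy) maps to one shared quantile. The
#' result is invariant to any strictly monotone transform of the input.
#'
#' @param values numeric vector, length >= 2, not all equal.
#' @return Transformed vector.
#' @export
rank_inverse_normal <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  if (length(unique(values)) == 1) {
    stop("constant input: rank-based transform undefined")
  }
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(values) + 1 / 4))
}

#' Encode treatment as an indicator design
#'
#' Binary mode yields a single 0/1 column. Multilevel mode encodes grades
#' B, C, D as indicator columns with grade A the reference (all-zero row).
#'
#' @param table a [region_table()].
#' @param mode `"binary"` or `"multilevel"`.
#' @return An object of class `treatment_design`: list with `mode` and the
#'   n x K `indicator` matrix (K = 1 or 3).
#' @export
encode_treatment <- function(table, mode = c("binary", "multilevel")) {
  mode <- match.arg(mode)
  tr <- table$treatment
  if (mode == "binary") {
    if (!is.numeric(tr) || !all(tr %in% c(0, 1))) {
      stop("binary mode requires a 0/1 treatment column")
    }
    ind <- matrix(as.numeric(tr), ncol = 1,
                  dimnames = list(NULL, "treated"))
  } else {
    tr <- as.character(tr)
    if (!all(tr %in% c("A", "B", "C", "D"))) {
      stop("multilevel mode requires grades A-D")
    }
    ind <- sapply(c("B", "C", "D"), function(g) as.numeric(tr == g))
    dimnames(ind) <- list(NULL, c("B", "C", "D"))
  }
  structure(list(mode = mode, indicator = ind), class = "treatment_design")
}

#' Decode a treatment design back to the original treatment vector
#'
#' @param design a `treatment_design`.
#' @return 0/1 vector (binary) or grade character vector (multilevel).
#' @export
decode_treatment <- function(design) {
  ind <- design$indicator
  if (design$mode == "binary") return(as.numeric(ind[, 1]))
  grades <- rep("A", nrow(ind))
  for (g in colnames(ind)) grades[ind[, g] == 1] <- g
  grades
}
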