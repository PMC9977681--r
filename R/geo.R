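#' Gridded rainfall field
#'
#' A single-band raster of mean annual precipitation (mm/yr) on a regular
#' planar grid. Values are stored as a matrix whose first row is the
#' northernmost; the geotransform is the lower-left corner plus a square cell
#' size, the layout used by the ESRI ASCII grid text format this package
#' reads and writes.
#'
#' @param values Numeric matrix, row 1 = north; values >= 0 or nodata.
#' @param xmin,ymin Lower-left corner coordinates (m).
#' @param cell_size Cell edge length (m); must be > 0.
#' @param nodata Sentinel for missing cells (default -9999).
#' @return Object of class \code{rainfall_field}.
#' @export
rainfall_field <- function(values, xmin = 0, ymin = 0, cell_size, nodata = -9999) {
  stopifnot(is.matrix(values), is.numeric(cell_size), cell_size > 0)
  v <- values
  v[v == nodata] <- NA_real_
  if (any(v < 0, na.rm = TRUE)) stop("rainfall values must be >= 0 or nodata")
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 cell_size = cell_size, nodata = nodata),
            class = "rainfall_field")
}

#' @export
print.rainfall_field <- function(x, ...) {
  rng <- range(x$values[x$values != x$nodata])
  cat(sprintf("<rainfall_field> %d x %d cells @ %g m, range %.1f-%.1f mm/yr\n",
              nrow(x$values), ncol(x$values), x$cell_size, rng[1], rng[2]))
  invisible(x)
}

field_extent <- function(field) {
  c(xmin = field$xmin,
    xmax = field$xmin + ncol(field$values) * field$cell_size,
    ymin = field$ymin,
    ymax = field$ymin + nrow(field$values) * field$cell_size)
}

#' Mean annual rainfall from a layer stack
#'
#' Collapses a stack of rainfall grids to a long-term mean annual field.
#' Monthly stacks are first summed within each year (12 consecutive layers
#' per year), then averaged across years; annual stacks are averaged
#' directly. Cells that are nodata in any layer propagate to nodata.
#'
#' @param layers List of numeric matrices with identical dimensions, ordered
#'   chronologically.
#' @param frequency \code{"annual"} (one layer per year) or \code{"monthly"}
#'   (twelve layers per year).
#' @param nodata Nodata sentinel shared by all layers.
#' @return Matrix of mean annual precipitation, nodata where any input was.
#' @export
mean_annual_rainfall <- function(layers, frequency = c("annual", "monthly"),
                                 nodata = -9999) {
  frequency <- match.arg(frequency)
  stopifnot(is.list(layers), length(layers) >= 1L)
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all layers must share the same grid")
  if (frequency == "monthly" && length(layers) %% 12L != 0L) {
    stop(sprintf("incomplete year: %d monthly layers leave %d months missing",
                 length(layers), 12L - length(layers) %% 12L))
  }
  arr <- vapply(layers, function(m) { m[m == nodata] <- NA_real_; m },
                layers[[1]])
  if (frequency == "monthly") {
    ny <- length(layers) %/% 12L
    annual <- vapply(seq_len(ny), function(y)
      apply(arr[, , (y - 1L) * 12L + 1:12, drop = FALSE], c(1, 2), sum),
      arr[, , 1])
    if (ny == 1L) dim(annual) <- c(dim(arr)[1:2], 1L)
  } else {
    annual <- arr
  }
  out <- apply(annual, c(1, 2), mean)   # NA (nodata) propagates
  out[is.na(out)] <- nodata
  out
}

#' Extract rainfall at points by bilinear interpolation
#'
#' Interpolates between the four surrounding cell centres; coordinates
#' within half a cell of the grid edge use the edge cell's value (clamped).
#' Points outside the field bounds, or with any nodata neighbour, return
#' \code{NA}.
#'
#' @param field A \code{rainfall_field}.
#' @param x,y Point coordinates (m), equal length.
#' @return Numeric vector of rainfall (mm/yr) with \code{NA} for nodata or
#'   out-of-bounds points.
#' @export
extract_rainfall <- function(field, x, y) {
  stopifnot(inherits(field, "rainfall_field"), length(x) == length(y))
  v <- field$values
  v[v == field$nodata] <- NA_real_
  nr <- nrow(v); nc <- ncol(v); cs <- field$cell_size
  ext <- field_extent(field)
  xmax <- ext[["xmax"]]; ymax <- ext[["ymax"]]
  inside <- x >= field$xmin & x <= xmax & y >= field$ymin & y <= ymax
  # fractional column/row measured in cell-centre coordinates
  fc <- (x - field$xmin) / cs - 0.5
  fr <- (ymax - y) / cs - 0.5              # row 1 is north
  fc <- pmin(pmax(fc, 0), nc - 1)
  fr <- pmin(pmax(fr, 0), nr - 1)
  c0 <- pmin(floor(fc), nc - 1); c1 <- pmin(c0 + 1, nc - 1)
  r0 <- pmin(floor(fr), nr - 1); r1 <- pmin(r0 + 1, nr - 1)
  wx <- fc - c0; wy <- fr - r0
  idx <- function(r, c) v[cbind(r + 1, c + 1)]
  val <- (1 - wy) * ((1 - wx) * idx(r0, c0) + wx * idx(r0, c1)) +
         wy       * ((1 - wx) * idx(r1, c0) + wx * idx(r1, c1))
  val[!inside] <- NA_real_
  val
}

#' Rainfall zone definition
#'
#' The four mean-annual-precipitation zones of the study domain, as
#' half-open intervals except that the 1,000 mm/yr upper study bound is
#' inclusive: hyper-arid [0, 150), arid [150, 300), semi-arid [300, 600),
#' sub-humid [600, 1000]. Rainfall above 1,000 mm/yr is outside the domain.
#'
#' @return Data frame with columns \code{zone}, \code{lower}, \code{upper}.
#' @export
zone_definition <- function() {
  data.frame(zone  = c("hyper-arid", "arid", "semi-arid", "sub-humid"),
             lower = c(0, 150, 300, 600),
             upper = c(150, 300, 600, 1000),
             stringsAsFactors = FALSE)
}

#' Classify rainfall into zones
#'
#' Half-open interval lookup against \code{\link{zone_definition}}; rainfall
#' above the domain bound (1,000 mm/yr, itself included in sub-humid)
#' returns \code{NA} (masked, out of domain), as does \code{NA} input.
#'
#' @param p Mean annual precipitation (mm/yr), vectorised; negatives error.
#' @param zones Zone table (defaults to \code{zone_definition()}).
#' @return Factor with the zone levels, \code{NA} when out of domain.
#' @export
classify_zone <- function(p, zones = zone_definition()) {
  stopifnot(is.numeric(p))
  if (any(p < 0, na.rm = TRUE)) stop("rainfall must be non-negative")
  upper_bound <- max(zones$upper)
  out <- rep(NA_integer_, length(p))
  for (i in seq_len(nrow(zones))) {
    hit <- !is.na(p) & p >= zones$lower[i] & p < zones$upper[i]
    out[hit] <- i
  }
  out[!is.na(p) & p == upper_bound] <- nrow(zones)  # domain bound inclusive
  factor(zones$zone[out], levels = zones$zone)
}

#' Per-hectare carbon density grid
#'
#' Assigns trees to grid cells by centroid and sums their carbon into a
#' density raster (Mg C per hectare). With the default 100 m cells each cell
#' is exactly one hectare. Carbon is conserved: cell value times cell area
#' (ha), summed, equals the summed per-tree carbon.
#'
#' @param crowns Data frame with \code{x}, \code{y} (m) and \code{carbon_kg}
#'   (no missing values; offending ids are reported). An \code{id} column is
#'   used in error messages when present.
#' @param extent Numeric vector \code{c(xmin, xmax, ymin, ymax)} (m).
#' @param cell_size Cell edge (m), default 100.
#' @return \code{rainfall_field}-shaped object of class \code{density_grid}
#'   holding Mg C/ha values (list: values, xmin, ymin, cell_size).
#' @export
carbon_density_grid <- function(crowns, extent, cell_size = 100) {
  stopifnot(all(c("x", "y", "carbon_kg") %in% names(crowns)))
  bad <- which(is.na(crowns$carbon_kg))
  if (length(bad)) {
    ids <- if ("id" %in% names(crowns)) crowns$id[bad] else bad
    stop("crowns without carbon estimates: ",
         paste(utils::head(ids, 5), collapse = ", "),
         if (length(ids) > 5) " ..." else "")
  }
  nc <- max(1L, ceiling((extent[2] - extent[1]) / cell_size))
  nr <- max(1L, ceiling((extent[4] - extent[3]) / cell_size))
  vals <- matrix(0, nr, nc)
  if (nrow(crowns)) {
    ci <- pmin(pmax(floor((crowns$x - extent[1]) / cell_size), 0), nc - 1)
    ri <- pmin(pmax(floor((extent[4] - crowns$y) / cell_size), 0), nr - 1)
    cell <- ri * nc + ci
    sums <- tapply(crowns$carbon_kg, cell, sum)
    k <- as.integer(names(sums))
    vals[cbind(k %/% nc + 1L, k %% nc + 1L)] <- as.numeric(sums)
  }
  cell_ha <- (cell_size / 100)^2
  structure(list(values = vals / 1000 / cell_ha,
                 xmin = extent[1], ymin = extent[3],
                 cell_size = cell_size, nodata = -9999,
                 cell_ha = cell_ha),
            class = c("density_grid", "rainfall_field"))
}

#' Rainfall-zone summaries of per-tree carbon
#'
#' Summarises estimated trees by rainfall zone: tree count, mean per-tree
#' carbon, carbon density over the zone's land area, linear-interpolation
#' percentiles of per-tree carbon, each zone's share of total carbon, and
#' mean crown area.
#'
#' @param crowns Data frame with \code{zone}, \code{carbon_kg},
#'   \code{crown_area_m2}.
#' @param zone_area_ha Named numeric vector of land area (ha) per zone, used
#'   as the density denominator; names must cover the zones present.
#' @param probs Percentiles of per-tree carbon to report.
#' @return Data frame, one row per zone in \code{\link{zone_definition}}
#'   order; zones with no trees keep n = 0 and \code{NA} statistics.
#' @export
zonal_summary <- function(crowns, zone_area_ha,
                          probs = c(0.05, 0.10, 0.25, 0.75, 0.90, 0.95)) {
  stopifnot(all(c("zone", "carbon_kg", "crown_area_m2") %in% names(crowns)))
  zones <- zone_definition()$zone
  total_carbon <- sum(crowns$carbon_kg, na.rm = TRUE)
  rows <- lapply(zones, function(z) {
    sel <- crowns[!is.na(crowns$zone) & crowns$zone == z, , drop = FALSE]
    n <- nrow(sel)
    area_ha <- if (z %in% names(zone_area_ha)) zone_area_ha[[z]] else NA_real_
    qs <- if (n) stats::quantile(sel$carbon_kg, probs, names = FALSE, type = 7)
          else rep(NA_real_, length(probs))
    data.frame(zone = z, n_trees = n,
               mean_carbon_kg = if (n) mean(sel$carbon_kg) else NA_real_,
               carbon_density_mg_ha = if (!is.na(area_ha) && area_ha > 0)
                 sum(sel$carbon_kg) / 1000 / area_ha else NA_real_,
               carbon_share_pct = if (total_carbon > 0)
                 100 * sum(sel$carbon_kg) / total_carbon else NA_real_,
               mean_crown_area_m2 = if (n) mean(sel$crown_area_m2) else NA_real_,
               t(stats::setNames(qs, paste0("p", probs * 100))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-tree carbon percentile profile along the rainfall gradient
#'
#' Bins trees by their extracted mean annual rainfall (default 25 mm bins)
#' and reports per-bin mean and percentiles of per-tree carbon, the
#' aggregation behind carbon-vs-rainfall profile figures.
#'
#' @param crowns Data frame with \code{rainfall_mm} and \code{carbon_kg}.
#' @param bin_width Rainfall bin width (mm/yr).
#' @param probs Percentiles to report.
#' @return Long data frame: \code{bin_centre_mm}, \code{statistic},
#'   \code{carbon_kg}.
#' @export
rainfall_profile <- function(crowns, bin_width = 25,
                             probs = c(0.05, 0.25, 0.75, 0.95)) {
  stopifnot(all(c("rainfall_mm", "carbon_kg") %in% names(crowns)))
  ok <- !is.na(crowns$rainfall_mm)
  bin <- floor(crowns$rainfall_mm[ok] / bin_width)
  carbon <- crowns$carbon_kg[ok]
  out <- lapply(sort(unique(bin)), function(b) {
    cc <- carbon[bin == b]
    data.frame(bin_centre_mm = (b + 0.5) * bin_width,
               statistic = c("mean", paste0("p", probs * 100)),
               carbon_kg = c(mean(cc),
                             stats::quantile(cc, probs, names = FALSE)),
               n = length(cc))
  })
  do.call(rbind, out)
}
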