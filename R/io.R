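#' Write crowns to GeoJSON
#'
#' Serialises circular tree crowns as a GeoJSON FeatureCollection of polygon
#' rings (regular polygons approximating each circle), with the crown
#' attributes as feature properties. Coordinates are planar metres (the
#' synthetic CRS); numbers are written with full precision so identical
#' inputs produce identical files.
#'
#' @param crowns Data frame with \code{id}, \code{x}, \code{y},
#'   \code{crown_area_m2} and optionally estimate columns
#'   (\code{mass_w_kg}, \code{mass_f_kg}, \code{mass_r_kg},
#'   \code{carbon_kg}, \code{zone}, \code{rainfall_mm}).
#' @param path Output file path.
#' @param n_vertices Polygon vertices per circle.
#' @return \code{path}, invisibly.
#' @export
write_crowns_geojson <- function(crowns, path, n_vertices = 24L) {
  stopifnot(all(c("id", "x", "y", "crown_area_m2") %in% names(crowns)))
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)
  prop_cols <- setdiff(names(crowns), c("x", "y"))
  features <- lapply(seq_len(nrow(crowns)), function(i) {
    r <- sqrt(crowns$crown_area_m2[i] / pi)
    ring <- cbind(crowns$x[i] + r * cos(ang), crowns$y[i] + r * sin(ang))
    list(type = "Feature",
         properties = as.list(crowns[i, prop_cols, drop = FALSE]),
         geometry = list(type = "Polygon",
                         coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read crowns from GeoJSON
#'
#' Reads a FeatureCollection written by \code{\link{write_crowns_geojson}}
#' (or any polygon collection with comparable properties); the centroid and
#' ring area are recomputed from the polygon by the shoelace formula, and a
#' \code{crown_area_m2} property, when present, takes precedence over the
#' ring area.
#'
#' @param path GeoJSON file path.
#' @return Data frame with \code{id}, \code{x}, \code{y},
#'   \code{crown_area_m2} plus any further properties found.
#' @export
read_crowns_geojson <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(identical(g$type, "FeatureCollection"))
  rows <- lapply(g$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) unlist(p)))
    n <- nrow(ring) - 1L
    xs <- ring[1:n, 1]; ys <- ring[1:n, 2]
    x2 <- ring[2:(n + 1L), 1]; y2 <- ring[2:(n + 1L), 2]
    area <- abs(sum(xs * y2 - x2 * ys)) / 2
    props <- f$properties
    area <- if (!is.null(props$crown_area_m2)) props$crown_area_m2 else area
    c(list(x = mean(xs), y = mean(ys), crown_area_m2 = area),
      props[setdiff(names(props), "crown_area_m2")])
  })
  cols <- unique(unlist(lapply(rows, names)))
  out <- as.data.frame(lapply(stats::setNames(cols, cols), function(cl)
    unlist(lapply(rows, function(r) if (is.null(r[[cl]])) NA else r[[cl]]))),
    stringsAsFactors = FALSE)
  out[, c(intersect(c("id", "x", "y", "crown_area_m2"), cols),
          setdiff(cols, c("id", "x", "y", "crown_area_m2")))]
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text single-band raster interchange: a 6-line header
#' (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value) followed by rows
#' north to south.
#'
#' @param field A \code{rainfall_field} (or \code{density_grid}).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_asc <- function(field, path) {
  v <- field$values
  v[is.na(v)] <- field$nodata
  hdr <- c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", field$xmin),
           sprintf("yllcorner %.10g", field$ymin),
           sprintf("cellsize %.10g", field$cell_size),
           sprintf("NODATA_value %.10g", field$nodata))
  body <- apply(v, 1, function(row) paste(format(row, trim = TRUE,
                                                 digits = 10), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path File written by \code{\link{write_asc}} (or any conforming
#'   ASCII grid).
#' @return A \code{rainfall_field}.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], "\\s+")
  vals <- stats::setNames(as.numeric(vapply(hdr, `[`, "", 2)),
                          tolower(vapply(hdr, `[`, "", 1)))
  m <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  rainfall_field(m, xmin = vals[["xllcorner"]], ymin = vals[["yllcorner"]],
                 cell_size = vals[["cellsize"]],
                 nodata = vals[["nodata_value"]])
}
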