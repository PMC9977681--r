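#' Normalized difference vegetation index
#'
#' \code{(nir - red) / (nir + red)} from non-negative reflectances,
#' vectorised (arrays in, arrays out). The degenerate case of both bands
#' zero returns 0 by convention. In early dry-season imagery NDVI separates
#' photosynthesising tree crowns from senescent herbaceous background.
#'
#' @param red,nir Red and near-infrared reflectance (>= 0), same shape.
#' @return NDVI in [-1, 1], same shape as the inputs.
#' @export
ndvi <- function(red, nir) {
  stopifnot(length(red) == length(nir))
  if (any(red < 0, na.rm = TRUE) || any(nir < 0, na.rm = TRUE))
    stop("reflectances must be non-negative")
  denom <- nir + red
  out <- (nir - red) / denom
  out[denom == 0] <- 0
  out
}

#' Seasonal/view-angle priority class of an image
#'
#' The second-round mosaic preference: class 1 = November-January with
#' |off-nadir| < 15 degrees; class 2 = November-January, 15-30 degrees;
#' class 3 = February-March, < 15 degrees; class 4 = February-March,
#' 15-30 degrees. Images from April-October or beyond 30 degrees off-nadir
#' are ineligible (\code{NA}).
#'
#' @param month Acquisition month(s), 1-12.
#' @param off_nadir_deg Signed off-nadir angle(s), degrees.
#' @return Integer class 1-4, or \code{NA} for ineligible records.
#' @export
priority_class <- function(month, off_nadir_deg) {
  stopifnot(all(month %in% 1:12), all(abs(off_nadir_deg) <= 90))
  early <- month %in% c(11L, 12L, 1L)
  late <- month %in% c(2L, 3L)
  a <- abs(off_nadir_deg)
  cls <- rep(NA_integer_, length(month))
  cls[early & a < 15] <- 1L
  cls[early & a >= 15 & a <= 30] <- 2L
  cls[late & a < 15] <- 3L
  cls[late & a >= 15 & a <= 30] <- 4L
  cls
}

#' First-round image ordering
#'
#' Orders candidate images by quality: cloud cover ascending, then sun
#' elevation descending, then absolute off-nadir angle ascending (view
#' closest to vertical first). Remaining ties break on later acquisition
#' year first, then image id.
#'
#' @param records Data frame with \code{cloud_pct}, \code{sun_elev_deg},
#'   \code{off_nadir_deg}, and optionally \code{year}, \code{image_id}.
#' @return The records reordered best-first.
#' @export
rank_round1 <- function(records) {
  stopifnot(nrow(records) >= 1L)
  yr <- if ("year" %in% names(records)) -records$year else
    rep(0, nrow(records))
  id <- if ("image_id" %in% names(records)) records$image_id else seq_len(nrow(records))
  records[order(records$cloud_pct, -records$sun_elev_deg,
                abs(records$off_nadir_deg), yr, id), , drop = FALSE]
}

#' Select the mosaic image for one tile
#'
#' Among the eligible candidates (a valid \code{\link{priority_class}}),
#' picks the image with the best (lowest) priority class, breaking ties by
#' the first-round ordering of \code{\link{rank_round1}}. Fully
#' deterministic and invariant to input order.
#'
#' @param records Candidate images of a single tile (data frame with
#'   \code{month}, \code{off_nadir_deg}, \code{cloud_pct},
#'   \code{sun_elev_deg}, ...).
#' @return The chosen record (one-row data frame with a
#'   \code{priority_class} column), or \code{NULL} when no record is
#'   eligible.
#' @export
select_tile_image <- function(records) {
  stopifnot(is.data.frame(records))
  if ("tile_id" %in% names(records) &&
      length(unique(records$tile_id)) > 1L)
    stop("records must belong to a single tile")
  records$priority_class <- priority_class(records$month,
                                           records$off_nadir_deg)
  elig <- records[!is.na(records$priority_class), , drop = FALSE]
  if (!nrow(elig)) return(NULL)
  best <- elig[elig$priority_class == min(elig$priority_class), , drop = FALSE]
  rank_round1(best)[1L, , drop = FALSE]
}

#' Select one image per tile over a whole catalog
#'
#' Applies \code{\link{select_tile_image}} to every tile. Tiles without an
#' eligible image are dropped (with a message), so no tree can be counted
#' twice: at most one image covers each tile.
#'
#' @param catalog Image catalog data frame with a \code{tile_id} column.
#' @return Data frame with one chosen record per selected tile, ordered by
#'   tile id.
#' @export
select_mosaic <- function(catalog) {
  stopifnot("tile_id" %in% names(catalog))
  tiles <- sort(unique(catalog$tile_id))
  picks <- lapply(tiles, function(tl)
    select_tile_image(catalog[catalog$tile_id == tl, , drop = FALSE]))
  empty <- vapply(picks, is.null, TRUE)
  if (any(empty))
    message(sum(empty), " tile(s) had no eligible image and were dropped")
  out <- do.call(rbind, picks[!empty])
  rownames(out) <- NULL
  out
}
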