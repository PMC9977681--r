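#' Synthetic dryland landscape configuration
#'
#' Describes a rectangular planar landscape with a linear west-east mean
#' annual rainfall gradient, per-zone tree densities and per-zone lognormal
#' crown-size laws. Defaults emulate the study conditions: zone mean crown
#' areas 15.1 / 18.4 / 20.9 / 28.1 m^2 (hyper-arid to sub-humid), a 3 m^2
#' detection threshold, and tree densities derived from the per-zone carbon
#' densities and per-tree carbon stocks (about 0.6 / 8.6 / 21 / 38 trees per
#' hectare).
#'
#' @param extent \code{c(xmin, xmax, ymin, ymax)} in metres.
#' @param rainfall_west,rainfall_east Gradient endpoints (mm/yr) at the west
#'   and east edges.
#' @param zone_density Named trees-per-hectare vector over the four zones.
#' @param zone_crown_mean Named mean crown area (m^2) per zone; the mean of
#'   the truncated lognormal, so generated samples average to these values.
#' @param zone_crown_sigma Named log-scale standard deviation per zone;
#'   the default 0.9 reproduces the reference tail fractions (about 88% of
#'   crowns below 50 m^2 and under 0.6% above 200 m^2).
#' @param min_crown_area Truncation threshold (m^2), default 3.
#' @param rain_cell_size Rainfall raster cell size (m).
#' @param seed Integer seed; the generator is a pure function of the config.
#' @return Object of class \code{landscape_config}.
#' @export
landscape_config <- function(extent = c(0, 10000, 0, 500),
                             rainfall_west = 0, rainfall_east = 1000,
                             zone_density = c("hyper-arid" = 0.6, "arid" = 8.6,
                                              "semi-arid" = 21, "sub-humid" = 38),
                             zone_crown_mean = c("hyper-arid" = 15.1, "arid" = 18.4,
                                                 "semi-arid" = 20.9, "sub-humid" = 28.1),
                             zone_crown_sigma = c("hyper-arid" = 0.9, "arid" = 0.9,
                                                  "semi-arid" = 0.9, "sub-humid" = 0.9),
                             min_crown_area = 3,
                             rain_cell_size = 500,
                             seed = 1L) {
  if ((extent[2] - extent[1]) <= 0 || (extent[4] - extent[3]) <= 0)
    stop("invalid config: extent must have positive area")
  if (any(zone_density < 0)) stop("invalid config: densities must be >= 0")
  if (any(zone_crown_mean <= min_crown_area))
    stop("invalid config: crown means must exceed min_crown_area")
  structure(list(extent = extent, rainfall_west = rainfall_west,
                 rainfall_east = rainfall_east, zone_density = zone_density,
                 zone_crown_mean = zone_crown_mean,
                 zone_crown_sigma = zone_crown_sigma,
                 min_crown_area = min_crown_area,
                 rain_cell_size = rain_cell_size, seed = as.integer(seed)),
            class = "landscape_config")
}

# meanlog of a lognormal truncated below at `lower` whose *truncated* mean
# equals `target`. Truncation inflates the mean, so the naive
# log(target) - sigma^2/2 would overshoot; solve for meanlog instead.
truncated_lognormal_meanlog <- function(target, sigma, lower) {
  trunc_mean <- function(mu) {
    exp(mu + sigma^2 / 2) *
      stats::pnorm((mu + sigma^2 - log(lower)) / sigma) /
      stats::pnorm((mu - log(lower)) / sigma)
  }
  stats::uniroot(function(mu) trunc_mean(mu) - target,
                 lower = log(target) - 4, upper = log(target) + 1,
                 tol = 1e-10)$root
}

# inverse-CDF sampler for the lower-truncated lognormal (deterministic draw
# count, so seeded streams stay aligned)
rtrunc_lnorm <- function(n, meanlog, sdlog, lower) {
  p0 <- stats::plnorm(lower, meanlog, sdlog)
  stats::qlnorm(p0 + stats::runif(n) * (1 - p0), meanlog, sdlog)
}

# Disjoint circle placement with a bucket grid; positions failing the
# overlap check are re-drawn up to `retries` times, then kept (counted).
place_disjoint_circles <- function(n, areas, xr, yr, retries = 20L) {
  r <- sqrt(areas / pi)
  bucket <- max(10, 2 * max(r))
  occ <- new.env(hash = TRUE, parent = emptyenv())
  xs <- ys <- numeric(n)
  clashes <- 0L
  key <- function(i, j) paste0(i, ",", j)
  for (k in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(retries)) {
      x <- stats::runif(1, xr[1], xr[2]); y <- stats::runif(1, yr[1], yr[2])
      bi <- floor(x / bucket); bj <- floor(y / bucket)
      ok <- TRUE
      for (i in (bi - 1L):(bi + 1L)) for (j in (bj - 1L):(bj + 1L)) {
        ids <- occ[[key(i, j)]]
        if (!is.null(ids)) {
          d2 <- (xs[ids] - x)^2 + (ys[ids] - y)^2
          if (any(d2 < (r[ids] + r[k])^2)) { ok <- FALSE; break }
        }
      }
      if (ok) { placed <- TRUE; break }
    }
    xs[k] <- x; ys[k] <- y
    bk <- key(floor(x / bucket), floor(y / bucket))
    occ[[bk]] <- c(occ[[bk]], k)
    if (!placed) clashes <- clashes + 1L
  }
  list(x = xs, y = ys, clashes = clashes)
}

#' Generate a synthetic landscape: rainfall field plus tree crowns
#'
#' Builds the rainfall raster (linear west-east gradient) and places trees
#' zone by zone: the gradient is inverted to find each zone's strip, the
#' number of trees is the strip area times the zone density, crown areas are
#' drawn from the zone's truncated lognormal, and crowns (circles) are
#' placed disjointly. Each tree's rainfall is then extracted from the raster
#' at its centroid and its zone classified from that value, so zone labels
#' are consistent with the rainfall field by construction.
#'
#' @param config A \code{\link{landscape_config}}.
#' @return List of class \code{landscape}: \code{field} (a
#'   \code{rainfall_field}), \code{crowns} (data frame: id, x, y,
#'   crown_area_m2, rainfall_mm, zone), and \code{config}.
#' @export
gen_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "landscape_config"))
  ext <- config$extent
  cs <- config$rain_cell_size
  nc <- max(1L, ceiling((ext[2] - ext[1]) / cs))
  nr <- max(1L, ceiling((ext[4] - ext[3]) / cs))
  xc <- ext[1] + (seq_len(nc) - 0.5) * cs
  grad <- function(x) config$rainfall_west +
    (config$rainfall_east - config$rainfall_west) * (x - ext[1]) / (ext[2] - ext[1])
  field <- rainfall_field(matrix(rep(grad(xc), each = nr), nr, nc),
                          xmin = ext[1], ymin = ext[3], cell_size = cs)
  zones <- zone_definition()
  withr::with_seed(config$seed, {
    crowns <- list()
    for (i in seq_len(nrow(zones))) {
      z <- zones$zone[i]
      dens <- if (z %in% names(config$zone_density))
        config$zone_density[[z]] else 0
      if (dens <= 0) next
      # strip of the gradient falling inside this zone's rainfall interval
      rng <- range(config$rainfall_west, config$rainfall_east)
      lo <- max(zones$lower[i], rng[1]); hi <- min(zones$upper[i], rng[2])
      if (hi <= lo && !(zones$lower[i] <= rng[1] && rng[2] < zones$upper[i]))
        next
      if (config$rainfall_east == config$rainfall_west) {
        xlo <- ext[1]; xhi <- ext[2]
        if (!(grad(ext[1]) >= zones$lower[i] && grad(ext[1]) < zones$upper[i]))
          next
      } else {
        inv <- function(p) ext[1] + (p - config$rainfall_west) /
          (config$rainfall_east - config$rainfall_west) * (ext[2] - ext[1])
        xlo <- min(inv(lo), inv(hi)); xhi <- max(inv(lo), inv(hi))
      }
      strip_ha <- (xhi - xlo) * (ext[4] - ext[3]) / 1e4
      n <- round(dens * strip_ha)
      if (n <= 0) next
      mu <- truncated_lognormal_meanlog(config$zone_crown_mean[[z]],
                                        config$zone_crown_sigma[[z]],
                                        config$min_crown_area)
      areas <- rtrunc_lnorm(n, mu, config$zone_crown_sigma[[z]],
                            config$min_crown_area)
      pos <- place_disjoint_circles(n, areas, c(xlo, xhi), c(ext[3], ext[4]))
      crowns[[z]] <- data.frame(x = pos$x, y = pos$y, crown_area_m2 = areas)
    }
    crowns <- if (length(crowns)) do.call(rbind, crowns) else
      data.frame(x = numeric(), y = numeric(), crown_area_m2 = numeric())
  })
  rownames(crowns) <- NULL
  crowns <- cbind(id = seq_len(nrow(crowns)), crowns)
  crowns$rainfall_mm <- if (nrow(crowns))
    extract_rainfall(field, crowns$x, crowns$y) else numeric()
  crowns$zone <- as.character(classify_zone(crowns$rainfall_mm))
  structure(list(field = field, crowns = crowns, config = config),
            class = "landscape")
}

#' Field destructive-sampling configuration
#'
#' Parameters for simulating the destructive-sampling campaigns behind the
#' allometric equations: per-component true power laws, sample sizes
#' (defaults 698 wood / 900 foliage / 26 root trees), and a multiplicative
#' lognormal mass noise whose default (sdlog 0.69) was calibrated by
#' simulation so the 80/20 subsampling uncertainty procedure at these sample
#' sizes yields a mean relative allometric uncertainty near 19.5%.
#'
#' @param true_models Named list of \code{allometric_model}s (wood, foliage,
#'   root) treated as the data-generating truth.
#' @param n_per_component Named sample counts; each must be >= 2.
#' @param noise_sigma Log-scale sd of the multiplicative mass noise (>= 0).
#' @param area_range Crown-area range (m^2) of the sampled trees; areas are
#'   drawn log-uniformly so small and large trees are both represented.
#' @param seed Integer seed.
#' @return Object of class \code{field_sample_config}.
#' @export
field_sample_config <- function(true_models = default_allometric_models(),
                                n_per_component = c(wood = 698, foliage = 900,
                                                    root = 26),
                                noise_sigma = 0.69,
                                area_range = c(1, 200),
                                seed = 1L) {
  if (any(n_per_component < 2)) stop("invalid config: need n >= 2 per component")
  if (noise_sigma < 0) stop("invalid config: noise_sigma must be >= 0")
  structure(list(true_models = true_models,
                 n_per_component = n_per_component,
                 noise_sigma = noise_sigma, area_range = area_range,
                 seed = as.integer(seed)),
            class = "field_sample_config")
}

#' Generate destructive-sampling field data
#'
#' Draws crown areas log-uniformly over \code{area_range} and masses as
#' \code{a * A^b * exp(noise)} with \code{noise ~ N(0, noise_sigma^2)},
#' independently per component.
#'
#' @param config A \code{\link{field_sample_config}}.
#' @return Named list (\code{wood}, \code{foliage}, \code{root}) of data
#'   frames with columns \code{component}, \code{crown_area_m2},
#'   \code{mass_kg}.
#' @export
gen_field_samples <- function(config = field_sample_config()) {
  stopifnot(inherits(config, "field_sample_config"))
  withr::with_seed(config$seed, {
    out <- lapply(names(config$n_per_component), function(comp) {
      n <- config$n_per_component[[comp]]
      m <- config$true_models[[comp]]
      A <- exp(stats::runif(n, log(config$area_range[1]),
                            log(config$area_range[2])))
      noise <- if (config$noise_sigma > 0)
        exp(stats::rnorm(n, 0, config$noise_sigma)) else rep(1, n)
      data.frame(component = comp, crown_area_m2 = A,
                 mass_kg = m$a * A^m$b * noise,
                 stringsAsFactors = FALSE)
    })
  })
  stats::setNames(out, names(config$n_per_component))
}

#' Generate evaluation plots with planted detection errors
#'
#' Builds a set of evaluation plots whose predicted crowns differ from the
#' labelled truth by exactly \code{round(n_true * omission_rate)} missed
#' trees and \code{round(n_true * commission_rate)} spurious predictions
#' (placed so they overlap no labelled crown); all remaining crowns match
#' one-to-one with identical geometry. Piping the result through
#' \code{\link{error_rates}} recovers the planted rates exactly.
#'
#' @param n_true Number of true (labelled) trees across all plots.
#' @param commission_rate,omission_rate Planted error fractions in [0, 1);
#'   their sum must be < 1.
#' @param seed Integer seed.
#' @param n_plots Number of plots the trees are spread over.
#' @param plot_size Plot width and height (m); mirrors 512 x 256 pixel
#'   evaluation windows at 0.5 m resolution.
#' @return List of \code{eval_plot} objects: \code{plot_id},
#'   \code{labelled}, \code{predicted} (data frames id, x, y,
#'   crown_area_m2) and \code{rainfall_mm}.
#' @export
gen_eval_fixture <- function(n_true, commission_rate = 0, omission_rate = 0,
                             seed = 1L, n_plots = 10L,
                             plot_size = c(256, 128)) {
  if (commission_rate < 0 || commission_rate >= 1 ||
      omission_rate < 0 || omission_rate >= 1)
    stop("rates must lie in [0, 1)")
  if (commission_rate + omission_rate >= 1)
    stop("commission and omission rates must sum to < 1")
  stopifnot(n_true >= 0)
  n_com <- round(n_true * commission_rate)
  n_om <- round(n_true * omission_rate)
  n_plots <- max(1L, min(n_plots, max(1L, n_true)))
  per_plot <- diff(round(seq(0, n_true, length.out = n_plots + 1L)))
  mu <- truncated_lognormal_meanlog(20, 0.9, 3)
  withr::with_seed(seed, {
    plots <- vector("list", n_plots)
    next_id <- 1L
    for (p in seq_len(n_plots)) {
      n <- per_plot[p]
      areas <- if (n) rtrunc_lnorm(n, mu, 0.9, 3) else numeric()
      pos <- place_disjoint_circles(n, areas, c(0, plot_size[1]),
                                    c(0, plot_size[2]))
      lab <- data.frame(id = seq.int(next_id, length.out = n),
                        x = pos$x, y = pos$y, crown_area_m2 = areas)
      next_id <- next_id + n
      plots[[p]] <- list(plot_id = p, labelled = lab,
                         rainfall_mm = stats::runif(1, 100, 900))
    }
    # plant omissions: drop these labelled trees from the predictions
    all_ids <- seq_len(n_true)
    omitted <- if (n_om) sample(all_ids, n_om) else integer()
    # plant commissions: spurious circles overlapping nothing
    com_plot <- if (n_com) sample(n_plots, n_com, replace = TRUE) else integer()
    for (p in seq_len(n_plots)) {
      lab <- plots[[p]]$labelled
      pred <- lab[!(lab$id %in% omitted), , drop = FALSE]
      nc <- sum(com_plot == p)
      if (nc) {
        areas <- rtrunc_lnorm(nc, mu, 0.9, 3)
        sp <- data.frame(id = integer(nc), x = numeric(nc), y = numeric(nc),
                         crown_area_m2 = areas)
        for (k in seq_len(nc)) {
          r <- sqrt(areas[k] / pi)
          repeat {
            x <- stats::runif(1, 0, plot_size[1])
            y <- stats::runif(1, 0, plot_size[2])
            rl <- sqrt(lab$crown_area_m2 / pi)
            if (!nrow(lab) ||
                all((lab$x - x)^2 + (lab$y - y)^2 >= (rl + r)^2)) break
          }
          sp$x[k] <- x; sp$y[k] <- y
          sp$id[k] <- n_true + 1000L * p + k   # ids disjoint from labels
        }
        pred <- rbind(pred, sp)
      }
      rownames(pred) <- NULL
      plots[[p]]$predicted <- pred
      class(plots[[p]]) <- "eval_plot"
    }
  })
  plots
}

#' Generate a synthetic satellite image catalog
#'
#' Draws image records spanning acquisition years 2002-2020, all calendar
#' months, off-nadir angles in (-45, 45) degrees, cloud cover 0-100% (skewed
#' low) and sun elevations 25-75 degrees, several candidate images per tile.
#'
#' @param n Number of records (>= 0).
#' @param seed Integer seed.
#' @param n_tiles Number of distinct mosaic tiles; defaults to about one
#'   tile per five images.
#' @return Data frame: \code{image_id}, \code{tile_id}, \code{year},
#'   \code{month}, \code{cloud_pct}, \code{sun_elev_deg},
#'   \code{off_nadir_deg}.
#' @export
gen_image_catalog <- function(n, seed = 1L,
                              n_tiles = max(1L, round(n / 5))) {
  stopifnot(n >= 0)
  if (n == 0)
    return(data.frame(image_id = character(), tile_id = character(),
                      year = integer(), month = integer(),
                      cloud_pct = numeric(), sun_elev_deg = numeric(),
                      off_nadir_deg = numeric(), stringsAsFactors = FALSE))
  withr::with_seed(seed, {
    out <- data.frame(
      image_id = sprintf("img%06d", seq_len(n)),
      tile_id = sprintf("tile%04d", sample(n_tiles, n, replace = TRUE)),
      year = sample(2002:2020, n, replace = TRUE),
      month = sample(1:12, n, replace = TRUE),
      cloud_pct = round(100 * stats::rbeta(n, 0.6, 4), 1),
      sun_elev_deg = round(stats::runif(n, 25, 75), 1),
      off_nadir_deg = round(stats::runif(n, -45, 45), 1),
      stringsAsFactors = FALSE)
  })
  out
}
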