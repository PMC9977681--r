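#' Crown-area allometric component model
#'
#' A power law \code{mass = a * A^b} relating crown area \code{A} (m^2) to the
#' oven-dry mass (kg) of one tree component (wood, foliage or root), as fitted
#' from destructive-sampling data by ordinary least squares on the log-log
#' scale.
#'
#' @param component One of \code{"wood"}, \code{"foliage"}, \code{"root"}.
#' @param a Multiplicative coefficient (kg m^(-2b)); must be > 0.
#' @param b Dimensionless exponent; must be > 0.
#' @param n Number of destructively sampled trees behind the fit.
#' @return An object of class \code{allometric_model}.
#' @export
allometric_model <- function(component = c("wood", "foliage", "root"), a, b,
                             n = NA_integer_) {
  component <- match.arg(component)
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a), a > 0,
            is.numeric(b), length(b) == 1L, is.finite(b), b > 0)
  structure(list(component = component, a = a, b = b, n = as.integer(n)),
            class = "allometric_model")
}

#' @export
print.allometric_model <- function(x, ...) {
  cat(sprintf("<allometric_model> %s: mass = %.4f * A^%.4f  (n = %s)\n",
              x$component, x$a, x$b,
              ifelse(is.na(x$n), "?", x$n)))
  invisible(x)
}

#' Default dryland allometric models
#'
#' The Sahelian/Sudanian crown-area power laws used throughout the package:
#' wood \code{3.9448 A^1.1068} (n = 698), foliage \code{0.2693 A^0.9441}
#' (n = 900) and root \code{0.8339 A^1.1730} (n = 26), mass in kg dry matter,
#' A in m^2.
#'
#' @return Named list of three \code{allometric_model} objects
#'   (\code{wood}, \code{foliage}, \code{root}).
#' @export
default_allometric_models <- function() {
  list(
    wood    = allometric_model("wood",    3.9448, 1.1068, 698L),
    foliage = allometric_model("foliage", 0.2693, 0.9441, 900L),
    root    = allometric_model("root",    0.8339, 1.1730, 26L)
  )
}

#' Predict component dry mass from crown area
#'
#' Evaluates the raw power law \code{a * area^b} without crown splitting.
#'
#' @param model An \code{allometric_model}.
#' @param area Crown area(s) in m^2; all must be > 0.
#' @return Dry mass in kg, same length as \code{area}.
#' @export
predict_component_mass <- function(model, area) {
  stopifnot(inherits(model, "allometric_model"), is.numeric(area))
  if (any(!is.finite(area) | area <= 0))
    stop("crown area must be positive and finite")
  model$a * area^model$b
}

#' Split a large crown into allometry-sized pieces
#'
#' Crowns larger than \code{threshold} (200 m^2) are split into
#' \code{floor(area/100)} pieces of 100 m^2 plus one remainder piece if the
#' remainder is non-zero; smaller crowns are returned unchanged. The pieces
#' always sum to \code{area}. This caps the extrapolation of the power laws,
#' which were fitted on single trees: very large mapped crowns are usually
#' clumps of several trees.
#'
#' @param area A single crown area in m^2, > 0.
#' @param threshold Area above which splitting applies (m^2).
#' @param piece Size of the full split pieces (m^2).
#' @return Numeric vector of sub-areas summing to \code{area}.
#' @export
split_crown <- function(area, threshold = 200, piece = 100) {
  stopifnot(is.numeric(area), length(area) == 1L, is.finite(area), area > 0)
  if (area <= threshold) return(area)
  k <- floor(area / piece)
  rem <- area - k * piece
  if (rem > 0) c(rep(piece, k), rem) else rep(piece, k)
}

# Vectorised split-aware power-law mass: sum of a*p^b over split pieces.
# For area <= threshold this is a*area^b; beyond, floor(area/100) full pieces
# plus a possible remainder. Used by estimate_tree_carbon on big inputs.
split_component_mass <- function(model, area, threshold = 200, piece = 100) {
  small <- area <= threshold
  out <- numeric(length(area))
  out[small] <- model$a * area[small]^model$b
  if (any(!small)) {
    a <- area[!small]
    k <- floor(a / piece)
    rem <- a - k * piece
    out[!small] <- k * model$a * piece^model$b +
      ifelse(rem > 0, model$a * rem^model$b, 0)
  }
  out
}

#' Estimate per-tree carbon from crown area
#'
#' Applies the large-crown splitting rule, evaluates the three component
#' power laws on each piece, sums wood + foliage + root dry mass and converts
#' to carbon with a fixed fraction (default 0.47 kg C per kg dry mass).
#' Crowns at or below \code{min_crown_area} are not trees under the detection
#' definition (green crown > 3 m^2) and yield \code{NA} rows rather than an
#' error; split pieces themselves may be arbitrarily small.
#'
#' @param area Vector of crown areas (m^2); values <= 0 are a domain error.
#' @param models Named list with \code{wood}, \code{foliage}, \code{root}
#'   \code{allometric_model}s; default \code{default_allometric_models()}.
#' @param carbon_fraction Carbon content of dry mass; default 0.47.
#' @param min_crown_area Detection threshold in m^2 (default 3); areas at or
#'   below it are filtered (NA), not errors.
#' @return Data frame with columns \code{crown_area_m2}, \code{mass_w_kg},
#'   \code{mass_f_kg}, \code{mass_r_kg}, \code{mass_total_kg},
#'   \code{carbon_kg} and logical \code{retained}.
#' @export
estimate_tree_carbon <- function(area, models = default_allometric_models(),
                                 carbon_fraction = 0.47, min_crown_area = 3) {
  stopifnot(is.numeric(area), carbon_fraction > 0, carbon_fraction <= 1)
  if (any(!is.finite(area) | area <= 0))
    stop("crown area must be positive and finite")
  retained <- area > min_crown_area
  mw <- mf <- mr <- rep(NA_real_, length(area))
  if (any(retained)) {
    a <- area[retained]
    mw[retained] <- split_component_mass(models$wood, a)
    mf[retained] <- split_component_mass(models$foliage, a)
    mr[retained] <- split_component_mass(models$root, a)
  }
  total <- mw + mf + mr
  data.frame(crown_area_m2 = area,
             mass_w_kg = mw, mass_f_kg = mf, mass_r_kg = mr,
             mass_total_kg = total,
             carbon_kg = carbon_fraction * total,
             retained = retained)
}

#' Carbon estimate for a single crown, with split bookkeeping
#'
#' Scalar variant of \code{\link{estimate_tree_carbon}} that also returns the
#' list of split sub-areas used, for auditing the splitting rule.
#'
#' @inheritParams estimate_tree_carbon
#' @return List with \code{mass_w}, \code{mass_f}, \code{mass_r},
#'   \code{mass_total}, \code{carbon} (kg) and \code{split_areas} (m^2).
#' @export
carbon_estimate <- function(area, models = default_allometric_models(),
                            carbon_fraction = 0.47) {
  stopifnot(length(area) == 1L)
  pieces <- split_crown(area)
  mw <- sum(predict_component_mass(models$wood, pieces))
  mf <- sum(predict_component_mass(models$foliage, pieces))
  mr <- sum(predict_component_mass(models$root, pieces))
  list(mass_w = mw, mass_f = mf, mass_r = mr,
       mass_total = mw + mf + mr,
       carbon = carbon_fraction * (mw + mf + mr),
       split_areas = pieces)
}

#' Fit a crown-area power law from field samples
#'
#' Ordinary least squares of log(mass) on log(area); the fitted intercept is
#' back-transformed to the multiplicative coefficient \code{a} with no bias
#' correction (no smearing), matching how the default equations were derived.
#' Natural logs are used; the base does not affect (a, b).
#'
#' @param samples Data frame with columns \code{crown_area_m2} and
#'   \code{mass_kg} (both > 0), and optionally \code{component}.
#' @param component Component label for the returned model; taken from the
#'   data if present.
#' @return An \code{allometric_model}.
#' @export
fit_component_model <- function(samples, component = NULL) {
  stopifnot(is.data.frame(samples),
            all(c("crown_area_m2", "mass_kg") %in% names(samples)))
  if (nrow(samples) < 2L) stop("need at least 2 samples to fit a power law")
  if (any(samples$crown_area_m2 <= 0) || any(samples$mass_kg <= 0))
    stop("areas and masses must be positive for the log-log fit")
  if (length(unique(samples$crown_area_m2)) < 2L)
    stop("degenerate design: all crown areas identical")
  if (is.null(component)) {
    component <- if ("component" %in% names(samples))
      as.character(samples$component[1L]) else "wood"
  }
  fit <- stats::lm(log(mass_kg) ~ log(crown_area_m2), data = samples)
  cf <- stats::coef(fit)
  allometric_model(component, a = exp(unname(cf[1L])), b = unname(cf[2L]),
                   n = nrow(samples))
}
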