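#' @keywords internal
# Intersection area of two circles at centre distance d with radii r1, r2.
circle_overlap_area <- function(d, r1, r2) {
  out <- numeric(length(d))
  full <- d <= abs(r1 - r2)
  out[full] <- pi * pmin(r1, r2)[full]^2
  lens <- !full & d < r1 + r2
  if (any(lens)) {
    dd <- d[lens]; a <- r1[lens]; b <- r2[lens]
    out[lens] <- a^2 * acos(pmin(pmax((dd^2 + a^2 - b^2) / (2 * dd * a), -1), 1)) +
      b^2 * acos(pmin(pmax((dd^2 + b^2 - a^2) / (2 * dd * b), -1), 1)) -
      0.5 * sqrt(pmax((-dd + a + b) * (dd + a - b) * (dd - a + b) * (dd + a + b), 0))
  }
  out
}

crown_area_class <- function(area) {
  cut(area, breaks = c(0, 15, 50, 200, Inf),
      labels = c("0-15", "15-50", "50-200", ">200"), right = FALSE)
}

#' Match predicted to labelled crowns
#'
#' One-to-one greedy matching of circular crowns by descending overlap area
#' (ties broken by smaller labelled id, then smaller predicted id).
#' Unmatched labelled crowns are omissions; unmatched predicted crowns are
#' commissions. When one prediction overlaps several labels it is matched to
#' the largest-overlap label and the remaining labels count as omissions.
#'
#' @param labelled,predicted Data frames with \code{id}, \code{x}, \code{y},
#'   \code{crown_area_m2} (circles of the given area at the given centre).
#' @param min_overlap Overlap (m^2) strictly above which a pair may match;
#'   default 0 (any positive overlap).
#' @return List of class \code{matching_result}: \code{pairs} (labelled_id,
#'   predicted_id, overlap_m2, labelled_area, predicted_area),
#'   \code{omissions}, \code{commissions} (id vectors), counts, and
#'   \code{per_class} counts over the crown-area classes 0-15, 15-50,
#'   50-200, >200 m^2.
#' @export
match_crowns <- function(labelled, predicted, min_overlap = 0) {
  for (d in list(labelled, predicted)) {
    stopifnot(all(c("id", "x", "y", "crown_area_m2") %in% names(d)))
    if (any(!is.finite(d$crown_area_m2) | d$crown_area_m2 <= 0))
      stop("invalid geometry: crown areas must be positive")
  }
  nl <- nrow(labelled); np <- nrow(predicted)
  pairs <- data.frame(labelled_id = integer(), predicted_id = integer(),
                      overlap_m2 = numeric(), labelled_area = numeric(),
                      predicted_area = numeric())
  if (nl && np) {
    rl <- sqrt(labelled$crown_area_m2 / pi)
    rp <- sqrt(predicted$crown_area_m2 / pi)
    cand <- expand.grid(i = seq_len(nl), j = seq_len(np))
    d <- sqrt((labelled$x[cand$i] - predicted$x[cand$j])^2 +
              (labelled$y[cand$i] - predicted$y[cand$j])^2)
    keep <- d < rl[cand$i] + rp[cand$j]
    cand <- cand[keep, , drop = FALSE]
    ov <- circle_overlap_area(d[keep], rl[cand$i], rp[cand$j])
    sel <- ov > min_overlap
    cand <- cand[sel, , drop = FALSE]; ov <- ov[sel]
    ord <- order(-ov, labelled$id[cand$i], predicted$id[cand$j])
    used_l <- logical(nl); used_p <- logical(np)
    take <- integer()
    for (k in ord) {
      if (!used_l[cand$i[k]] && !used_p[cand$j[k]]) {
        used_l[cand$i[k]] <- TRUE; used_p[cand$j[k]] <- TRUE
        take <- c(take, k)
      }
    }
    if (length(take))
      pairs <- data.frame(labelled_id = labelled$id[cand$i[take]],
                          predicted_id = predicted$id[cand$j[take]],
                          overlap_m2 = ov[take],
                          labelled_area = labelled$crown_area_m2[cand$i[take]],
                          predicted_area = predicted$crown_area_m2[cand$j[take]])
  }
  om_ids <- setdiff(labelled$id, pairs$labelled_id)
  co_ids <- setdiff(predicted$id, pairs$predicted_id)
  lab_class <- crown_area_class(labelled$crown_area_m2)
  pred_class <- crown_area_class(predicted$crown_area_m2)
  per_class <- data.frame(
    class = levels(lab_class),
    n_labelled = as.integer(table(lab_class)),
    n_omission = as.integer(table(lab_class[labelled$id %in% om_ids])),
    n_predicted = as.integer(table(pred_class)),
    n_commission = as.integer(table(pred_class[predicted$id %in% co_ids])))
  structure(list(pairs = pairs, omissions = om_ids, commissions = co_ids,
                 omission_areas = labelled$crown_area_m2[labelled$id %in% om_ids],
                 n_labelled = nl, n_predicted = np,
                 n_matched = nrow(pairs), per_class = per_class),
            class = "matching_result")
}

#' Pooled commission and omission error rates
#'
#' Pools counts across plots (micro-average). The primary rates follow the
#' trees-evaluated convention: commissions and omissions are both expressed
#' per labelled (evaluated) tree, so that the net detection uncertainty is
#' their signed difference. The per-predicted-crown commission rate (user's
#' accuracy convention) is also reported as
#' \code{commission_rate_predicted}. Per-class rates use the class's
#' labelled count as denominator and are \code{NA} when that count is zero.
#'
#' @param matchings A \code{matching_result} or list of them (one per plot).
#' @return List: pooled counts, \code{commission_rate},
#'   \code{omission_rate}, \code{net_rate} (fractions),
#'   \code{commission_rate_predicted}, and a \code{per_class} data frame.
#' @export
error_rates <- function(matchings) {
  if (inherits(matchings, "matching_result")) matchings <- list(matchings)
  stopifnot(length(matchings) >= 1L)
  nl <- sum(vapply(matchings, `[[`, 1L, "n_labelled"))
  np <- sum(vapply(matchings, `[[`, 1L, "n_predicted"))
  nc <- sum(vapply(matchings, function(m) length(m$commissions), 1L))
  no <- sum(vapply(matchings, function(m) length(m$omissions), 1L))
  per_class <- Reduce(function(a, b) {
    a[-1] <- a[-1] + b[-1]; a
  }, lapply(matchings, `[[`, "per_class"))
  per_class$commission_rate <- ifelse(per_class$n_labelled > 0,
                                      per_class$n_commission / per_class$n_labelled, NA)
  per_class$omission_rate <- ifelse(per_class$n_labelled > 0,
                                    per_class$n_omission / per_class$n_labelled, NA)
  list(n_labelled = nl, n_predicted = np,
       n_commissions = nc, n_omissions = no,
       n_errors = nc + no,
       commission_rate = if (nl > 0) nc / nl else NA_real_,
       omission_rate = if (nl > 0) no / nl else NA_real_,
       net_rate = if (nl > 0) (nc - no) / nl else NA_real_,
       commission_rate_predicted = if (np > 0) nc / np else NA_real_,
       per_class = per_class)
}

#' Per-tree crown-area RMSE
#'
#' Root-mean-square error of predicted versus labelled crown area over all
#' labelled crowns; a missed (omitted) tree contributes its full labelled
#' area as error.
#'
#' @param matching A \code{matching_result} (or list, pooled).
#' @return RMSE in m^2.
#' @export
area_rmse <- function(matching) {
  if (inherits(matching, "matching_result")) matching <- list(matching)
  errs <- unlist(lapply(matching, function(m)
    c(m$pairs$predicted_area - m$pairs$labelled_area, m$omission_areas)))
  n_lab <- sum(vapply(matching, `[[`, 1L, "n_labelled"))
  if (n_lab == 0L) stop("no labelled crowns: RMSE undefined")
  sqrt(sum(errs^2) / n_lab)
}

#' Sample evaluation plots from a landscape with a wet-side bias
#'
#' Draws rectangular evaluation plots from a synthetic landscape so that an
#' expected fraction \code{wet_bias} of them lies above the
#' \code{rain_threshold} isohyet (most trees grow on the wet side, so
#' unbiased sampling would waste most plots on empty desert). Plots devoid
#' of trees are excluded from the returned set, mirroring the filtering of
#' vegetation-free evaluation areas.
#'
#' @param landscape A \code{landscape} from \code{\link{gen_landscape}}.
#' @param n_plots Number of plots to draw (> 0) before the empty-plot
#'   filter.
#' @param wet_bias Probability a plot is drawn above the threshold.
#' @param rain_threshold Isohyet (mm/yr) separating wet from dry.
#' @param plot_size Plot width and height (m).
#' @param seed Integer seed.
#' @return List of \code{eval_plot}s with identical labelled and predicted
#'   sets (a perfect detector; plant errors with
#'   \code{\link{gen_eval_fixture}} to study imperfect ones).
#' @export
sample_eval_plots <- function(landscape, n_plots, wet_bias = 0.8,
                              rain_threshold = 200, plot_size = c(256, 128),
                              seed = 1L) {
  stopifnot(inherits(landscape, "landscape"), n_plots > 0)
  ext <- landscape$config$extent
  rw <- landscape$config$rainfall_west; re <- landscape$config$rainfall_east
  # x beyond which rainfall exceeds the threshold (linear gradient)
  if (re != rw) {
    xt <- ext[1] + (rain_threshold - rw) / (re - rw) * (ext[2] - ext[1])
    xt <- min(max(xt, ext[1]), ext[2])
  } else {
    xt <- if (rw > rain_threshold) ext[1] else ext[2]
  }
  wet_rng <- sort(c(xt, if (re >= rw) ext[2] else ext[1]))
  dry_rng <- sort(c(if (re >= rw) ext[1] else ext[2], xt))
  has_wet <- diff(wet_rng) > plot_size[1]
  has_dry <- diff(dry_rng) > plot_size[1]
  if (!has_wet || !has_dry)
    warning("landscape does not span both sides of the rainfall threshold; ",
            "sampling without bias")
  crowns <- landscape$crowns
  withr::with_seed(seed, {
    plots <- list()
    for (p in seq_len(n_plots)) {
      wet <- stats::runif(1) < wet_bias
      rng <- if ((wet && has_wet) || !has_dry) wet_rng else dry_rng
      x0 <- stats::runif(1, rng[1], rng[2] - plot_size[1])
      y0 <- stats::runif(1, ext[3], max(ext[3], ext[4] - plot_size[2]))
      inside <- crowns$x >= x0 & crowns$x < x0 + plot_size[1] &
                crowns$y >= y0 & crowns$y < y0 + plot_size[2]
      if (!any(inside)) next   # vegetation-free plot: excluded
      lab <- crowns[inside, c("id", "x", "y", "crown_area_m2")]
      rownames(lab) <- NULL
      plots[[length(plots) + 1L]] <- structure(
        list(plot_id = p, labelled = lab, predicted = lab,
             rainfall_mm = extract_rainfall(landscape$field,
                                            x0 + plot_size[1] / 2,
                                            y0 + plot_size[2] / 2)),
        class = "eval_plot")
    }
  })
  plots
}

#' Evaluate a set of plots end to end
#'
#' Matches every plot and pools the error rates and the per-tree area RMSE.
#'
#' @param plots List of \code{eval_plot}s.
#' @return List: \code{rates} (see \code{\link{error_rates}}),
#'   \code{area_rmse_m2}, \code{matchings}.
#' @export
evaluate_plots <- function(plots) {
  stopifnot(length(plots) >= 1L)
  matchings <- lapply(plots, function(p) match_crowns(p$labelled, p$predicted))
  list(rates = error_rates(matchings),
       area_rmse_m2 = area_rmse(matchings),
       matchings = matchings)
}
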