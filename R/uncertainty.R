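#' One 80/20 subsampling error for a component
#'
#' Randomly splits one component's destructive samples into training (80%)
#' and validation (20%) parts, refits the log-log power law on the training
#' part, and on the validation part computes the mean observed mass mu, the
#' mean predicted mass mu-hat, and the absolute error Delta = |mu - mu-hat|.
#'
#' @param samples Data frame with \code{crown_area_m2}, \code{mass_kg}.
#' @param train_fraction Fraction used for fitting (default 0.8).
#' @param seed Integer seed for the split.
#' @return List: \code{delta} (kg), \code{mu} (kg, mean observed validation
#'   mass), \code{n_validation}.
#' @export
subsample_component_delta <- function(samples, train_fraction = 0.8,
                                      seed = 1L) {
  stopifnot(is.data.frame(samples))
  if (nrow(samples) < 5L)
    stop("need at least 5 samples for an 80/20 split")
  withr::with_seed(seed, {
    idx <- sample(nrow(samples), round(train_fraction * nrow(samples)))
  })
  split_delta(samples, idx)
}

# Delta/mu for a given training index set (shared by the repetition loop).
split_delta <- function(samples, train_idx) {
  train <- samples[train_idx, , drop = FALSE]
  valid <- samples[-train_idx, , drop = FALSE]
  model <- fit_component_model(train)
  mu <- mean(valid$mass_kg)
  mu_hat <- mean(predict_component_mass(model, valid$crown_area_m2))
  list(delta = abs(mu - mu_hat), mu = mu, n_validation = nrow(valid))
}

#' Combine component absolute errors in quadrature
#'
#' Treats the wood, foliage and root errors as independent and returns
#' \code{sqrt(delta_f^2 + delta_w^2 + delta_r^2)} (kg).
#'
#' @param delta_f,delta_w,delta_r Absolute component errors (kg), >= 0.
#' @return Combined absolute allometric error (kg).
#' @export
component_quadrature <- function(delta_f, delta_w, delta_r) {
  d <- c(delta_f, delta_w, delta_r)
  if (any(!is.finite(d) | d < 0)) stop("errors must be non-negative")
  sqrt(sum(d^2))
}

#' Allometric uncertainty by repeated 80/20 subsampling
#'
#' Repeats the per-component 80/20 split \code{n_reps} times (default 10).
#' In each repetition the component absolute errors are combined in
#' quadrature and divided by the validation-mean total mass
#' (mu_w + mu_f + mu_r) to give a relative uncertainty; the mean over
#' repetitions is the allometric uncertainty of the carbon prediction.
#' The small root dataset (26 trees) leaves only 5-6 validation trees per
#' repetition; a warning notes this but the estimate is used as-is.
#'
#' @param samples Named list (\code{wood}, \code{foliage}, \code{root}) of
#'   field-sample data frames.
#' @param n_reps Number of repetitions (default 10).
#' @param train_fraction Training fraction (default 0.8).
#' @param seed Master seed; repetition r uses the r-th draw of a single
#'   seeded stream, so rep 1 is unchanged when n_reps grows.
#' @return List of class \code{uncertainty_report} with per-repetition
#'   deltas and relative uncertainties, and their mean
#'   \code{delta_allometric_rel_mean}.
#' @export
allometric_uncertainty <- function(samples, n_reps = 10L,
                                   train_fraction = 0.8, seed = 1L) {
  stopifnot(all(c("wood", "foliage", "root") %in% names(samples)))
  if (any(vapply(samples, nrow, 1L) < 5L))
    stop("each component needs at least 5 samples")
  n_root_val <- nrow(samples$root) - round(train_fraction * nrow(samples$root))
  if (n_root_val < 10L)
    warning(sprintf("root validation split has only %d trees per repetition",
                    n_root_val))
  withr::with_seed(seed, {
    splits <- lapply(seq_len(n_reps), function(r)
      lapply(samples, function(s)
        sample(nrow(s), round(train_fraction * nrow(s)))))
  })
  reps <- lapply(seq_len(n_reps), function(r) {
    d <- mapply(split_delta, samples, splits[[r]], SIMPLIFY = FALSE)
    delta_allo <- component_quadrature(d$foliage$delta, d$wood$delta,
                                       d$root$delta)
    mu_mass <- d$wood$mu + d$foliage$mu + d$root$mu
    list(delta_w = d$wood$delta, delta_f = d$foliage$delta,
         delta_r = d$root$delta, delta_allometric_abs = delta_allo,
         mu_mass = mu_mass, delta_rel = delta_allo / mu_mass)
  })
  rel <- vapply(reps, `[[`, 1, "delta_rel")
  structure(list(
    delta_w = vapply(reps, `[[`, 1, "delta_w"),
    delta_f = vapply(reps, `[[`, 1, "delta_f"),
    delta_r = vapply(reps, `[[`, 1, "delta_r"),
    delta_allometric_abs = vapply(reps, `[[`, 1, "delta_allometric_abs"),
    mu_mass = vapply(reps, `[[`, 1, "mu_mass"),
    delta_allometric_rel_per_rep = rel,
    delta_allometric_rel_mean = mean(rel),
    n_reps = n_reps, train_fraction = train_fraction, seed = seed),
    class = "uncertainty_report")
}

#' @export
print.uncertainty_report <- function(x, ...) {
  cat(sprintf(
    "<uncertainty_report> mean relative allometric uncertainty %.1f%% over %d reps\n",
    100 * x$delta_allometric_rel_mean, x$n_reps))
  invisible(x)
}

#' Relative error in total mapped crown area
#'
#' \code{|predicted - labelled| / labelled} over pooled evaluation-plot
#' crown-area totals.
#'
#' @param labelled_total Total hand-labelled crown area (m^2), > 0.
#' @param predicted_total Total predicted crown area (m^2).
#' @return Relative error (fraction).
#' @export
crown_area_relative_error <- function(labelled_total, predicted_total) {
  stopifnot(is.numeric(labelled_total), is.numeric(predicted_total))
  if (labelled_total <= 0) stop("labelled total area must be > 0")
  abs(predicted_total - labelled_total) / labelled_total
}

#' Per-plot-mean variant of the crown-area relative error
#'
#' Averages the per-plot relative area errors instead of pooling totals; the
#' two estimators differ when plot sizes vary, and both are exposed because
#' the reference protocol does not pin one down.
#'
#' @param labelled Per-plot labelled area totals (m^2), all > 0.
#' @param predicted Per-plot predicted area totals (m^2).
#' @return Mean per-plot relative error (fraction).
#' @export
crown_area_relative_error_per_plot <- function(labelled, predicted) {
  stopifnot(length(labelled) == length(predicted))
  if (any(labelled <= 0)) stop("labelled plot areas must be > 0")
  mean(abs(predicted - labelled) / labelled)
}

#' Total carbon uncertainty
#'
#' Combines the crown-area mapping uncertainty and the mean allometric
#' uncertainty in quadrature: \code{sqrt(delta_area^2 + delta_allometric^2)}.
#' With the reference values delta_area = 3.3% and mean allometric
#' uncertainty 19.5% this gives 19.8%.
#'
#' @param delta_area Relative crown-area mapping error (fraction), >= 0.
#' @param delta_allometric Mean relative allometric uncertainty (fraction),
#'   >= 0.
#' @return Combined relative uncertainty (fraction).
#' @export
total_uncertainty <- function(delta_area, delta_allometric) {
  if (delta_area < 0 || delta_allometric < 0)
    stop("uncertainties must be non-negative")
  sqrt(delta_area^2 + delta_allometric^2)
}
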