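#' Pipeline configuration
#'
#' Collects every knob of the end-to-end synthetic run: the landscape and
#' field-sample generator configs, allometric defaults, carbon fraction,
#' density-grid cell size, evaluation-fixture rates, uncertainty repetition
#' count and the output directory. All stages derive their seeds from the
#' single \code{seed} so a config reproduces a run exactly.
#'
#' @param landscape A \code{\link{landscape_config}}.
#' @param field_samples A \code{\link{field_sample_config}}.
#' @param models Allometric models used for carbon estimation.
#' @param carbon_fraction Dry-mass carbon content, default 0.47.
#' @param cell_size Density-grid cell size (m), default 100.
#' @param eval_n_true,eval_commission,eval_omission Planted-error evaluation
#'   fixture parameters.
#' @param n_reps Uncertainty subsampling repetitions, default 10.
#' @param catalog_n Synthetic image-catalog size.
#' @param out_dir Output directory, or \code{NULL} to skip writing files.
#' @param seed Master seed.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(landscape = landscape_config(seed = seed),
                            field_samples = field_sample_config(seed = seed + 1L),
                            models = default_allometric_models(),
                            carbon_fraction = 0.47,
                            cell_size = 100,
                            eval_n_true = 1000L,
                            eval_commission = 0.049,
                            eval_omission = 0.027,
                            n_reps = 10L,
                            catalog_n = 500L,
                            out_dir = NULL,
                            seed = 1L) {
  seed <- as.integer(seed)
  structure(list(landscape = landscape, field_samples = field_samples,
                 models = models, carbon_fraction = carbon_fraction,
                 cell_size = cell_size, eval_n_true = eval_n_true,
                 eval_commission = eval_commission,
                 eval_omission = eval_omission, n_reps = n_reps,
                 catalog_n = catalog_n, out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Validate pipeline inputs
#'
#' Schema and sanity checks on crowns, rainfall field and field samples:
#' positive crown areas, crowns inside the rainfall field bounds, positive
#' masses, n >= 2 per component. Problems are reported, not thrown;
#' \code{level} separates fatal errors from warnings.
#'
#' @param crowns Crown data frame (or \code{NULL} to skip).
#' @param field A \code{rainfall_field} (or \code{NULL}).
#' @param samples Named list of field-sample data frames (or \code{NULL}).
#' @return Data frame of diagnostics (\code{level}, \code{message});
#'   zero rows when everything is valid.
#' @export
validate_inputs <- function(crowns = NULL, field = NULL, samples = NULL) {
  diag <- list()
  note <- function(level, msg)
    diag[[length(diag) + 1L]] <<- data.frame(level = level, message = msg)
  if (!is.null(crowns)) {
    bad <- which(!is.finite(crowns$crown_area_m2) | crowns$crown_area_m2 <= 0)
    if (length(bad))
      note("error", paste0("non-positive crown area for id(s): ",
                           paste(utils::head(crowns$id[bad], 5), collapse = ", ")))
    if (!is.null(field)) {
      ext <- field_extent(field)
      out <- which(crowns$x < ext["xmin"] | crowns$x > ext["xmax"] |
                   crowns$y < ext["ymin"] | crowns$y > ext["ymax"])
      if (length(out))
        note("warning", paste0(length(out),
                               " crown(s) outside the rainfall field bounds"))
    }
  }
  if (!is.null(field) && all(field$values != field$nodata))
    note("info", "rainfall raster has no nodata cells")
  if (!is.null(samples)) {
    for (comp in names(samples)) {
      s <- samples[[comp]]
      if (nrow(s) < 2L)
        note("error", paste0(comp, ": fewer than 2 samples"))
      if (any(s$mass_kg <= 0) || any(s$crown_area_m2 <= 0))
        note("error", paste0(comp, ": non-positive mass or area"))
    }
  }
  if (length(diag)) do.call(rbind, diag) else
    data.frame(level = character(), message = character())
}

#' Run the full synthetic carbon-accounting pipeline
#'
#' Executes generate -> allometry -> zonation -> aggregation -> evaluation
#' -> uncertainty -> image selection on a synthetic landscape, optionally
#' writing all products (crown GeoJSON, rainfall and density ASCII grids,
#' zone summary CSV, evaluation and uncertainty JSON, mosaic selection CSV,
#' and a machine-readable run report).
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Run report (list): per-stage record counts, carbon totals, zone
#'   summary, evaluation rates, uncertainty budget and stage timings.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  stage_time <- function(name, start)
    timings[[name]] <<- round(tic() - start, 3)

  s <- tic()
  land <- gen_landscape(config$landscape)
  crowns <- land$crowns
  stage_time("generate", s)

  s <- tic()
  if (nrow(crowns)) {
    est <- estimate_tree_carbon(crowns$crown_area_m2, config$models,
                                config$carbon_fraction,
                                config$landscape$min_crown_area)
    crowns <- cbind(crowns, est[, c("mass_w_kg", "mass_f_kg", "mass_r_kg",
                                    "mass_total_kg", "carbon_kg", "retained")])
    crowns <- crowns[crowns$retained, setdiff(names(crowns), "retained")]
  } else {
    for (cl in c("mass_w_kg", "mass_f_kg", "mass_r_kg", "mass_total_kg",
                 "carbon_kg")) crowns[[cl]] <- numeric(0)
  }
  stage_time("allometry", s)

  s <- tic()
  ext <- config$landscape$extent
  grid <- carbon_density_grid(crowns, ext, config$cell_size)
  zones_present <- zone_definition()$zone
  strip_ha <- vapply(zones_present, function(z) {
    sel <- !is.na(crowns$zone) & crowns$zone == z
    if (!any(sel)) return(NA_real_)
    # zone land area from the gradient geometry
    zd <- zone_definition(); i <- match(z, zd$zone)
    rw <- config$landscape$rainfall_west; re <- config$landscape$rainfall_east
    if (re == rw) return((ext[2] - ext[1]) * (ext[4] - ext[3]) / 1e4)
    frac <- (min(zd$upper[i], max(rw, re)) - max(zd$lower[i], min(rw, re))) /
      abs(re - rw)
    max(frac, 0) * (ext[2] - ext[1]) * (ext[4] - ext[3]) / 1e4
  }, 1)
  zsum <- zonal_summary(crowns, strip_ha[!is.na(strip_ha)])
  stage_time("aggregate", s)

  s <- tic()
  fixture <- gen_eval_fixture(config$eval_n_true, config$eval_commission,
                              config$eval_omission, seed = config$seed + 2L)
  evaluation <- evaluate_plots(fixture)
  stage_time("evaluate", s)

  s <- tic()
  samples <- gen_field_samples(config$field_samples)
  unc <- allometric_uncertainty(samples, n_reps = config$n_reps,
                                seed = config$seed + 3L)
  lab_total <- sum(vapply(fixture, function(p) sum(p$labelled$crown_area_m2), 1))
  pred_total <- sum(vapply(fixture, function(p) sum(p$predicted$crown_area_m2), 1))
  delta_area <- crown_area_relative_error(lab_total, pred_total)
  delta_total <- total_uncertainty(delta_area, unc$delta_allometric_rel_mean)
  stage_time("uncertainty", s)

  s <- tic()
  catalog <- gen_image_catalog(config$catalog_n, seed = config$seed + 4L)
  mosaic <- if (nrow(catalog)) select_mosaic(catalog) else catalog
  stage_time("select_images", s)

  report <- list(
    n_trees = nrow(crowns),
    total_carbon_kg = sum(crowns$carbon_kg),
    total_mass_kg = sum(crowns$mass_total_kg),
    carbon_fraction = config$carbon_fraction,
    zone_summary = zsum,
    evaluation = evaluation$rates[c("n_labelled", "n_predicted",
                                    "n_commissions", "n_omissions",
                                    "commission_rate", "omission_rate",
                                    "net_rate")],
    area_rmse_m2 = evaluation$area_rmse_m2,
    uncertainty = list(
      delta_allometric_rel_mean = unc$delta_allometric_rel_mean,
      delta_allometric_rel_per_rep = unc$delta_allometric_rel_per_rep,
      delta_area = delta_area,
      delta_total = delta_total),
    n_catalog = nrow(catalog),
    n_tiles_selected = nrow(mosaic),
    seed = config$seed,
    timings_s = as.list(timings))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    op <- function(f) file.path(config$out_dir, f)
    if (nrow(crowns)) write_crowns_geojson(crowns, op("crowns.geojson"))
    utils::write.csv(crowns, op("crowns.csv"), row.names = FALSE)
    write_asc(land$field, op("rainfall.asc"))
    write_asc(grid, op("carbon_density.asc"))
    utils::write.csv(zsum, op("zone_summary.csv"), row.names = FALSE)
    utils::write.csv(catalog, op("image_catalog.csv"), row.names = FALSE)
    if (nrow(catalog))
      utils::write.csv(mosaic, op("mosaic_selection.csv"), row.names = FALSE)
    # timings are log information, not results; keep the file reproducible
    jsonlite::write_json(report[setdiff(names(report),
                                        c("zone_summary", "timings_s"))],
                         op("report.json"), auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  report$elapsed_s <- round(tic() - t0, 3)
  report
}
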