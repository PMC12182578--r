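#' Run configuration
#'
#' One object holding everything a pipeline run needs: the synthetic
#' landscape configuration (or pre-built inputs), the groups to map, the
#' seeds, the hyperparameter candidate lists (defaults are the full
#' 13 x 9 protocol) and the validation toggles.
#'
#' @param landscape A [landscape_config()] describing the synthetic world.
#' @param groups Groups to map (default [POP_GROUPS]).
#' @param split_seed,model_seed Seeds for the train/test split and forests.
#' @param trees,depths Hyperparameter candidates.
#' @param filter_min_rows Minimum rows for the middle-99% filter.
#' @param do_consistency,do_coarse_validation,do_variation Validation
#'   toggles.
#' @param outdir Output directory (`NULL` = keep results in memory only).
#' @return A `run_config` list.
#' @export
run_config <- function(landscape = landscape_config(),
                       groups = POP_GROUPS,
                       split_seed = 1L, model_seed = 2L,
                       trees = RF_CANDIDATE_TREES,
                       depths = RF_CANDIDATE_DEPTHS,
                       filter_min_rows = 200,
                       do_consistency = TRUE,
                       do_coarse_validation = TRUE,
                       do_variation = TRUE,
                       outdir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

write_artifact <- function(files, obj, name, outdir, writer) {
  if (is.null(outdir)) return(files)
  path <- file.path(outdir, name)
  writer(obj, path)
  c(files, path)
}

#' Run the full downscaling pipeline
#'
#' Orchestrates every stage on a synthetic landscape: generation, the
#' inhabited mask, the training table, per-group model tuning, weighting
#' and mass-conserving allocation, the summed-ages grid and proportions,
#' and (per toggles) the consistency, coarse-source and spatial-variation
#' validations. Deterministic under the config's seeds. With `outdir` set,
#' grids are written as ESRI ASCII rasters, tables as CSV, reports as
#' JSON, plus a checksum manifest.
#'
#' @param config A [run_config()].
#' @return List with the landscape, truth, censuses, mask, models and
#'   reports, population and proportion grids, validation results and the
#'   manifest (when written).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  files <- character(0)

  land <- generate_landscape(config$landscape)
  truth <- generate_true_population(land, config$landscape)
  census <- tabulate_census(truth, land$zones, "township")
  census_county <- tabulate_census(truth, land$zones, "county")
  census_city <- tabulate_census(truth, land$zones, "city")

  mask <- compute_mask(land$stack)
  areas <- inhabited_area(mask, land$zones)
  covs <- aggregate_covariates(land$stack, land$zones, mask)
  table <- build_training_table(census, covs, areas)

  fit <- fit_density_models(table, config$groups,
                            split_seed = config$split_seed,
                            model_seed = config$model_seed,
                            trees = config$trees, depths = config$depths,
                            filter_min_rows = config$filter_min_rows)

  pop <- run_group_mappings(census, fit$models, land$stack, mask,
                            land$zones, config$groups)
  age_groups <- setdiff(config$groups, "total")
  total_sum <- sum_age_groups(pop[age_groups])
  props <- lapply(pop[age_groups], proportions,
                  total_sum_grid = total_sum)

  consistency <- NULL
  if (config$do_consistency && "total" %in% config$groups)
    consistency <- consistency_by_region(pop$total, total_sum, land$zones,
                                         level = "city")

  coarse <- NULL
  if (config$do_coarse_validation)
    coarse <- coarse_source_validation(
      census, census_county, land$stack, mask, land$zones,
      coarse_level = "county", groups = config$groups,
      split_seed = config$split_seed, model_seed = config$model_seed,
      trees = config$trees, depths = config$depths,
      filter_min_rows = config$filter_min_rows)

  variation <- NULL
  if (config$do_variation) {
    baseline <- baseline_county_share_product(pop$total, census_county,
                                              land$zones, age_groups)
    base_sum <- sum_age_groups(baseline)
    variation <- list()
    for (g in age_groups) {
      variation[[g]] <- list(
        mapped = spatial_variation(props[[g]], land$zones, "township"),
        baseline = spatial_variation(
          proportions(baseline[[g]], base_sum), land$zones, "township"))
    }
  }

  if (!is.null(outdir)) {
    wg <- function(g, p) write_grid(g, p)
    files <- write_artifact(files, pop$total, "population_total_pop.asc",
                            outdir, wg)
    files <- write_artifact(files, total_sum,
                            "population_total_pop_sum.asc", outdir, wg)
    for (g in age_groups) {
      files <- write_artifact(files, pop[[g]],
                              sprintf("population_%s.asc", g), outdir, wg)
      files <- write_artifact(files, props[[g]],
                              sprintf("prop_%s.asc", g), outdir, wg)
    }
    files <- write_artifact(files, census, "census_township.csv", outdir,
                            function(o, p) write_census(o, p))
    files <- write_artifact(files, fit$report, "model_report.json", outdir,
                            function(o, p) jsonlite::write_json(
                              o, p, dataframe = "rows", auto_unbox = TRUE,
                              digits = NA))
    if (!is.null(consistency))
      files <- write_artifact(files, consistency$by_unit,
                              "consistency_by_city.csv", outdir,
                              function(o, p) utils::write.csv(
                                o, p, row.names = FALSE))
    if (!is.null(coarse))
      files <- write_artifact(files, coarse$report,
                              "coarse_source_report.csv", outdir,
                              function(o, p) utils::write.csv(
                                o, p, row.names = FALSE))
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)))
    utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                     row.names = FALSE)
  } else manifest <- NULL

  list(config = config, landscape = land, truth = truth, census = census,
       census_county = census_county, census_city = census_city,
       mask = mask, areas = areas, training_table = table, fit = fit,
       pop = pop, total_sum = total_sum, props = props,
       consistency = consistency, coarse = coarse, variation = variation,
       manifest = manifest)
}
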