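#' Agreement metrics between estimated and actual zone counts
#'
#' R-squared, RMSE (persons) and the OLS fit of estimated (response) on
#' actual (predictor) counts — so a slope below 1 reads as underestimation
#' in more populous zones. R-squared here is that of the OLS fit (squared
#' Pearson correlation): perfectly proportional estimates score 1 even
#' when biased, and the bias is read off the slope. This differs from the
#' held-out model R-squared of [evaluate_on_test()], which penalizes bias.
#'
#' @param actual,estimated Numeric vectors of zone counts.
#' @return List with `n`, `r2`, `rmse`, `slope`, `intercept`.
#' @export
agreement_metrics <- function(actual, estimated) {
  ok <- is.finite(actual) & is.finite(estimated)
  a <- actual[ok]; e <- estimated[ok]
  fit <- stats::lm(e ~ a)
  list(n = length(a), r2 = stats::cor(a, e)^2,
       rmse = sqrt(mean((e - a)^2)),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Coarse-source validation
#'
#' Reruns the whole mapping with counts from a coarser administrative level
#' (county instead of township): densities and covariate aggregates are
#' rebuilt at the coarse level, models retuned, counts allocated over
#' coarse zones, and the resulting grids aggregated back to the fine zones
#' and compared with the fine census. Because allocation conserves mass
#' within its own source zones, fine-source mapping aggregated to fine
#' zones is exact; the coarse-source agreement is therefore a lower bound
#' on fine-source accuracy.
#'
#' @param census_fine Fine-level census table (with `a60_64`).
#' @param census_coarse Coarse-level census table (with `a60_64`).
#' @param stack Covariate stack.
#' @param mask Inhabited mask.
#' @param zones Fine-level `zone_map` (labels at the fine level; the
#'   hierarchy must contain the coarse level).
#' @param coarse_level Coarse admin level (default `"county"`).
#' @param groups Groups to validate (default [POP_GROUPS]).
#' @param split_seed,model_seed,trees,depths,filter_min_rows Passed to
#'   [fit_density_models()] for the coarse-level models.
#' @return List with `report` (per-group data.frame of agreement metrics),
#'   `scatter` (per-group actual/estimated pairs by fine zone) and
#'   `pop_grids` (the coarse-source population grids).
#' @export
coarse_source_validation <- function(census_fine, census_coarse, stack,
                                     mask, zones,
                                     coarse_level = "county",
                                     groups = POP_GROUPS,
                                     split_seed = 1L, model_seed = 2L,
                                     trees = RF_CANDIDATE_TREES,
                                     depths = RF_CANDIDATE_DEPTHS,
                                     filter_min_rows = 200) {
  zc <- coarsen_zone_map(zones, coarse_level)
  if (!all(census_coarse$zone_id %in% zc$units$zone_id))
    stop("coarse census zones absent from the hierarchy")
  areas_c <- inhabited_area(mask, zc)
  cov_c <- aggregate_covariates(stack, zc, mask)
  tab_c <- build_training_table(census_coarse, cov_c, areas_c)
  fit <- fit_density_models(tab_c, groups, split_seed = split_seed,
                            model_seed = model_seed, trees = trees,
                            depths = depths,
                            filter_min_rows = filter_min_rows)
  grids <- run_group_mappings(census_coarse, fit$models, stack, mask, zc,
                              groups)
  rows <- list(); scatter <- list()
  for (g in groups) {
    est <- zonal_aggregate(grids[[g]], zones, stat = "sum")
    act <- census_fine[[g]][match(est$zone_id, census_fine$zone_id)]
    ok <- !is.na(act) & !is.na(est$value)
    m <- agreement_metrics(act[ok], est$value[ok])
    rows[[g]] <- data.frame(group = g, n = m$n, r2 = m$r2, rmse = m$rmse,
                            slope = m$slope, intercept = m$intercept)
    scatter[[g]] <- data.frame(group = g, zone_id = est$zone_id[ok],
                               actual = act[ok], estimated = est$value[ok])
  }
  list(report = do.call(rbind, rows), scatter = do.call(rbind, scatter),
       pop_grids = grids, model_report = fit$report)
}

#' City size classes
#'
#' The five city classes by total population: small (< 0.5 million),
#' medium (0.5-1.0), large (1.0-5.0), very large (5.0-10.0) and extremely
#' large (> 10.0 million). Intervals are closed on the left: a city of
#' exactly 1.0 million is "large".
#'
#' @param totals Numeric vector of city total populations (persons).
#' @return Factor with the five class labels.
#' @export
city_size_class <- function(totals) {
  cut(totals, breaks = c(-Inf, 0.5e6, 1e6, 5e6, 10e6, Inf),
      labels = c("small", "medium", "large", "very_large",
                 "extremely_large"),
      right = FALSE)
}

#' Stratify zone-level agreement by city size
#'
#' Recomputes the agreement metrics of a coarse-source validation within
#' city size classes: each fine zone is assigned to its ancestor city,
#' cities are classed by their total population, and metrics are computed
#' per class and group.
#'
#' @param scatter `scatter` data.frame from [coarse_source_validation()].
#' @param zones The fine-level `zone_map`.
#' @param city_totals data.frame `zone_id`, `total` for cities (e.g. a
#'   city-level census table).
#' @return data.frame per (group, size class): `n` zones, `r2`, `rmse`,
#'   `slope`.
#' @export
stratify_by_city_size <- function(scatter, zones, city_totals) {
  city <- ancestor_at_level(zones, scatter$zone_id, "city")
  if (anyNA(city)) stop("some zones have no ancestor city")
  tot <- city_totals$total[match(city, city_totals$zone_id)]
  if (anyNA(tot)) stop("some cities lack a total population")
  cls <- city_size_class(tot)
  out <- list()
  for (g in unique(scatter$group)) for (k in levels(cls)) {
    sel <- scatter$group == g & cls == k
    if (sum(sel) < 3) {
      out[[paste(g, k)]] <- data.frame(group = g, size_class = k,
                                       n = sum(sel), r2 = NA_real_,
                                       rmse = NA_real_, slope = NA_real_)
      next
    }
    m <- agreement_metrics(scatter$actual[sel], scatter$estimated[sel])
    out[[paste(g, k)]] <- data.frame(group = g, size_class = k, n = m$n,
                                     r2 = m$r2, rmse = m$rmse,
                                     slope = m$slope)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Spatial variation of age-structure proportions
#'
#' For every unit at `level`, the population standard deviation (ddof = 0,
#' configurable) of the proportion grid over the unit's valid cells; units
#' with fewer than 2 valid cells are excluded. Summarized by the mean and
#' IQR across units. Works for any gridded product on the same lattice, so
#' external datasets can be compared like-for-like.
#'
#' @param prop A proportion `grid`.
#' @param zones A `zone_map`.
#' @param level Admin level defining the spatial extent.
#' @param ddof 0 (population SD, default) or 1 (sample SD).
#' @return List with `by_unit` (data.frame `zone_id`, `n_cells`, `sd`) and
#'   `summary` (`mean`, `q25`, `q75`, `n_units`).
#' @export
spatial_variation <- function(prop, zones, level = "township", ddof = 0) {
  stopifnot_coregistered(prop, zones$labels, "proportions and zones")
  ids <- zones_at_level(zones, level)
  fine <- sort(unique(as.vector(zones$labels$values)))
  fine <- fine[fine > 0]
  anc <- ancestor_at_level(zones, fine, level)
  lab <- c(0, anc)[match(zones$labels$values, c(0, fine))]
  ok <- grid_valid(prop) & lab > 0
  v <- prop$values[ok]; z <- lab[ok]
  n <- tapply(v, z, length)
  sds <- tapply(v, z, function(x) {
    m <- mean(x)
    sqrt(sum((x - m)^2) / (length(x) - ddof))
  })
  by_unit <- data.frame(zone_id = as.numeric(names(n)),
                        n_cells = as.numeric(n), sd = as.numeric(sds))
  by_unit <- by_unit[by_unit$zone_id %in% ids & by_unit$n_cells >= 2, ]
  x <- by_unit$sd
  list(by_unit = by_unit,
       summary = c(mean = mean(x),
                   q25 = stats::quantile(x, 0.25, type = 7, names = FALSE),
                   q75 = stats::quantile(x, 0.75, type = 7, names = FALSE),
                   n_units = nrow(by_unit)))
}

#' County-share baseline age-group product
#'
#' The comparison baseline: each age-group grid is the gridded total
#' multiplied by the county's census share of that group, so every cell of
#' a county carries the same age structure. Used to contrast against the
#' per-group dasymetric mapping in [spatial_variation()].
#'
#' @param total_grid Gridded total population.
#' @param census_coarse County-level census table (with `a60_64`).
#' @param zones Fine-level `zone_map` containing the county level.
#' @param groups Age groups (default the four age groups).
#' @return Named list of baseline population `grid`s.
#' @export
baseline_county_share_product <- function(total_grid, census_coarse, zones,
                                          groups = setdiff(POP_GROUPS,
                                                           "total")) {
  fine <- sort(unique(as.vector(zones$labels$values)))
  fine <- fine[fine > 0]
  anc <- ancestor_at_level(zones, fine, "county")
  lab <- c(0, anc)[match(zones$labels$values, c(0, fine))]
  denom <- Reduce(`+`, lapply(groups, function(g) census_coarse[[g]]))
  out <- lapply(groups, function(g) {
    share <- census_coarse[[g]] / denom
    sh_cell <- share[match(lab, census_coarse$zone_id)]
    v <- total_grid$values * sh_cell
    v[is.na(v) | !grid_valid(total_grid)] <- total_grid$nodata
    gg <- total_grid
    gg$values <- matrix(v, nrow(total_grid$values))
    gg
  })
  names(out) <- groups
  out
}
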